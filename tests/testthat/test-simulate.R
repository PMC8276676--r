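test_that("single conversion follows its closed form and conserves mass", {
  mod <- chain_model(x0 = 2, k = 1)
  tr <- simulate_model(mod, t_end = 5)
  t <- tr[, "time"]
  expect_equal(tr[, "Y"], 2 * (1 - exp(-t)), tolerance = 1e-6)
  expect_equal(unname(tr[, "X"] + tr[, "Y"]), rep(2, length(t)),
               tolerance = 1e-7)
})

test_that("mutual-consumption inhibition follows its closed form", {
  # dY = -k*I*Y, dI = -k*I*Y: Y - I is conserved and Y is logistic,
  # Y(t) = D / (1 - (I0/Y0) exp(-k D t)) with D = Y0 - I0
  mod <- pathway_model("toy",
    list(toy_species("I", "inhibitor", 1), toy_species("Y", "gene", 3),
         toy_species("P", "process", 0)),
    list(edge_inh("I", "Y", 1), edge_drv("Y", "P", 0.01, 1)))
  tr <- simulate_model(mod, t_end = 6)
  t <- tr[, "time"]
  expect_equal(tr[, "Y"], 2 / (1 - (1 / 3) * exp(-2 * t)), tolerance = 1e-6)
  expect_equal(unname(tr[, "Y"] - tr[, "I"]), rep(2, length(t)),
               tolerance = 1e-7)
})

test_that("a model with no edges has constant trajectories", {
  mod <- pathway_model("toy",
    list(toy_species("X", initial = 1.5),
         toy_species("P", "process", 0)),
    list(edge_act("X", "P", 1e-12)))   # negligible link for reachability
  tr <- simulate_model(mod, t_end = 4)
  expect_equal(unname(tr[, "X"]), rep(1.5, nrow(tr)), tolerance = 1e-9)
})

test_that("activation-only models conserve mass and are homogeneous", {
  mod <- pathway_model("toy",
    list(toy_species("A", initial = 3), toy_species("B", initial = 1),
         toy_species("C", initial = 0.5), toy_species("P", "process", 0)),
    list(edge_act("A", "B", 2), edge_act("B", "C", 1),
         edge_act("B", "P", 1), edge_act("C", "P", 0.5)))
  tr <- simulate_model(mod, t_end = 10, rtol = 1e-8)
  total <- rowSums(tr[, c("A", "B", "C", "P")])
  expect_lt(max(abs(total - 4.5)), 10 * 1e-8 * 4.5)
  # doubling every initial doubles every trajectory (linearity)
  mod2 <- mod
  mod2$species <- lapply(mod2$species, function(s) {
    s$initial <- 2 * s$initial; s
  })
  tr2 <- simulate_model(mod2, t_end = 10, rtol = 1e-8)
  expect_equal(unclass(tr2[, -1]), unclass(2 * tr[, -1]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("flux splitting keeps total outflow at k*[S]", {
  # two outbound activation edges with k = 1 must drain X like one edge
  mod <- pathway_model("toy",
    list(toy_species("X", initial = 2), toy_species("P1", "process", 0),
         toy_species("P2", "process", 0)),
    list(edge_act("X", "P1", 1), edge_act("X", "P2", 1)))
  tr <- simulate_model(mod, t_end = 5)
  expect_equal(tr[, "X"], 2 * exp(-tr[, "time"]), tolerance = 1e-6)
  expect_equal(tr[, "P1"], tr[, "P2"], tolerance = 1e-9)
})

test_that("zero initial state stays identically zero", {
  mod <- chain_model(x0 = 0)
  tr <- simulate_model(mod, t_end = 5)
  expect_true(all(abs(tr[, c("X", "Y")]) < 1e-12))
})

test_that("process trajectories of the shipped models are non-decreasing and non-negative", {
  for (dz in c("psoriasis", "cSCC")) {
    tr <- simulate_model(il17_model(dz))
    for (p in process_species(attr(tr, "model"))) {
      expect_true(all(diff(tr[, p]) > -1e-8), info = paste(dz, p))
    }
    expect_true(all(tr[, -1] > -1e-8), info = dz)
  }
})

test_that("peak finds the plateau value and its onset", {
  mod <- chain_model(x0 = 2, k = 2)   # Y = 2 (1 - exp(-2 t))
  tr <- simulate_model(mod, t_end = 10)
  pk <- peak(tr, "Y")
  expect_equal(pk[["value"]], 2, tolerance = 1e-4)
  # first grid time with Y >= 0.995 * max: exp(-2 t) <= 0.005 -> t >= 2.65
  expect_equal(pk[["t_peak"]], 2.7, tolerance = 0.06)
  expect_error(peak(tr, "nope"), "not in trajectory")
})

test_that("trajectories are grid-stable and reproducible", {
  tr1 <- simulate_model(il17_model("psoriasis"))
  tr2 <- simulate_model(il17_model("psoriasis"))
  expect_identical(unclass(tr1), unclass(tr2))
  # doubling the grid changes the sampled peak negligibly
  tr3 <- simulate_model(il17_model("psoriasis"), n_points = 401)
  expect_equal(max(tr3[, "autoimmune_pathology"]),
               max(tr1[, "autoimmune_pathology"]), tolerance = 1e-5)
})
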