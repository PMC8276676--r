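# ODE construction and integration for pathway models.

#' Build the ODE right-hand side of a pathway model
#'
#' Assembles the mass-action rate function implied by the model's edges
#' (see the kinetics table in [pathway_model()]). Activation edges from a
#' common source split its outflow equally so total consumption stays
#' `k*[S]`; inhibition consumes inhibitor and target alike; catalysis
#' converts substrate to product at `k*[E]*[SUB]` leaving the enzyme
#' unchanged; drive edges add `k*[S]^m` to the target without consuming
#' the source; decay removes `k*[S]`.
#'
#' @param model a `PathwayModel`.
#' @return a function `(t, state, parms)` suitable for [deSolve::ode()].
#' @export
build_odes <- function(model) {
  nm <- .model_ids(model)
  idx <- function(s) match(s, nm)
  act_src <- vapply(model$edges, function(e)
    if (e$kind == "activation") e$source else NA_character_, character(1))
  n_out <- table(act_src[!is.na(act_src)])
  terms <- lapply(model$edges, function(e) {
    k <- e$k
    switch(e$kind,
      activation = {
        s <- idx(e$source); t <- idx(e$target)
        kk <- k / as.numeric(n_out[[e$source]])
        function(x, dx) {
          f <- kk * x[s]; dx[s] <- dx[s] - f; dx[t] <- dx[t] + f; dx
        }
      },
      inhibition = {
        i <- idx(e$source); t <- idx(e$target)
        function(x, dx) {
          f <- k * x[i] * x[t]; dx[i] <- dx[i] - f; dx[t] <- dx[t] - f; dx
        }
      },
      catalysis = {
        en <- idx(e$source); s <- idx(e$substrate); t <- idx(e$target)
        function(x, dx) {
          f <- k * x[en] * x[s]; dx[s] <- dx[s] - f; dx[t] <- dx[t] + f; dx
        }
      },
      drive = {
        s <- idx(e$source); t <- idx(e$target); m <- e$m
        function(x, dx) { dx[t] <- dx[t] + k * x[s]^m; dx }
      },
      decay = {
        s <- idx(e$source)
        function(x, dx) { dx[s] <- dx[s] - k * x[s]; dx }
      })
  })
  function(t, state, parms) {
    dx <- numeric(length(state))
    for (f in terms) dx <- f(state, dx)
    list(dx)
  }
}

#' Simulate a pathway model
#'
#' Integrates the model with a stiff-capable solver (lsoda) on a uniform
#' output grid. Activation-only models conserve total mass to solver
#' accuracy; models with inhibition or decay lose mass monotonically
#' (drive edges add non-conserved output activity).
#'
#' @param model a `PathwayModel`.
#' @param t_end simulation horizon in dimensionless time units
#'   (default 10).
#' @param rtol,atol solver tolerances.
#' @param n_points output grid size (>= 200 recommended; default 201).
#' @return a `pathway_trajectory`: the deSolve output matrix (column
#'   `time` plus one column per species) with the model attached as an
#'   attribute.
#' @export
simulate_model <- function(model, t_end = 10, rtol = 1e-8, atol = 1e-10,
                           n_points = 201) {
  state <- .model_state(model)
  rhs <- build_odes(model)
  out <- deSolve::ode(y = state, times = seq(0, t_end, length.out = n_points),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    .fail("ODE integration failed for model '", model$disease, "'")
  }
  structure(out, model = model, class = c("pathway_trajectory",
                                          class(out)))
}

#' Peak (plateau) value and onset time of a trajectory
#'
#' Returns the maximum concentration over the output grid and, as
#' `t_peak`, the earliest grid time at which the trajectory is within
#' 0.5\% of that maximum. For monotone plateauing curves this is the
#' plateau onset; for genuinely peaked curves it is the argmax.
#'
#' @param trajectory a `pathway_trajectory` from [simulate_model()].
#' @param species species id.
#' @return named numeric vector `c(t_peak, value)`.
#' @export
peak <- function(trajectory, species) {
  if (!species %in% colnames(trajectory)) {
    .fail("species '", species, "' not in trajectory")
  }
  y <- trajectory[, species]
  v <- max(y)
  t_peak <- trajectory[which(y >= v * 0.995)[1], "time"]
  c(t_peak = unname(t_peak), value = unname(v))
}

#' Write a trajectory as TSV
#'
#' @param trajectory a `pathway_trajectory`.
#' @param path output path (`time` column plus one column per species).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  .write_tsv(as.data.frame(unclass(trajectory)), path)
}
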