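# Local sensitivity analysis of process outputs with respect to species
# initial values, with full normalisation and max-over-time summary.

#' Compute fully-normalised local sensitivities
#'
#' For each (output `Y`, input `X`) pair, perturbs the input's initial
#' value by a central finite difference,
#' `s(t) = [Y(t; X0(1+h)) - Y(t; X0(1-h))] / (2 h X0)`, and fully
#' normalises: `n(t) = s(t) * X0 / Y(t)`, the dimensionless
#' log-derivative `dlog Y / dlog X0`. Times where the output has not yet left
#' zero (`Y(t) <= atol`) are excluded rather than producing spurious
#' infinities. The matrix entry is `max |n(t)|` over the remaining grid;
#' an output that never leaves zero gives `NA` (flagged, not silently 0).
#'
#' Inputs with zero initial value are perturbed by the absolute step
#' `h_abs`; their fully-normalised sensitivity is 0 by construction.
#'
#' @param model a seeded `PathwayModel`.
#' @param outputs output species ids (default: all process species).
#' @param inputs input species ids (default: all gene-like species, i.e.
#'   roles gene/deg/complex/inhibitor, excluding internal fixed pools).
#' @param t_end,rtol,atol,n_points integration settings as in
#'   [simulate_model()].
#' @param h_rel relative perturbation (default 1e-3).
#' @param h_abs absolute step for zero-valued initials.
#' @return a numeric outputs x inputs matrix of class
#'   `sensitivity_matrix`, summarised by max absolute normalised
#'   sensitivity over time.
#' @examples
#' mod <- il17_model("psoriasis")
#' S <- compute_sensitivities(mod, inputs = c("MAPKs", "AP1"))
#' round(S, 2)
#' @export
compute_sensitivities <- function(model, outputs = NULL, inputs = NULL,
                                  t_end = 10, h_rel = 1e-3, h_abs = 1e-3,
                                  rtol = 1e-8, atol = 1e-10,
                                  n_points = 201) {
  if (is.null(outputs)) outputs <- process_species(model)
  if (is.null(inputs)) {
    fixed <- vapply(model$species, function(s) isTRUE(s$fixed), logical(1))
    ids <- .model_ids(model)
    roles <- vapply(model$species, `[[`, character(1), "role")
    inputs <- ids[roles != "process" & !fixed]
  }
  ids <- .model_ids(model)
  stray <- setdiff(c(outputs, inputs), ids)
  if (length(stray)) .fail("unknown species: ", paste(stray, collapse = ", "))
  base <- simulate_model(model, t_end = t_end, rtol = rtol, atol = atol,
                         n_points = n_points)
  state0 <- .model_state(model)
  S <- matrix(NA_real_, length(outputs), length(inputs),
              dimnames = list(outputs, inputs))
  resim <- function(x0) {
    m <- model
    m$species <- mapply(function(s, v) { s$initial <- v; s },
                        m$species, x0, SIMPLIFY = FALSE)
    simulate_model(m, t_end = t_end, rtol = rtol, atol = atol,
                   n_points = n_points)
  }
  for (inp in inputs) {
    X0 <- state0[[inp]]
    h <- if (X0 > 0) h_rel * X0 else h_abs
    xp <- state0; xp[inp] <- X0 + h
    xm <- state0; xm[inp] <- max(X0 - h, 0)
    hh <- xp[inp] - xm[inp]
    up <- resim(xp); um <- resim(xm)
    for (outp in outputs) {
      Y <- base[, outp]
      s <- (up[, outp] - um[, outp]) / hh
      n <- s * X0 / Y
      ok <- Y > atol & is.finite(n)
      S[outp, inp] <- if (any(ok)) max(abs(n[ok])) else NA_real_
    }
  }
  structure(S, class = c("sensitivity_matrix", "matrix"),
            t_end = t_end, h_rel = h_rel)
}

#' Classify high-sensitivity inputs
#'
#' Flags (output, input) pairs whose summarised sensitivity strictly
#' exceeds the threshold; an entry exactly at the threshold is not
#' flagged.
#'
#' @param S a `sensitivity_matrix` from [compute_sensitivities()].
#' @param threshold high-sensitivity bound (default 1.5).
#' @return list with `threshold`, `pairs` (data.frame `output`, `input`,
#'   `sensitivity`) and `inputs_flagged` (inputs high for at least one
#'   output).
#' @export
classify_high <- function(S, threshold = 1.5) {
  hit <- which(!is.na(S) & S > threshold, arr.ind = TRUE)
  pairs <- data.frame(output = rownames(S)[hit[, 1]],
                      input = colnames(S)[hit[, 2]],
                      sensitivity = S[hit],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$sensitivity, pairs$input), , drop = FALSE]
  rownames(pairs) <- NULL
  list(threshold = threshold, pairs = pairs,
       inputs_flagged = sort(unique(pairs$input)))
}

#' Long-format sensitivity report
#'
#' One row per (output, input) pair, sorted by sensitivity descending
#' with ties broken by input id, ready to write as TSV.
#'
#' @param S a `sensitivity_matrix`.
#' @param H optional [classify_high()] result; defaults to threshold 1.5.
#' @return data.frame `output`, `input`, `sensitivity`, `flagged`.
#' @export
sensitivity_report <- function(S, H = classify_high(S)) {
  out <- expand.grid(output = rownames(S), input = colnames(S),
                     stringsAsFactors = FALSE)
  out$sensitivity <- S[cbind(out$output, out$input)]
  out$flagged <- !is.na(out$sensitivity) & out$sensitivity > H$threshold
  out <- out[order(-out$sensitivity, out$input), , drop = FALSE]
  rownames(out) <- NULL
  out
}
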