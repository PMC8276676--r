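# Shared in-code fixtures for the test suite.

# tiny expression matrix with explicit values: one row per supplied gene
toy_matrix <- function(values_by_gene, groups) {
  vals <- do.call(rbind, values_by_gene)
  rownames(vals) <- names(values_by_gene)
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  ph <- stats::setNames(groups, colnames(vals))
  expression_matrix(vals, ph)
}

# minimal pathway model builders -------------------------------------------

toy_species <- function(id, role = "gene", initial = 0.5,
                        members = character(0), fixed = NULL) {
  s <- list(id = id, role = role, members = members, initial = initial)
  if (!is.null(fixed)) s$fixed <- fixed
  s
}

edge_act <- function(s, t, k = 1) {
  list(kind = "activation", source = s, target = t, k = k)
}
edge_inh <- function(s, t, k = 1) {
  list(kind = "inhibition", source = s, target = t, k = k)
}
edge_drv <- function(s, t, k = 1, m = 1) {
  list(kind = "drive", source = s, target = t, k = k, m = m)
}
edge_dec <- function(s, k = 1) list(kind = "decay", source = s, k = k)

# X -> Y single conversion, Y a process output
chain_model <- function(x0 = 2, k = 1) {
  pathway_model("toy",
    list(toy_species("X", "gene", x0),
         toy_species("Y", "process", 0)),
    list(edge_act("X", "Y", k)))
}

# exhaustive hypergeometric upper tail by enumerating all draws
enum_hyper_p <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)    # first K universe elements are the set
  mean(hits >= x)
}
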