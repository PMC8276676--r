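# Reaction-network representation of the IL-17 signalling sub-pathway.
#
# A PathwayModel is a list of role-tagged species (with initial
# concentrations in arbitrary units) and typed reaction edges. Five edge
# kinds cover the kinetics used by the shipped disease models:
#
#   activation  source -> target   mass-action conversion, flux k*[S];
#                                  when a source has several outbound
#                                  activation edges each carries k*[S]/m so
#                                  branching does not inflate outflow
#   inhibition  source -| target   second-order mutual consumption,
#                                  flux k*[I]*[T] removed from BOTH the
#                                  target and the inhibitor (stoichiometric
#                                  neutralisation, as in A20-type negative
#                                  regulation)
#   catalysis   source : substrate -> target
#                                  enzyme-mediated conversion, flux
#                                  k*[E]*[SUB]; the enzyme is unchanged
#   drive       source => target   non-consuming induction/output
#                                  accumulation, target gains k*[S]^m; the
#                                  cooperativity exponent m (1, 2 or 3)
#                                  models dimeric/oligomeric action
#   decay       source -> (sink)   first-order turnover, flux k*[S]
#
# Processes (autoimmune pathology, neutrophil recruitment, immunity to
# extracellular pathogens) are terminal outputs: they accumulate drive
# flux and have no outbound edges.

.EDGE_KINDS <- c("activation", "inhibition", "catalysis", "drive", "decay")

.CAPTION_GROUPS <- list(
  psoriasis = list(
    MAPKs = c("MAPK13", "MAPK14"),
    chemokines = c("CXCL1", "CXCL2", "CXCL5", "CXCL8", "CXCL10",
                   "CCL2", "CCL7", "CCL20"),
    antimicrobial = c("S100A7", "S100A8", "S100A9", "LCN2"),
    tissue_remodeling = c("MMP1", "MMP9"),
    C1 = c("HSP90AA1", "TRAF3IP2"),
    C2 = c("TAB2", "TAB3", "MAP3K7"),
    C3 = c("ANAPC5", "TNFAIP3"),
    AP1 = c("FOSL1", "FOS")),
  cSCC = list(
    MAPKs = c("MAPK3", "MAPK9", "MAPK10", "MAPK11", "MAPK14"),
    chemokines = c("CXCL1", "CXCL2", "CXCL8", "CCL20"),
    antimicrobial = c("DEFB4A", "DEFB4B", "S100A7", "S100A8", "S100A9",
                      "LCN2"),
    tissue_remodeling = c("MMP1", "MMP3", "MMP9", "MMP13"),
    AP1 = c("FOSL1", "JUN")))

#' Construct and validate a pathway model
#'
#' @param disease disease label (`"psoriasis"`, `"cSCC"`, or free text for
#'   toy models).
#' @param species list of species entries; each a list with `id`, `role`
#'   (one of `"gene"`, `"deg"`, `"complex"`, `"inhibitor"`, `"process"`),
#'   optional `members` (gene symbols for grouped species/complexes),
#'   `initial` (non-negative; processes must start at 0) and optional
#'   `fixed` (logical: initial is a structural constant that
#'   [apply_initial_values()] must not touch, used for activated/secreted
#'   state pools that start empty).
#' @param edges list of edge entries; each a list with `kind` (see
#'   Details), `source`, `k` (> 0) and, depending on kind, `target`,
#'   `substrate`, `m`.
#' @param check_groups check the canonical family memberships (MAPKs,
#'   chemokines, antimicrobial, tissue remodeling, complexes) for the two
#'   shipped diseases when those species are present.
#' @return a validated object of class `PathwayModel`.
#' @export
pathway_model <- function(disease, species, edges, check_groups = TRUE) {
  model <- structure(list(disease = disease, species = species,
                          edges = edges),
                     class = "PathwayModel")
  validate_pathway_model(model, check_groups = check_groups)
  model
}

#' @export
print.PathwayModel <- function(x, ...) {
  roles <- vapply(x$species, `[[`, character(1), "role")
  kinds <- vapply(x$edges, `[[`, character(1), "kind")
  cat(sprintf("PathwayModel '%s': %d species (%d processes), %d edges\n",
              x$disease, length(x$species), sum(roles == "process"),
              length(x$edges)))
  cat("edge kinds:", paste(sprintf("%s=%d", names(table(kinds)),
                                   table(kinds)), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a pathway model
#'
#' Checks the schema (roles, kinds, references, positivity), that process
#' species start at zero and have no outbound edges, that every process is
#' reachable from the rest of the network, and (for the shipped diseases)
#' the canonical family memberships.
#'
#' @param model a `PathwayModel`.
#' @param check_groups see [pathway_model()].
#' @return `model`, invisibly; errors name the offending field.
#' @export
validate_pathway_model <- function(model, check_groups = TRUE) {
  sp <- model$species
  ids <- vapply(sp, `[[`, character(1), "id")
  if (anyDuplicated(ids)) .fail("duplicate species ids")
  roles <- vapply(sp, `[[`, character(1), "role")
  bad_role <- setdiff(roles, c("gene", "deg", "complex", "inhibitor",
                               "process"))
  if (length(bad_role)) .fail("unknown species role: ", bad_role[1])
  for (s in sp) {
    if (is.null(s$initial) || s$initial < 0) {
      .fail("species '", s$id, "': initial must be a non-negative number")
    }
    if (s$role == "process" && s$initial != 0) {
      .fail("process species '", s$id, "' must have initial 0")
    }
  }
  procs <- ids[roles == "process"]
  seen <- character(0)
  for (e in model$edges) {
    if (!e$kind %in% .EDGE_KINDS) .fail("unknown edge kind: ", e$kind)
    if (is.null(e$k) || e$k <= 0) {
      .fail(e$kind, " edge from '", e$source, "': k must be > 0")
    }
    refs <- c(e$source, e$target, e$substrate)
    missing <- setdiff(refs, ids)
    if (length(missing)) {
      .fail(e$kind, " edge references unknown species '", missing[1], "'")
    }
    if (e$kind != "decay" && identical(e$source, e$target)) {
      .fail("self-loop on species '", e$source, "'")
    }
    if (e$kind == "drive" && !(e$m %in% c(1, 2, 3))) {
      .fail("drive edge to '", e$target, "': m must be 1, 2 or 3")
    }
    if (e$source %in% procs || identical(e$substrate, procs[procs %in% e$substrate])) {
      if (e$source %in% procs) {
        .fail("process '", e$source, "' cannot be an edge source")
      }
    }
    seen <- c(seen, e$source)
  }
  # reachability: every process must receive flux through some chain of
  # edges starting from a non-process species
  adj <- lapply(model$edges, function(e) {
    tgt <- e$target
    if (is.null(tgt)) return(NULL)
    src <- c(e$source, e$substrate)
    cbind(src, tgt)
  })
  adj <- do.call(rbind, adj)
  reachable <- setdiff(ids, procs)
  repeat {
    new <- unique(adj[adj[, 1] %in% reachable, 2])
    if (all(new %in% reachable)) break
    reachable <- union(reachable, new)
  }
  unreachable <- setdiff(procs, reachable)
  if (length(unreachable)) {
    .fail("process '", unreachable[1], "' is not reachable from the network")
  }
  if (isTRUE(check_groups) && model$disease %in% names(.CAPTION_GROUPS)) {
    canon <- .CAPTION_GROUPS[[model$disease]]
    for (nm in names(canon)) {
      i <- match(nm, ids)
      if (is.na(i)) next
      got <- sort(norm_symbols(sp[[i]]$members))
      if (!identical(got, sort(canon[[nm]]))) {
        .fail("species '", nm, "' in the ", model$disease,
              " model must group exactly {",
              paste(canon[[nm]], collapse = ", "), "}")
      }
    }
  }
  invisible(model)
}

#' Load a pathway model from JSON
#'
#' @param path JSON file (schema: `disease`, `species`, `edges`; see
#'   [pathway_model()]).
#' @param check_groups see [pathway_model()].
#' @return a validated `PathwayModel`.
#' @export
load_pathway_model <- function(path, check_groups = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$disease) || is.null(raw$species) || is.null(raw$edges)) {
    .fail(path, ": model JSON needs 'disease', 'species' and 'edges'")
  }
  species <- lapply(raw$species, function(s) {
    s$members <- as.character(unlist(s$members))
    s$initial <- as.numeric(s$initial)
    s
  })
  pathway_model(raw$disease, species, raw$edges,
                check_groups = check_groups)
}

#' Save a pathway model to JSON
#'
#' Writes the schema read by [load_pathway_model()]; load -> save -> load
#' is the identity.
#'
#' @param model a `PathwayModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_pathway_model <- function(model, path) {
  jsonlite::write_json(list(disease = model$disease,
                            species = model$species, edges = model$edges),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Seed a pathway model with average expression values
#'
#' Applies the initial-state rules used for the disease simulations:
#' differentially expressed species get their average log2 expression from
#' `table`; grouped species (families, complexes) get the mean of their
#' members' values, members absent from the table contributing `default`;
#' non-differential singleton genes get `default` (0.5, the midpoint of
#' the nominal 0-1 range); process species stay at zero; species marked
#' `fixed` (activated/secreted pools that must start empty) are untouched.
#'
#' @param model a `PathwayModel`.
#' @param table data.frame `gene`, `avg_expr` (e.g.
#'   [il17_avg_expression()] filtered to the model's disease), or an empty
#'   data.frame to seed every gene species at `default`.
#' @param default initial value for species without table entries.
#' @return the seeded `PathwayModel`; table rows matching no species are
#'   listed in `attr(, "unmatched")`.
#' @export
apply_initial_values <- function(model, table, default = 0.5) {
  if (!is.null(table$disease) && length(unique(table$disease)) == 1 &&
      !is.na(model$disease) && model$disease %in% names(.CAPTION_GROUPS) &&
      unique(table$disease) != model$disease) {
    .fail("table disease '", unique(table$disease),
          "' does not match model disease '", model$disease, "'")
  }
  vals <- stats::setNames(as.numeric(table$avg_expr),
                          norm_symbols(table$gene))
  used <- character(0)
  model$species <- lapply(model$species, function(s) {
    if (s$role == "process") { s$initial <- 0; return(s) }
    if (isTRUE(s$fixed)) return(s)
    id <- norm_symbols(s$id)
    if (length(s$members)) {
      mem <- norm_symbols(s$members)
      got <- vals[mem]
      got[is.na(got)] <- default
      used <<- c(used, intersect(mem, names(vals)))
      s$initial <- mean(got)
    } else if (id %in% names(vals)) {
      s$initial <- unname(vals[id])
      used <<- c(used, id)
    } else {
      s$initial <- default
    }
    s
  })
  attr(model, "unmatched") <- setdiff(names(vals), used)
  validate_pathway_model(model)
}

#' Load a shipped IL-17 disease model, seeded and ready to simulate
#'
#' Loads the psoriasis or cSCC IL-17 sub-pathway model shipped with the
#' package and applies the disease's average-expression initial values
#' (see [il17_avg_expression()] and [apply_initial_values()]).
#'
#' @param disease `"psoriasis"` or `"cSCC"`.
#' @param seeded apply the average-expression initial values (default
#'   TRUE); if FALSE the role-based defaults from the fixture are kept.
#' @return a `PathwayModel`.
#' @examples
#' mod <- il17_model("psoriasis")
#' traj <- simulate_model(mod)
#' peak(traj, "autoimmune_pathology")
#' @export
il17_model <- function(disease = c("psoriasis", "cSCC"), seeded = TRUE) {
  disease <- match.arg(disease)
  file <- c(psoriasis = "psoriasis_il17.json", cSCC = "cscc_il17.json")
  model <- load_pathway_model(system.file("extdata", file[[disease]],
                                          package = "il17path",
                                          mustWork = TRUE))
  if (seeded) {
    model <- apply_initial_values(model, il17_avg_expression(disease))
  }
  model
}

# named initial-state vector
.model_state <- function(model) {
  stats::setNames(vapply(model$species, `[[`, numeric(1), "initial"),
                  vapply(model$species, `[[`, character(1), "id"))
}

# species ids by role
.model_ids <- function(model, roles = NULL) {
  ids <- vapply(model$species, `[[`, character(1), "id")
  if (is.null(roles)) return(ids)
  ids[vapply(model$species, `[[`, character(1), "role") %in% roles]
}

#' Process species of a model
#'
#' @param model a `PathwayModel`.
#' @return character vector of process species ids.
#' @export
process_species <- function(model) .model_ids(model, "process")
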