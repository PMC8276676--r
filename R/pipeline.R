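# Pipeline driver: binds the stages into the end-to-end workflow and
# writes per-stage artifacts plus a run manifest.

#' Configure a pipeline run
#'
#' Defaults reproduce the analysis settings: stringent regime 0.005/1.0,
#' relaxed regime 0.05/0.5, enrichment alpha 0.05, simulation horizon 10
#' time units, sensitivity threshold 1.5.
#'
#' @param out_dir artifact directory (created if missing).
#' @param seed integer seed driving every synthetic stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("synth", "de", "intersect", "enrich", "common-pathway",
#'   "model-sim", "sensitivity")`.
#' @param n_genes,n_per_group,deg_fraction,effect_size,sigma synthetic
#'   data settings (two datasets per disease are generated).
#' @param enrich_alpha significance level for enrichment.
#' @param t_end simulation horizon.
#' @param sens_threshold high-sensitivity bound.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("synth", "de", "intersect", "enrich",
                                       "common-pathway", "model-sim",
                                       "sensitivity"),
                            n_genes = 400L, n_per_group = 5L,
                            deg_fraction = 0.08, effect_size = 2,
                            sigma = 0.5, enrich_alpha = 0.05, t_end = 10,
                            sens_threshold = 1.5) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_genes = n_genes, n_per_group = n_per_group,
                 deg_fraction = deg_fraction, effect_size = effect_size,
                 sigma = sigma, enrich_alpha = enrich_alpha, t_end = t_end,
                 sens_threshold = sens_threshold),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in workflow order on self-contained
#' synthetic datasets: data generation, differential expression per
#' contrast, cross-dataset DEG intersection, gene-set enrichment, the
#' common significant pathway, seeding and simulation of the shipped
#' IL-17 disease models, and their sensitivity analysis. Every stage
#' writes TSV/JSON artifacts into `config$out_dir`; a manifest (JSON)
#' records the configuration, seed and an md5 checksum for every output
#' file. Reruns with the same configuration are bit-identical for the
#' deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  results <- list()
  written <- character(0)
  emit <- function(df, name) {
    p <- outfile(name)
    .write_tsv(df, p)
    written <<- c(written, p)
    p
  }
  log_stage <- function(...) message("[il17path] ", sprintf(...))

  diseases <- c("psoriasis", "cSCC")
  datasets <- list()
  if ("synth" %in% config$stages) {
    for (i in 1:2) for (dz in diseases) {
      id <- sprintf("%s_ds%d", dz, i)
      sp <- synth_spec(config$n_genes,
                       stats::setNames(c(config$n_per_group,
                                         config$n_per_group),
                                       c("lesional", "normal")),
                       deg_fraction = config$deg_fraction,
                       effect_size = config$effect_size,
                       sigma = config$sigma,
                       seed = .substream_seed(config$seed,
                                              10L * i + match(dz, diseases)))
      d <- generate_microarray(sp)
      # plant the differential signal in IL-17 member genes so the
      # enrichment stage can recover the pathway from the demo data
      syms <- il17_avg_expression(dz)$gene
      planted <- which(d$truth$is_deg)
      k <- min(length(planted), length(syms))
      if (k > 0) {
        rn <- rownames(d$matrix$values)
        sel <- planted[seq_len(k)]
        rn[match(d$truth$gene[sel], rn)] <- syms[seq_len(k)]
        rownames(d$matrix$values) <- rn
        d$truth$gene[sel] <- syms[seq_len(k)]
      }
      datasets[[id]] <- d
      write_expression_tsv(d$matrix, outfile(id, "_expr.tsv"),
                           outfile(id, "_phenotype.tsv"))
      written <- c(written, outfile(id, "_expr.tsv"),
                   outfile(id, "_phenotype.tsv"))
      emit(d$truth, paste0(id, "_truth.tsv"))
    }
    log_stage("synth: %d datasets x %d genes", length(datasets),
              config$n_genes)
    results$datasets <- datasets
  }

  de_results <- list()
  if ("de" %in% config$stages && length(datasets)) {
    ct <- contrast_spec("lesional", "normal", "stringent")
    for (id in names(datasets)) {
      res <- run_de(datasets[[id]]$matrix, ct)
      de_results[[id]] <- res
      emit(res, paste0(id, "_de.tsv"))
      emit(volcano_table(res), paste0(id, "_volcano.tsv"))
      log_stage("de: %s: %d genes in, %d DEGs out", id, nrow(res),
                sum(res$is_deg))
    }
    results$de <- de_results
  }

  deg_sets <- lapply(de_results, call_degs)
  if ("intersect" %in% config$stages && length(deg_sets) >= 2) {
    for (dz in diseases) {
      ids <- grep(dz, names(deg_sets), value = TRUE)
      if (length(ids) >= 2) {
        common <- intersect_degs(deg_sets[ids])
        emit(data.frame(gene = common), paste0(dz, "_common_degs.tsv"))
        log_stage("intersect: %s: %d common DEGs", dz, length(common))
        results$common_degs[[dz]] <- common
      }
    }
  }

  enr <- list()
  if ("enrich" %in% config$stages && length(deg_sets)) {
    gmt <- read_gmt(system.file("extdata", "il17_sets.gmt",
                                package = "il17path", mustWork = TRUE))
    for (id in names(deg_sets)) {
      universe <- rownames(datasets[[id]]$matrix$values)
      # toy collections reference the synthetic gene space plus the IL-17
      # member symbols; restrict DEGs/universe join to measured genes
      res <- enrich(deg_sets[[id]], universe, gmt,
                    alpha = config$enrich_alpha)
      enr[[id]] <- res
      emit(res, paste0(id, "_enrichment.tsv"))
      log_stage("enrich: %s: %d/%d pathways significant", id,
                sum(res$significant), nrow(res))
    }
    results$enrichment <- enr
  }

  if ("common-pathway" %in% config$stages && length(enr) >= 2) {
    common <- common_significant_pathways(enr)
    emit(data.frame(pathway = common), "common_pathways.tsv")
    log_stage("common-pathway: %d pathway(s) shared", length(common))
    results$common_pathways <- common
  }

  if ("model-sim" %in% config$stages) {
    for (dz in diseases) {
      mod <- il17_model(dz)
      traj <- simulate_model(mod, t_end = config$t_end)
      write_trajectory(traj, outfile(dz, "_trajectory.tsv"))
      written <- c(written, outfile(dz, "_trajectory.tsv"))
      pk <- peak(traj, process_species(mod)[1])
      log_stage("model-sim: %s peak %.2f at t=%.2f", dz, pk["value"],
                pk["t_peak"])
      results$trajectories[[dz]] <- traj
    }
  }

  if ("sensitivity" %in% config$stages) {
    for (dz in diseases) {
      mod <- il17_model(dz)
      S <- compute_sensitivities(mod, t_end = config$t_end)
      H <- classify_high(S, threshold = config$sens_threshold)
      emit(sensitivity_report(S, H), paste0(dz, "_sensitivity.tsv"))
      log_stage("sensitivity: %s: flagged %s", dz,
                paste(H$inputs_flagged, collapse = ", "))
      results$sensitivity[[dz]] <- list(S = S, high = H)
    }
  }

  manifest <- list(
    package = "il17path",
    version = as.character(utils::packageVersion("il17path")),
    seed = config$seed,
    stages = config$stages,
    config = unclass(config),
    files = lapply(stats::setNames(nm = basename(written)), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))))
  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifest <- manifest_path
  invisible(results)
}
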