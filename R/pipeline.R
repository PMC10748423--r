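#' Assemble and validate a pipeline run configuration
#'
#' A run configuration either points at real input files (`paths`) or
#' requests synthetic data (`synthetic`). Thresholds default to the
#' analysis constants used throughout: significance cutoff `alpha = 0.05`
#' (strict), multi-screen overlap at `min_screens = 2`, `top_k = 100`
#' aggregated candidates as the custom gene set, and GSEA with 1000
#' permutations, weighting exponent 1 and an FDR acceptance threshold of
#' 0.25.
#'
#' @param config a named list, or path to a YAML file holding one.
#'   Recognized keys: `synthetic` (list of [synthetic_config()] arguments)
#'   or `paths` (list with `space`, `screens` — a list of per-screen
#'   `path`/`screen_id`/`measure_column`/`gene_column` entries — and
#'   optionally `drivers`, `gene_sets`, `targets`, `de_table`); `alpha`;
#'   `min_screens`; `top_k`; `gsea` (list with `n_perm`, `p_exp`,
#'   `fdr_threshold`); `seed`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(alpha = 0.05, min_screens = 2, top_k = 100,
                   gsea = list(n_perm = 1000, p_exp = 1,
                               fdr_threshold = 0.25),
                   seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$gsea)) {
    if (is.null(config$gsea[[nm]])) config$gsea[[nm]] <- defaults$gsea[[nm]]
  }
  if (is.null(config$paths) && is.null(config$synthetic)) {
    config$synthetic <- list()
  }
  stopifnot(config$alpha > 0, config$alpha <= 1,
            config$min_screens >= 1, config$top_k >= 1,
            config$gsea$n_perm >= 1, config$gsea$fdr_threshold > 0)
  structure(config, class = "run_config")
}

#' Run the full screen meta-analysis pipeline
#'
#' Orchestrates the end-to-end analysis: load or simulate the inputs,
#' build one base ranker per screen, compute the cross-screen overlap and
#' the geometric-mean aggregated ranking, extract the candidate list and
#' its top-k gene set, run overrepresentation and novelty analyses, and —
#' when an expression table or the synthetic expression layer is available
#' — the preranked GSEA stage. All stage outputs are written to `outdir`
#' as TSV/GMT/JSON, together with the resolved configuration, and a
#' machine-readable summary is returned. Re-running with the same
#' configuration and seed reproduces all outputs.
#'
#' @param config a `run_config`, a list coercible to one, or a YAML path.
#' @param outdir output directory (created if needed).
#' @return invisibly, the run summary list: per-stage counts
#'   (`n_candidates_aggregated`, `n_overlap_candidates`,
#'   `n_known_targets`, `n_novel`), GSEA results, output paths and seed.
#' @export
run_pipeline <- function(config, outdir = tempfile("screenra_run")) {
  config <- run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  synthetic <- !is.null(config$synthetic)
  if (synthetic) {
    syn_args <- config$synthetic
    syn_args$seed <- config$seed
    cfg <- stage("simulate", do.call(synthetic_config, syn_args))
    sim <- stage("simulate", simulate_screens(cfg))
    space <- sim$space
    screens <- sim$screens
    drivers <- sim$truth$drivers
    gene_sets <- stage("simulate",
                       simulate_annotations(space, seed = config$seed + 1))
    targets <- stage("simulate",
                     simulate_target_list(space, seed = config$seed + 2))
  } else {
    p <- config$paths
    space <- stage("load", load_gene_space(p$space))
    screens <- stage("load", lapply(p$screens, function(s) {
      do.call(load_screen_table, s)
    }))
    drivers <- if (!is.null(p$drivers)) {
      harmonize_symbol(readLines(p$drivers, warn = FALSE))
    } else character()
    gene_sets <- if (!is.null(p$gene_sets)) read_gmt(p$gene_sets) else NULL
    targets <- if (!is.null(p$targets)) {
      harmonize_symbol(readLines(p$targets, warn = FALSE))
    } else character()
  }

  # --- base rankers -------------------------------------------------------
  rankers <- stage("rank", lapply(screens, build_base_ranker,
                                  alpha = config$alpha))
  for (rk in rankers) {
    utils::write.table(as.data.frame(rk),
                       file.path(outdir,
                                 paste0("ranker_", rk$screen_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- overlap ------------------------------------------------------------
  overlap <- stage("overlap", compute_overlap(rankers))
  overlap_candidates <- stage("overlap",
    select_multi_screen_candidates(overlap,
                                   min_count = config$min_screens,
                                   drivers = drivers))
  write_overlap_table(overlap, rankers,
                      file.path(outdir, "overlap_table.tsv"))
  writeLines(overlap_candidates,
             file.path(outdir, "overlap_candidates.txt"))

  # --- aggregation --------------------------------------------------------
  agg <- stage("aggregate", aggregate_geometric(rankers, space))
  candidates <- aggregated_candidates(agg)
  write_aggregated_list(candidates, rankers,
                        file.path(outdir, "aggregated_candidates.tsv"))
  k_top <- min(config$top_k, nrow(candidates))
  top_set <- stage("aggregate", select_top_k(candidates, k_top))
  write_gmt(top_set, file.path(outdir, "top_gene_set.gmt"))

  # --- enrichment + novelty ----------------------------------------------
  ora <- NULL
  if (!is.null(gene_sets)) {
    ora <- stage("enrich",
                 hypergeometric_enrichment(candidates$gene, gene_sets,
                                           space))
    utils::write.table(ora, file.path(outdir, "ora_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  novelty <- stage("enrich", annotate_novelty(candidates$gene, targets))
  writeLines(novelty$known, file.path(outdir, "known_targets.txt"))
  writeLines(novelty$novel, file.path(outdir, "novel_candidates.txt"))

  # --- GSEA ---------------------------------------------------------------
  gsea_res <- NULL
  de <- NULL
  if (synthetic) {
    expr <- stage("gsea", simulate_expression(cfg,
                                              shift_genes =
                                                sim$truth$positives,
                                              seed = config$seed + 3))
    de <- stage("gsea", simple_de(expr$expression, expr$labels))
  } else if (!is.null(config$paths$de_table)) {
    de <- stage("gsea", utils::read.table(config$paths$de_table,
                                          header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE))
  }
  if (!is.null(de)) {
    metric <- stage("gsea", rank_metric(de))
    utils::write.table(de, file.path(outdir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gsea_res <- stage("gsea",
                      gsea_preranked(metric, top_set,
                                     n_perm = config$gsea$n_perm,
                                     seed = config$seed + 4,
                                     p_exp = config$gsea$p_exp))
    utils::write.table(gsea_res, file.path(outdir, "gsea_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- summary ------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    n_space = length(space),
    n_screens = length(screens),
    per_screen_k = stats::setNames(vapply(rankers, `[[`, integer(1), "k"),
                                   vapply(rankers, `[[`, character(1),
                                          "screen_id")),
    n_candidates_aggregated = nrow(candidates),
    n_overlap_candidates = length(overlap_candidates),
    n_known_targets = length(novelty$known),
    n_novel = length(novelty$novel),
    top_k = k_top,
    gsea = if (!is.null(gsea_res)) {
      lapply(seq_len(nrow(gsea_res)), function(i) {
        as.list(gsea_res[i, c("gene_set_name", "set_size", "es", "nes",
                              "nominal_p", "fdr_q")])
      })
    },
    outputs = list(dir = outdir),
    version = as.character(utils::packageVersion("screenra")))
  resolved <- unclass(config)
  yaml::write_yaml(resolved, file.path(outdir, "resolved_config.yaml"))
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
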