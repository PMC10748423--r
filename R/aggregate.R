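#' Aggregate base rankers over a gene space
#'
#' Combines the per-screen base rankers into one aggregated ranking by
#' Borda-style scoring: each gene's aggregate score is a mean of its ranks
#' across screens, and the aggregated list is ordered ascending by score
#' (lower = stronger selection). The default and reference method is the
#' geometric mean, `exp(mean(log rank))`, computed in log space.
#'
#' Missing-data rule: screens that did not test a gene contribute nothing to
#' its score — the mean runs over testing screens only. "Not tested" (no
#' rank) is a different state from "tested but not significant" (rank
#' `k + 1`); imputing a space-sized rank for untested genes would crush
#' candidates from small-coverage screens. An imputation variant
#' (`impute_untested = TRUE`, untested rank = space size + 1) is provided
#' for sensitivity analysis.
#'
#' Genes tested by at least one screen but absent from the gene space are
#' excluded from the output, with a message reporting the count. Score ties
#' are broken by `n_identified` descending, then `n_tested` descending,
#' then symbol, so corroborated genes come first and output is
#' deterministic.
#'
#' @param rankers list of `base_ranker` objects.
#' @param space a `gene_space` (the underlying universe).
#' @param method aggregation mean: `"geometric"` (default), `"arithmetic"`,
#'   `"median"`, or `"l2"` (quadratic mean).
#' @param impute_untested if `TRUE`, screens that did not test a gene
#'   contribute rank `length(space) + 1` instead of being skipped.
#' @return an `aggregated_list`: data frame with columns `gene`,
#'   `aggregate_score`, `n_tested`, `n_identified`, `ever_significant`,
#'   sorted ascending by score, with attribute `method_tag`.
#' @export
aggregate_ranks <- function(rankers, space,
                            method = c("geometric", "arithmetic",
                                       "median", "l2"),
                            impute_untested = FALSE) {
  method <- match.arg(method)
  if (!length(rankers)) stop("no base rankers supplied", call. = FALSE)
  stopifnot(all(vapply(rankers, inherits, logical(1), "base_ranker")))
  space <- harmonize_symbol(as.character(space))
  tested_any <- unique(unlist(lapply(rankers, `[[`, "tested")))
  stray <- setdiff(tested_any, space)
  if (length(stray)) {
    message("aggregate_ranks: ", length(stray),
            " tested gene(s) absent from the gene space; excluded")
  }
  genes <- sort(intersect(tested_any, space))
  if (!length(genes)) {
    stop("no tested gene lies in the gene space", call. = FALSE)
  }

  rmat <- matrix(NA_real_, nrow = length(genes), ncol = length(rankers),
                 dimnames = list(genes, NULL))
  identified <- matrix(FALSE, nrow = length(genes), ncol = length(rankers))
  for (j in seq_along(rankers)) {
    rk <- rankers[[j]]
    idx <- match(names(rk$ranks), genes)
    keep <- !is.na(idx)
    rmat[idx[keep], j] <- rk$ranks[keep]
    identified[idx[keep], j] <- rk$ranks[keep] <= rk$k
  }
  n_tested <- rowSums(!is.na(rmat))
  n_identified <- rowSums(identified)
  if (impute_untested) {
    rmat[is.na(rmat)] <- length(space) + 1
  }

  score <- switch(method,
    geometric  = exp(rowMeans(log(rmat), na.rm = TRUE)),
    arithmetic = rowMeans(rmat, na.rm = TRUE),
    median     = apply(rmat, 1L, stats::median, na.rm = TRUE),
    l2         = sqrt(rowMeans(rmat^2, na.rm = TRUE))
  )

  ord <- order(score, -n_identified, -n_tested, genes)
  out <- data.frame(gene = genes[ord],
                    aggregate_score = unname(score[ord]),
                    n_tested = as.integer(n_tested[ord]),
                    n_identified = as.integer(n_identified[ord]),
                    ever_significant = n_identified[ord] > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method_tag = method,
            class = c("aggregated_list", "data.frame"))
}

#' Geometric-mean Borda aggregation
#'
#' The package's reference aggregation: [aggregate_ranks()] with
#' `method = "geometric"`.
#'
#' @inheritParams aggregate_ranks
#' @return an `aggregated_list` (see [aggregate_ranks()]).
#' @export
aggregate_geometric <- function(rankers, space, impute_untested = FALSE) {
  aggregate_ranks(rankers, space, method = "geometric",
                  impute_untested = impute_untested)
}

#' Restrict an aggregated list to candidate genes
#'
#' The exported candidate list keeps only genes significant in at least one
#' screen; genes whose only evidence is `k + 1` ranks everywhere stay in the
#' full aggregated list but are not candidates.
#'
#' @param agg an `aggregated_list`.
#' @return the `aggregated_list` subset to `ever_significant` genes.
#' @export
aggregated_candidates <- function(agg) {
  stopifnot(inherits(agg, "aggregated_list"))
  out <- agg[agg$ever_significant, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, method_tag = attr(agg, "method_tag"),
            class = class(agg))
}

#' Take the strongest k genes as a named gene set
#'
#' Extracts the first `k_top` genes of an aggregated list (e.g. the top 100
#' aggregated candidates) as a single-set [gene_set_collection], for use as
#' a custom gene set in enrichment analysis.
#'
#' @param agg an `aggregated_list` (typically [aggregated_candidates()]
#'   output).
#' @param k_top number of genes to take; must not exceed the list length.
#' @param set_name name of the resulting gene set.
#' @return a `gene_set_collection` with one set of `k_top` genes.
#' @export
select_top_k <- function(agg, k_top = 100,
                         set_name = "T cell infiltration") {
  stopifnot(inherits(agg, "aggregated_list"))
  if (k_top < 1 || k_top > nrow(agg)) {
    stop("k_top must be between 1 and ", nrow(agg), call. = FALSE)
  }
  sets <- stats::setNames(list(agg$gene[seq_len(k_top)]), set_name)
  new_gene_set_collection(sets)
}

#' Write an aggregated list with per-screen ranks
#'
#' @param agg an `aggregated_list`.
#' @param rankers the `base_ranker` list it was aggregated from.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_aggregated_list <- function(agg, rankers, path) {
  stopifnot(inherits(agg, "aggregated_list"))
  per_screen <- lapply(rankers, function(rk) {
    rk$ranks[match(agg$gene, names(rk$ranks))]
  })
  names(per_screen) <- paste0("rank.",
                              vapply(rankers, `[[`, character(1),
                                     "screen_id"))
  out <- cbind(data.frame(rank_position = seq_len(nrow(agg)),
                          gene = agg$gene,
                          aggregate_score = agg$aggregate_score,
                          n_tested = agg$n_tested,
                          n_identified = agg$n_identified),
               as.data.frame(per_screen, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
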