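#' Cross-screen overlap table
#'
#' For every gene tested by at least one screen, counts how many screens
#' tested it (`n_tested`), how many identified it as a significant candidate
#' (`n_identified`, i.e. its rank is at most `k` in that screen), and the
#' percentage of testing screens that identified it. Genes tested by no
#' screen do not appear.
#'
#' @param rankers list of `base_ranker` objects (one per screen).
#' @return an `overlap_table`: data frame with columns `gene`,
#'   `n_identified`, `n_tested`, `pct_identified` (percent on 0-100, full
#'   precision; round for display), ordered by gene symbol.
#' @export
compute_overlap <- function(rankers) {
  if (!length(rankers)) stop("no base rankers supplied", call. = FALSE)
  stopifnot(all(vapply(rankers, inherits, logical(1), "base_ranker")))
  genes <- sort(unique(unlist(lapply(rankers, `[[`, "tested"))))
  n_tested <- integer(length(genes))
  n_identified <- integer(length(genes))
  names(n_tested) <- names(n_identified) <- genes
  for (rk in rankers) {
    n_tested[rk$tested] <- n_tested[rk$tested] + 1L
    hits <- names(rk$ranks)[rk$ranks <= rk$k]
    n_identified[hits] <- n_identified[hits] + 1L
  }
  structure(data.frame(gene = genes,
                       n_identified = unname(n_identified),
                       n_tested = unname(n_tested),
                       pct_identified = 100 * unname(n_identified) /
                         unname(n_tested),
                       stringsAsFactors = FALSE),
            class = c("overlap_table", "data.frame"))
}

#' Select genes identified by multiple screens
#'
#' Filters the overlap table to genes identified in at least `min_count`
#' screens, removes driver genes via [filter_driver_genes()], and orders the
#' result by strength of corroboration (`n_identified` descending, percent
#' descending, symbol).
#'
#' @param table an `overlap_table` from [compute_overlap()].
#' @param min_count minimum number of identifying screens (default 2,
#'   "identified in two or more independent screens").
#' @param drivers character vector of driver genes to exclude (default
#'   none).
#' @return character vector of selected genes.
#' @export
select_multi_screen_candidates <- function(table, min_count = 2,
                                           drivers = character()) {
  stopifnot(inherits(table, "overlap_table"), min_count >= 1)
  hits <- table[table$n_identified >= min_count, , drop = FALSE]
  hits <- hits[order(-hits$n_identified, -hits$pct_identified, hits$gene), ,
               drop = FALSE]
  filter_driver_genes(hits$gene, drivers)
}

#' Write the overlap table with per-screen ranks
#'
#' Exports the overlap table in supplementary-table style: one row per gene
#' with its rank in each screen (`"NA"` when the screen did not test the
#' gene, the literal `"k+1"` when tested but not significant, the numeric
#' rank otherwise), followed by the identification count, tested count and
#' rounded percentage.
#'
#' @param table an `overlap_table`.
#' @param rankers the list of `base_ranker` objects the table was built
#'   from.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(table, rankers, path) {
  stopifnot(inherits(table, "overlap_table"))
  per_screen <- lapply(rankers, function(rk) {
    col <- rep("NA", nrow(table))
    idx <- match(table$gene, names(rk$ranks))
    tested <- !is.na(idx)
    r <- rk$ranks[idx[tested]]
    col[tested] <- ifelse(r <= rk$k, as.character(r), "k+1")
    col
  })
  names(per_screen) <- vapply(rankers, `[[`, character(1), "screen_id")
  out <- cbind(data.frame(gene = table$gene, stringsAsFactors = FALSE),
               as.data.frame(per_screen, check.names = FALSE),
               data.frame(n_identified = table$n_identified,
                          n_tested = table$n_tested,
                          pct_identified = round(table$pct_identified)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
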