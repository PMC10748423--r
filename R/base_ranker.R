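#' Build a base ranker from a screen result
#'
#' Converts one screen's significance table into the base-ranker
#' representation used for aggregation: genes whose significance measure is
#' strictly below `alpha` are ranked `1..k` in ascending order of the
#' measure, and every other tested gene — non-significant or
#' tested-but-unmeasured — receives rank `k + 1`. Genes the screen did not
#' test carry no rank at all (they are `NA` with respect to this screen).
#'
#' Ties in the measure are broken by larger effect size when the screen
#' carries an effect column, then by harmonized symbol order, so ranking is
#' deterministic.
#'
#' @param screen a `screen_result`.
#' @param alpha significance threshold; a gene is significant iff its
#'   measure is strictly less than `alpha`. Default 0.05.
#' @return a `base_ranker`: list with `screen_id`, `k` (number of
#'   significant genes), `ranks` (named integer vector over all tested
#'   genes; significant genes hold a permutation of `1..k`, the rest `k+1`),
#'   `tested`, and `alpha`.
#' @export
build_base_ranker <- function(screen, alpha = 0.05) {
  stopifnot(inherits(screen, "screen_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be a single value in (0, 1]", call. = FALSE)
  }
  m <- screen$measures
  genes <- names(m)
  sig <- !is.na(m) & m < alpha
  k <- sum(sig)
  ranks <- rep.int(k + 1L, length(genes))
  names(ranks) <- genes
  if (k > 0L) {
    sig_genes <- genes[sig]
    eff <- if (!is.null(screen$effects)) {
      e <- screen$effects[sig_genes]
      e[is.na(e)] <- 0
      e
    } else {
      rep.int(0, k)
    }
    ord <- order(m[sig_genes], -eff, sig_genes)
    ranks[sig_genes[ord]] <- seq_len(k)
  }
  structure(list(screen_id = screen$screen_id,
                 k = as.integer(k),
                 ranks = stats::setNames(as.integer(ranks), genes),
                 tested = genes,
                 alpha = alpha),
            class = "base_ranker")
}

#' @export
print.base_ranker <- function(x, ...) {
  cat("base_ranker '", x$screen_id, "': ", length(x$tested),
      " tested, k = ", x$k, " significant (alpha = ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Serialize a base ranker to a data frame
#'
#' @param x a `base_ranker`.
#' @param ... unused.
#' @return data frame with columns `gene`, `rank`, `significant`,
#'   `screen_id`, one row per tested gene, ordered by rank then symbol.
#' @export
as.data.frame.base_ranker <- function(x, ...) {
  df <- data.frame(gene = names(x$ranks),
                   rank = unname(x$ranks),
                   significant = unname(x$ranks <= x$k),
                   screen_id = x$screen_id,
                   stringsAsFactors = FALSE)
  df[order(df$rank, df$gene), , drop = FALSE]
}

#' Remove driver genes from a candidate list
#'
#' Drops genes known to drive T-cell malignancy (or any other exclusion
#' list) from a candidate collection, preserving the input order of the
#' survivors. The number removed is reported via `message()`.
#'
#' @param genes character vector of candidate genes (harmonized).
#' @param drivers character vector of genes to exclude (harmonized).
#' @return `genes` with all members of `drivers` removed, order preserved.
#' @export
filter_driver_genes <- function(genes, drivers) {
  keep <- !(genes %in% drivers)
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message("filter_driver_genes: removed ", n_removed, " driver gene(s)")
  }
  out <- genes[keep]
  if (length(genes) && !length(out)) {
    warning("all candidate genes were driver-filtered", call. = FALSE)
  }
  out
}
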