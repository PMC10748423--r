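#' Build the ranking metric for preranked GSEA
#'
#' Computes the per-gene ranking score
#' `-log10(adjusted p) * average log2 fold-change` from a differential
#' expression table and returns genes sorted by descending score. Adjusted
#' p-values of exactly zero are clamped to `1e-300` before the logarithm so
#' the metric stays finite. Score ties are broken by symbol so the hit
#' order — on which the enrichment score can depend — is fixed.
#'
#' @param de_table data frame with columns `gene`, `adjusted_p` (in
#'   \[0,1\]) and `avg_log2FC`.
#' @return a `ranked_metric`: data frame `gene`, `score`, sorted descending
#'   by score.
#' @export
rank_metric <- function(de_table) {
  need <- c("gene", "adjusted_p", "avg_log2FC")
  missing_cols <- setdiff(need, names(de_table))
  if (length(missing_cols)) {
    stop("DE table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  p <- de_table$adjusted_p
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("adjusted_p must lie in [0,1]", call. = FALSE)
  }
  p <- pmax(p, 1e-300)
  genes <- harmonize_symbol(de_table$gene)
  if (anyDuplicated(genes)) stop("duplicate genes in DE table", call. = FALSE)
  score <- -log10(p) * de_table$avg_log2FC
  ord <- order(-score, genes)
  structure(data.frame(gene = genes[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_metric", "data.frame"))
}

#' Weighted running-sum enrichment score
#'
#' The preranked GSEA statistic: walking down the ranked metric, the
#' running sum increases by `|score|^p_exp / sum(|score at hits|^p_exp)` at
#' each gene-set member ("hit") and decreases by `1 / (N - n_hits)` at each
#' non-member. The enrichment score (ES) is the maximum-magnitude deviation
#' of the running sum from zero; the sum itself starts and ends at zero.
#' `p_exp = 1` is the classic weighted statistic; `p_exp = 0` reduces to
#' the unweighted Kolmogorov-Smirnov form.
#'
#' If all hit scores are exactly zero the hit increments fall back to equal
#' weights (the `p_exp = 0` form) so the statistic remains defined.
#'
#' @param metric a `ranked_metric`.
#' @param gene_set character vector of member genes.
#' @param p_exp weighting exponent (default 1).
#' @return list with elements `es` (in \[-1,1\]) and `running_sum` (numeric
#'   vector of length `nrow(metric)`).
#' @export
enrichment_score <- function(metric, gene_set, p_exp = 1) {
  stopifnot(inherits(metric, "ranked_metric"))
  hits <- metric$gene %in% harmonize_symbol(gene_set)
  if (!any(hits)) {
    stop("gene set not represented in the ranked metric", call. = FALSE)
  }
  if (all(hits)) {
    stop("gene set covers the whole ranked metric", call. = FALSE)
  }
  es_running(metric$score, which(hits), p_exp)
}

# Core running-sum computation on a score vector already sorted descending.
# hit_idx: integer positions of the gene set within the ranking.
es_running <- function(scores, hit_idx, p_exp) {
  N <- length(scores)
  nh <- length(hit_idx)
  w <- numeric(N)
  hw <- abs(scores[hit_idx])^p_exp
  if (sum(hw) == 0) hw <- rep.int(1, nh)
  w[hit_idx] <- hw / sum(hw)
  miss <- rep.int(1 / (N - nh), N)
  miss[hit_idx] <- 0
  running <- cumsum(w - miss)
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running)
}

# ES only, for permutation nulls (avoids building the full profile list).
es_only <- function(scores, hit_idx, p_exp) {
  es_running(scores, hit_idx, p_exp)$es
}

#' Preranked GSEA with a gene-label permutation null
#'
#' Computes the weighted enrichment score of each gene set against the
#' ranked metric and assesses it against a null of random gene sets of the
#' same size (gene-label permutation — the only permutation scheme
#' available for preranked input). For each set:
#'
#' * `nominal_p` is the add-one-smoothed fraction of same-sign null ES
#'   whose magnitude reaches the observed one:
#'   `(1 + #same-sign null |ES*| >= |ES|) / (1 + #same-sign null)`.
#' * `nes` is `es / mean(|same-sign null ES|)` (0 with a warning when no
#'   null shares the sign).
#' * `fdr_q` is the Benjamini-Hochberg adjustment of the nominal p-values
#'   across the evaluated sets; a single-set run therefore reports
#'   `fdr_q == nominal_p`. (This deliberately replaces the NES-histogram
#'   FDR of the desktop GSEA tool, which needs a large set collection.)
#'
#' With `exhaustive = TRUE` the null enumerates every same-size gene set
#' (all `choose(N, m)` of them) instead of sampling; feasible only for tiny
#' instances and capped at 100,000 combinations.
#'
#' Results are deterministic given `seed`.
#'
#' @param metric a `ranked_metric`.
#' @param sets a `gene_set_collection`.
#' @param n_perm number of null permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @param p_exp weighting exponent passed to [enrichment_score()].
#' @param exhaustive enumerate the complete same-size null instead of
#'   sampling.
#' @return data frame with one row per set: `gene_set_name`, `set_size`,
#'   `es`, `nes`, `nominal_p`, `fdr_q`, `n_same_sign` (size of the
#'   same-sign null used in the denominator), `n_permutations`, `seed`;
#'   running sums are attached as attribute `running_sums` (named list).
#' @export
gsea_preranked <- function(metric, sets, n_perm = 1000, seed = 1,
                           p_exp = 1, exhaustive = FALSE) {
  stopifnot(inherits(metric, "ranked_metric"),
            inherits(sets, "gene_set_collection"),
            n_perm >= 1)
  N <- nrow(metric)
  set.seed(as.integer(seed))
  rows <- vector("list", length(sets))
  profiles <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    members <- sets[[i]]
    hit_idx <- which(metric$gene %in% members)
    if (!length(hit_idx)) {
      stop("gene set '", names(sets)[i],
           "' not represented in the ranked metric", call. = FALSE)
    }
    if (length(hit_idx) >= N) {
      stop("gene set '", names(sets)[i],
           "' is at least as large as the ranked metric", call. = FALSE)
    }
    m <- length(hit_idx)
    obs <- es_running(metric$score, hit_idx, p_exp)

    if (exhaustive) {
      n_comb <- choose(N, m)
      if (n_comb > 1e5) {
        stop("exhaustive null too large (", n_comb, " combinations)",
             call. = FALSE)
      }
      combs <- utils::combn(N, m)
      null_es <- apply(combs, 2L, es_only, scores = metric$score,
                       p_exp = p_exp)
      n_null <- ncol(combs)
    } else {
      null_es <- vapply(seq_len(n_perm), function(b) {
        es_only(metric$score, sort(sample.int(N, m)), p_exp)
      }, numeric(1))
      n_null <- n_perm
    }

    same_sign <- if (obs$es >= 0) null_es >= 0 else null_es < 0
    n_same <- sum(same_sign)
    extreme <- sum(same_sign & abs(null_es) >= abs(obs$es))
    nominal_p <- (1 + extreme) / (1 + n_same)
    if (n_same > 0L) {
      nes <- obs$es / mean(abs(null_es[same_sign]))
    } else {
      warning("no same-sign null ES for set '", names(sets)[i],
              "'; NES set to 0", call. = FALSE)
      nes <- 0
    }
    rows[[i]] <- data.frame(gene_set_name = names(sets)[i],
                            set_size = m,
                            es = obs$es, nes = nes,
                            nominal_p = nominal_p,
                            n_same_sign = n_same,
                            n_permutations = n_null,
                            seed = as.integer(seed),
                            stringsAsFactors = FALSE)
    profiles[[i]] <- obs$running_sum
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$nominal_p, method = "BH")
  out <- out[, c("gene_set_name", "set_size", "es", "nes", "nominal_p",
                 "fdr_q", "n_same_sign", "n_permutations", "seed")]
  names(profiles) <- names(sets)
  attr(out, "running_sums") <- profiles
  out
}

#' Minimal two-group differential expression
#'
#' A deliberately simple per-gene two-group comparison used to make the
#' synthetic GSEA stage self-contained: a two-sided Wilcoxon rank-sum test
#' per gene with Benjamini-Hochberg adjustment, and
#' `avg_log2FC = log2((mean1 + eps) / (mean2 + eps))` on the expression
#' scale, group 1 being the first level of `labels`. It is not intended to
#' reproduce any single-cell DE tool's output.
#'
#' @param expression numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns.
#' @param labels factor or character vector of length `ncol(expression)`
#'   with exactly two levels; each group needs at least two samples.
#' @param eps pseudo-value guarding the fold-change ratio (default
#'   `1e-9`).
#' @return data frame `gene`, `p_value`, `adjusted_p`, `avg_log2FC`, one
#'   row per gene in input order.
#' @export
simple_de <- function(expression, labels, eps = 1e-9) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must define exactly two groups", call. = FALSE)
  }
  if (length(labels) != ncol(expression)) {
    stop("labels length must match the number of samples", call. = FALSE)
  }
  g1 <- labels == levels(labels)[1L]
  g2 <- !g1
  if (sum(g1) < 2L || sum(g2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  p <- apply(expression, 1L, function(x) {
    suppressWarnings(stats::wilcox.test(x[g1], x[g2])$p.value)
  })
  m1 <- rowMeans(expression[, g1, drop = FALSE])
  m2 <- rowMeans(expression[, g2, drop = FALSE])
  data.frame(gene = rownames(expression),
             p_value = unname(p),
             adjusted_p = unname(stats::p.adjust(p, method = "BH")),
             avg_log2FC = unname(log2((m1 + eps) / (m2 + eps))),
             stringsAsFactors = FALSE)
}
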