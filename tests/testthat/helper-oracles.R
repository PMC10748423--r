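# Shared fixtures and independent oracles for the test suite.
# Oracles here deliberately use the most direct (brute-force) formulation
# of each quantity, independent of the package's code paths.

# A random screen_result: n genes, runif measures, a fraction of them
# unmeasured (tested-only).
rand_screen <- function(n, screen_id = "s1", frac_na = 0.1) {
  genes <- sprintf("RG%04d", sample.int(9999, n))
  m <- stats::runif(n)
  m[stats::runif(n) < frac_na] <- NA
  new_screen_result(screen_id, "p", stats::setNames(m, genes))
}

# A panel of screens over a shared symbol universe, with per-screen random
# coverage, suitable for overlap/aggregation tests.
rand_panel <- function(n_genes, n_screens, frac_na = 0) {
  genes <- sprintf("PG%03d", seq_len(n_genes))
  screens <- lapply(seq_len(n_screens), function(s) {
    tested <- sort(sample(genes, sample(seq(2, n_genes), 1)))
    m <- stats::runif(length(tested))
    if (frac_na > 0) m[stats::runif(length(m)) < frac_na] <- NA
    new_screen_result(sprintf("s%d", s), "p", stats::setNames(m, tested))
  })
  list(genes = genes, screens = screens)
}

# Brute-force per-gene aggregation score from a list of base rankers.
oracle_agg_score <- function(rankers, gene, method = "geometric") {
  r <- unlist(lapply(rankers, function(rk) rk$ranks[gene]))
  r <- r[!is.na(r)]
  switch(method,
         geometric = exp(mean(log(r))),
         arithmetic = mean(r),
         median = stats::median(r),
         l2 = sqrt(mean(r^2)))
}

# Direct (unweighted) Kolmogorov-Smirnov style enrichment score: maximum
# magnitude difference between the hit and miss empirical step functions.
oracle_ks_es <- function(n, hit_idx) {
  hit_cdf <- cumsum(seq_len(n) %in% hit_idx) / length(hit_idx)
  miss_cdf <- cumsum(!(seq_len(n) %in% hit_idx)) / (n - length(hit_idx))
  d <- hit_cdf - miss_cdf
  d[which.max(abs(d))]
}

# Direct weighted running-sum ES, written as an explicit position loop so
# it shares nothing with the vectorized implementation.
oracle_weighted_es <- function(scores, hit_idx, p_exp) {
  n <- length(scores)
  nr <- sum(abs(scores[hit_idx])^p_exp)
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_idx) {
      acc <- acc + abs(scores[i])^p_exp / nr
    } else {
      acc <- acc - 1 / (n - length(hit_idx))
    }
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# Exhaustive hypergeometric upper tail by enumerating every candidate draw:
# background 1..bg, term = {1..K}, candidates of size n, observed overlap q.
oracle_hyper_tail <- function(bg, K, n, q) {
  draws <- utils::combn(bg, n)
  mean(colSums(draws <= K) >= q)
}

# Build a single-term collection + background objects for ORA calls.
ora_fixture <- function(bg, K, n, q) {
  genes <- sprintf("H%02d", seq_len(bg))
  term <- genes[seq_len(K)]
  stopifnot(q <= min(K, n), n - q <= bg - K)
  cand <- c(genes[seq_len(q)], rev(genes)[seq_len(n - q)])
  list(background = genes,
       collection = new_gene_set_collection(list(T1 = term)),
       candidates = cand)
}

# A ranked metric with the given descending scores and generic gene names.
make_metric <- function(scores, genes = sprintf("M%03d", seq_along(scores))) {
  rank_metric(data.frame(gene = genes, adjusted_p = 0.1,
                         avg_log2FC = scores / -log10(0.1)))
}
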