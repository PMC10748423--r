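test_that("ranking metric computes -log10(p) * log2FC and sorts", {
  de <- data.frame(gene = c("A", "B", "C"),
                   adjusted_p = c(0.01, 1, 0.1),
                   avg_log2FC = c(2, 3, -1))
  m <- rank_metric(de)
  sc <- stats::setNames(m$score, m$gene)
  expect_equal(unname(sc["A"]), 4)
  expect_equal(unname(sc["B"]), 0)
  expect_equal(unname(sc["C"]), -1)
  expect_identical(m$gene, c("A", "B", "C"))  # descending score
  expect_true(!is.unsorted(rev(m$score)))

  # p = 0 is clamped, keeping the metric finite
  m0 <- rank_metric(data.frame(gene = "Z", adjusted_p = 0,
                               avg_log2FC = 1))
  expect_true(is.finite(m0$score))
  expect_equal(m0$score, 300)

  expect_error(rank_metric(data.frame(gene = "A", adjusted_p = 0.1)),
               "lacks column")
  # ties in score are broken by symbol for a fixed hit order
  mt <- rank_metric(data.frame(gene = c("B", "A"), adjusted_p = 0.1,
                               avg_log2FC = 1))
  expect_identical(mt$gene, c("A", "B"))
})

test_that("a set containing only the top-ranked gene scores ES = 1", {
  m <- make_metric(c(5, 4, 3, 2, 1))
  es <- enrichment_score(m, m$gene[1])
  expect_equal(es$es, 1)
  expect_equal(es$running_sum[1], 1)
  expect_equal(es$running_sum[length(es$running_sum)], 0)
})

test_that("p_exp = 0 reduces to the classic KS statistic", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    m <- make_metric(sort(stats::rnorm(n), decreasing = TRUE))
    hit_idx <- sort(sample(n, sample(2:(n - 2), 1)))
    es <- enrichment_score(m, m$gene[hit_idx], p_exp = 0)
    expect_equal(es$es, oracle_ks_es(n, hit_idx), tolerance = 1e-12)
    # invariance under strictly monotone transform of the scores
    m2 <- make_metric(rank(-seq_len(n)) * 10 + 1)
    es2 <- enrichment_score(m2, m2$gene[hit_idx], p_exp = 0)
    expect_equal(es2$es, es$es, tolerance = 1e-12)
  }
})

test_that("weighted running sum matches a position-by-position oracle", {
  # 6-gene list, 2-gene set at positions 2 and 5, p_exp = 1:
  # hit weights 2/2.25 and 0.25/2.25, miss decrement 1/4
  m <- make_metric(c(3, 2, 1, 0.5, 0.25, 0.1))
  es <- enrichment_score(m, m$gene[c(2, 5)], p_exp = 1)
  expect_equal(es$running_sum,
               c(-1 / 4,
                 -1 / 4 + 2 / 2.25,
                 -2 / 4 + 2 / 2.25,
                 -3 / 4 + 2 / 2.25,
                 -3 / 4 + 2.25 / 2.25,
                 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2 / 2.25 - 1 / 4, tolerance = 1e-12)

  set.seed(62)
  for (rep in 1:15) {
    n <- sample(6:30, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    mm <- make_metric(scores)
    hit_idx <- sort(sample(n, sample(2:4, 1)))
    p_exp <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(mm, mm$gene[hit_idx], p_exp = p_exp)
    expect_equal(es$es, oracle_weighted_es(scores, hit_idx, p_exp),
                 tolerance = 1e-12)
    expect_equal(es$running_sum[n], 0, tolerance = 1e-12)
    expect_true(abs(es$es) <= 1 + 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(63)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    m <- make_metric(scores)
    hit_idx <- sort(sample(n, 6))
    out <- enrichment_score(m, m$gene[hit_idx], p_exp = 1)
    if (abs(max(out$running_sum) + min(out$running_sum)) < 1e-12) {
      next  # exact two-sided tie: ES sign is a convention choice
    }
    ref <- fgsea::calcGseaStat(scores, selectedStats = hit_idx,
                               gseaParam = 1)
    expect_equal(out$es, ref, tolerance = 1e-8)
  }
})

test_that("empty or full set intersections are rejected", {
  m <- make_metric(c(3, 2, 1))
  expect_error(enrichment_score(m, "ABSENT"), "not represented")
  expect_error(enrichment_score(m, m$gene), "whole")
})

test_that("preranked GSEA is deterministic and p is minimum at the top", {
  m <- make_metric(seq(40, 1) / 4)
  sets <- new_gene_set_collection(list(TOPSET = m$gene[1:5]))
  r1 <- gsea_preranked(m, sets, n_perm = 100, seed = 99)
  r2 <- gsea_preranked(m, sets, n_perm = 100, seed = 99)
  expect_identical(r1, r2)

  # set occupying the top positions: ES = 1 exactly and the nominal p is
  # the smallest value the same-sign add-one rule can produce for the run
  expect_equal(r1$es, 1)
  expect_equal(r1$nominal_p, 1 / (1 + r1$n_same_sign))
  expect_equal(r1$fdr_q, r1$nominal_p)  # single set: BH is the identity
  expect_equal(sign(r1$nes), sign(r1$es))
})

test_that("exhaustive null p matches complete enumeration on 6 genes", {
  scores <- c(2.5, 1.5, 0.9, 0.5, -0.3, -1.2)
  m <- make_metric(scores)
  sets <- new_gene_set_collection(list(S = m$gene[c(1, 3)]))
  res <- gsea_preranked(m, sets, seed = 1, exhaustive = TRUE)
  expect_equal(res$n_permutations, 15L)

  null_es <- apply(utils::combn(6, 2), 2L, function(idx) {
    oracle_weighted_es(scores, idx, p_exp = 1)
  })
  obs <- oracle_weighted_es(scores, c(1, 3), p_exp = 1)
  same <- if (obs >= 0) null_es >= 0 else null_es < 0
  p_oracle <- (1 + sum(same & abs(null_es) >= abs(obs))) / (1 + sum(same))
  expect_equal(res$nominal_p, p_oracle, tolerance = 1e-12)
  expect_equal(res$nes, obs / mean(abs(null_es[same])), tolerance = 1e-12)
})

test_that("simple DE: symmetry, closed-form fold change, exact rank-sum p", {
  # both groups hold the same values (permuted columns) -> zero fold change
  x <- matrix(rep(c(1, 3, 1, 3), each = 2), nrow = 2,
              dimnames = list(c("g1", "g2"), NULL))
  de <- simple_de(x, c("a", "a", "b", "b"))
  expect_equal(de$avg_log2FC, c(0, 0))

  # group-1 mean double group-2 mean, eps negligible -> log2FC = 1
  y <- matrix(c(4, 4, 4, 2, 2, 2), nrow = 1,
              dimnames = list("g", NULL))
  de2 <- simple_de(y, c("a", "a", "a", "b", "b", "b"), eps = 1e-12)
  expect_equal(de2$avg_log2FC, 1, tolerance = 1e-9)

  # rank-sum p against exact enumeration of all C(6,3) label splits
  set.seed(64)
  for (rep in 1:5) {
    vals <- sample(100, 6)  # tie-free
    z <- matrix(vals, nrow = 1, dimnames = list("g", NULL))
    labs <- rep(c("a", "b"), each = 3)
    p_pkg <- simple_de(z, labs)$p_value
    splits <- utils::combn(6, 3)
    w_obs <- sum(rank(vals)[1:3]) - 6  # Mann-Whitney U of group a
    w_all <- apply(splits, 2L, function(idx) sum(rank(vals)[idx]) - 6)
    p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    expect_equal(p_pkg, p_exact, tolerance = 1e-12)
  }

  expect_error(simple_de(x, c("a", "a", "a", "a")), "two groups")
  expect_error(simple_de(x[, 1:2, drop = FALSE], c("a", "b")),
               "at least 2")
})
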