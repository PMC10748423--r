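small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_genes = 200, n_screens = 3,
                   coverage = c(0.1, 0.5, 1), n_true = 10, n_drivers = 5,
                   seed = seed,
                   expression = list(n_per_group = 6, delta = 2,
                                     sigma = 0.5, set_size = 20,
                                     baseline_mu = 5), ...)
}

test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_true = 5000), "n_true")
  expect_error(synthetic_config(beta_a = 0), "beta_a")
  expect_error(synthetic_config(detect_prob = 2), "detect_prob")
  expect_error(synthetic_config(coverage = c(0.5, 1)), "coverage")
  expect_error(synthetic_config(expression = list(n_per_group = 1)),
               "n_per_group")
})

test_that("screen simulation is a pure function of the seed", {
  a <- simulate_screens(small_cfg(seed = 5))
  b <- simulate_screens(small_cfg(seed = 5))
  expect_identical(a$truth$positives, b$truth$positives)
  for (i in seq_along(a$screens)) {
    expect_identical(a$screens[[i]]$measures, b$screens[[i]]$measures)
  }
  c_ <- simulate_screens(small_cfg(seed = 6))
  expect_false(identical(a$screens[[3]]$measures,
                         c_$screens[[3]]$measures))
})

test_that("coverage masks and generated screens obey the invariants", {
  sim <- simulate_screens(small_cfg(seed = 7))
  expect_length(sim$space, 200L)
  expect_length(sim$screens, 3L)
  # coverage = 1 screen tests everything
  expect_setequal(sim$screens[[3]]$tested, as.character(sim$space))
  expect_length(sim$screens[[1]]$tested, 20L)
  expect_true(all(sim$truth$positives %in% as.character(sim$space)))
  expect_false(any(sim$truth$drivers %in% sim$truth$positives))
  for (i in seq_along(sim$screens)) {
    scr <- sim$screens[[i]]
    expect_true(all(scr$measures >= 0 & scr$measures <= 1))
    expect_setequal(scr$tested,
                    names(which(sim$truth$tested[[scr$screen_id]])))
    # alternative draws only happen for tested positives
    alt <- sim$truth$alternative[[scr$screen_id]]
    expect_true(all(names(which(alt)) %in% sim$truth$positives))
    # and the screen passes the base-ranker law
    rk <- build_base_ranker(scr)
    expect_identical(sort(unname(rk$ranks[rk$ranks <= rk$k])),
                     seq_len(rk$k))
  }
})

test_that("a flat alternative (beta_a = 1) leaves positives unranked", {
  # with beta_a = 1 the "alternative" is Uniform(0,1): positives are
  # statistically indistinguishable from nulls, so their normalized
  # positions in the aggregated list should be uniform
  set.seed(70)
  pos_frac <- c()
  for (s in 1:50) {
    cfg <- synthetic_config(n_genes = 120, n_screens = 3,
                            coverage = c(0.25, 0.5, 1), n_true = 6,
                            beta_a = 1, detect_prob = 0.6, n_drivers = 0,
                            seed = 7000 + s)
    sim <- simulate_screens(cfg)
    rks <- lapply(sim$screens, build_base_ranker)
    agg <- suppressMessages(aggregate_geometric(rks, sim$space))
    pos <- match(sim$truth$positives, agg$gene)
    pos_frac <- c(pos_frac, (pos - 0.5) / nrow(agg))
  }
  ks <- suppressWarnings(stats::ks.test(pos_frac, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression simulation plants the requested shift", {
  cfg <- synthetic_config(n_genes = 300, seed = 8,
                          expression = list(n_per_group = 20, delta = 2,
                                            sigma = 0.5, set_size = 40,
                                            baseline_mu = 5))
  ex <- simulate_expression(cfg)
  expect_identical(dim(ex$expression), c(300L, 40L))
  expect_equal(table(ex$labels)[["tumor"]], 20L)
  expect_length(ex$planted_set, 40L)

  de <- simple_de(ex$expression, ex$labels)
  planted_fc <- de$avg_log2FC[de$gene %in% ex$planted_set]
  expect_lt(abs(mean(planted_fc) - 2), 0.3)

  ex2 <- simulate_expression(cfg)
  expect_identical(ex$expression, ex2$expression)

  # explicit shift genes are honored
  ex3 <- simulate_expression(cfg, shift_genes = c("G000001", "G000002"))
  expect_identical(ex3$planted_set, c("G000001", "G000002"))
  expect_error(simulate_expression(cfg, shift_genes = "NOPE"),
               "outside the synthetic gene space")
})

test_that("null expression (delta = 0) yields uniform rank-sum p-values", {
  # with 10 samples per group the rank-sum test is exact and its p-value
  # discrete, so the uniformity check maps each p through the exact
  # Wilcoxon null with a randomized PIT (exactly uniform under the null)
  # before applying the KS test
  m <- 10
  u_support <- 0:(m * m)
  probs <- stats::dwilcox(u_support, m, m)
  p_of_u <- vapply(u_support, function(u) {
    if (u > m * m / 2) {
      min(1, 2 * (1 - stats::pwilcox(u - 1, m, m)))
    } else if (u < m * m / 2) {
      min(1, 2 * stats::pwilcox(u, m, m))
    } else 1
  }, numeric(1))
  p_levels <- sort(unique(p_of_u))
  mass <- vapply(p_levels, function(pk) sum(probs[p_of_u == pk]),
                 numeric(1))
  cum_below <- cumsum(c(0, mass[-length(mass)]))

  ps_all <- c()
  for (s in 1:4) {
    cfg <- synthetic_config(n_genes = 250, seed = 800 + s,
                            expression = list(n_per_group = m, delta = 0,
                                              sigma = 0.5, set_size = 10,
                                              baseline_mu = 5))
    ex <- simulate_expression(cfg)
    ps_all <- c(ps_all, simple_de(ex$expression, ex$labels)$p_value)
  }
  k <- vapply(ps_all, function(p) which.min(abs(p_levels - p)), integer(1))
  expect_true(all(abs(p_levels[k] - ps_all) < 1e-9))  # p's match the null
  set.seed(801)
  pit <- cum_below[k] + stats::runif(length(k)) * mass[k]
  ks <- stats::ks.test(pit, "punif")
  expect_gt(ks$p.value, 0.01)
  n <- length(ps_all)
  expect_gte(sum(ps_all < 0.05), stats::qbinom(0.005, n, 0.05))
  expect_lte(sum(ps_all < 0.05), stats::qbinom(0.995, n, 0.05))
})

test_that("annotation and target simulation are seeded and bounded", {
  space <- sprintf("G%06d", 1:150)
  col <- simulate_annotations(space, n_terms = 12, size_range = c(5, 30),
                              seed = 9)
  expect_length(col, 12L)
  expect_true(all(lengths(col) >= 5 & lengths(col) <= 30))
  expect_true(all(unlist(col) %in% space))
  col2 <- simulate_annotations(space, n_terms = 12, size_range = c(5, 30),
                               seed = 9)
  expect_identical(unclass(col)[], unclass(col2)[])
  expect_error(simulate_annotations(space, size_range = c(10, 500)),
               "size_range")

  # enrichment weighting pulls the listed genes into the first term
  planted <- space[1:20]
  hits <- vapply(1:30, function(s) {
    cc <- simulate_annotations(space, n_terms = 1, size_range = c(30, 30),
                               seed = s, enrich_genes = planted,
                               enrich_odds = 20)
    length(intersect(cc[[1]], planted))
  }, numeric(1))
  expect_gt(mean(hits), 30 * 20 / 150)  # far above the uniform expectation

  t1 <- simulate_target_list(space, n_targets = 25, seed = 10)
  t2 <- simulate_target_list(space, n_targets = 25, seed = 10)
  expect_identical(t1, t2)
  expect_length(t1, 25L)
})
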