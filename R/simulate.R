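#' Configuration for synthetic screen data
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults describe the benchmark condition used throughout the
#' package's validation: a 2,000-gene space interrogated by six screens of
#' widely heterogeneous coverage (from 25 genes, 1.25% of the space, up to
#' the whole space — mirroring the spread from focused in vivo libraries to
#' genome-wide screens), 30 planted true positives whose p-values are drawn
#' from the skewed-small alternative `Beta(beta_a, 1)` with per-screen
#' detection probability `detect_prob`, uniform p-values for everything
#' else, and a two-group expression layer in which a chosen gene set is
#' mean-shifted in log2 space.
#'
#' `detect_prob < 1` models between-screen heterogeneity: a true regulator
#' can be a hit in one screening technology and indistinguishable from null
#' in another, which is why most real candidates are identified by a single
#' screen only.
#'
#' @param n_genes size of the synthetic gene space.
#' @param n_screens number of screens.
#' @param coverage numeric vector of per-screen coverage fractions in
#'   (0, 1], length `n_screens` (values > 1 are interpreted as explicit
#'   gene counts).
#' @param n_true number of planted true positives.
#' @param beta_a shape of the `Beta(beta_a, 1)` alternative, in (0, 1];
#'   smaller = more strongly skewed toward 0.
#' @param detect_prob probability that a tested true positive draws from
#'   the alternative rather than the null, in \[0, 1\].
#' @param n_drivers number of synthetic driver genes (sampled among
#'   non-positives) for the overlap driver filter.
#' @param seed integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param expression list of expression-layer parameters: `n_per_group`
#'   (samples per group), `delta` (planted mean shift, log2 units),
#'   `sigma` (within-group standard deviation, log2 units), `set_size`
#'   (planted gene-set size), `baseline_mu` (mean baseline log2
#'   expression).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_screens = 6,
                             coverage = c(0.0125, 0.05, 0.1, 0.5, 1, 1),
                             n_true = 30,
                             beta_a = 0.1,
                             detect_prob = 0.6,
                             n_drivers = 20,
                             seed = 1,
                             expression = list(n_per_group = 20,
                                               delta = 2,
                                               sigma = 0.5,
                                               set_size = 100,
                                               baseline_mu = 5)) {
  cfg <- list(n_genes = n_genes, n_screens = n_screens,
              coverage = coverage, n_true = n_true, beta_a = beta_a,
              detect_prob = detect_prob, n_drivers = n_drivers,
              seed = seed, expression = expression)
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid synthetic_config field '", field, "': ", why,
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_genes) && cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(is.numeric(cfg$n_screens) && cfg$n_screens >= 1, "n_screens",
      "must be >= 1")
  chk(length(cfg$coverage) == cfg$n_screens, "coverage",
      "must have one entry per screen")
  cov_frac <- ifelse(cfg$coverage > 1, cfg$coverage / cfg$n_genes,
                     cfg$coverage)
  chk(all(cov_frac > 0 & cov_frac <= 1), "coverage",
      "fractions must lie in (0, 1]")
  chk(cfg$n_true >= 0 && cfg$n_true <= cfg$n_genes, "n_true",
      "must lie in [0, n_genes]")
  chk(cfg$beta_a > 0 && cfg$beta_a <= 1, "beta_a", "must lie in (0, 1]")
  chk(cfg$detect_prob >= 0 && cfg$detect_prob <= 1, "detect_prob",
      "must lie in [0, 1]")
  chk(cfg$n_drivers >= 0 && cfg$n_drivers <= cfg$n_genes, "n_drivers",
      "must lie in [0, n_genes]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  ex <- cfg$expression
  chk(is.list(ex), "expression", "must be a list")
  ex_defaults <- list(n_per_group = 20, delta = 2, sigma = 0.5,
                      set_size = 100, baseline_mu = 5)
  for (nm in names(ex_defaults)) {
    if (is.null(ex[[nm]])) ex[[nm]] <- ex_defaults[[nm]]
  }
  chk(ex$n_per_group >= 2, "expression$n_per_group", "must be >= 2")
  chk(ex$sigma > 0, "expression$sigma", "must be > 0")
  chk(ex$set_size >= 1 && ex$set_size <= cfg$n_genes,
      "expression$set_size", "must lie in [1, n_genes]")
  cfg$expression <- ex
  cfg$coverage_n <- as.integer(pmax(1, round(ifelse(cfg$coverage > 1,
                                                    cfg$coverage,
                                                    cfg$coverage *
                                                      cfg$n_genes))))
  structure(cfg, class = "synthetic_config")
}

# Synthetic symbols: G000001, G000002, ...
synthetic_symbols <- function(n) {
  sprintf("G%06d", seq_len(n))
}

#' Simulate a panel of genetic screens with planted ground truth
#'
#' Generates a synthetic gene space, one screen per coverage entry, and the
#' accompanying truth record. Each screen tests a seeded random subset of
#' its coverage size (screens with coverage 1 test everything). A tested
#' true positive draws its p-value from `Beta(beta_a, 1)` with probability
#' `detect_prob` and from `Uniform(0, 1)` otherwise; every other tested
#' gene draws from `Uniform(0, 1)`. Output is fully reproducible from the
#' configuration seed.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `space` (a `gene_space`), `screens` (list of
#'   `screen_result`), and `truth` (a `synthetic_truth`: `positives`,
#'   `drivers`, per-screen logical `tested` masks over the space, and
#'   per-screen `alternative` draw flags).
#' @export
simulate_screens <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(as.integer(config$seed))
  symbols <- synthetic_symbols(config$n_genes)
  space <- as_gene_space(symbols)
  positives <- sort(sample(symbols, config$n_true))
  non_positive <- setdiff(symbols, positives)
  drivers <- sort(sample(non_positive, min(config$n_drivers,
                                           length(non_positive))))

  screens <- vector("list", config$n_screens)
  tested_masks <- vector("list", config$n_screens)
  alt_flags <- vector("list", config$n_screens)
  for (s in seq_len(config$n_screens)) {
    n_cov <- config$coverage_n[s]
    tested <- if (n_cov >= config$n_genes) symbols else
      sort(sample(symbols, n_cov))
    is_pos <- tested %in% positives
    alt <- is_pos & (stats::runif(length(tested)) < config$detect_prob)
    p <- stats::runif(length(tested))
    if (any(alt)) {
      p[alt] <- stats::rbeta(sum(alt), config$beta_a, 1)
    }
    screens[[s]] <- new_screen_result(
      screen_id = sprintf("screen%d", s),
      measure_name = "p",
      measures = stats::setNames(p, tested))
    mask <- stats::setNames(symbols %in% tested, symbols)
    tested_masks[[s]] <- mask
    alt_flags[[s]] <- stats::setNames(alt, tested)
  }
  names(tested_masks) <- names(alt_flags) <-
    vapply(screens, `[[`, character(1), "screen_id")
  truth <- structure(list(positives = positives,
                          drivers = drivers,
                          tested = tested_masks,
                          alternative = alt_flags),
                     class = "synthetic_truth")
  list(space = space, screens = screens, truth = truth)
}

#' Simulate a two-group expression matrix with a mean-shifted gene set
#'
#' Emulates a tumor-infiltrating versus peripheral comparison: per-gene
#' baseline log2 expression is drawn around `baseline_mu`, within-group
#' values are normal with standard deviation `sigma` in log2 space, and
#' the planted gene set's group-1 (tumor) mean is shifted by `delta` log2
#' units. The returned matrix is on the count-like scale `2^x`, so the
#' planted genes' expected log2 fold-change (group 1 over group 2) is
#' `delta`.
#'
#' @param config a `synthetic_config` (fields under `expression`).
#' @param shift_genes optional character vector naming the genes to shift;
#'   defaults to a seeded random sample of `expression$set_size` genes.
#' @param seed seed for this generator; defaults to `config$seed`.
#' @return list with `expression` (genes x samples numeric matrix),
#'   `labels` (factor, levels `tumor`, `peripheral`), and `planted_set`
#'   (character vector of shifted genes).
#' @export
simulate_expression <- function(config, shift_genes = NULL,
                                seed = config$seed) {
  config <- validate_synthetic_config(config)
  ex <- config$expression
  set.seed(as.integer(seed))
  symbols <- synthetic_symbols(config$n_genes)
  if (is.null(shift_genes)) {
    shift_genes <- sort(sample(symbols, ex$set_size))
  } else {
    shift_genes <- harmonize_symbol(shift_genes)
    if (!all(shift_genes %in% symbols)) {
      stop("shift_genes outside the synthetic gene space", call. = FALSE)
    }
  }
  n <- ex$n_per_group
  labels <- factor(rep(c("tumor", "peripheral"), each = n),
                   levels = c("tumor", "peripheral"))
  base_mu <- stats::rnorm(config$n_genes, mean = ex$baseline_mu, sd = 1)
  log2x <- matrix(stats::rnorm(config$n_genes * 2 * n,
                               mean = base_mu, sd = ex$sigma),
                  nrow = config$n_genes, ncol = 2 * n)
  shift_idx <- match(shift_genes, symbols)
  log2x[shift_idx, labels == "tumor"] <-
    log2x[shift_idx, labels == "tumor"] + ex$delta
  expr <- 2^log2x
  dimnames(expr) <- list(symbols,
                         paste0(ifelse(labels == "tumor", "T", "P"),
                                seq_len(2 * n)))
  list(expression = expr, labels = labels, planted_set = shift_genes)
}

#' Simulate a gene-set collection over a gene space
#'
#' Draws `n_terms` synthetic annotation terms with sizes uniform on
#' `size_range`. Optionally the first term is enriched for a given gene
#' list at a stated odds ratio: membership is sampled without replacement
#' with weight `enrich_odds` for the listed genes and 1 otherwise
#' (`enrich_odds = 1` reduces to uniform sampling).
#'
#' @param space a `gene_space` (or character vector).
#' @param n_terms number of terms.
#' @param size_range integer vector `c(min, max)` of term sizes.
#' @param seed integer seed.
#' @param enrich_genes optional genes to overrepresent in the first term.
#' @param enrich_odds odds ratio of the enrichment (default 1 = none).
#' @return a `gene_set_collection` of `n_terms` sets named `TERM001`, ...
#' @export
simulate_annotations <- function(space, n_terms = 50,
                                 size_range = c(10, 100), seed = 1,
                                 enrich_genes = NULL, enrich_odds = 1) {
  space <- as.character(space)
  stopifnot(length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2])
  if (size_range[2] > length(space)) {
    stop("size_range exceeds the gene space", call. = FALSE)
  }
  set.seed(as.integer(seed))
  weights <- rep.int(1, length(space))
  if (!is.null(enrich_genes)) {
    weights[space %in% harmonize_symbol(enrich_genes)] <- enrich_odds
  }
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                  replace = TRUE)
  sets <- lapply(seq_len(n_terms), function(i) {
    w <- if (i == 1L) weights else rep.int(1, length(space))
    sort(sample(space, sizes[i], prob = w))
  })
  names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
  new_gene_set_collection(sets,
                          descriptions = sprintf("synthetic term %d",
                                                 seq_len(n_terms)))
}

#' Simulate a known-therapeutic-target list
#'
#' A seeded random subset of the gene space standing in for a list of
#' genes already under therapeutic development, for use with
#' [annotate_novelty()].
#'
#' @param space a `gene_space` (or character vector).
#' @param n_targets number of target genes.
#' @param seed integer seed.
#' @return character vector of target genes.
#' @export
simulate_target_list <- function(space, n_targets = 50, seed = 1) {
  space <- as.character(space)
  stopifnot(n_targets >= 0, n_targets <= length(space))
  set.seed(as.integer(seed))
  sort(sample(space, n_targets))
}
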