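---
title: "Combining genetic screens by rank aggregation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining genetic screens by rank aggregation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenra)
```

# The problem

Independent genetic screens for the same phenotype — for example, T-cell
intrinsic regulators of tumor infiltration — differ in three ways that
make naive hit-list intersection lossy: genome coverage (a focused 25-gene
library versus a whole-genome screen), the significance measure reported
(p-value or FDR, from heterogeneous statistical pipelines), and detection
idiosyncrasies (a true regulator may be a strong hit in a transposon
screen and invisible to an shRNA screen). `screenra` treats each screen as
a *partial ranked list* and combines them over a fixed gene universe, so
that a gene untested by a screen is never penalized for that screen's
silence, while "tested and not significant" is informative.

# Base rankers

A screen's candidate table is reduced to a rank vector. With significance
measures $m(g) \in [0,1]$ and threshold $\alpha$:

* genes with $m(g) < \alpha$ (strictly) are ranked $1..k$ ascending in
  $m$;
* every other tested gene — above threshold or tested without a reported
  measure — receives rank $k+1$;
* untested genes receive no rank.

Strict inequality at $\alpha$ is deliberate: the threshold is a published
convention ("less than 0.05") and a measure exactly at it is not a hit.
Ties in $m$ are broken by larger effect size when the table carries one,
else by harmonized symbol order; the tie-break never affects which genes
are significant, only their order within the significant block, and makes
the ranking a deterministic function of the input.

Symbols are harmonized by whitespace-trimming and upper-casing. This is a
stand-in for ortholog mapping: it lets mouse-style (`Aak1`) and
human-style (`AAK1`) identifiers of the same gene meet, and it is
idempotent, but it is *not* an ortholog service — genes whose orthologs
have different symbols will not be matched, a known limitation.

# Geometric Borda aggregation

Over the gene space, each gene $g$ tested by the screen subset $S(g)$
receives

$$ s(g) = \exp\!\Big(\tfrac{1}{|S(g)|}\sum_{i \in S(g)} \log r_i(g)\Big), $$

the geometric mean of its ranks where it was tested, computed in log
space so large spaces cannot overflow a product. The list is sorted
ascending (a gene ranked 1 everywhere attains the minimum score 1.0), and
ties are resolved by more screens identifying, then more screens testing,
then symbol — corroboration first, then determinism.

Two design points were genuinely open:

**Missing data.** We do *not* impute a space-sized rank for untested
genes: "NA (not tested)" and "$k+1$ (tested, not significant)" are
distinct states, and imputing $N+1$ for a 25-gene screen's 19,975
untested genes would crush every candidate that small screen produced.
The imputing variant remains available (`impute_untested = TRUE`) for
sensitivity analysis, because the alternative convention is defensible
when screens are believed to have tested a representative sample.
A consequence of the default worth knowing: a gene significant *only* in
a small-coverage screen is scored by very few ranks, so small screens
punch above their weight; the per-gene `n_tested`/`n_identified` columns
are exported precisely so users can see how much evidence backs a score.

**Candidate definition.** Genes never significant anywhere are retained
in the full aggregated list (flagged `ever_significant = FALSE`) but
excluded from the exported candidate list: an aggregate score built
exclusively from $k+1$ ranks measures nothing about selection strength.

The geometric mean is the reference method; arithmetic, median and
quadratic (L2) means are provided as comparison baselines
(`aggregate_ranks(method = ...)`), and the AM–GM inequality between the
geometric and arithmetic variants is exercised in the test suite.

# Overlap analysis

`compute_overlap()` counts, per gene, testing screens and identifying
screens (rank $\le k$), with the identified percentage carried at full
precision and rounded only for display. Multi-screen candidates
(`n_identified >= 2` by default) are driver-filtered *last*, mirroring
the practice of removing known malignancy drivers from a final overlap
list rather than from each screen's input; the count removed is always
reported.

# Overrepresentation analysis

Enrichment of a candidate list against a term is the upper-tail
hypergeometric probability
$P(X \ge q)$, $X \sim \mathrm{Hypergeom}(B, K, n)$, with $B$ the
background size, $K$ the term size in the background, $n$ the candidate
count and $q$ the overlap. Two conventions are supported because the
field uses both and published analyses rarely state which: background
restricted to genes annotated in at least one term of the collection
(the default, matching common ORA practice) or the full supplied space
(`use_full_space = TRUE`). Multiple testing is controlled by
Benjamini–Hochberg across the tested terms; specialized corrections tied
to a specific web service's internal term graph are intentionally not
reproduced.

# Preranked GSEA

The per-gene ranking metric is
$-\log_{10}(\text{adjusted } p)\cdot \overline{\log_2 \mathrm{FC}}$,
with $p = 0$ clamped to $10^{-300}$ so the metric stays finite, and score
ties broken by symbol — the enrichment score can depend on hit order, so
the order must be fixed.

The enrichment score walks the ranking: hits add
$|s|^{p_{\exp}}/\sum_{hits}|s|^{p_{\exp}}$, misses subtract
$1/(N - n_{hits})$; ES is the maximum-magnitude deviation (first such
position on an exact tie), and the running sum ends at zero by
construction. $p_{\exp} = 1$ (the classic weighted statistic) is the
default; $p_{\exp} = 0$ gives the unweighted Kolmogorov–Smirnov form,
which is invariant under monotone transforms of the metric. If every hit
score is exactly zero the hit weights fall back to equal, keeping the
statistic defined.

Significance uses gene-label permutations — random same-size gene sets —
the only null available for preranked input. The nominal p is add-one
smoothed over the same-sign null:
$(1 + \#\{\text{same-sign } |ES^*| \ge |ES|\}) / (1 + \#\text{same-sign})$.
Restricting to the observed sign keeps the null calibrated: under a true
null the rejection rate at 0.05 sits at 0.05 (checked by simulation in
the acceptance suite), whereas dividing by all permutations would halve
the effective null and double the rejection rate. NES divides ES by the
mean same-sign null magnitude. FDR is Benjamini–Hochberg across the
evaluated sets — with one custom set per run this reduces to the nominal
p — a documented divergence from the NES-histogram FDR of the desktop
GSEA tool, which needs a large set collection to be meaningful. An
exhaustive null (`exhaustive = TRUE`) enumerates all same-size sets on
tiny instances and is what the enumeration oracles in the tests compare
against.

The bundled two-group differential expression (`simple_de()`) is a
per-gene two-sided Wilcoxon rank-sum test with BH adjustment and
$\log_2((\bar{x}_1+\varepsilon)/(\bar{x}_2+\varepsilon))$ fold changes
($\varepsilon = 10^{-9}$, relevant only near zero means). It exists so
the synthetic pipeline is self-contained; it does not attempt to
reproduce any single-cell DE tool.

# What the generator simulates — and what it does not

`synthetic_config()` defaults define the package's benchmark condition:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | gene-space size |
| `n_screens` | 6 | screens in the panel |
| `coverage` | 0.0125, 0.05, 0.1, 0.5, 1, 1 | per-screen tested fraction, 25-gene-library to whole-genome spread |
| `n_true` | 30 | planted positives |
| `beta_a` | 0.1 | alternative $p \sim \mathrm{Beta}(a, 1)$; small $a$ = strongly skewed to 0 |
| `detect_prob` | 0.6 | per-screen chance a tested positive draws from the alternative |
| `expression$delta` | 2 | planted shift, log2 units |
| `expression$sigma` | 0.5 | within-group SD, log2 units |
| `expression$n_per_group` | 20 | samples per group |

$\mathrm{Beta}(a,1)$ is the standard skewed-small alternative for
p-values; `detect_prob` models between-technology heterogeneity — most
real multi-screen candidates are identified by a single screen, and a
detection probability well below 1 reproduces that. The expression layer
draws per-gene baselines in log2 space, shifts the planted set's
"tumor" group by `delta`, and exponentiates, so planted genes' expected
log2 fold change equals `delta` exactly.

The generator does **not** simulate raw reads, guide- or insertion-level
counts, screen-specific statistical pipelines, correlated gene effects,
or single-cell structure (clusters, dropout, patient effects). Passing
tests on synthetic data therefore demonstrates the correctness and
calibration of the *statistical machinery* under the stated model, not
performance on any particular real screen collection.

One property of the benchmark condition deserves emphasis. With
`detect_prob = 0.6` and $\mathrm{Beta}(0.1,1)$ alternatives, the
probability that a tested positive is a hit in a given screen is
$0.6\cdot 0.05^{0.1} + 0.4\cdot 0.05 \approx 0.465$, and the probability
that a positive is a hit in *no* screen (given the coverage spread) is
about 0.20. An undetected positive cannot outrank genes that are
significant somewhere, so roughly 80% recovery is the *oracle ceiling*
for any aggregation method under these defaults, before rank noise from
uniform-null false positives is paid. The measured recovery of planted
positives in the top $2\,n_{true}$ of the aggregated list (reported by
`scripts/acceptance.R`, ~0.7 over ten seeds) should be read against that
ceiling; the generator parameters are the study condition and are not
adjusted to flatter the ranking.

# Numerical and degenerate-input choices

* Aggregation scores are computed as `exp(mean(log r))`, never as a
  product of ranks.
* A screen where nothing is significant has $k = 0$ and every tested
  gene at rank 1 — aggregation then treats it as uninformative rather
  than failing.
* Empty gene spaces, empty candidate lists, gene sets absent from a
  metric, single-group expression input, GMT lines with fewer than three
  fields, and measures outside $[0,1]$ are errors naming the offending
  object; duplicate symbols and out-of-space genes are warnings with
  counts, never silent drops.
* All generators and the permutation null are pure functions of their
  seed; the pipeline derives stage seeds (`seed+1` … `seed+4`) so stages
  are independent but jointly reproducible.

# Validation scale

The test suite validates each statistic against an independent oracle at
sizes where enumeration is exact: 1,000 random screens for the rank law;
200 random instances (≤ 50 genes × 6 screens) against a brute-force
geometric mean; every hypergeometric configuration with background ≤ 15
against complete draw enumeration; GSEA against hand-computed running
sums, a complete 15-set null, the `fgsea` statistic, and a 200-run null
calibration; and the planted-shift condition over 20 seeds against the
FDR < 0.25 convention. These sizes were chosen so the oracles are exact
and the suite stays fast; the statistics themselves are size-agnostic.

# Known limitations

* Symbol harmonization is case-folding, not orthology.
* The geometric mean over testing screens only rewards genes tested by
  few screens when those screens rank them well; consult `n_tested`
  before acting on a top candidate.
* The permutation FDR across few sets is coarse (BH on a handful of
  nominal p-values); for large collections a NES-based FDR would be
  preferable.
* `simple_de()` ignores expression covariates, library size and batch —
  it is a harness component, not a DE method.
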