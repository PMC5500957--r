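---
title: "Recurrent breakpoint detection: model, assumptions and design choices"
author: "breakrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent breakpoint detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakrec)
```

# What the package models

Segmented DNA copy number profiles are piecewise-constant by construction:
a segmentation algorithm (typically Circular Binary Segmentation, as run by
CGHcall or QDNAseq) has already reduced each sample to maximal runs of
features sharing one log2-ratio. `breakrec` starts *after* that step. Every
boundary between two runs is a CNA-associated breakpoint, located at the
genomic start of the downstream segment's first feature. Platform
granularity means the true break lies somewhere between the last upstream
feature and the first downstream one; that uncertainty interval
`[upstream end + 1, downstream start]` travels with the breakpoint and is
what gets intersected with gene extents.

Three assumptions carry the statistics:

1. **Uniform feature spacing.** Features are (nearly) equally distributed
   over the genome, so at feature level each of the `N` features is an
   exchangeable candidate position and sample `s` hits any one of them with
   probability `p_s = N_s / N`.
2. **Independence across samples.** Tumors are unrelated patients, so the
   cohort count at a position is a sum of independent Bernoulli draws.
3. **Binary gene hits.** A gene is either broken in a sample or not;
   several breakpoints of one sample inside one gene count once. This is
   what makes the gene-level count a Poisson-binomial variable.

## The exact null

For probabilities `p_1..p_S` the distribution of the count `T` is obtained
by expanding the probability generating function
$\prod_s (1 - p_s + p_s x)$ one factor at a time — an $O(S^2)$ convolution
that is exact to floating point. With cohorts of a few hundred samples this
costs microseconds, so no approximation is used anywhere, including in the
far tails:

```{r pgf}
pb <- poisson_binomial(c(0.1, 0.2, 0.3))
pb$pmf          # P(T = 0..3)
pb$tail[3]      # P(T >= 2)
```

P-values are inclusive upper tails `P(T >= t_obs)` — the standard
exact-test convention; a unit with no hits gets p = 1 by construction.
Tails are accumulated from the top of the support downward to limit
cancellation and clamped into [0, 1].

## The gene-level covariate model

A uniform null is untenable at gene level: longer genes, genes spanning
more features, and samples with heavier breakpoint burdens all hit more
often under pure chance. The correction is a pooled linear probability
model: the `G × S` binary outcomes are regressed by ordinary least squares
on `gene_length` (bp), `gene_feature_count` and `sample_breakpoints`
(main effects only, untransformed by default; `log_covariates = TRUE`
applies `log1p`). Fitted values, clipped into `[1e-10, 1 - 1e-10]`, become
the null probabilities `p_{g,s}`.

A linear (rather than logistic) probability model keeps the estimator
closed-form and unbiased for the pooled hit rates, at a price documented
under *Limitations*: predictions are not confined to [0, 1] and the clip
floor is consequential for genes predicted at or below zero. The outcome
is the binary hit indicator, not a per-gene breakpoint count — the Bernoulli
null requires a probability per (gene, sample) cell, and the binary
outcome is the quantity whose expectation that probability is.

## Discreteness-aware FDR

An exact test on `S` trials cannot produce a p-value below
$\alpha^*_g = \prod_s p_{g,s}$ (the tail at the full cohort). Tests that
cannot reach the rejection region only dilute Benjamini–Hochberg. The
Tarone–Gilbert procedure therefore finds the smallest `K ≥ 1` with
$\#\{g : \alpha^*_g \le \alpha/K\} \le K$, keeps the multiplicity set
$R = \{g : \alpha^*_g \le \alpha/K\}$, and runs BH within `R` at level
$\alpha$; genes outside `R` are never rejected and carry adjusted value 1.
When every $\alpha^*_g \to 0$ the procedure reduces exactly to BH on all
genes. Adjusted values are defined as the smallest level at which a gene is
rejected and are computed by bisection over $\alpha$ (41 iterations,
resolution ~5e-13); because the multiplicity set shrinks, they may
legitimately fall below BH-adjusted values, so `fdr >= p_value` is *not*
an invariant at gene level.

Feature level stays with plain BH: the shared null makes the per-feature
minimum attainable value identical across features, so Tarone-style
exclusion has nothing to remove there.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `filter` | `"none"` | — | keep every boundary unless the analyst opts into a selection; the CNA-associated mode needs discrete calls that not every upstream pipeline provides |
| `threshold` (deviation filter) | 0.2 | log2-ratio | an arbitrary but common shift floor for admixed tumor material; the filter uses strict `>` ("exceeds") |
| `tol` (segment equality) | 0 | log2-ratio | segmentation output is exactly piecewise-constant; raise to ~1e-8 only for values that round-tripped through text at differing precision |
| `map_mode` | `"interval"` | — | mapping by the full uncertainty interval; point-mapping (`"feature"`) systematically misses genes inside large inter-probe gaps |
| `n_mode` | `"all"` | — | `p_s = N_s / N` with `N` all features; `"eligible"` subtracts the per-chromosome first features, which can never host a breakpoint — the conventions differ by `#chromosomes / N`, negligible on real grids, and `"all"` is the definition the statistics were built around |
| `alpha` | 0.1 | FDR | the conventional discovery threshold for recurrent breakpoint genes |
| `gene_fdr` | `"gilbert"` | — | the discreteness-aware procedure is the point of the gene-level analysis; `"bh"` is provided for comparison |

# The synthetic cohort generator

`simulate_cohort()` emulates the package's *input*, not raw data: features
placed per chromosome with near-uniform spacing (default mean 30 kb —
a typical 105k-array density — with ±20% jitter, 60 bp feature width),
per-sample burdens `N_s` drawn uniformly from `breakpoint_range` (default
5..50), boundaries scattered uniformly over non-chromosome-first features,
and segment levels alternating between neutral (0) and an aberrant level
(±0.45 log2, approximating single-copy change with stromal admixture) with
matching discrete calls. Planted genes force a boundary inside their extent
for `round(penetrance × n_samples)` randomly chosen samples. Everything is
reproducible from `config$seed`, and the caller's RNG stream is restored
afterwards.

Because adjacent segments always differ in value *and* call, every planted
boundary survives all three selection filters, which is what makes exact
round-trip tests possible. The generator deliberately omits probe-level
noise, waviness, GC bias, mis-segmentation, and spatially correlated
breakpoints (e.g. chromothripsis): passing tests demonstrate correctness of
the detection/mapping/testing machinery on well-formed segmented input, not
robustness to upstream segmentation errors or to clustered breakage in real
tumors.

# Numerical and degenerate-input choices

- Segments are runs of *exactly* equal values (`tol = 0`); ties in p-value
  rankings are broken by observed count only in the summary display, never
  in the statistics.
- `p = 0` and `p = 1` trials are handled exactly by the PGF product (the
  factor is degenerate, not special-cased).
- The minimum attainable p-value $\prod_s p_{g,s}$ is computed as
  `exp(rowSums(log(p)))`; for realistic cohorts it underflows to 0, which
  is the correct continuous-limit behaviour (every gene enters the
  multiplicity set).
- Features with a missing segmented value in any sample are dropped
  cohort-wide at load (with a warning), keeping one shared `N` across
  samples, which the feature-level null assumes. How the original
  ecosystem handles multi-sample missingness is not documented; the
  cohort-wide drop is this package's choice.
- An all-zero gene-hit matrix, an empty gene list, an empty grid, burdens
  exceeding the feature count, and probabilities outside [0, 1] are hard
  errors, not silent results.

# Validation design

The test suite validates the statistics at sizes chosen to exercise each
property fully: PGF exactness against brute-force enumeration over all
$2^S$ outcomes for `S ≤ 15` (200 random vectors, tolerance 1e-12);
feature-level size on 500 null cohorts of 50 samples × 1,000 features with
`N_s ~ U{5..50}`; exact round-trip detection on 100 noise-free cohorts
under all three filters; planted-gene recovery (rank 1 and Gilbert FDR
< 0.1) on 50 cohorts of 200 samples × 5,000 features × 500 genes with one
gene at 25% penetrance over a ~1.5% background gene-hit rate; and
covariate-model consistency at two pooled sizes.

One subtlety deserves record. An exact discrete test is conservative: the
achievable level just below 0.05 is `P(T >= t*)` for the smallest `t*`
whose tail clears 0.05, so the realized fraction of null tests with
`p < 0.05` sits *below* 5% (around 3% under the null-cohort design above,
where the mean cohort count is ≈1.4 and the 0.05 threshold falls between
the `P(T ≥ 4)` and `P(T ≥ 5)` jumps). The size check therefore asserts the
fraction lies within the 99% binomial band around 0.05 computed over
replicates — a conservative exact test must stay inside it from below, and
an anti-conservative implementation would breach it from above.

# Limitations

- **Linear probability model pathologies.** Genes whose covariates predict
  a hit probability ≤ 0 are clipped to 1e-10, so a single stray hit in such
  a gene produces an extreme p-value. Keep gene annotations comparable in
  scale (no single gene vastly longer than the rest), or the pooled
  regression will also absorb a strong gene's own signal into its null
  through leverage.
- **Gilbert vs BH.** The Tarone-style multiplicity reduction is not a
  uniform improvement: for *very* small cohorts (a handful of samples) a
  test observing its own support maximum can have a small p-value yet be
  excluded from the multiplicity set. In the package's regime — cohorts of
  tens to hundreds of samples, where minimum attainable values are
  astronomically small — the Gilbert set contains the BH set, which is what
  the test suite asserts under that regime.
- **No spatial modelling.** Neighbouring features are treated as
  independent test units; clustered breakage inflates regional counts and
  is not modelled.
- **No partner-locus inference.** Only CNA-associated break positions are
  identified; translocation partners and SV types are out of scope, as is
  upstream normalization, segmentation and calling.
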