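---
title: "Simulating single-cell chromatin accessibility data from latent embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single-cell chromatin accessibility data from latent embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The generative model

scATAC-seq data arrive as a sparse peak-by-cell matrix of small counts:
most entries are 0, a cell's total count (library size) spans an order of
magnitude or more across cells, and per-peak totals have a long right
tail. `accessim` generates such matrices from low-dimensional latent
embeddings so that cell *states* are exactly known, while the marginal
statistics are borrowed from a reference dataset.

A simulated count `x_ij` is Poisson with mean `λ_ij`, where the mean
matrix is built in four steps:

1. **Embeddings.** A cell embedding matrix `C` (`nembed × ncell`), a
   peak-wise effect matrix `P` (`npeak × nembed`, standard normal entries
   zeroed with probability `eta`), and a cell-wise effect vector `l`
   (standard normal). `C` stacks a homogeneous block (entries
   `N(1, sigma^2)`, biology shared by all cells) on a heterogeneous block
   that encodes the requested cell states (see modes below). The product
   `Λ̃ = P C` is the raw parameter matrix.
2. **Statistic models.** Three distributions are estimated from the
   reference: log library size, log cell non-zero proportion, and peak
   summation. In pseudo-cell-type mode these are fit per cell type
   (two-component Gaussian mixtures for the two cell-level statistics, a
   discrete long-tailed family for peak summation); in discrete and
   continuous modes a single kernel density estimate per statistic is fit
   on the whole matrix, which adapts to arbitrary mixtures of states.
3. **Correction.** `Λ̃` contains negative entries, so it is passed
   through an activation (softplus by default) and then corrected so the
   implied statistics match targets sampled from the fitted models.
4. **Sampling.** Independent Poisson draws; for binarized references a
   Bernoulli variant emits `1` with the Poisson non-zero probability
   `1 − exp(−λ)`.

## Modes

**Discrete.** Population centers form an `nhete × npop` matrix `H`; each
of its rows is drawn from the multivariate normal `N(1, Σ)`. An
off-diagonal entry of `Σ` makes the corresponding pair of populations'
center coordinates correlated, hence the populations more alike; the
diagonal scale sets how far centers sit from each other. Cell `j` of
population `k` receives `c_ij ~ N(h_ik, sigma^2)`.

**Continuous.** The user supplies a Newick tree with branch lengths.
Cells are assigned to branches proportionally to length
(largest-remainder rounding, ties by branch order in the Newick string,
at least one cell per branch) and spaced uniformly along each branch,
the first cell one spacing below the branch's parent node, the last
exactly on its child node. Per embedding dimension the virtual root cell
draws `N(1, sigma^2)` and each subsequent cell adds a
`N(0, interval)` increment along the predecessor chain — Brownian motion
indexed by tree distance. A cell's deviation from the root therefore has
variance equal to its pseudotime, and two cells' deviations covary by
the pseudotime of their last common ancestor. The virtual root is not
emitted as a data cell.

**Pseudo-cell-type.** Each reference cell type is simulated separately
with a homogeneous-only CEM (all `nembed` dimensions); the type's
identity comes entirely from its fitted statistic models, which is
appropriate because the reference data already carry the heterogeneity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nembed` | 12 | total latent dimensions |
| `nhete` | 10 | heterogeneous (state-carrying) dimensions; `< nembed` |
| `sigma` | 0.5 | embedding standard deviation; larger → more within-state dispersion |
| `eta` | 0.5 | PEM zeroing probability; sparsifies peak-embedding coupling |
| `activation` | softplus | `exponential` amplifies embedding differences (useful for batch recipes) |
| `covariance` | — | `npop × npop` PSD matrix of population-center similarity |
| `effect_sd` (hubs) | 0.1 | within-hub deviation around the shared effect vector; larger → weaker co-accessibility |
| batch `noise_mean/sd` | 0/0 | Gaussian noise on the PEM (biological) or on Λ (technical) |

For benchmark recipes that need well-separated populations we use
`covariance = 2 * diag(npop)` with `sigma = 0.5`; unit-diagonal
covariance gives closer, harder-to-separate populations.

# Correction: matching the reference statistics

Targets are sampled once per run: `ncell` library sizes (exponentiated
draws from the log-library model), `ncell` non-zero proportions
(exponentiated, clamped to (0, 1]), and `npeak` peak summations (clamped
at 0). Because library sizes and peak summations are sampled
independently, their totals disagree; the peak targets are rescaled by
one global factor so both totals match. Without this, the final
correction stage would push the ratio into every row sum.

- **Peak-wise correction** rank-matches sorted targets to sorted row
  sums (the r-th largest row sum receives the r-th largest target) and
  rescales each row, preserving within-row proportions and the row-sum
  ordering exactly. Rank matching (a quantile map) rather than random
  assignment keeps the embedding-driven structure — hub peaks stay
  coherent, population-specific peaks stay population-specific.
- **Cell-wise correction** first rank-matches library-size targets to
  the CEV scores `s_j = l·C_j` (the CEV's documented role: ranking cells
  by intended depth); sparsity targets are rank-matched alongside, which
  reflects the empirical positive association between depth and
  non-zero fraction and keeps the assignment deterministic. Each column
  is then shaped by a power transform `λ → λ^γ` — monotone, hence
  order-preserving within the cell — with `γ ∈ [0.05, 20]` solved by
  root bisection so the column's expected Poisson non-zero proportion
  `mean(1 − exp(−λ))` equals its target after renormalizing the column
  to its library-size target. Unattainable proportions are clamped to
  the nearest attainable value and the affected cells flagged with a
  warning. The final renormalization makes column sums exact to
  floating-point precision.

A single peak-then-cell pass leaves a systematic row-sum distortion:
the power shaping compresses the dynamic range of rows. The pipeline
therefore *alternates* the two corrections ten times, always ending with
the cell-wise step, so the library-size and sparsity contracts hold
exactly on the output while row sums converge to their targets. Ten
alternations were chosen as the point where the row-sum mismatch is far
below sampling noise; the cost is linear in the matrix size.

# Statistic estimation choices

- **GMM.** Two components, EM as implemented in mclust with
  unequal variances (equal-variance fallback for near-degenerate data).
  The fit is deterministic given the data.
- **Log-variant family.** Peak summations are long-tailed with support
  including 0; we use the zero-shifted log-series
  `PMF(k; p) = −p^(k+1) / ((k+1) ln(1−p))`, `k ≥ 0`, fit by
  maximum likelihood (1-D optimization on `p`). Five alternatives
  (Poisson, negative binomial, geometric, Zipf, logarithmic) can be fit
  and auto-selected by the smaller one-sample KS statistic; Zipf and
  logarithmic have support starting at 1 and are fit to `values + 1`.
  Sampling from the heavy-tailed families inverts a CDF table truncated
  at the `1 − 1e-9` quantile (capped for power-law tails), renormalized.
- **KDE.** Gaussian kernel with Scott's-rule bandwidth; sampling
  resamples data points plus kernel noise, redrawing up to 100 times
  when a draw leaves the statistic's domain, then projecting onto the
  boundary.
- **Log transforms** use the natural log; zero library sizes or
  proportions are excluded from fitting (cells that would produce them
  are removed by the reference filters).

# Evaluation utilities

- `lsi_embed()` is the standard scATAC reduction (binarize, TF-IDF,
  truncated SVD). By default components keep their singular-value
  scaling, which is what clustering uses. `milisi()` standardizes the
  components before computing neighborhoods, because otherwise the
  depth-driven first component dominates all distances and neighborhood
  sizes collapse.
- `milisi()` uses the perplexity-calibrated Gaussian neighborhood
  construction over `3 × perplexity` nearest neighbors and reports the
  median inverse Simpson index of the real/synthetic label (2 = perfect
  mixing, 1 = complete separation). Exact duplicates of a cell (distance
  0 up to floating-point tolerance) are excluded from its neighborhood,
  as is the cell itself: a duplicate carries no information about local
  mixing, and excluding it makes the duplicated-dataset limit exactly 2.
- `clustering_scores()` computes ARI by pair counting, AMI with the
  hypergeometric expected-MI correction and arithmetic-mean
  normalization, and homogeneity `1 − H(truth|pred)/H(truth)`.
- JSD in `quantile_compare()` is measured in nats on a shared 100-bin
  histogram with a `1e-12` floor; the binning is a convention, stated
  here because the divergence value depends on it.
- When scoring planted interaction hubs from counts, correlations should
  be computed on depth-normalized counts (divide each column by its
  library size): library-size variation alone induces a uniform positive
  correlation between all peak pairs that otherwise masks the hub
  signal. This mirrors how co-accessibility methods control for depth.

# What the fixture emulates — and what it does not

`make_fixture()` generates the reference used in examples and tests:
Gamma-distributed per-peak rates (long-tailed peak summations),
type-specific peak programs, a two-mode lognormal library-size
distribution (so the two-component GMM is identifiable), and Poisson
counts. It reproduces the *marginal* properties the simulator corrects
for, which is exactly what the tests exercise. It does not reproduce
genomic covariates (GC content, peak width), fragment-level artifacts,
doublets, or the empirical covariance structure of real chromatin — so
passing tests demonstrate the simulator's contracts and recoverable
ground truths, not fidelity to any particular tissue.

# Numerical and reproducibility choices

- Every stage draws from a named substream seeded by a hash of the root
  seed and the stage name (`substream_seed()`), so adding a stage never
  perturbs the draws of earlier ones and identical configurations are
  bit-reproducible, down to the written files.
- Bisection on `γ` targets the proportion to `1e-3`; column
  renormalization is exact. Ties in rank matching follow R's stable
  order. Degenerate inputs are handled explicitly: zero-variance KDE
  data yield a point-mass sampler with a warning; all-zero rows in the
  peak-wise correction receive their matched target spread uniformly;
  exponential activation clips exponents at 30 and counts the clipped
  entries.
- Problem sizes in tests and the acceptance script — a 2000-peak ×
  500-cell reference, 500 simulated cells, 10,000 replicate dimensions
  for the Brownian check — are the package's documented study scale:
  large enough that Monte-Carlo error sits well below every tolerance,
  small enough to iterate on quickly.

# Known limitations

- The correction matches marginal distributions; joint structure between
  library size and sparsity beyond their rank association is not
  modeled.
- Peak-summation targets are matched in distribution but individual
  peaks' final sums drift slightly from their matched targets because
  the cell-wise step runs last (the drift shrinks with the correction
  alternations).
- Hub detectability depends on where the shared effect vector lands in
  the accessibility spectrum: a hub whose peaks end up with very low
  counts is genuinely hard to recover from correlations — the same
  behaviour reported for co-accessibility inference on real-scale
  benchmarks.
- The Bernoulli (binarized) variant matches the cell non-zero proportion
  exactly but treats the library size as the implied non-zero count; for
  binarized references these coincide by definition.
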