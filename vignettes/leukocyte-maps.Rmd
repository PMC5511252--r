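---
title: "Discriminant leukocyte maps: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant leukocyte maps: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukomap)
```

## The model

Multicolour flow cytometry yields, per individual $i$, a matrix
$X_i$ of $N_i$ cells by $J$ marker intensities, and per individual a
clinical group label $g \in \{\text{control}, \text{challenged}\}$.
`leukomap` discriminates the groups while staying linear and
interpretable at every level. The chain is:

**Stage 1 — multiset preprocessing.** Intensities are
$\log_{10}$-transformed; if the global minimum $v_{\min}$ is below 1 a
shift of $1 - v_{\min}$ is added first, so the minimum maps to 0 and the
transform is defined for the negative values that uncompensated
acquisitions contain. Centring and scaling respect the *multiset*
structure (cells nested in individuals nested in groups): the centre is
the unweighted mean over individuals of the per-individual marker means,
$m = \tfrac1I \sum_i m_i$, and the scale per marker is
$s_j = \sqrt{\tfrac1I \sum_i \operatorname{var}_j(X_i)}$, the root of the
mean per-individual variance. Both statistics are invariant to replicating
any individual's cells, so acquisition depth cannot tilt the model — the
usual grand mean and pooled standard deviation over cells would be
dominated by deeply measured samples. Per-individual, per-group and
median-based centring variants, and per-individual/per-group scaling, are
available as configuration (`center_mode`, `scale_mode`); mode choice is
explicit, never automatic, and can be compared by cross-validated accuracy.

**Stage 2 — base model.** A PCA of the pooled preprocessed cells
describes marker co-expression variability. Each individual's block is
divided by its cell count before the decomposition, so the loadings are
the top right singular vectors of the count-balanced matrix; cells (of
training and held-out samples alike) are scored by plain projection
$T = X_{cs} P$. Loadings are orthonormal; each component's sign is fixed
so its largest-magnitude element is positive, making runs reproducible.
Per-individual explained variance is reported as the variance of that
individual's scores over the trace of its own centred covariance — the
one definition under which an individual's fractions over all $J$
components sum to one.

**Stage 3 — histograms.** Score clouds cannot be compared between
individuals cell by cell, so each individual becomes a density on a grid
shared by the study: per component the bin width is
$\delta_k = (P_{99.95} - P_{0.05})/F$ (percentiles of the pooled training
scores, linearly interpolated), i.e. the range without the 0.1% most
extreme cells, split into $F$ bins. Counts are divided by $N_i$, so every
histogram has total mass 1 and the (mostly uninformative) cell count drops
out. A separable Gaussian smoothing with standard deviation $\sigma$ bins
per axis absorbs the small instrumental/biological shifts that would
otherwise put equivalent cells of different samples into adjacent bins.

**Stage 4 — top model.** Histograms are flattened (column-major; the
round trip with the map refolding is exact) into a samples-by-bins matrix
$C$, near-constant bins are dropped, and a two-class OPLS-DA is fitted to
the centred $C$ and the centred $\pm 1$ group coding: `n_ortho` orthogonal
signal correction (OSC) components — directions of between-sample
variation uncorrelated with the class — are deflated first, then exactly
one predictive PLS component is fitted (a two-class problem has one
predictive direction). With `n_ortho = 0` the model reduces to
single-component PLS-DA, which is how the implementation is validated
against an independent NIPALS oracle. The unit-length predictive weight
vector refolded onto the $F \times F$ grid is the leukocyte map; positive
bins mark cell regions over-represented in the challenged group, negative
bins regions over-represented in controls. A sample's prediction score is
its centred, OSC-deflated histogram projected on the weights; the sign
classifies (threshold 0; a score exactly at the threshold is counted as a
misclassification — conservative and deterministic).

**Validation.** `double_cross_validate()` runs leave-sample-out double
cross-validation: outer folds partition individuals (never cells),
stratified by group and reshuffled across iterations with logged, derived
seeds. Within each outer training set an inner cross-validation selects
`n_ortho` from a candidate grid (default `{0, 1, 2}` in the nested recipe;
ties resolve to fewer components). Every fitted statistic — log shift,
centres, scales, loadings, bin grid, variance mask, column centring,
weights — derives from the training individuals of that fold only; the
test suite asserts this by refitting folds from scratch and comparing
scores bitwise.

## Parameters, defaults and units

| Parameter | Default | Units / meaning |
|---|---|---|
| `center_mode`, `scale_mode` | `overall`, `pooled` | multiset centring/scaling described above |
| `k_base` | 2 | base components; histograms and maps are 2-D at the default |
| `bins_f` | 500 | bins per histogram dimension |
| `smoothing_factor` | 5 | Gaussian kernel width in bins (`smoothing_bandwidth = "sigma"`; an FWHM convention is available) |
| `variance_threshold` | 1e-6 | bin *density*-variance filter (see below) |
| `n_ortho` / `n_ortho_grid` | 1 / `{0,1,2}` | OSC components, fixed or inner-CV selected |
| `outer_folds`, `n_iterations` | 6, 20 | the cross-validation recipe |

The kernel is truncated at $\pm 4\sigma$ and uses half-sample-symmetric
("reflect") boundaries; the resulting smoothing matrix is doubly
stochastic, so smoothing conserves total mass exactly, and the histogram
is renormalized afterwards only as a guard against floating-point drift.
Smoothing order relative to normalization is immaterial under this
convention, which is why renormalization is mandated. Separability means
one 1-D pass per axis equals the full $K$-dimensional convolution, which
the tests verify against a direct nested-loop oracle; histograms with
$K > 2$ dimensions reuse the same per-axis pass.

**Why the variance filter works on densities.** The filter drops bins
whose across-sample variance is below $10^{-6}$. For mass-normalized
histograms the value of a bin scales with the bin volume
$\prod_k \delta_k$: refining the grid drives every bin fraction — and
hence every variance — towards zero, so an absolute threshold on raw
fractions would silently remove *all* bins at fine resolutions (at
$F = 500$, a population carrying mass fraction $p$ can contribute at most
about $p/(2\pi\sigma_\text{eff}^2)$ to any smoothed bin, bounding all
fraction variances around $10^{-8}$). Bin *densities* (fraction / bin
volume) converge to a resolution-independent limit, so the threshold is
applied on the density scale, where $10^{-6}$ is a mild filter that
removes empty and numerically negligible tail bins. The retained-bin mask
is part of the fitted model and is applied unchanged to held-out samples.

**Numerical and degenerate-input choices.** Percentiles use linear
interpolation between order statistics so grids are bit-reproducible.
Bins are half-open $[e_f, e_{f+1})$ with the last upper edge closed; a
cell exactly on an interior edge belongs to the upper bin. Cells outside
the trimmed training range — including the 0.1% trimmed tails and
held-out cells beyond them — are clipped into the boundary bins, so every
cell contributes and mass stays 1 (`clip_policy = "clip"`); discarding
them would break the normalization semantics for held-out samples.
Held-out intensities below the training log-shift floor are clipped to
the training minimum (log value 0), mirroring the same policy. The
per-individual variance in the scaling stage uses the population
($1/N$) convention, which makes the replication invariance exact; the
across-sample bin filter uses the ordinary $n-1$ sample variance.
Zero-variance markers, empty individuals, single-class responses,
rank-exhausted OSC requests and an all-removed bin mask raise immediate,
named errors rather than propagating NaNs. Inner-CV ties resolve to the
smallest `n_ortho`; the sign convention of the base loadings and the
$\pm 1$ coding (control $=-1$, so positive map weights mean
"challenged-enriched") pin all remaining sign freedom.

## What the synthetic cohorts emulate

`simulate_cohort()` draws two-group cohorts with known ground truth:
Gaussian cell populations in $\log_{10}$ marker space whose mixing
fractions differ between groups, per-individual cell counts drawn from a
range (so acquisition depth varies), per-individual jitter of each
population mean (biological variability between donors), and optionally a
*continuum* population whose mean drifts linearly across cells —
emulating activation gradients in which cells do not form a discrete
cluster. Cells are exponentiated to the raw intensity scale, so the
pipeline's log transform recovers the generative geometry, and
`write_fixture_fcs()` emits real FCS 3.1 files to exercise ingestion.

The preset scenarios fix the study conditions used throughout the tests:
`lps_like` (2 × 8 individuals, 1,500–2,500 cells, 6 markers, a broad
resting population — $\log_{10}$ sd 0.06, i.e. ~15% CV — at 95% vs 70%,
and a compact activated continuum population — sd 0.025 with a drift
along the CD16−/CD62L−/CD11b+ axis — at 5% vs 30%), `null` (2 × 20
individuals drawn from one law; fraction values identical between groups)
and `aml_like` (8 markers, a blast-like population shifted along a single
marker at 2% vs 25%). The jitter scale, 0.015 log units (~4% intensity
shifts), is chosen so that between-individual population shifts are on
the order of a few histogram bins — the regime the smoothing stage is
designed to absorb. The fractions and geometry are *test parameters of
this package*, not measurements.

What passing on these cohorts does and does not show: the generator
produces clean Gaussian(-continuum) mixtures without spillover, doublets,
debris, acquisition-time drift, or heavy non-Gaussian tails, and its
between-individual variability is isotropic jitter rather than structured
batch effects. Success here demonstrates that the implementation recovers
what the model assumes — equal-weighting, count-invariance, localization
of a planted difference, chance-level behaviour under exchangeability —
not that real studies will reach any particular accuracy.

## Open design points and how they were resolved

* **Unsupervised top model** (PCA instead of OPLS-DA on the histograms) is
  out of scope; the supervised chain is the deliverable.
* **Base-component pairs.** When more than two base components are fitted,
  `rank_pc_pairs()` evaluates every unordered pair as histogram axes by
  cross-validated accuracy and reports the ranking; selection is explicit
  (`hist_pcs = c(1, 3)`), never silent.
* **Median centring** uses medians at both levels (per individual, then
  across individuals) and keeps the default variance-based scaling; a
  median-based scaling variant is not defined here.
* **Null-calibration testing.** Repeated cross-validation iterations
  re-score the same individuals, so accuracy uncertainty is governed by
  the number of individuals, not by individuals × iterations; the test
  suite's chance-level band uses $n = 40$ accordingly.
* **Problem sizes.** The test and acceptance runs use the preset cohort
  sizes above with the default 500-bin grid; a full nested
  cross-validation of the `lps_like` preset refits the entire pipeline
  480 times and completes in a few minutes on one core.

## Known limitations

Two-class designs only (multi-class OPLS-DA is out of scope); leukocyte
maps are defined for 2-D histograms (higher-dimensional top models still
fit and predict, but are not refolded); no compensation/spillover
handling or logicle/arcsinh transforms — data are used as acquired, log10
only; the FCS reader covers list-mode FCS 3.0/3.1 with float or uniform
16/32-bit integer data and does not parse spillover keywords or escaped
delimiters.
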