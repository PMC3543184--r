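---
title: "Methods: translatome quantification from polysome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome quantification from polysome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatomics)
```

## The experiment being modeled

A bacterial culture in exponential growth is lysed after arresting
translation elongation; the extract is resolved on a sucrose gradient and
eluted as 11 fractions while A254 absorbance is recorded. Fraction roles are
assigned experimentally (rRNA quantification): fraction 1 holds free RNA,
fractions 2 and 3 the 30S and 50S ribosomal subunits, fraction 4 the
monosome, fractions 5–11 polysomes of increasing size. For transcriptomics,
the first two and the last four elution fractions are pooled, giving seven
RNA pools (B–H) which are hybridized to microarrays alongside an
unfractionated reference aliquot (A). Three independent replicate series are
assumed throughout; the inter-series normalization requires at least two.

This package takes those artifacts — an intensity tensor, empty-spot
background statistics, per-fraction total RNA quantities, the absorbance
trace with fraction boundaries and roles — and computes per-gene ribosome
occupancy and density plus covariance models of their determinants. Because
no public dataset accompanies the design, a synthetic generator reproduces
every input with known ground truth; it is first-class, tested code.

## Ribosome calibration

Polysome peaks beyond a few ribosomes are not resolved individually, so
ribosome numbers for the heavy fractions are extrapolated from the monosome
peak with the log-linear law `ln t = a ln P + b` (`t` elution time, `P`
polysome size). Per replicate, the slope comes from an ordinary
least-squares fit on the resolved peaks; `a` is the mean of the replicate
slopes, and `b` is anchored analytically at the monosome peak
(`b = ln t_monosome`) rather than co-fitted, because the monosome position is
the one per-replicate quantity measured directly. Inverting the law at the
boundary times of each pooled fraction gives a ribosome range; the
*representative* number is the arithmetic midpoint of the bounds, reported
to one decimal, with fraction D pinned to exactly 1 (it is the monosome by
construction). The midpoint is a convention: per-fraction averages of the
underlying per-replicate values would differ slightly, but no alternative is
better identified, and the midpoint stays within one rounding unit of
typical reported values. Midpoints are pre-rounded at 10 decimals before the
one-decimal report so that last-bit noise from the `exp`/`log` inversion
cannot flip the rounding.

With the default gradient layout (`a = 0.5`, monosome at `t = 10`), the
representative numbers per fraction are 1, 2.1, 4.2, 7.5 and 13.8 for D–H.

## Engaged ribosomes

The share of ribosomes engaged in translation is the trapezoidal area of the
absorbance trace over elution fractions 4–11 divided by the area over 2–11,
as a percentage. Fraction 1 (free RNA) is excluded from both. Window edges
falling between samples are linearly interpolated, making the integral exact
for piecewise-linear traces; the statistic is invariant under uniform
rescaling of the absorbance. Zero denominator area is an error, not a 0/0.

## Normalization

Three stages, in order, on genes passing the cutoff:

1. **Cutoff.** Per array, cutoff = mean + 1 SD of the empty spots; a gene is
   kept if its across-replicate mean intensity exceeds the cutoff on at
   least one of the eight arrays. (Whether the cutoff should use
   replicate-averaged or per-replicate intensities is ambiguous in the
   underlying design; replicate-averaged is implemented.)
2. **Reference standardization.** Intensities on B–H are divided by the mean
   array-A intensity of the same replicate over kept genes, removing
   per-replicate detector scale. The kept-gene count replaces any
   dataset-specific constant.
3. **RNA-quantity correction.** Equal RNA amounts are hybridized per array,
   so spot signal is a per-microgram share; multiplying by
   `RNA_fraction / RNA_reference` (µg) restores abundance proportionality
   across fractions.
4. **Inter-series centering/reduction.** Per fraction array and replicate,
   the replicate's values are regressed on the across-replicate mean;
   corrected values are `(N − b̂)/r̂`. The replicate mean is computed from
   the same data being corrected — a statistical circularity accepted as
   part of the procedure. The correction collapses any exact affine
   per-replicate distortion onto the common profile (verified to 1e-8 in the
   tests), but by construction it cannot remove a distortion component
   shared by all replicates, including a common additive offset.

Centering can push low-signal values negative; they are clipped to zero for
proportion computation and the gene-replicate flagged, since proportions
must be nonnegative and the procedure itself is silent on the case.

## Translatome variables

Per gene and replicate, proportions are the corrected intensities divided by
their sum over B–H (each vector sums to 1 within 1e-9, enforced by test).
Occupancy is the D–H sum per replicate, averaged over the replicates with
valid (non-degenerate) data.

**Peak fraction.** The modal loading state is assigned by a bootstrap on
residuals: residuals of each replicate value from the per-fraction mean,
pooled *within the gene* across all seven fractions and replicates
(cross-gene pooling would mix intensity scales); each of 10 000 bootstrap
data sets adds resampled residuals onto the per-fraction means, and the
argmax over D–H is recorded, ties broken deterministically toward the
lighter fraction (and flagged). If one fraction is modal in ≥ 95% of the
sets it is the peak. Otherwise the assignment widens: windows of 2, then 3,
… adjacent fractions within D–H are merged by summing proportions and the
full bootstrap is re-run on the merged categories. A window qualifies when
its merged bootstrap support reaches the threshold; among qualifying windows
the one covering the largest share of the single-fraction argmax mass is
chosen. The containment condition matters: without it, merging two mid-sized
adjacent fractions can outgrow the true modal fraction purely by summation,
assigning a widened peak that does not contain the fractions the bootstrap
actually hesitates between. Widening at the full width D–H always succeeds,
so the recursion terminates. For two replicates and small residual pools the
bootstrap frequencies are checked against exact enumeration of all residual
assignments.

**Density.** Genes with a single-fraction peak get
`density = 100 · R(peak) / CDS length` (ribosomes per 100 nt); widened or
unassigned peaks leave density undefined. Densities strictly above
`100/30 ≈ 3.33` — more ribosomes than can physically fit at a ~30 nt
footprint — are flagged and excluded from modeling but retained in the
records; a density of exactly 100/30 is retained (strict inequality).
Unannotated 5'UTRs inflate density for short genes, which is why the flag
concentrates there; no 5'UTR correction is applied.

## Statistical models

**Enrichment** uses the hypergeometric distribution `H(m, n2−m, n1)` with
the *strictly greater* tail `P(N > n_obs)` — deliberately not the more
common `P(N ≥ n_obs)`; the implementation is verified against brute-force
subset enumeration for every universe of ≤ 12 genes.

**Covariance models.** Occupancy, density, or protein level (log scale) is
modeled as a linear combination of quantitative features — log-transformed
when strictly positive (mRNA concentration, half-life, CDS length, CAI,
aromaticity), raw when sign-changing (chromosome position, GRAVY, folding
energies ΔGup/ΔGdown) — each centred and reduced, plus deviation-coded
functional-category terms. The response is log-transformed and standardized
the same way, so all coefficients are standardized effects. Selection is
stepwise in both directions from the full model under AIC (exhaustive
subset search is available for ≤ 12 candidate terms); category levels enter
selection individually so single levels can be retained. Coefficient
p-values are the usual least-squares t-tests; adjusted R² equals the closed
form `1 − (1−R²)(n−1)/(n−p−1)` (asserted in tests). Genes with missing
feature values are dropped with the count logged. Perfectly collinear
covariates abort with a diagnostic naming the pair.

A consequence of the AIC penalty (2 per parameter) worth stating explicitly:
a pure-noise covariate survives selection with asymptotic probability
`P(χ²₁ > 2) ≈ 0.157`. Stepwise AIC is therefore *sparse but not
conservative* — on average roughly one in six null covariates is retained,
whatever the implementation. The test suite asserts this rate rather than
pretending selection is consistent.

**Protein level** is fitted twice — without and with occupancy and density
offered as candidate covariates — and the two adjusted R² values are
compared.

## The synthetic generator

`synthetic_config()` fixes the study conditions; one seed determines every
output. Defaults, with rationale:

| Parameter | Default | Meaning |
|---|---|---|
| `n_replicates` | 3 | independent culture/gradient/array series |
| `occupancy_mean`, `occupancy_sd` | 0.66, 0.06 | marginal of true occupancy |
| `peak_weights` | D 0.17 / H 0.83 | two loading classes: monosome-dominated and heavily loaded |
| `loss_mean`, `loss_sd` | 0.60, 0.16 | mRNA recovery after fractionation, drawn per fraction × replicate, constant across genes |
| `fraction_rna_range` | 29.7–436.3 µg | total RNA per fraction |
| `noise_cv` | 0.05 | multiplicative log-normal spot noise |
| `distortion_r_range`, `distortion_b_range` | 0.8–1.25, 0–30 | per-array affine distortion the inter-series step must undo |
| `kernel_decay` | 0.55 | within-gene geometric spread of engaged mass around the peak |
| `cds_meanlog`, `cds_sdlog` | log 900, 0.6 | CDS length (nt), log-normal, typical of a small bacterial genome |
| `engaged_fraction` | 0.61 | target polysomal share of the absorbance area |

The intensity forward model is multiplicative log-normal noise on a
positive, right-skewed signal (array intensities are positive and
right-skewed); fraction recovery is gene-independent within a fraction and
replicate. True occupancy is drawn with a log-normal marginal matched by the
delta method to a Gaussian(0.66, 0.06) truncated to (0, 1] — at this
coefficient of variation the two are indistinguishable — so that log
occupancy can simultaneously carry the configured standardized feature
effects used by the model-recovery tests. Residual SDs default so the
standardized linear predictor has unit total variance, making fitted
standardized coefficients directly comparable to the configured effects.

The within-gene mRNA distribution is not identified by the experimental
design beyond its peak; a discretized unimodal kernel (geometric decay per
fraction of distance from the peak, non-engaged mass split equally between B
and C) is a modeling convenience. Its decay default, 0.55, was chosen on an
identifiability argument: per-fraction recovery draws are shared across
genes, so if the kernel is too flat, one unlucky recovery draw can flip the
apparent peak of *every* heavily loaded gene to an adjacent fraction at
once; at 0.55 the peak-versus-neighbour gap exceeds the typical
three-replicate-average recovery distortion while the per-fraction abundance
means stay in a realistic range. One functional category is given a known
positive effect so the qualitative model term is exercised.

What the generator does **not** emulate: spot-level image artifacts,
background subtraction and gridding (intensities are post-background);
print-tip or spatial effects; polycistronic coupling between genes;
sequence-driven correlations among features (features are independent given
the configured effects); peak shapes in the absorbance trace beyond
Gaussians. Passing the round-trip and recovery tests therefore shows the
*pipeline algebra* is right and the estimators are consistent under
realistic noise — not that real arrays meet these assumptions.

## Numerical choices and degenerate inputs

- Proportion vectors must sum to 1 within 1e-9; post-correction replicate
  agreement is asserted at 1e-8; exact log-linear calibration recovery at
  1e-12.
- Argmax ties in a bootstrap set break toward the lighter fraction,
  deterministically; exact ties in the mean proportions are additionally
  flagged.
- All-zero gene-replicates yield undefined proportions, are excluded from
  the occupancy average, and genes with fewer than two valid replicates get
  no peak.
- Per-gene bootstrap seeds derive from the global seed plus the gene index
  (kept below 2³¹), so assignments are reproducible and independent of
  evaluation order.
- The density filter is strict (`> 100/30` excluded); the boundary case is
  retained.

## Problem sizes in the test suite

Round-trip and conservation checks run on 200–1000 genes × 3 replicates
with 10 000 bootstrap sets; bootstrap-versus-enumeration checks use
2-replicate fixtures with binary-fraction proportions so the enumeration is
exact in floating point; model recovery uses 100 simulated data sets of 814
genes, the complete-case size typical of this design once missing half-life
measurements are dropped. These sizes keep the full suite under a minute of
bootstrap work while leaving Monte-Carlo error well below the asserted
tolerances.

## Known limitations

- The inter-series correction equalizes replicates but cannot identify a
  distortion common to all replicates; absolute occupancies are biased if
  all series share an additive offset.
- Per-fraction mRNA recovery is not correctable by the procedure; it is a
  genuine noise floor for proportion estimates, shared across genes.
- Stepwise AIC retains null covariates at the χ² rate discussed above;
  selected models should be read as rankings of evidence, not as consistent
  support recovery.
- Representative ribosome numbers use the midpoint convention; per-replicate
  averaging would shift heavy-fraction densities by a few percent.
- Density ignores 5'UTR length, overestimating loading for short genes —
  the reason the 3.33 filter exists.
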