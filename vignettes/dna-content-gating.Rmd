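---
title: "DNA-content gating and reference-cell calibration for the comet assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-content gating and reference-cell calibration for the comet assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometcal)
```

## The measurement model

In the comet assay, single cells embedded in agarose are lysed and
electrophoresed; fragmented DNA migrates out of the nucleoid "head" into a
"tail", and the gel is stained with a fluorescent DNA dye. Image-analysis
scorers report, per comet, a damage metric — Tail %DNA (TD, the percentage
of the comet's fluorescence located in the tail) or Tail Moment (TM, tail
fraction times a tail-length measure) — and the total fluorescence
intensity (TFI), the integrated background-subtracted staining signal.

cometcal is built on a single physical premise: *as long as staining and
imaging are unsaturated, TFI is proportional to the DNA mass of the cell*,
whether or not the cell is damaged. Migration redistributes fluorescence
between head and tail; it does not change the total. DNA mass differs
between cells by ploidy (1n spermatids vs 2n somatic cells vs 4c premeiotic
spermatocytes in a testicular suspension) and by species genome size
(turbot erythrocytes at 0.86 pg per haploid genome vs human cells at
3.50 pg), so comets can be *gated* on the TFI axis into biologically
meaningful classes, and damage can then be summarized class by class. The
package's image-simulation module exists purely to exercise this premise at
toy scale: it renders comets with known DNA signal and damage fraction,
quantifies them blind to the ground truth, and checks that recovered TFI is
linear in DNA content — and that a saturating detector destroys that
linearity, which is why the premise fails for overexposed images.

## Gating by TFI

`classify_by_tfi()` applies fixed thresholds with a left-closed,
right-open interval convention `[c1, c2)`: a comet exactly on a cut point
belongs to the interval above it, deterministically. The conventional
three-line gate for human testicular suspensions (350 000 / 600 000 /
950 000 a.u.) is interpreted as *two* class-separating cuts plus an *upper
exclusion bound*: three lines cannot separate exactly three classes, and
the brightest objects (doublets, debris, saturated blobs) are better
excluded than assigned, so the default `overflow_policy` is `"exclude"`.
Users who prefer the alternative reading can pass `"assign-top"`.

`find_thresholds()` derives cuts from the data. The `"mixture"` method
fits a Gaussian mixture with unequal variances to log(TFI) — intensities
are positive and right-skewed, and on the log scale a constant staining
coefficient of variation becomes a constant SD — by
expectation-maximization (convergence tolerance 1e-8 on the log-likelihood,
at most 500 iterations). Initialization matters more than the EM itself on
ploidy data, where the haploid class can outnumber the 4c class three to
one: we start from the moments of both a quantile split and an equal-width
split of log(TFI), plus seed-controlled jittered restarts, and keep the
best likelihood. Component counts 1..k are compared by BIC; if BIC prefers
fewer than the requested k, the function raises a degenerate-separation
error rather than returning cuts through a single mode — a forced split of
one tight mode would otherwise *increase* the likelihood and silently
produce nonsense gates. Cuts are placed where adjacent components have
equal posterior probability (solved analytically as a quadratic, with a
density-valley fallback). The `"valley"` method is the non-parametric
alternative: a kernel density estimate of log(TFI) (Silverman's bandwidth,
512-point grid) with cuts at the deepest minima between the k highest
modes. Both methods append an upper exclusion cut at the 99.5th TFI
percentile by default, mirroring the three-line convention.

`compare_class_damage()` asks whether mean damage differs between gated
classes using the maximum absolute pairwise difference of class means as
the statistic and a label-permutation null. The +1-corrected p-value
`(1 + #{permuted >= observed}) / (1 + N)` is never exactly zero; when the
number of distinct relabelings is small the test enumerates all of them
and is exact.

## Internal reference cells

Absolute TFI drifts between experiments with lamp intensity and staining
efficiency, so a threshold learned in one experiment does not transfer.
Mixing small-genome fish erythrocytes into the gel provides an internal
standard: in a turbot/human mixture the two TFI distributions are so far
apart (expected ratio = ratio of diploid DNA masses = 7.0/1.72 ≈ 4.07)
that an interval of intensities contains no comets at all.

`find_gap()` finds that empty interval by scanning adjacent gaps in the
sorted TFI values, ignoring the outermost 1% on each side so a lone
outlier can neither fabricate nor destroy a gap, and requiring the gap to
exceed 5% of the trimmed TFI range. Failure is an explicit error: it is
the signature of a reference genome too close to the sample's (rainbow
trout, 2.4–2.7 pg, against human 3.50 pg — a 1.4-fold expected ratio —
produces one merged cloud). `check_separability()` warns below a 2-fold
expected ratio for the same reason. The reference population is assumed to
sit *below* the gap by default, but that is a parameter: a future
reference species could be larger-genomed than the sample.

`normalize_intensity()` multiplies every TFI by
`target_reference_median / median(reference TFI)`. The median, not the
mean, so that a handful of heavily damaged or atypical reference comets
cannot skew the factor; one scalar factor, so every intensity ratio in the
dataset is preserved exactly and gates transfer across experiments after
normalization.

## Dose–response calibration

`summarize_dose_series()` collapses a labeled dose series to one point per
(population, dose) — the mean TD by default (the median is available; both
are supported because summary conventions differ between reports), with
cell count and SD. `fit_linear()` then fits ordinary least squares of the
damage center on dose, *after excluding* dose points whose center exceeds
the assay's dynamic range, 80 %TD by default: above that level most of the
DNA is already in the tail and damage no longer responds linearly to dose,
as seen at 15 Gy in irradiated human lymphocytes. The cutoff applies to
the per-dose center, not per cell, because it describes saturation of the
population response; excluded doses are listed on the returned curve. The
fit is unweighted by default (the per-dose SDs are similar in practice and
the historical fits were unweighted); inverse-variance weighting is one
argument away.

`gy_equivalent()` inverts the calibration, flooring at 0 Gy and refusing
values beyond the dynamic range rather than extrapolating.
`lesions_from_gy()` converts dose-equivalents to lesion counts only with
an explicit, user-supplied lesions-per-Gy yield — the package bundles no
constant because the yield depends on the lesion type and assay
conditions. `slope_per_genome_mass()` divides a curve's slope by the DNA
mass per cell: fish cells accumulate less damage per Gy roughly in
proportion to their smaller DNA target, and per-mass slopes put the two
populations on a common footing. `tfi_dose_invariance()` is the matching
QC check: median TFI should be flat in dose (the package reports the
relative slope per Gy with a bootstrap interval); a trend flags staining
drift or saturation, not biology.

## What the synthetic data emulate

The generator exists so every stage is testable without any deposited
data; its defaults *are* the study conditions the analysis targets.

* **TFI**: lognormal per population, geometric mean = `tfi_scale`,
  coefficient of variation 0.15, truncated at ±3 log-SDs. Truncation makes
  inter-population gaps *exact zeros* rather than asymptotic ones, so gap
  tests assert equality, not probability. The 0.15 CV reproduces visually
  distinct ploidy modes of the kind scorers actually gate on.
* **Testicular fixture** (`simulate_testicular()`): three populations
  (1n/2n/4c) at geometric-mean TFI 255 000 / 471 000 / 761 000 a.u. and
  proportions 59.4 / 23.5 / 17.2% (normalized to sum to one — as published
  they sum to 100.1%). Class counts are apportioned exactly by largest
  remainder: n = 1600 always yields 949/376/275 comets, n = 100 yields
  59/24/17, so fixture composition is deterministic and the only
  between-seed variability in gated proportions is boundary
  misclassification (a few cells per class).
* **Damage**: expected TD(d) = 100·(1 − exp(−(b0 + β·d))) with
  b0 = −ln(1 − baseline/100) — linear at low dose, saturating toward 100%.
  Per-cell TD is beta-distributed on [0, 100] around the expectation
  (concentration `cell_dispersion`), so the [0, 100] invariant is
  structural, never clipped. TM is emitted as
  `tm_tail_scale · TD² / 100` — tail fraction times a tail length growing
  with TD — with the scale calibrated analytically so the expected
  control-cell TM is 2.35, the middle of the 2.2–2.5 band reported for
  undamaged testicular classes; the testicular control model uses
  `cell_dispersion = 600` (control TD spread under 1 point) so the
  smallest class's mean TM stays inside that band at fixture size.
* **Mixture dose series** (`simulate_mixture_dose_series()`): turbot FE
  and human PBMN mixed 1:1 across doses 0/1.5/3/6/8/10/15 Gy, 100 cells
  per population per dose (the conventional two-gels-of-fifty scoring
  depth). Geometric-mean TFI is 25 000 a.u. per pg of diploid DNA mass —
  chosen once so the truncated supports end below 70 000 and resume above
  100 000 a.u., reproducing the observed empty interval, with the FE/PBMN
  median ratio pinned to the 4.07 genome-mass ratio. The PBMN damage rate
  is solved so expected TD reaches 85% at 15 Gy (inside the saturation
  regime, past the 80% dynamic range); the FE rate is the PBMN rate scaled
  by the diploid genome-mass ratio 1.72/7.0, the smaller-target argument.
  TFI is dose-independent by construction.

What the generator does *not* emulate, and what passing tests therefore do
not show: scorer-specific noise signatures and head/tail split algorithms,
inter-gel electrophoresis gradients, storage-induced damage accumulation
in frozen fish cells, cell-cycle substructure within a ploidy class, and
any TD↔TM conversion (none is defined here; the two metrics are generated
jointly but analyzed as alternatives). Real-data thresholds remain an
experiment-level property — that is the point of the reference cells.

## The image simulator

`render_comet()` draws one comet: an isotropic Gaussian head (SD 1.6 px)
integrating to (1−f)·D and a one-sided exponential tail (decay length
80 px) along +x integrating to f·D, both integrated analytically per pixel
and renormalized on the 96×384 grid so the noise-free,
background-subtracted pixel sum equals D to machine precision. Optional
constant background, Poisson shot noise, and a saturation ceiling
(clipping) complete the model. The head is kept compact relative to the
tail decay so the column-profile peak stays on the head center even at
damage fraction 0.8; with a broader head the tail plateau shifts the
apparent peak and the fixed split rule below under-counts tail mass.

`quantify_comet()` sees only pixels (handed a full image object, it strips
everything but the pixel matrix). Background is the median of the
outermost 2-pixel border; the object mask is pixels above background plus
3 border-MADs; TFI is the masked, background-subtracted sum. The head
center is the column-profile peak; the head SD is estimated by
interpolating the one-sigma quantile of the left (tail-free) cumulative
flank — a second-moment estimate is biased several percent low by pixel
discretization — and the head/tail split sits at the center plus two
estimated SDs. These are documented conventions of a deliberately simple
scorer, not a claim of equivalence to any commercial algorithm.

## Numerical choices and degenerate inputs

* Ties at a cut point follow the interval convention, never randomness.
* EM: tolerance 1e-8 on log-likelihood, max 500 iterations, SD floor 1e-6,
  component death (weight < 1e-8) discards the restart.
* Permutation p-values carry the +1 correction; exhaustive enumeration is
  used automatically when feasible (n ≤ 12 labels).
* A TFI of exactly 0 is an invalid record (no stained object), not an
  undamaged cell; optional fields are stored as missing, never as 0.
* Invalid table rows are either fatal (`policy = "reject"`) or dropped
  with an exact per-row log (`policy = "drop"`); nothing is silently
  filtered, and no comet is ever excluded for being too dim or too bright.
* Degenerate situations raise classed conditions
  (`cometcal_no_gap_error`, `cometcal_degenerate_separation_error`,
  `cometcal_insufficient_points_error`, ...) so pipelines can branch on
  them.

## Problem sizes

The test suite and the acceptance script run at the fixture sizes above:
1600-comet testicular fixtures, 1400-comet mixture series (100 cells per
population per dose), 10^5 comets for the proportion-convergence check,
25–50 seeds for parameter-recovery checks at 100 cells per dose, and
single 96×384 images. These sizes match the scoring depth of the emulated
experiments; everything completes in well under a minute per module on a
laptop.

## A worked pass through the pipeline

```{r pipeline}
testis <- simulate_testicular(1600, seed = 1)
th <- threshold_set(c(350000, 600000, 950000), c("1n", "2n", "4c"))
class_summary(classify_by_tfi(testis, th), damage_metric = "tail_moment")

mix <- simulate_mixture_dose_series(seed = 1)
gate <- find_gap(mix)
gate
parts <- split_reference_sample(mix, gate)
parts$reference$class_label <- "FE"
parts$sample$class_label <- "PBMN"
labeled <- comet_dataset(rbind(as.data.frame(parts$reference),
                               as.data.frame(parts$sample)))
pts <- summarize_dose_series(labeled)
human <- fit_linear(pts, population = "PBMN", genome_mass_pg = 3.50)
fish <- fit_linear(pts, population = "FE", genome_mass_pg = 0.86)
human
fish
gy_equivalent(30, human)
slope_per_genome_mass(human) / slope_per_genome_mass(fish)
```
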