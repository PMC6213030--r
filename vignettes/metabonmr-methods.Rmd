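---
title: "Models and methods behind metabonmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabonmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

metabonmr implements the standard comparative ¹H-NMR metabolomics chain
for a two-group microbial study — preprocessing, discriminant modelling
with resampling validation, STOCSY, univariate selection, and
correlation networks — together with a synthetic-cohort generator that
provides ground truth for every stage. This vignette records the models,
the tunable parameters and their defaults, the numerical choices, and
the design decisions taken where the problem left the design open.

## The synthetic cohort: what it emulates

The generator mimics a study in which one terrestrial and three marine
bacterial strains are each cultured in six replicate flasks and profiled
by 1D ¹H NMR, giving 6 terrestrial versus 18 marine samples. Its
components:

* **Peak library.** ~50 metabolites, each with 1–4 Lorentzian
  resonances (half-width at half-maximum 0.003 ppm) placed in
  δ 0.65–9.50 excluding the water window (4.70, 5.10). Extra peaks of a
  metabolite sit either within ±0.03 ppm of an anchor (a multiplet) or
  elsewhere (a second proton group). The Lorentzian is the natural NMR
  lineshape; 0.003 ppm makes a peak span a few 0.015-ppm bins, as in
  practice at high field.
* **Concentrations.** Per-metabolite baseline means are log-normal
  (sdlog 0.4) around 1; within-group variation is log-normal with
  CV 0.15. Concentrations are positive and biological variation is
  multiplicative, hence the log-normal choice. The study this design
  mirrors does not report a within-strain variance, so the CV is a free
  simulator parameter, chosen once as a realistic replicate-culture
  spread, not an estimate of any real study's variance.
* **Planted effects.** log₂FC of the marine group relative to the
  terrestrial group; the default plants |log₂FC| = 1 on 10 of 50
  metabolites (5 up, 5 down). The differential set in the ground truth
  is exactly the metabolites with non-zero planted effect.
* **Nuisance processes.** Per-sample dilution ~ U(0.5, 2)
  (multiplicative, what PQN must undo); per-peak chemical-shift jitter
  ~ N(0, 0.001 ppm); additive Gaussian noise (sd 0.005); a slow
  sinusoidal baseline (amplitude 0.01, random phase); and a broad
  residual-water Lorentzian at 4.90 ppm (half-width 0.08 ppm, random
  amplitude per sample) that exists so water exclusion is meaningfully
  tested. The water artifact deliberately does **not** scale with
  dilution — it is a solvent feature, not an analyte.
* **Axis.** 16 384 uniform points over δ 0.65–9.50, fine enough that
  binning rather than discretization dominates.

What it does **not** emulate: J-coupling evolution, relaxation, field
inhomogeneity, phasing errors, 2D spectra, or vendor raw formats. Peak
positions are fixed per library rather than pH-dependent. Passing tests
on this generator therefore demonstrates the statistical machinery and
the preprocessing contracts, not robustness to every artifact of real
spectrometers.

## Preprocessing

**Referencing and alignment.** `reference_to_tsp()` shifts the axis so
the maximum in a window around 0 ppm (the TSP methyl singlet) sits at
exactly 0.00. `align_spectra()` applies one global integer-point shift
per spectrum, chosen to maximize cross-correlation with the point-wise
median spectrum, bounded by ±0.03 ppm. Segment-wise alignment
(icoshift-style) is intentionally out of scope: a single global shift is
transparent, and the binning step absorbs residual sub-bin
misalignment.

**Baseline correction.** `baseline_correct()` implements asymmetric
least squares: minimize Σ wᵢ(yᵢ−zᵢ)² + λΣ(Δ²z)² with w = 0.001 above
the curve and 0.999 below, so the smooth curve hugs the signal floor.
The estimate runs on an 8× mean-decimated copy (λ = 1e5 on that grid)
and is interpolated back; baselines are slow features, so decimation
costs nothing and keeps the solve linear-time. Correction matters
beyond aesthetics: an uncorrected additive baseline, divided by each
sample's normalization factor, becomes a shared per-sample component
that biases quotient estimates and induces spurious inter-bin
correlations.

**Binning.** Uniform 0.015-ppm bins over δ 0.65–9.50, half-open
[low, high) so every axis point belongs to exactly one bin; a point at
exactly the upper range edge belongs to none, and the conservation
property (cells of a row sum to the spectrum total) is stated over
[0.65, 9.50) accordingly. 8.85/0.015 gives exactly 590 bins. Bins whose
center falls strictly inside an excluded region are dropped — the water
window removes 27 bins, leaving 563. Exclusion happens **before**
normalization so the artifact never influences quotients. "Average
width 0.015 ppm" is implemented as exactly uniform width; no adaptive
bucketing rule was available to implement. The internal axis is stored
ascending; the NMR display convention (descending) is applied only in
plots.

**Quotient normalization.** `pqn_normalize()` follows the standard
procedure: (1) scale each row to total area 100; (2) reference = per-bin
median over rows (overridable); (3) per-row quotient = median of
row/reference; (4) divide the row by its quotient. Two reported
quantities deserve care: `quotients` is the median fold change of step
(3), and `dilution_factors` is the full original→normalized scale
(area factor × quotient), which is the quantity proportional to the
physical dilution. One deliberate refinement: the step-(3) median is
taken over the signal-carrying bins (reference at or above the median of
its positive values, `ref_quantile = 0.5`) rather than all
positive-reference bins. Bins in the noise/baseline floor carry no
dilution information, and with a residual baseline present the all-bins
median tracks baseline-over-dilution instead of dilution; filtering to
signal bins is the practical remedy and `ref_quantile = 0` restores the
unfiltered behavior. On noise-free cohorts the recovered factors are
proportional to the planted dilutions to ~1e-7 relative; a second
normalization pass leaves no residual dilution structure (the area step
inside the procedure means second-pass median quotients are not
literally 1, so idempotence is stated — and tested — on the total
factors).

**Scaling.** `pareto_scale()` centers each column and divides by the
square root of its sample standard deviation (n−1 denominator) — the
chemometrics compromise that keeps large peaks influential without
letting them drown small ones. Zero-variance columns are centered only
and flagged, never divided. Means and standard deviations are stored so
the transform is exactly invertible (`pareto_unscale()`).

## Multivariate models

**PCA** is the singular value decomposition of the scaled matrix;
explained fractions are d²/Σd². Component signs are fixed by making the
largest-magnitude loading entry positive, so results are reproducible
across BLAS implementations.

**PLS-DA** is NIPALS PLS1 against the centered class indicator
(terrestrial = 0, marine = 1), deflating X by t·pᵀ per component. For a
single response the weight update is a fixed point after one pass; the
loop still checks convergence (tolerance 1e-12, max 500 iterations) and
errors naming the component if a degenerate weight or null score vector
appears. R²Y = 1 − SS_res/SS_tot of y is non-decreasing in components
by construction. Two components are the default, matching the
two-dimensional score plots such studies present.

**Q²** uses stratified k-fold cross-validation (default 7-fold, the
common chemometrics choice; the fold count must lie in [2, 2·min group
size]). Folds are assigned round-robin within each shuffled group, which
guarantees every training split contains both classes whenever each
group has ≥ 2 samples. Centering and Pareto scaling are re-estimated on
each training split only — no information from held-out samples leaks
into the scaling. Q² = 1 − PRESS/TSS with PRESS pooled over folds.

**Permutation test.** Labels are permuted uniformly (default n = 200);
R²Y (full fit) and Q² (cross-validated) are recorded per permutation,
and the empirical p on Q² is (1 + #{Q²_perm ≥ Q²_obs})/(n + 1) — Q²
rather than R²Y because Q² is the overfitting-sensitive statistic. On
null cohorts the p-value is approximately uniform; on the default
planted cohort it reaches the resolution floor 1/(n+1).

**Loading profile and selection.** Per bin, the back-scaled loading is
the covariance of the (scaled) bin with the first latent-variable
scores, sign-oriented so positive means higher in the terrestrial
group; the color dimension is |r|, the absolute Pearson correlation of
the bin with the class indicator. Bins are significant at the exact
critical correlation r = t/√(t² + df) with df = n − 2 (≈ 0.404 at
n = 24, α = 0.05) — a standard choice, recorded as an assumption since
no selection rule is prescribed by the kind of study this mirrors.
Metabolite-level significance uses each metabolite's maximum-|r|
annotated bin.

**STOCSY** correlates a driver bin (nearest kept bin center to the
requested ppm; drivers inside an excluded region are an error) against
all bins. Resonances of one molecule share a concentration and
correlate near 1; independent metabolites correlate near 0 after proper
normalization.

## Univariate selection

Per metabolite, Shapiro–Wilk runs on each group; both must pass at
α = 0.05 for the two-sided t-test, otherwise the Mann–Whitney U test is
used. Numerical choices: the t-test is Welch's (unequal variances — a
safer default than the pooled-variance form); the Mann–Whitney always
uses the tie-corrected normal approximation with continuity correction,
so tied data are handled uniformly and identical groups give p = 1;
constant groups, where Shapiro–Wilk is undefined, are routed to
Mann–Whitney since normality cannot be affirmed. Fold change is the
ratio of group means, marine over terrestrial, computed on normalized
**unscaled** integrals (Pareto scaling destroys ratios). Adjustment is
Benjamini–Hochberg. Selection requires p < 0.05 AND (FC > 1.5 or
FC < 0.67); raw p is the default criterion with `use_adjusted_p`
exposing the stricter alternative, since the two conventions coexist in
practice. The fold-change plot's dashed guides at FC ∈ {0.8, 1.2} and
{0.5, 2.0} (20% and 100% variation) are annotations, not selection
criteria.

## Quantification and its limits

`quantify_metabolites()` sums the bins whose centers fall in a
metabolite's integration windows. For synthetic cohorts,
`annotation_from_truth()` picks each metabolite's **least contaminated**
resonance: the expected foreign Lorentzian integral inside the window
(weighted by concentration × height) divided by the peak's own integral,
minimized over the metabolite's peaks — the algorithmic version of an
analyst choosing an isolated peak to integrate. At the default library's
peak density (~107 peaks over 8.45 ppm) some metabolites have no clean
resonance; their measured fold changes are attenuated toward 1 by
overlap, which is an inherent property of window integration in crowded
regions, not of the statistical machinery downstream. Differential
recovery of the testing machinery itself is therefore assessed on the
cohort's ground-truth concentration table (the "ready table" route),
where sensitivity for |log₂FC| = 1 at CV 0.15 and n = 6 vs 18 is
essentially 1; the spectral route typically recovers 7–10 of the 10
planted effects per cohort.

## Networks

Correlations are computed per group (a marine network uses marine
samples only). Edges require strictly |r| > 0.6; the sign is kept as an
edge attribute (the warm/cool encoding), weight is |r|, nodes carry
log₂FC. Constant metabolites yield undefined correlations, recorded as
0 and flagged. A caveat worth stating: at n = 6 per group, |r| > 0.6 is
not statistically significant at α = 0.05 — the threshold is
descriptive, and the network comparison (exclusive edges, sign flips)
should be read as exploratory. The characteristic set is the plain
intersection of the PLS-DA-significant and univariate-differential
metabolite sets, sorted by name for stability.

## Pipeline, reproducibility, problem sizes

`run_pipeline()` executes simulate/ingest → preprocess → PCA → PLS-DA
(+ permutations) → quantify → univariate → intersection → networks. One
master seed is split deterministically into per-stage seeds, so the
simulation, the fold assignment and the permutations are independently
reproducible. Every CSV/JSON output carries the configuration hash; two
runs with the same configuration and seed are byte-identical, with the
single exception of `run.log`, which records wall-clock timings. Config
files are YAML (JSON accepted) with every threshold surfaced.

The tests and the acceptance script run at the study's own scale —
24 samples × 563 bins, 16 384-point spectra, 200 permutations, and 20
replicate simulations where a criterion is an average over seeds —
chosen as the smallest sizes at which the design's claims are
meaningful. Degenerate inputs are handled explicitly throughout:
zero-variance columns are flagged and not divided, flat TSP windows
warn rather than divide by zero, fully tied rank tests report p = 1,
constant metabolites get r = 0 with a flag, and a training fold with a
single class is an error rather than a silent misfit.

## Known limitations

* Global (not segment-wise) alignment; severe local shift drift would
  require icoshift-style methods.
* Window integration cannot deconvolve overlapped resonances; crowded
  regions attenuate fold changes (see above). Curve-fitting
  quantification is out of scope.
* The permutation p cannot go below 1/(n_permutations + 1).
* PQN assumes a majority of non-differential signal bins; massively
  asymmetric perturbations would bias any quotient method.
* The generator's nuisance amplitudes (noise, baseline, jitter) are
  plausible but synthetic; absolute performance numbers transfer to
  real data only qualitatively.
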