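---
title: "Methods: cardiac cycle, HARP strain, ageing transcriptome and morphometry"
author: "cardioage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac cycle, HARP strain, ageing transcriptome and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioage)
```

`cardioage` packages the quantitative analytics used to phenotype chronic
heart failure and cardiac ageing in mice: cardiac-cycle segmentation of LV
time–volume curves, harmonic-phase (HARP) strain analysis of tagged MRI,
an ageing-gene classification of bulk RNA-seq differential-expression
results, capillary/fibrosis histomorphometry, and the small closed-form
perfusion and enzyme-assay formulas. Every stage has a seeded synthetic
generator that produces inputs with known ground truth, so the whole
pipeline is testable without any imaging or sequencing data.

## Cardiac-cycle segmentation (PLR)

A cycle of LV volumes `V(t)` sampled over one R–R interval (origin at the
R wave, i.e. end-diastole) is modelled as four linear phases: isovolumetric
contraction (IVC), ejection, isovolumetric relaxation (IVR) and filling.
`fit_plr()` searches the three interior knots exhaustively over the sample
grid, solving the least-squares problem for each knot triple in closed form
(C++ backend), subject to the cardiac sign pattern: ejection slope negative,
filling slope positive, isovolumetric slopes negligible. Ties in SSE go to
the earlier breakpoints, which makes the fit deterministic.

Two model variants exist:

* **flat (default)** — the isovolumetric segments are constant-volume
  plateaus. This is the physiological meaning of "isovolumetric", and it
  matters statistically: EDV and ESV become plateau levels estimated from
  all plateau samples rather than extrapolated segment endpoints. With free
  plateau slopes, the SSE-optimal fit under realistic noise (~1 µl on a
  45 µl stroke volume) tilts the plateaus and biases EF by up to ~3 points;
  the flat model keeps the worst-case EF error under 2 points across 100
  simulated cycles while recovering every breakpoint within one frame.
* **free** — general continuous piecewise-linear slopes, with the
  isovolumetric magnitudes capped at `max_isovol_ratio` (default 0.1) times
  the smaller of the ejection/filling magnitudes.

After the grid search a Nelder–Mead polish optimises the knot times
continuously (infeasible proposals score infinity, so the polish can only
improve the fit). The grid-monotonicity property — SSE non-increasing under
candidate-grid refinement — applies to the raw grid search and is tested
with `refine = FALSE`.

Derived indices follow the standard formulas: `SV = EDV − ESV`,
`EF = 100·SV/EDV`, `CO = SV·HR`, `CI = CO/BSA`. The body-surface area uses
the Meeh allometry `BSA = k·m^(2/3)` with `k = 9.8 cm²/g^(2/3)` by default;
the convention is overridable (`subject_meta()`), and with it a cardiac
output of 18.3 ml/min at 26.1 g body mass yields a cardiac index of
~212 µl/min/cm², consistent with published murine cohort means. Ejection and
filling rates are the PLR slopes normalised to SV and R–R
(`ER = |s_ej|·RR/SV`), which makes them dimensionless and invariant to
volume and time units. The four phase durations are breakpoint gaps in % of
R–R and always sum to exactly 100.

**Biphasic filling.** The generator's optional biphasic filling consists of
three ramps — early (E) filling at `e_peak`, a low-rate diastasis, then
atrial (A) filling at `a_peak`. A two-ramp E→A shape was rejected because
its dV/dt has no valley between the two plateaus, making the A wave's
topographic prominence identically zero — no peak detector can then
distinguish E/A from fused filling. `ea_ratio()` finds the two most
prominent dV/dt maxima in temporal order (plateau-aware, with signal edges
treated as non-constraining so terminal plateaus keep their prominence) and
flags fusion when fewer than two peaks clear the prominence threshold
(default 5% of the dV/dt range), mirroring the convention of reporting "/"
for fused filling. `FR` uses the steepest filling sub-slope when an up-to-
two-knot refit of the filling samples at least halves the single-ramp SSE.

```{r plr-example}
sim <- sim_time_volume_curve(cycle_sim_config(noise_sd = 1, seed = 7))
fit <- fit_plr(sim$tvc)
tidy(fit)
derive_indices(sim$tvc, fit, subject_meta(body_mass = 26.1))
```

## HARP strain from tagged MRI

The tagged phantom reproduces a murine SPAMM protocol: 30 × 30 mm field of
view, 192 × 192 matrix, square tags of 0.6 mm span and 0.2 mm line width —
50 tag periods across the FOV, i.e. ~3.8 pixels per period. The tag grid is
the product of two periodic line profiles. The profile is the raised-cosine
squared pulse *truncated to its first Fourier harmonic by default*: at this
sampling density an MR acquisition resolves only the fundamental, and
evaluating the full pulse analytically at pixel centres would alias its 3rd
and 5th harmonics straight into the HARP band-pass (the folded 3rd harmonic
lands at 42 cycles/FOV at half the main peak's magnitude — an artefact no
scanner would produce). `n_harmonics` can be raised for coarser tags.

Deformations are specified by their spatial→material map about the image
centre (identity, rigid translation, Cartesian stretch, or an analytic
radial profile), ramped linearly over the frames so frame 0 is always the
reference grid. Folding (non-positive Jacobian, or a non-monotone radial
map — a pure determinant test misses radial reflections) is rejected.

`harp_phase_maps()` isolates, per tag direction, the first harmonic peak
nearest the nominal wavevector (±20%, with a 5× spectral-background
detection floor), applies a raised-cosine annular band-pass of radius half
the DC-to-peak distance, and takes the phase of the inverse FFT. Both the
`+k` and conjugate `−k` peaks are filtered; `strain_field()` averages their
phase gradients (the peak-combination step), which cancels any asymmetry of
the band-pass window. Gradients use wrap-aware one-pixel differences (each
one-pixel phase step stays below π for stretches in [0.8, 1.9] at this
geometry). Stacking the two directions gives `∇Φ = 2π K F⁻¹`; the tag
wavevector matrix `K` is calibrated from the frame-0 mask-mean gradients,
which forces zero strain on the reference frame and absorbs FFT-bin
quantisation. Radial and circumferential engineering strains are
`√(eᵀ(FᵀF)e) − 1` (×100%) along the polar unit vectors about the LV centre.
Pixels where `|det F|` leaves `[0.2, 5]` on more than 10% of the mask raise
an unreliable-deformation warning.

`segment_strain_curves()` averages the maps over eight 45° sectors
(sector 1 starting at the anterior reference angle, 90° by default,
counterclockwise); empty sectors are flagged and excluded from the global
average. `strain_indices()` reduces one segment-averaged curve to the
scalar indices: peak-systolic, end-systolic and post-systolic strain, the
post-systolic strain index `PSI = (Epost − Ees)/Emax`, time-to-peak
`TpeakSI = Tpeak/RR`, systolic stretch (the maximal opposite-sign systolic
excursion), and the systolic/early/atrial strain rates from centred finite
differences in cycle-fraction units. The post-systolic search window is
closed at end-systole so that a curve peaking exactly at end-systole has
`Epost = Ees` and `PSI = 0`. End-systole defaults to the time of the
absolute strain extremum when no cycle fit is supplied. Where a reference
did not pin down an exact formula (the peak-combination scheme, `Emax`
within PSI, the systolic-stretch definition), the choices above are this
package's operationalisation and are exercised against a brute-force oracle
in the tests.

## Ageing transcriptome analytics

Counts are TMM-normalised via edgeR (published defaults; factors rescaled
to geometric mean 1) and converted to cpm against factor-adjusted library
sizes. The coverage filter retains genes with cpm > 0.5 in **strictly more
than 3** samples of at least one genotype × age group — the most literal
reading of the rule; both threshold and group definition are configurable.

The DE engine is intentionally simple: logFC as the difference of group
means of `log2(cpm + 0.5)` (the 0.5 offset avoids log 0), two-sided Welch
t, BH adjustment within the comparison, and the strict DEG rule
`|logFC| > 1` **and** adjusted p `< 0.05`. Reproducing empirical-Bayes
moderation is out of scope; the classification layer consumes any table
with the DEG columns, so externally produced DE results can be slotted in.

The classification itself: with `DEG(a)` the wild-type DEG set of age *a*
versus 4 months,

* genes of the **aged** heart = `DEG(14) \ ∪ DEG(6..12)`,
* genes of the **ageing** heart = `DEG(14) ∩ ∪ DEG(6..12)`,
* **cardiac-ageing genes** = their union = `DEG(14)`.

Disjointness and the union identity are asserted on every call. The same
classifier applies verbatim to over-represented process term ids per age
group. `contribution_fraction()` reports the share of a transgenic-vs-wild-
type DEG set that is cardiac-ageing. Over-representation uses the one-sided
Fisher exact (hypergeometric upper-tail) test against the filtered
background with BH correction; the significance flag applies to adjusted
p-values by default (`adjust = FALSE` switches to raw p, since the
published wording is ambiguous). PCA rank-normalises each gene across
samples (mid-ranks, `qnorm((r − 0.5)/n)`, then z-scoring) before the SVD,
making scores invariant to any monotone transform of the data.

The count generator plants four disjoint signature kinds (aged-only,
ageing with staggered onset ages, persistent and age-specific
heart-failure effects) in NB counts with `variance = mean + φ·mean²`.
Planted genes receive a baseline-expression floor (`planted_min_cpm`,
default 5 cpm): a differential signature planted below the detection floor
is not a recoverable ground truth, because the `log2(cpm + 0.5)` offset
compresses any fold change there below the DEG criterion. The default
design (54,532 genes; both genotypes at 4–14 months in 2-month steps; n = 5
per group) mirrors the sequenced-cohort structure; the per-group n is a
modelling choice, as the published design does not state it for all 50
samples.

## Histomorphometry

`extract_components()` labels 8-connected components (EBImage's 4-connected
labelling plus a diagonal union-find merge), derives ellipse-equivalent
axes from second central moments (axis length = 4√eigenvalue), and
classifies the sectioning orientation by aspect ratio: < 1.5 transverse,
1.5–3 oblique, ≥ 3 longitudinal. These thresholds are this package's
operationalisation of the visual classes and are exposed as arguments.
Lumens come from an explicit lumen mask (a blob belongs to the unique wall
component enclosing it) or from enclosed background holes. The nearest-
capillary statistic is the mean over oblique/transverse components of the
minimal edge-to-edge boundary-pixel distance to any other such component —
gap distance, not centroid distance (switchable in principle; centroid
distances are derivable from the component table). Fibrosis is
`100·collagen/(collagen + myocardium)` by pixel counts.

The mask generator places non-overlapping ellipses (conservative
bounding-circle rejection sampling with bounded retries), draws aspect
ratios per orientation class, and paints collagen by thresholding a smooth
value-noise field, then flips individual pixels to hit the target fraction
to within one pixel — so collagen-recovery checks are exact by
construction.

## Assay formulas

`fit_kinetic_slope()` is ordinary least squares on a fluorescence–time
trace (optional curvature-based linear-range trimming, off by default to
match the plain linear-slope convention).
`ace_activity() = slope/f_1µmol × Y` with dilution factor `Y = 33.33` for
plasma (U/L) and `10` for tissue homogenate (U/g), both overridable; the
fluorescence of 1 µmol converted substrate is an instrument calibration and
therefore a required input. `flow_response()` computes `ΔCF = peak −
baseline` (optionally per gram of ventricle) and coronary reserve
`peak/baseline`, flagging reserve < 1.

## Reproducibility, problem sizes and limitations

All generator randomness derives from one user seed through labelled
substreams (`substream_seed()`), so identical configurations give
byte-identical outputs on any platform. The test suite exercises: 100 noisy
synthetic cycles for PLR recovery; 192² tagged phantoms at stretches
0.85–1.25 and SNR 20; a 4,000-gene, 6-age, n = 5 chain-recovery simulation;
and exhaustive hypergeometric enumeration up to N = 60 — sizes chosen so
the whole suite runs in well under a minute while the recovery claims stay
statistically meaningful.

What the synthetic data does *not* emulate — and what passing tests
therefore do not establish about real data: tag fading and through-plane
motion in tagged MRI (no MR physics is simulated), realistic cardiac
motion beyond analytic deformations, RNA-seq batch/run structure and
gene–gene correlation, stain-segmentation errors upstream of the
morphometry masks, and interactive segmentation of cine MRI (volumes are
inputs). The DE engine is a simplified stand-in; absolute DEG counts from
moderated pipelines will differ, which is why the classification layer
accepts external DEG tables.
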