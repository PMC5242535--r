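---
title: "Models and methods behind hdpheno"
author: "hdpheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hdpheno re-implements the computational battery of a longitudinal mouse
phenotyping study — serial T2-weighted MRI, tensor-based morphometry,
stereology, threshold densitometry and the accompanying cohort statistics —
on top of a synthetic-data layer with exact ground truth. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic validation does and does not demonstrate.

## Coordinate and array conventions

Images are plain R arrays indexed `[x, y, z]`, 1-based, column-major; world
coordinates are `(index - 1) * spacing` in mm. Displacement fields are
stored in voxel units on the fixed-image grid and warping samples the moving
image at `x + u(x)` (resampling convention). This one convention is used by
every generator and operator in the package; it is the idiomatic choice for
R's native array layout.

## The synthetic cohort

### Anatomy

The phantom brain is an ellipsoidal envelope containing a cortical shell and
four ellipsoidal structures (striatum, hippocampus, corpus callosum,
ventricles), plus a cheek-muscle block outside the brain that serves as the
internal control tissue. The default grid is 64 × 96 × 64 voxels at
0.15625 × 0.15625 × 0.5 mm — the in-plane resolution and slice thickness of
a typical in vivo mouse protocol (156 µm, 0.5 mm slices). Anatomical realism
beyond "disjoint labelled regions of controllable volume" is deliberately
out of scope: every estimator downstream consumes labels, intensities and
geometry, not mouse neuroanatomy.

Regions are rasterised by voxel centre. Scaling a region to a target volume
multiplies its semi-axes by `(V_target / V_ref)^(1/3)`; the cortex is the
exception — its outer surface co-scales with the brain envelope while its
inner surface is derived from the target shell volume, so cortical atrophy
thins the shell rather than shrinking the whole annulus (and the interior
cavity never collapses onto the structures it contains). Overlapping or
degenerate (sub-voxel) region configurations raise errors rather than
silently relabelling.

Per-region absolute volumes are not published as numbers in the source
material, only as figure panels; the defaults (brain 460 mm³, cortex
120 mm³, striatum 16 mm³, hippocampus 14 mm³, corpus callosum 5 mm³,
ventricles 4 mm³) are order-of-magnitude plausible for an adult mouse and
are documented as arbitrary.

### Growth-then-atrophy trajectories

Each region follows

\[
V(a) \;=\; P \cdot \frac{b + (1-b)\,\sigma((a - m)/\tau)}
                        {b + (1-b)\,\sigma((p - m)/\tau)}, \qquad a \le p,
\]

a logistic rise normalised to reach the genotype-specific peak volume $P$ at
the peak age $p$ (36 weeks by default — the age at which wild-type brains
stop growing), followed by a linear decline losing the configured fraction
$d$ of the peak by the final age (94 weeks):

\[
V(a) \;=\; P\left(1 - d\,\frac{a - p}{94 - p}\right), \qquad a > p .
\]

The logistic/linear family is the simplest one that reproduces the
qualitative sequence slower growth → growth arrest → progressive atrophy.
Wild-type regions have $d = 0$; the disease genotype combines a lower peak
(lost growth, `peak_factor` 0.875–0.96 per region) with post-peak declines
calibrated to the phenotype this package emulates: striatum 27%, cortex
12%, hippocampus 21%. Because the genotype gap at the final age compounds
lost growth and atrophy, the cortical WT-vs-HD gap (≈23%) exceeds the
HD-internal 12% decline — a property the tests assert. Ventricles enlarge
in disease (higher peak, no decline); sexes differ by a 6% volume factor.

Behavioural measures follow a wild-type age curve with a genotype deficit
ramping linearly from a per-sex onset age to its final-age value —
locomotor activity 34% (males, onset 38 weeks) and 39% (females, onset 16
weeks), forelimb grip 25%/18%, with the cognitive measures (odor, social)
kept at zero deficit, mirroring the phenotype's motor-selective profile.

### Noise, missingness, outliers

Volumes carry a per-subject multiplicative size factor (log-normal,
CV 4%) shared across ages — the longitudinal design — plus a 1% per-scan
factor and a uniform sub-voxel positioning jitter that also averages away
rasterisation bias (with uniform jitter the expected voxel count equals the
analytic volume divided by the voxel volume). Behavioural values use a 5%
subject factor and 5% residual; these CVs describe a tightly controlled
inbred cohort and are what makes the study-scale design (n = 10 per cell)
recover effect sizes to a few percentage points. Observations go missing
with probability 0.03 and are replaced by ±4 group-SD outliers with
probability 0.01 — large enough that a Grubbs screen has true positives to
find. A ±4 SD shift at n = 10 inflates the within-cell SD, so single-pass
recall sits near 40%, not 100%; that is a property of the test, not a bug
in the screen.

### MR rendering

Voxel signal is `S0(region) · exp(-TE / T2(region))` plus Gaussian (default)
or Rician noise. Defaults: grey-matter structures at T2 45 ms, corpus
callosum 37 ms with S0 chosen so the first-echo white:grey ratio is 1.25,
CSF 120 ms, muscle 25 ms; noise SD is the grey first-echo signal divided by
the target SNR of 5.4. The echo train is `TE · (1:8)` with TE = 10 ms.

### What the generator does not emulate

Partial-volume mixing, bias fields, motion artefacts, anatomically realistic
shapes, repeat-length variation, and any behaviour-level mechanism (the
behavioural tables are draws from parametric curves, not simulations of
behaviour). Passing tests therefore demonstrate that the estimators recover
what they are defined to recover under the stated noise model — not that
they are robust to everything real data contains.

## Relaxometry

`fit_t2_map()` solves the voxel-wise mono-exponential model by log-linear
least squares, which is exact on noiseless data for any T2 in the validity
window (1–2000 ms). Under noise the log transform down-weights the
high-signal early echoes; `refine = TRUE` follows the log-linear initialiser
with a vectorised Gauss–Newton refinement of the true nonlinear
least-squares problem (8 iterations on `(S0, 1/T2)`), which the tests pin
against a dense grid-search oracle.

Validity policy (an open choice documented here): a voxel is invalid when
its *first* echo is non-positive or the fitted T2 leaves the window. At
SNR ≈ 5 the late echoes of short-T2 tissue (muscle, T2 25 ms: the eighth
echo sits at ~4% of S0) routinely dip below zero; requiring all echoes
positive would exclude most muscle voxels and bias the survivors' ROI mean
upward by selection on positive noise. Negative late echoes are clamped for
the log-linear initialiser and used as-is by the refinement. Invalid voxels
are flagged, never zeroed, and `roi_mean_t2()` reports how many it
excluded.

## Registration

### Linear (6 / 9 dof)

Rigid registration parameterises rotation angles and translations about the
image centre; 9 dof adds per-axis log-scales. Although the source protocol
phrases 9 dof as "uniform scaling", nine parameters require three scales;
`uniform_scale = TRUE` collapses the scale block to one factor (7 dof) for
sensitivity analysis. Optimisation is Nelder–Mead over a 2–3 level
multi-resolution pyramid with a polish restart; the tests require 0.5° / 0.1
voxel recovery of known transforms. The rigid family has unit determinant
by construction, so 6-dof resampling never changes volume.

The population template is the iterated register-and-average mean with
drift control: after each cycle the average transform parameters are undone
on the template, so it does not migrate toward any input.

### Intensity scaling

Before matching, images are rescaled by mapping their 1st/99th intensity
percentiles to 0/1. A z-score (the more common default) is *wrong* for this
package's use case: two images whose object occupies different fractions of
the field map the same tissue class to different plateau values, leaving an
intensity mismatch that no deformation can remove — in practice the solver
then distorts geometry to absorb it. Quantile scaling keeps tissue classes
aligned regardless of object size. The `normalise` argument retains
`"zscore"` and `"none"`.

### Viscous-fluid solver

`register_fluid()` implements greedy compositional flow:

1. force: the gradient-normalised (demons) term
   `(f - w) ∇w / (|∇w|² + (f - w)²)`, gated to zero where the residual is
   below a noise floor (2% of the intensity range) or the gradient is
   negligible — ungated, noise-level residuals over near-zero gradients
   produce O(1) spurious velocities in flat regions;
2. velocity: Gaussian smoothing of the force with `sigma_fluid` (default
   2.5 voxels) — regularising the *velocity* rather than the displacement is
   what permits large-deformation, fluid-like behaviour;
3. step: scaled so the largest update is `max_step` voxels (default 0.4),
   composed into the running field (`u ← αv ∘ u`), accepted only if SSD
   decreases (backtracking halves the step otherwise);
4. regridding: when the active increment's minimum Jacobian falls below
   `regrid_jmin` (default 0.5) the increment is folded into a base field
   and reset. The warped image is always resampled from the *original*
   moving image through the composed total field — re-rendering the moving
   image at each regrid would compound interpolation blur;
5. stopping: relative SSD improvement below `tol` for 5 consecutive
   accepted steps, a stalled backtrack, or the iteration budget.

All operators are dimension-generic; 2-D images are first-class, which is
what keeps the registration test suite fast. On the canonical disk pair
(radius 10 template, radius 12 subject) the solver converges in a handful of
iterations and the mean Jacobian inside the template disk reproduces the
analytic area ratio 1.44; the Jacobian integral over the template mask
conserves object area to a few percent.

One caveat the tests make explicit: intensity-driven registration is blind
to displacement in regions without gradients (the aperture problem). The
warp-recovery test therefore uses a smoothed-noise pattern with gradients
everywhere; on flat-interior blobs any such method recovers boundary motion
only.

## TBM statistics

Group differences in Jacobian maps are tested with the unequal-variance
(Welch) t statistic per voxel; Jacobians are analysed untransformed by
default (`log_jacobian` is available). Significance comes from permutation:
genotype labels are shuffled across subjects (optionally within sex
strata), the t map is recomputed, and the absolute null statistics of *all*
voxels are pooled into one null distribution. With V voxels and P
permutations the pool holds V·P values, which is how a desk-scale run
reaches the pooled-null size `ceil(V/q)` that full-scale analyses quote
(42,000 / 0.05 = 840,000) with a modest P. Per-voxel p-values use the
plus-one convention `p = (1 + #{null ≥ |t|}) / (1 + pool)` — never exactly
zero — and Benjamini–Hochberg at level q produces the significance mask,
which is monotone in q. When fewer distinct relabellings exist than
requested, the null is enumerated exhaustively (with a warning), and the
tests check this against brute force.

Pooling assumes the null distribution is exchangeable across voxels; the
false-positive calibration (200 null repeats at 16 × 16 resolution,
any-discovery rate ≤ q plus binomial error) runs at the statistics layer on
smooth-noise maps, where that assumption holds by construction. The
planted-effect check runs the full pipeline — fluid registration of 20 noisy
subjects to a template, Jacobians, pooled-permutation FDR — and requires
Dice > 0.5 against the planted region.

## Stereology

The Cavalieri estimator `V = ΣP · (a/p) · d` and optical fractionator
`N = ΣQ⁻ / (ssf · asf · tsf)` are implemented with explicit design objects;
the standard section design (50 µm sections, 450 µm gap) enters as a 500 µm
period and ssf = 1/10, and the counting design (65 × 35 µm frame,
200/400 µm grids, 18 µm thickness, 0.5 µm guards, 17 µm dissector) is the
default. Samplers apply these designs to planted ground truth — point grids
on analytic ellipsoid cross-sections, half-open counting frames over
uniformly placed particles (each particle counted by its unique point, the
unbiased counting-frame rule) — and the tests verify unbiasedness over
random design phases.

The coefficient of error is Gundersen–Jensen with smoothness class m = 1:
noise variance ΣP, systematic variance
`max(0, (3(A − ΣP) − 4B + C)/240)`. For a constant count sequence this
published formula leaves a small positive systematic term (CE 0.0547 vs the
pure-Poisson 0.05 for four sections of 100); the package reports the
standard formula rather than forcing that term to zero, and the tests
assert the noise-dominated approximation rather than exact equality.

## Histology quantification

Section images are on a 0–255 transmitted-light scale with *low* values
dark. Under this reading the two standard thresholds nest correctly:
nuclear (dense) staining at ≤ 90 is a subset of total aggregated staining
at ≤ 130. The opposite (darkness-value) orientation is retained behind a
flag; applied to the same numeric thresholds it breaks the subset relation,
which `two_level_quantification()` detects and reports as an orientation
error rather than silently returning nuclear > total. Area fractions are
per field of view; tiling into equal fields averages exactly to the
whole-image fraction.

Cortical thickness drops N vertical lines (default 10) across the outer
(pial) boundary's x-range and measures the segment to the inner boundary
(corpus-callosum dorsal horn), averaging over sections (default 3); lines
that fail to intersect a truncated inner boundary are excluded with a
warning.

## Cohort statistics

* **Grubbs** — `G = max|x − mean|/sd` against
  `((n−1)/√n)·sqrt(t²/(n−2+t²))`, `t = qt(1 − α/2n, n−2)`; single pass per
  genotype × sex × age × measure cell by default (iterative behind a flag),
  matching the per-dataset exclusion narrative of such studies. As α → 0
  the critical value approaches the attainable maximum `(n−1)/√n`, and the
  implementation guards that limit so nothing is flagged there.
* **Factorial ANOVA** — least squares with sum-to-zero contrasts and Type
  III sums of squares (`car::Anova`), robust to the unbalanced cells that
  missing data produce; age enters as a categorical between-subject factor
  (the standard workaround when missing values preclude repeated-measures
  ANOVA). On balanced designs Type III reproduces the classical sequential
  decomposition exactly; a constant response returns all-zero F by
  definition.
* **Correlations** — pairwise-complete Pearson with
  `α_adj = 0.05 / choose(k, 2)`: 6 measures → 0.0033, 7 → 0.0024.
* **Post hoc** — pairwise Welch t tests with p multiplied by the number of
  comparisons, capped at 1.

## Problem sizes

The test suite and acceptance script choose sizes that keep every check
meaningful: full-resolution (64 × 96 × 64) phantoms for the effect-size
recovery runs (three seeds × 10 animals per genotype × sex, disease-group
scans rasterised for volumetry); a coarse 40 × 56 × 40 grid for the n = 40
calibration-closure test; 48² images for the registration and TBM pipeline
checks; 16² maps for the 200-repeat FDR calibration. These are the
package's validation conditions, not claims about minimal hardware.

## Known limitations

* The fluid solver is a greedy first-order approximation of fluid
  registration, not a Navier–Stokes solver; it inherits the aperture
  problem of all intensity-driven methods.
* Long T2 (CSF ≈ 120 ms) is poorly conditioned with an 80 ms echo train;
  ROI means there are noticeably noisier than for grey matter.
* The behavioural generator produces parametric group curves; it cannot
  expose analysis failures caused by real behavioural distributions
  (floor/ceiling effects, bimodality).
* Stereology samplers treat particles as points (unique-point counting);
  lost-caps effects from finite particle size are represented only through
  the guard zones.
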