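---
title: "Methods: phantom-validated diffusion tractography network analysis"
author: "tractnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated diffusion tractography network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, parameters and design
choices. Everything quantitative stated here is computed by the test suite or
by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## 1. Signal model and phantom generation

Each voxel's diffusion-weighted signal follows the multi-tensor forward model

$$S(\mathbf g, b) = S_0\Big(\sum_i f_i\, e^{-b\,\mathbf g^\top D_i \mathbf g}
 + f_{bg}\, e^{-b\, d_{bg}}\Big),$$

with per-bundle tensors \(D_i\) oriented along the local bundle tangent and an
isotropic background compartment taking up the remaining volume fraction.
Magnitude noise is Rician, \(|S + n_1 + i\,n_2|\) with
\(n_1, n_2 \sim N(0, \sigma^2)\), the standard magnitude-MRI model.

Defaults mirror a high-angular-resolution ex-vivo protocol: 126 gradient
directions at \(b = 3000\) s/mm² plus one \(b=0\) volume (a deterministic
Fibonacci-spiral direction set), 0.7 mm isotropic voxels on a 40×40×20 grid,
bundle eigenvalues \((1.7, 0.3, 0.3)\times10^{-3}\) mm²/s (FA 0.799), bundle
volume fraction 0.85, background diffusivity \(0.7\times10^{-3}\) mm²/s, and
\(S_0 = 100\) with \(\sigma = 2\) for cohort work (SNR 50 at \(b=0\)). The
background diffusivity is chosen high enough that background voxels keep a
stable, low-FA tensor fit at this shell — spurious high-FA noise voxels would
otherwise seed phantom streamlines.

The atlas places nine paired grey-matter regions (prefrontal, cingulate,
temporal cortices, caudate, putamen, thalamus, amygdala, hippocampus,
hippocampal formation) as axis-aligned boxes on three straight bundles per
hemisphere: an *anxiety* bundle (amygdala → hippocampal formation → cingulate
cortex), a *memory* bundle (hippocampal formation → hippocampus → temporal →
prefrontal cortex) and a network-free bundle carrying only striatum and
thalamus labels. Geometric realism is deliberately absent: only the traversal
logic, fiber counting and statistics are under test, not anatomy. The
hippocampal formation deliberately has one label with two spatial components
so that it can be required by both networks without forcing the bundles to
intersect.

### What the generator emulates — and what it does not

The generator reproduces the *statistical* structure the analyses assume: a
two-group cohort (11 controls vs 10 cases by default), regionally reduced
anisotropy in cases (principal eigenvalue scaled by \(1-\)`fa_effect` inside
the effect regions, default 0.3), thinned network bundles in cases
(`thinning`, default 0.3), and behavioral outcomes monotonically coupled to a
latent severity shared with group membership. It does **not** emulate curved
or crossing anatomical tracts at cohort scale, partial-volume cortical
geometry, registration misalignment across subjects (all subjects share a
grid), susceptibility or fixation artefacts. Passing tests therefore
demonstrate correctness of the algorithms under their stated assumptions, not
performance on real acquisitions.

Two generator choices deserve explanation:

* **Thinning is outer-shell demotion.** The thinning fraction removes the
  outermost bundle voxels (by centerline distance, deterministic), modeling a
  uniformly narrower bundle rather than salt-and-pepper axonal dropout.
  Random per-subject voxel dropout would make case groups bimodal at every
  planted voxel and conflate two effects (anisotropy reduction and geometric
  loss) in the voxelwise test; a narrower bundle keeps the two planted
  effects separable — the eigenvalue effect drives the t-map, the thinning
  drives the fiber count.
* **Severity drives behavior, group drives imaging.** Cases receive the
  stated imaging effect sizes; the latent severity (controls centered at 0,
  cases at 1, SD 0.3) drives only the behavioral outcomes (latency rises
  log-linearly, central exploration and discrimination index fall, etc.).
  This plants the sign structure of every brain–behavior correlation while
  keeping the imaging contrast a clean two-sample problem.

## 2. Tensor model and scalar maps

The tensor is fitted per masked voxel by weighted log-linear least squares on
\(\ln S = \ln S_0 - b\,\mathbf g^\top D\,\mathbf g\) with weights \(S^2\)
(the first-order variance correction for log-transformed Rician-mean data).
Non-positive samples are excluded; voxels with fewer than seven usable
samples return a flagged zero tensor. A nonlinear fit was considered and
rejected: at phantom SNR the weighted linear fit recovers noiseless
eigenvalues to \(10^{-9}\) mm²/s (verified in the tests) and is deterministic
and an order of magnitude faster.

Scalar maps use the trace-normalized Westin convention, giving the exact
conservation law \(c_l + c_p + c_s = 1\) on every voxel with positive trace —
a testable invariant, which is why this normalization was chosen over the
\(\lambda_1\)-normalized variant. Degenerate (zero-trace) tensors are
assigned FA \(=c_l=c_p=c_s=0\) and flagged, matching common tool behavior.

## 3. Q-ball ODF and peaks

The analytic Q-ball reconstruction fits real, even-order spherical harmonics
to the normalized shell signal with Laplace–Beltrami regularization
(\(\min_c \|Bc - s\|^2 + \lambda\, c^\top L^2 c\), \(L = \mathrm{diag}(l(l+1))\))
and applies the Funk–Radon transform as the per-order scaling
\(2\pi P_l(0)\). Defaults are order 6 and \(\lambda = 0.006\), the de-facto
analytic Q-ball defaults; order 6 needs 28 coefficients, comfortably
determined by 126 directions, and resolves 90° crossings (verified: two
orthogonal peaks at a balanced two-tensor crossing).

ODF amplitudes are min–max normalized per voxel at evaluation time on a
subdivided icosahedron (3 subdivisions, 642 vertices, ≈8° spacing). Peaks are
mesh local maxima above 0.5 of the per-voxel maximum, greedily deduplicated
within 25°, antipodal pairs collapsed with a canonical sign
(largest-magnitude component positive). A constant (isotropic) ODF has no
well-defined maxima and returns zero peaks by construction.

## 4. Deterministic tractography

Streamlines are seeded once at the center of every masked voxel with
FA ≥ 0.2 and integrated bidirectionally with fixed-step second-order
Runge–Kutta over trilinearly interpolated peak directions. At each corner of
the interpolation cell the peak best aligned (by \(|\cos|\)) with the
previous direction is chosen and sign-aligned before weighting — this is what
makes the scheme antipodally symmetric and able to cross fiber crossings
coherently. Termination: interpolated FA < 0.15, turning angle > 60° per
step, or leaving the volume; streamlines shorter than 2.1 mm (3 voxels) are
discarded. The step is 0.35 mm (half a voxel). None of these parameters has
a published reference value for the emulated protocol; they are the common
deterministic-tractography defaults and all are configurable. One seed per
voxel center (rather than random subvoxel seeding) keeps fiber counts — the
study's key metric — fully deterministic.

The inner integration loop is implemented in C++ (Rcpp): it is the only hot
loop in the package, and a compiled implementation keeps whole-cohort runs
interactive.

## 5. Network extraction and metrics

A streamline belongs to a network when it traverses **all** required regions
and **at least one** optional region. Membership is evaluated on the
polyline resampled at one tenth of its inter-point spacing, each sample
mapped to its nearest voxel's label. The resampling makes point sampling
equivalent to a dense voxel trace (the test suite checks exact agreement
with an independently coded brute-force oracle), so region corners crossed
between tracking steps are not missed. For the left/right analyses only
labels of that hemisphere count; a fiber touching required regions in
different hemispheres belongs to the global network only. Each streamline is
counted once — the possibility of double-counting bilateral fibers in the
global analysis is resolved as counted-once and recorded here.

The two metrics are the fiber ratio \(|network|/|whole\ brain|\) (undefined,
and rejected, for an empty whole-brain set) and the mean FA sampled
trilinearly at every point of every member streamline, pooled across points.
Pooling (rather than averaging per-streamline means) weights long fibers
more; the choice is stated in the output metadata. "Striatum" in the
anxiety network's optional set is realized as caudate ∪ putamen.

## 6. Voxel-based analysis

Registration is a 12-parameter affine (translation, rotation, log-scale,
shear) maximizing normalized cross-correlation of FA maps, optimized
multi-resolution — rigid parameters first (Nelder–Mead at half and full
resolution), then the full affine by quasi-Newton refinement. The rigid-first
staging exists because a joint 12-parameter search trades rotation against
scale and stalls short of the optimum; with it, planted 2-voxel translations
are recovered within 0.07 voxel and 10° rotations within 0.4°. A
deformable, tensor-metric registration was deliberately not implemented:
synthetic subjects share a grid up to affine perturbation, so an affine map
is sufficient for the phantom studies this package supports. **Reusing the
VBA chain on real data would require replacing this stage with a deformable
registration.**

Tensor reorientation follows the preservation-of-principal-directions rule:
\(e_1 \mapsto F e_1 / \|F e_1\|\), \(e_2\) mapped and re-orthogonalized,
\(e_3\) completing the frame, eigenvalues untouched; singular local maps
leave the voxel unrotated and flagged.

Smoothing is a 3×3×3 local minimum-mean-square-error (Wiener-type) filter,
\( \hat x = \bar x + \max(0, 1 - \sigma_n^2/\sigma_{loc}^2)(x - \bar x)\),
with neighborhood weights attenuated by \(\exp(-\Delta e^2 / 2h^2)\) across
edges of a guidance map. The noise variance defaults to the median local
variance (robust when most of the volume is homogeneous) and \(h\) to half
the edge map's SD. Because the output is a convex combination of the voxel
and a convex neighborhood mean, smoothing can never leave the input range —
an asserted invariant.

The group map fits `value ~ group + gender` per voxel and reports the
control-minus-case t (positive where cases are reduced) with two-sided p,
masked at uncorrected p < 0.01; no multiple-comparisons correction is
applied, by design, matching the exploratory analysis the package
implements. A gender covariate aliased with group is dropped with a warning.
Brain–behavior maps use Spearman correlation; with a gender covariate, ranks
of both sides are residualized on gender first (partial rank correlation —
the literal reading of "adjusting for gender" applied to ranks), displayed at
p < 0.001 and \(|\rho| > 0.2\). Two-sided tests throughout; sidedness is a
documented choice, not a given.

Template consensus repeats the register–smooth–test chain with each listed
subject as template and intersects the per-template significance masks in the
first template's frame. Strict all-template intersection is the literal
reading of requiring differences "consistently noted in all the templates";
a majority-vote alternative was considered and rejected as a weaker, less
auditable criterion.

## 7. Behavioral scoring and statistics

Open-field logs are timestamped grid positions (6×6 grid, central 2×2
internal) plus grooming/rearing events within a 600 s session. Latency is
the first departure from the starting square (600 s if never); crossings are
counted at cell changes and classified by destination; dwell accrues to the
occupied square until the next sample; exploring time is the total duration
of intervals that end in a crossing, and velocity is squares per exploring
second. Halving the sampling interval changes zone times by <1% (tested), so
scoring is robust to log resolution.

The discrimination index is \((N - F)/(N + F)\) with learning defined
strictly as DI > 0. Exclusion follows the stated rules: nothing explored in
familiarization, or the familiar object never explored in testing. One
boundary case is contradictory in the source contract (testing with
\(N>0, F=0\)): the package computes DI (here +1) *and* flags the record
excluded, leaving DI missing only when \(N+F=0\); excluded records are
dropped from group analyses.

Group comparisons route by per-group Shapiro–Wilk at \(\alpha = 0.05\):
normal variables report mean (SD) and a gender-adjusted linear model on raw
values; non-normal variables report median (IQR) with the model on
\(\log(x + \text{offset})\), offset 1 for zero-valued variables (and a shift
to 1 for the rare negative-valued variable — without it a symmetric variable
occasionally mis-routed by Shapiro–Wilk would crash the log branch).
Categorical variables use the uncorrected chi-squared statistic — the plain
textbook formula, which the tests verify by hand evaluation. The
inter-observer ICC is the single-measure two-way mixed model, absolute
agreement by default (a consistency variant is exposed); absolute agreement
is the stricter and therefore safer default when the variant is unspecified.

## 8. Problem sizes and numerical choices

Cohort-level validation (tests and the acceptance script) runs on a 24×24×12
grid at 0.7 mm with the full 127-volume scheme — small enough that a
21-subject simulate–fit–ODF–track cycle takes well under a minute on one
core, large enough that each bundle spans ≈19 voxels and the planted-effect
t-map has ~200 planted voxels. Single-voxel recovery checks use the same
scheme on 8×8×6 grids. The 100-run null calibration of the voxelwise test
uses synthetic scalar-map cohorts (the object the test consumes), because the
null distribution of the t statistic does not depend on the DWI simulation
upstream; one full zero-effect DWI cohort additionally verifies the null
fiber-ratio contrast.

Other numerical conventions, stated once: world coordinates in mm (RAS),
0-based voxel indices, diagonal voxel-to-world affines for phantoms;
streamlines stored in world mm (TCK, Float32); eigenvalues sorted descending
with negatives clamped to zero and flagged; all seeded randomness flows from
a single integer seed, and identical seeds give bit-identical phantoms,
tractograms and pipeline outputs (tested).

## 9. Known limitations

* Affine-only registration (see §6) — adequate for shared-grid phantoms,
  insufficient for real brains.
* Single-shell, Gaussian-compartment signal model: no exchange, no
  restriction, no multi-shell models (DKI, NODDI, CSD are out of scope).
* The phantom's bundles are straight and disjoint at cohort scale, so the
  tracker's crossing behavior is exercised only in dedicated two-bundle
  tests, not in cohort runs.
* Absolute fiber counts depend on seeding density and thresholds and are not
  comparable across tools; only ratios and group contrasts are meaningful,
  which is why the metrics are defined as they are.
* Behavioral effect sizes are calibrated to reproduce sign and significance
  structure, not any particular printed group means.
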