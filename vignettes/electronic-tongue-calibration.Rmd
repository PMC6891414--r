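---
title: "Voltammetric electronic-tongue calibration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltammetric electronic-tongue calibration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etongue)
```

## The problem

An electronic tongue (ET) quantifies several analytes simultaneously from an
array of *low-selectivity* sensors: no single electrode resolves diazepam,
flunitrazepam and lorazepam — their reduction signals overlap heavily — but
six differently modified electrodes produce six different mixtures of the
same underlying information, and a multivariate model can disentangle them.
`etongue` implements the complete calibration pipeline for this setting:

1. a tilted full-factorial **calibration design** plus a random external test
   set (`build_design()`),
2. six-sensor cyclic **voltammogram acquisition**, here emulated by a
   phenomenological simulator (`simulate_sample()`),
3. **wavelet compression** of the 4512-point raw fingerprint to 144
   approximation coefficients (`compress_records()`),
4. a single-hidden-layer **perceptron regressor** with the classical
   MATLAB-style transfer functions and an exhaustive architecture search
   (`et_mlp()`, `architecture_search()`),
5. **evaluation** by obtained-versus-expected regression lines and NRMSE
   (`evaluate_model()`), and a **PCA complementarity diagnostic** for the
   array (`complementarity_report()`).

## The simulator

Real voltammograms for this chemistry are dominated by the two-electron
reduction of the benzodiazepines' 4,5-azomethine group, which appears as a
broad cathodic peak whose position and magnitude differ by electrode and by
compound. The simulator reproduces that *statistical structure* — not the
electrochemistry. For sensor $s$ and potential $E$ on the descending
(cathodic) half-cycle:

$$ i_s(E) = b_{0,s}\,d(E) + b_{1,s}E
   + \sum_{a=1}^{3} \frac{S_{sa}\,c_a}{1 + c_a/K_{sa} + \sum_b G_{ab} c_b}
     \, e^{-\tfrac{1}{2}\left(\frac{E - E^0_{sa}}{w_{sa}}\right)^2}, $$

where $d(E)=\pm 1$ is the sweep direction (the capacitive offset changes
sign with direction), $S$ is the low-concentration sensitivity (µA/ppm),
$K$ a Michaelis-type saturation constant (ppm), $G$ a symmetric
cross-suppression matrix (ppm⁻¹) modelling competition between analytes at
the electrode, and $E^0, w$ the Gaussian peak position and width (V). The
ascending half carries the same peaks scaled by an `anodic_fraction`
(quasi-reversible mirror signal). Gaussian noise with standard deviation
$\sigma_{abs} + \sigma_{rel}\cdot i_{\text{full-scale}}$ is added last.

Parameters that matter, with defaults:

* **Potential grid** — one stabilized triangular cycle, −1.5 → +1.5 → −1.5 V,
  752 points (376 per half). Six sensors give the canonical 4512 raw values
  per sample. Electrode cleaning, conditioning and replicate-cycle drift are
  *not* modelled; the simulator returns the stabilized cycle directly.
* **Sensor bank** — `et_default_bank()` ships six documented parameter sets
  with distinct sensitivity patterns (the 6×3 sensitivity matrix has full
  column rank, the algebraic prerequisite for resolving a ternary mixture)
  and staggered peak potentials. These are package constants emulating the
  qualitative diversity of a modified-graphite array, not measurements.
* **Saturation and interference** — $K$ in 35–60 ppm gives a mildly
  saturating response over the 0–30 ppm working domain; $G$ entries of
  0.003–0.008 ppm⁻¹ couple the analytes. Together they make the
  concentration–response map genuinely nonlinear.
* **Noise** — default $\sigma_{rel} = 0.5\%$ of full scale, the package's
  canonical measurement-noise level; fixtures at 0% and 2% bracket it.
* **Seeding** — one master seed; every per-sample, per-sensor stream is
  derived by stable hashing of (seed, sample id, sensor index), so any
  record can be regenerated in isolation, bit-identically.

What the simulator does **not** emulate: electrode fouling and drift,
replicate-cycle variability, pH/buffer effects, real peak asymmetries
(Gaussian peaks are an idealization), and correlated (non-white) noise.
Passing tests therefore demonstrate the *pipeline's* correctness and its
ability to invert a known nonlinear sensing model — not instrument-grade
performance on real extracts.

## The calibration design

`design_spec()` defaults encode the canonical plan: a 3-level, 3-factor full
factorial (27 standards spanning 0–30 ppm per analyte), *tilted* 45° about
each axis so that each analyte takes many distinct values instead of three,
plus 9 external test mixtures drawn uniformly at random — a 75/25 split.

The tilt convention had to be fixed by the package, since "tilted in each
axis" admits many readings: we rotate by $R_x(\theta)R_y(\theta)R_z(\theta)$
about the design centroid, then apply **one** uniform isotropic rescale and
a translation so the rotated cloud's bounding box sits centred inside the
domain cube. Because rotation plus isotropic scaling is a similarity map,
all pairwise distance ratios of the factorial are preserved (this is tested
to 1e−9), and every emitted concentration stays inside [0, 30] ppm. Should
tilting ever produce coincident points (it does not at the defaults), the
package raises an error rather than silently de-duplicating. The random test
concentrations are freshly drawn per seed; there is no canonical test set to
reproduce.

## Wavelet compression

Each 752-point trace is reduced to its depth-5 **approximation
coefficients** under a periodized orthonormal Daubechies-3 transform,
implemented in the package (filter pair of 6 taps; periodization yields
exactly $\lceil n/2 \rceil$ coefficients per level, so
752 → 376 → 188 → 94 → 47 → 24). Six sensors give the 144-coefficient
feature vector, a 96.8% compression. The per-sensor transform (rather than
one transform of the concatenated 4512-vector) preserves the block
structure "24 coefficients per sensor".

Numerical notes:

* The forward/inverse pair was verified during development against an
  independent reference implementation (PyWavelets, `periodization` mode),
  including odd-length levels; frozen reference coefficients are asserted in
  the test suite, and perfect reconstruction holds to 1e−10.
* Odd-length levels are periodized by repeating the final sample. This
  makes the transform of such levels slightly *over-complete*: coefficient
  energy can exceed signal energy by up to the duplicated sample's share
  (e.g. a constant 752-point signal has approximation energy
  $768c^2 > 752c^2$). Energy non-expansion is therefore exact — and tested —
  on lengths divisible by $2^{\text{depth}}$.
* A depth-5 transform is the only standard convention that maps 752 points
  to exactly 24 coefficients; the package treats the "third compression
  variant" of common usage (after 88.9% and 94.1% variants at depths 3 and
  4) as this depth-5 setting, and reports its own exact compression
  percentages.

## The network

`et_mlp()` fits a fully connected 144–$h$–3 network. The transfer-function
registry carries the five classical MATLAB names — `hardlims`, `satlins`,
`purelin`, `logsig`, `tansig`. (Historical lists of "the five functions"
sometimes name `satlins` twice; the package takes `logsig` as the
conventional fifth and keeps `hardlims` in the search grid even though its
zero subgradient means such configurations cannot train — the search simply
never selects them.)

Training and its design choices:

* **Optimizer** — deterministic full-batch L-BFGS-B on the mean squared
  error of scaled targets, with analytic backpropagated gradients; up to
  `epochs` (default 2000) iterations, converging on a relative-improvement
  plateau. The line search only accepts descent, so the final training loss
  never exceeds the initial loss. Same data + seed ⇒ identical weights.
* **Initialisation** — uniform $(-0.5, 0.5)/\sqrt{\text{fan-in}}$ from the
  seeded stream.
* **Input scaling** — one *global* min–max affine map of all 144 features
  to [−1, 1] (per-feature scaling is available as an option). The
  coefficients share units (µA); scaling each feature separately would
  stretch baseline-only coefficients — whose across-sample variation is
  almost pure measurement noise — to full range, and we found it degrades
  external-test NRMSE several-fold. Zero-variance features map to 0.
* **Target scaling** — per analyte to [−0.8, 0.8] (`target_span = 0.8`).
  With a saturating output neuron (`tansig`), targets at the edge of the
  activation's range are reachable only with unbounded weights; keeping the
  design extremes at ±0.8 leaves them in the responsive region. This is the
  classical prescription for saturating heads, and it both deepens training
  convergence and improves generalization. Test data always use the
  training scalings.
* **Capacity note** — the fixed 5-unit `satlins` hidden layer has a real
  approximation floor on this problem (scaled MSE plateaus near $10^{-3}$
  for every optimizer we tried, including a Levenberg–Marquardt prototype);
  the architecture search regularly prefers slightly larger `tansig` hidden
  layers when allowed to choose.

**Model selection.** `architecture_search()` scans hidden sizes 2–9 crossed
with the five transfer functions in both layers — 200 configurations — and
scores each by 3-fold cross-validated combined NRMSE *on the training
standards only*; the external test set never participates in selection.
Ties break to the first configuration in scan order. The winner is refitted
on all 27 standards.

## Evaluation

The figure of merit is the normalized root mean squared error

$$ \mathrm{NRMSE} = \sqrt{\frac{\sum_{ij}(\hat c_{ij} - c_{ij})^2}
                               {\sum_{ij} c_{ij}^2}}, $$

pooled over samples and analytes ("combined") or computed per analyte. This
normalization — residual norm over reference norm — is the one consistent
with values of a few percent on a 0–30 ppm domain and is scale-invariant; a
range-normalized variant (`normalization = "range"`) is provided for
comparison with literature using that convention. Per analyte and subset,
`evaluate_model()` also reports the obtained-versus-expected ordinary
least-squares line (ideal slope 1, intercept 0) with both the correlation
coefficient $r$ and $R^2$, since published tables are not always explicit
about which is meant.

## The PCA diagnostic

Array qualification follows the classical experiment: five replicates of
each single compound at 25 ppm measured with all six sensors, one PCA row
per (sensor, replicate) voltammogram — 90 rows of 752 variables. Only
centering is applied (no autoscaling: the variables share units, and
autoscaling would inflate flat baseline regions). `et_pca()` uses the SVD
with a deterministic sign convention (largest-magnitude loading entry
positive). The report summarises per-(sensor, compound) score centroids and
a mean silhouette width over compound groups; a positive silhouette means
compounds separate beyond replicate scatter — the complementarity that
justifies the array.

## Reproducibility and problem sizes

Every stochastic step flows from one master seed through stable hashing, so
`run_pipeline()` reruns are bit-identical, which the test suite checks on
full CSV artifacts. The default run — 36 samples × 6 sensors × 752 points,
wavelet compression, one 144-5-3 network — completes in roughly two seconds;
the full 200-configuration search adds under a minute. The test suite
exercises the performance analysis at the default conditions with medians
over 5 seeded runs, and the search-based recovery property on one seed;
these sizes were chosen as the smallest that make the stochastic medians
stable.

## Known limitations

* The simulator's phenomenology (Gaussian peaks, Michaelis-type saturation,
  pairwise suppression) is the minimal structure that makes a purely linear
  calibrator suboptimal and a nonlinear one worthwhile; it is not a
  substitute for measured voltammograms, and absolute current magnitudes
  are package conventions.
* The 9 mV instrument step quoted for this chemistry implies ~667 points
  per cycle; the package fixes 752 points so that six sensors give exactly
  4512 raw values, and treats the printed step as nominal.
* `hardlims` networks cannot learn by gradient descent (zero subgradient);
  they are retained for grid fidelity only.
* Real-matrix applicability (urine, serum), detection limits and linear
  ranges are out of scope.
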