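---
title: "Global-brain functional connectivity: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-brain functional connectivity: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The statistic

Global-brain functional connectivity (GFC, elsewhere GBC) summarises, for
every gray-matter voxel, how strongly its resting-state BOLD time series
co-fluctuates with the rest of the brain:

$$\mathrm{GFC}(a) \;=\; \frac{1}{n-1}\sum_{b \neq a} f\!\big(r(T_a, T_b)\big),$$

where $r$ is the Pearson correlation between the series of voxels $a$ and
$b$, $n$ is the number of gray-matter voxels, and $f$ is either the identity
(`mode = "mean_r"`) or the Fisher transform $\operatorname{atanh}$
(`mode = "mean_z"`). The default is `mean_z`: transforming each pairwise
correlation before averaging is the variance-stabilised reading of a
"Fisher z-scores matrix", and per-subject maps are then already in z units
for group modelling. `mean_r` is retained both as a cross-check and because
it admits an exact $O(nT)$ algorithm (see *Numerics*). Self-correlation is
excluded from the sum — the average is over "every other voxel" — and an
`include_self` flag exists for sensitivity analyses. Negative correlations
enter the average untouched; some GBC variants threshold at $r > 0$, and not
doing so here is a documented difference, not an oversight.

Two implementations coexist deliberately. `gfc_bruteforce()` is an explicit
double loop over `stats::cor` calls — slow, obviously correct, and the test
oracle. `gfc_fast()` standardises columns to zero mean and unit norm so that
$r(a,b) = z_a^\top z_b$; `mean_r` then collapses to
$\mathrm{GFC}(a) = (z_a^\top S - 1)/(n-1)$ with $S=\sum_b z_b$, and `mean_z`
computes the correlation matrix in column blocks (`block_size`, default 512)
so memory stays bounded at $n \times \text{block}$. The suite pins
`gfc_fast` to the oracle at $10^{-10}$ in both modes.

Degenerate (zero-variance) voxels receive GFC 0 and a flag rather than
propagating NaN; pairwise correlations are clipped to
$|r| \le 1 - 10^{-7}$ before $\operatorname{atanh}$ so duplicated columns
produce a large finite value instead of infinity.

# Preprocessing chain

The cleaning chain runs in a fixed, logged order: drop initial volumes →
gross-motion QC → spatial smoothing → linear detrend → band-pass → nuisance
regression → FD scrubbing.

* **Volume dropping** (`k_drop = 10`): the first 10 frames (20 s at TR 2 s)
  are discarded from image and motion trace in lockstep, covering
  magnetisation steady-state and subject settling.
* **Motion QC** (`2 mm / 2°`): a subject fails if any frame's translation or
  rotation parameter exceeds the limit on any axis, judged on the parameter
  values themselves (displacement from the reference frame) — the common
  toolbox convention; max-displacement variants exist and would be stricter.
* **Smoothing** (`fwhm_mm = 4`): separable Gaussian per frame,
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units (0.566
  voxels at 4 mm / 3 mm). The truncated kernel is renormalised at the grid
  boundary, so constant images are preserved exactly and interior sources
  keep their mass.
* **Detrend**: per-voxel OLS residuals against intercept + frame index. A
  finite sine window is not orthogonal to a ramp, so detrending leaves a
  small residual ($\approx 3/\pi k$ of amplitude at $k$ cycles) on
  arbitrary-phase oscillations; this is a property of linear detrending
  itself, and the tests check transparency on phase-centred oscillations
  where the projection vanishes.
* **Band-pass** (`0.01–0.08 Hz`): ideal rectangular filter on DFT bins
  (`low ≤ f ≤ high` kept, DC removed since `low > 0`). Ideal filters are the
  convention of this literature's toolchains; they are transparent for
  bin-aligned frequencies and ring at the circular wrap for non-aligned
  ones. The synthetic generator draws its latent frequencies strictly inside
  the band, so the band-pass preserves the signal of interest.
* **Nuisance regression** (27 columns): intercept, the Friston-24 expansion
  $[p(t), p(t\!-\!1), p(t)^2, p(t\!-\!1)^2]$ of the six rigid-body
  parameters, and the mean signals of the white-matter and CSF compartments.
  The WM mask is eroded by one voxel first (`erode_wm`) so the regressor is
  white-matter *centred*; if erosion would empty a small mask, the uneroded
  mask is used with a warning. WM/CSF signals are detrended and filtered
  exactly like the data before entering the design, so regression cannot
  reintroduce out-of-band content. The global (whole gray-matter mean)
  signal is deliberately **not** removed: GFC is computed on data that
  retain it. Rank-deficient designs (an all-zero motion trace, a saturated
  parameter whose square is numerically constant) are repaired by dropping
  dependent columns with a warning.
* **Framewise displacement**: Power convention,
  $FD_t = \sum|\Delta \text{trans}| + 50\,\text{mm} \times \sum|\Delta \text{rot}|$,
  $FD_1 = 0$; the sphere radius is a config key.
* **Scrubbing** (`FD > 0.2 mm`): offending frames are deleted outright — no
  1-back/2-forward augmentation, matching the plain reading of the
  threshold rule — and the chain errors if fewer than `scrub_floor` (30)
  frames survive. Scrubbing runs **last**, after filtering: filtering a
  non-contiguous series is ill-defined, and ordering it last guarantees
  deleted frames cannot re-enter. Whether the original toolchains scrub
  before or after filtering is generally unstated; this is our documented
  choice, not an inference about anyone's code.

# Group inference

Per-voxel OLS of the subject GFC maps on
`[intercept, group, mean FD, age]`, group coded patient = 1 / control = 0 so
negative $t$ means lower connectivity in patients. Family-wise error is
controlled by the permutation distribution of $\max_v |t_v|$ under the
Freedman–Lane scheme: maps are regressed on the covariates alone, residuals
are permuted across subjects, the covariate fit is added back, and the full
model is refit per permutation. The adjusted p-value of voxel $v$ is
$(1 + \#\{\max\text{-}t_\pi \ge |t_v|\})/(P+1)$, so its smallest attainable
value is $1/(P+1)$ — choose `n_perm` accordingly (default 1000; a warning
fires when `n_perm < 1/\alpha - 1`). Permutation max-statistic FWE replaces
the random-field-theory machinery of SPM-style pipelines: it is
assumption-light, exact at any sample size, and testable at desk scale.
Voxel-level FWE is the inference; cluster extraction (26-connectivity by
default, 6/18 available) is descriptive, reporting size, peak $|t|$ voxel,
its mm coordinate through the affine, and effect direction. Testing is
two-sided.

A caution the permutation suite quantifies rather than hides: with a shared
global latent, GFC maps have genuine spatial correlation, but group labels
remain exchangeable under the null, so the family-wise error rate stays at
its nominal level (checked over 100 null cohorts).

# ROI, correlation and classification stages

Cluster features are plain arithmetic means of the (Fisher-z) GFC values
over member voxels, one value per subject per cluster. Illness-duration
correlations are Pearson, computed in the patient group only, with the
two-sided p from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ and Bonferroni adjustment
over the number of clusters. Demographic tables use Student's
pooled-variance t-test (Welch behind a flag) and the Pearson chi-square
*without* continuity correction — the uncorrected convention is pinned by a
test because the Yates variant gives a visibly different p on a small 2×2
table.

Classification evaluates each cluster's mean GFC separately as a diagnostic
feature: an RBF-kernel soft-margin SVM (`e1071`), leave-one-out
cross-validated over a $(C, \gamma)$ grid (default $\log_2 C \in
\{-5,\dots,15\}$, $\log_2\gamma \in \{-15,\dots,3\}$, step 2), the feature
standardised with training-fold statistics only. The grid point with the
best LOOCV accuracy is reported, ties resolved toward smaller $C$ then
smaller $\gamma$, with pooled held-out confusion counts. Selection and
reporting share the same LOOCV loop — *non-nested*, hence optimistically
biased on label-independent features. That bias is measured in the suite
(permuted labels yield mean best-grid accuracies well above 50%) instead of
being silently corrected; `nested = TRUE` provides the unbiased variant.
ROC analysis runs on the raw feature scale (not SVM decision values), so the
reported cut-off is in interpretable Fisher-z units; AUC uses the
rank/Mann–Whitney formulation with mid-rank ties, and the cut-off maximises
the Youden index with ties resolved toward higher specificity. With
patients showing *decreased* connectivity, `direction = "lower"` calls
values below the cut-off patient.

# The synthetic cohort generator

The generator exists so every downstream stage is testable with no data
download; its defaults encode the study conditions the pipeline targets:
20 patients vs 23 controls, a 24×24×24 grid at 3 mm, 250 volumes at TR 2 s,
ages ~N(52.6, 8.7²) / N(49.7, 6.5²) truncated to 18–65 and rounded,
deterministic sex counts of 7/13 and 4/19, mean-FD targets of 0.31 mm
(patients) and 0.39 mm (controls), and illness durations around
21 ± 15 months.

Each gray-matter voxel's series is
$y_v(t) = b_g(v)\,g(t) + b_r(v)\,s_r(t) + a\,[w(t)+c(t)]/2 + \sigma\,\varepsilon_v(t) + 100,$
with $g$ a global latent shared by all gray-matter voxels, $s_r$ a latent
private to each effect region, and $w, c$ white-matter/CSF nuisance latents
that dominate their own compartments and leak weakly ($a = 0.15$) into gray
matter. All latents are sums of 12 sinusoids with frequencies drawn
uniformly in 0.012–0.078 Hz and random phases — slightly inside the
analysis band so finite-window leakage does not cross the band edge, and
chosen over filtered noise because the spectral claim ("all latent power
in-band") is then exactly checkable. Controls couple to $g$ with weight
$b_g \sim N(0.8, 0.06^2)$ everywhere; patients use the same draw outside
the effect regions and a reduced $N(0.35, 0.06^2)$ inside them, so the
between-group difference is local by construction. Two default regions — a
deep "thalamus-like" 6 mm-radius blob and a larger inferior
"cerebellum-like" blob — mirror the two-cluster structure typical of
case-control findings; they are geometric conveniences, not anatomical
claims. The reduction from 0.8 to 0.35 is a free parameter: the source
setting provides no effect-size information beyond peak t values on
unavailable data, so the default was fixed once at a level that a
40-subject study detects reliably, and is not calibrated to any printed
number.

Illness duration is `21 + 12·(standardised subject coupling) + N(0, 9²)`
months, truncated at 1 and rounded — implying a truth correlation of about
0.8 between a patient's effect-region coupling and duration, and an
SD of ~15 months.

Motion traces are damped random walks (AR(1), decay 0.97) whose per-frame
step magnitudes follow a two-state heavy-tailed mixture (72% quiet frames;
restless frames ~9× larger with a log-normal spread), with positions
soft-saturated at 1.3 mm / 1.3° and the whole trace rescaled so the
realised mean FD hits its target exactly before spike injection. The
saturation is what reconciles three constraints that a plain Gaussian walk
cannot satisfy simultaneously: mean FD near 0.35 mm, a skewed FD profile in
which the scrubbing threshold removes a minority of frames (median FD
≈ 0.14 mm, roughly 30–40% of frames above 0.2 mm), and parameter
excursions that never trip the 2 mm / 2° exclusion. A zero FD target
returns an all-zero trace.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: scanner drift beyond linear, physiological
(cardiac/respiratory) aliasing, spatially varying noise, motion-by-signal
interactions (the image itself is motion-free; motion exists only in the
parameter files), EPI distortion, and anatomical variability. Cohorts store
per-subject seeds and regenerate images deterministically on demand
(`cohort_image`), keeping cohort objects small while bit-reproducible;
`write_cohort()` materialises the full NIfTI/TSV/JSON layout including
`truth.json`, so recovery tests never reach into the simulator's internals.

# Numerical choices and degenerate inputs

* Gray-matter mask: probability strictly `> 0.2` (the boundary voxel is
  excluded; `≥` would change $n$ and hence every GFC value).
* Column order of the time-series matrix: ascending x-fastest scan of mask
  voxels, identical across runs and platforms.
* Voxel indices are 1-based internally (R convention), 0-based in the
  affine map; coordinates are only ever reported in mm.
* Correlation clipping at $1 - 10^{-7}$; clipping is applied by integer
  indexing because masked assignment over ~10⁷-entry blocks dominates
  runtime otherwise.
* Zero-residual voxels in the GLM report $t = 0$ with a flag instead of 0/0.
* `mean_r` GFC lies in $(-1, 1]$ per voxel; the grand mean cannot fall
  below $-1/(n-1)$ (positive semi-definiteness of the correlation matrix).
  The per-voxel lower bound $-1/(n-1)$ sometimes quoted for this statistic
  is not a theorem — a voxel anti-correlated with the bulk can sit below it.
* Blocked and unblocked `mean_z` agree to ~10⁻¹³, not bitwise: BLAS kernels
  differ with operand shape.
* All randomness flows from explicit integer seeds through an internal
  stream-derivation rule; generators save and restore the caller's RNG
  state.

# Problem sizes in the test-suite

The statistical suites run at the sizes the analysis targets: oracle
equivalence at 200 voxels × 60 frames over 20 seeds; family-wise error
calibration over 100 null cohorts of 43 subjects × ~3,260 gray voxels × 240
frames with 500 permutations (matrix-level generation, `mean_r` mode —
the null cohorts contain no motion artefacts or nuisance structure by
construction, so the image-plumbing stages are exercised elsewhere);
effect-region recovery over 10 full end-to-end pipeline runs at the default
cohort geometry with 500 permutations; duration-correlation recovery over
20 cohorts against the generator's ground-truth regions; classifier
permutation behaviour over 200 LOOCV repetitions on a reduced 3×3
$(C,\gamma)$ grid plus 1000 AUC permutations. These sizes are the package's
own choice of desk-scale rigour: large enough for the Monte-Carlo bounds
asserted, small enough to run routinely.

# Known limitations

* No reslicing or registration: all inputs must share one grid; mismatch is
  an error, never a silent resample.
* No random-field theory, TFCE, cluster-mass inference, or small-volume
  correction; voxel-level permutation FWE only.
* No ICA denoising, RETROICOR, despiking, or slice-timing correction;
  motion parameters are consumed, not estimated.
* ROC confidence intervals and cross-validated calibration are out of
  scope; the ROC validates separability of a single feature.
* Stage outputs are written per run directory but runs are not resumable
  from cached artifacts; a full desk-scale run takes about a minute, so
  caching machinery was judged not worth its complexity.
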