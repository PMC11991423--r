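---
title: "Methods: simulation, two-step phase-shifting reconstruction, and learned single-frame inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, two-step phase-shifting reconstruction, and learned single-frame inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In-line (coaxial) digital holography records, on a single sensor, the
interference between the wave diffracted by a semi-transparent sample —
here, plankton-like amplitude objects suspended in seawater — and a clean
plane reference wave travelling along the same axis. The complex object
wave can be recovered algebraically if several holograms are recorded with
known reference-phase offsets; *generalized* phase-shifting reconstruction
drops the requirement that the offsets be controlled, estimating the phase
step from the interferograms themselves. This package implements the
two-frame variant of that pipeline end to end: a scalar-diffraction
simulator, the closed-form two-step inversion, a labeled synthetic dataset
generator, a compact learned single-frame inverter, and standard
image-quality and detection metrics.

## Forward model

A thin object is a transmission function
\(o(x,y) = e^{-a(x,y)} e^{i\phi(x,y)}\), with \(a \ge 0\) the absorption
map and \(\phi\) the phase delay. The plankton regime uses pure amplitude
objects, \(\phi \equiv 0\), on an empty (fully transmitting) background.
Illumination is a unit plane wave, so the exit wave equals \(o\) itself.
Propagation over the recording distance \(z\) uses paraxial (Fresnel)
scalar diffraction. The recorded frames for reference phases \(0\) and
\(\delta\) are

\[
I_1 = A_o^2 + A_r^2 + 2 A_r A_o \cos\varphi_o, \qquad
I_2 = A_o^2 + A_r^2 + 2 A_r A_o \cos(\varphi_o - \delta),
\]

together with the object-wave intensity \(I_o = A_o^2\) and the reference
intensity \(I_r = A_r^2\).

### Numerical propagator

`fresnel_propagate()` applies the single-FFT transfer-function kernel
\(H(f_x,f_y) = e^{ikz} e^{-i\pi\lambda z (f_x^2+f_y^2)}\). Because
\(|H| = 1\), total power is conserved exactly and propagation by \(-z\)
undoes propagation by \(+z\) to machine precision — a property the
reconstruction path depends on, and the reason this discretization was
preferred over sampling the spatial chirp. The \(e^{ikz}\) prefactor is
retained (it cancels in every intensity); \(z = 0\) is an exact identity
with no FFT applied. The propagator is validated against a dense
DFT-matrix evaluation of the same discretized kernel (an \(O(N^3)\)
direct-sum oracle with no shared FFT code) on 32 × 32 grids.

The sampled kernel is alias-free only for
\(|z| \le N p^2 / \lambda\) (pixel pitch \(p\), smaller grid dimension
\(N\)); `fresnel_propagate()` warns beyond that distance, and errors in
strict mode. Notably, the reference recording geometry (530 nm, 5 µm
pitch, 512², z = 24 cm) lies far beyond this limit — the source work does
not state how its simulation handled sampling — so the quantitative
desk-scale geometry here (64², z = 2.4 mm) was chosen inside the limit,
keeping every desk result exactly invertible.

## Two-step generalized phase-shifting reconstruction

With \(A_r = \sqrt{\operatorname{mean}(I_r)}\), the object wave on the
recording plane is recovered pointwise:

\[
\operatorname{Re}(U_o) = \frac{I_1 - I_o - I_r}{2A_r},\qquad
\operatorname{Im}(U_o) =
\frac{I_2 - I_1\cos\delta - (1-\cos\delta)(I_o+I_r)}{2A_r\sin\delta}.
\]

The formula divides by \(\sin\delta\); steps with
\(|\sin\delta| \le 10^{-3}\) are rejected as degenerate. Refocusing to the
object plane is inverse Fresnel propagation over \(-z\), and the amplitude
is max-normalized to \([0,1]\). On simulated scenes the whole chain is
exact to ~1e-15 relative error, which is the basis of the exact-recovery
acceptance test.

### Phase-step estimation

When \(\delta\) is unknown, normalize the interference terms:
\(c_1 = (I_1 - I_o - I_r)/(2\sqrt{I_o I_r}) = \cos\varphi_o\) and
\(c_2 = \cos(\varphi_o - \delta)\). If \(\varphi_o\) is broadly
distributed across the frame, \(\langle c_1 c_2\rangle /
\sqrt{\langle c_1^2\rangle\langle c_2^2\rangle} \to \cos\delta\), giving
\(\hat\delta = \arccos(\cdot) \in (0,\pi)\). The two-frame problem cannot
distinguish \(\pm\delta\), hence the branch choice. Pixels with
\(I_o\) below \(10^{-3}\) of its maximum are excluded. The estimator's
validity regime is *diffuse* phase: after Fresnel diffraction of compact
amplitude objects the background phase is nearly constant, so estimator
tests use the generator's diffuse-phase mode (uniform random phase per
pixel), where recovery is better than 0.01 rad at 128² for
\(\delta \in [0.3, 2.8]\). Two identical interferograms (\(\delta = 0\))
raise an explicit estimation-failure error.

## Synthetic scenes and datasets

`make_shape()` draws four procedurally generated silhouette families
(elongated-with-tail, 4-fold radial, bell-with-tentacles, slender rod),
standing in for the four plankton species of the external image bank the
original dataset was built from, which is not bundled or downloaded.
`compose_scene()` places a random number of them — rotated by quarter
turns, flipped one of three ways — on an empty frame by rejection
sampling so that silhouette *supports* (not boxes) are pairwise disjoint;
an object that cannot be placed in 200 attempts is dropped, and only
falling below the minimum count is an error. Boxes are tight pixel
bounding boxes, exported in YOLO center-normalized form with coordinates
quantized to the 6-decimal file precision at construction (so label files
round-trip exactly). Opacity maps to absorption via
\(a = -\log(\max(1 - \text{opacity}, 10^{-3}))\); the clip keeps fully
opaque pixels finite.

`build_dataset()` writes max-normalized holograms (the recorded scale
factor is kept in the manifest so the algebra stays exact), two-step
reconstructions as learning labels, YOLO label files and a JSON manifest;
identical seeds give byte-identical trees. The reference scale is
10,000 scenes split 9000/1000; the desk profile (64², 2–4 objects,
z = 2.4 mm) reproduces the *logic* at ~500/50. The simulated phase step
defaults to \(\pi/2\) (the source work never states its simulation value);
a randomized mode draws \(\delta \sim U[0.3, 2.8]\) to exercise the
estimator.

What a green desk-scale test does **not** establish: robustness to sensor
noise, quantization of real 8-bit cameras, partial coherence, background
non-uniformity, or object overlap — the generator models none of these
(an optional experimental background frame can be divided out, but is
never simulated).

## The add-skip encoder–decoder

The learned inverter maps one normalized interferogram directly to the
reconstructed amplitude image. It is a symmetric U-shaped network built
from (3×3 convolution → batch normalization → ReLU) units, 2×2 max
pooling down, learnable 2×2 stride-2 transposed convolutions up, and
*additive* skip connections — summing encoder features into the decoder
instead of concatenating them, which removes the doubled-width decoder
convolutions and with it a large share of the parameters (the `cat`
variant is provided for the comparison; the parameter-count ordering is
asserted in tests). A 1×1 convolution with a sigmoid produces the
\([0,1]\) output. No deep-learning framework is available in the target
environment, so convolution, batch norm, pooling, transposed convolution,
Adam and backpropagation are implemented in C++ (RcppArmadillo), fully
deterministic given the seed.

Training uses MSE loss and Adam under a staged learning-rate schedule.
The reference schedule is lr 0.01 × 10 cycles, 0.001 × 40, 0.0001 × 50,
0.00008 × 200 (one cycle = one epoch); the desk schedule keeps the same
four rates compressed to 2/30/8/4 cycles with minibatches of 5.
Reference topology: depth 4, widths 32/64/128/256, two conv units per
level. Desk topology: depth 3, widths 8/16/32, one conv unit per level —
chosen, together with the desk stage lengths and batch size, by watching
training-loss convergence at desk scale before freezing the acceptance
runs: the second stage (lr 0.001) does most of the work on this task, so
it holds the bulk of the cycles, and the small batch size matters more
than block depth at this scale (it quadruples the number of Adam steps
per cycle; doubling the conv units per level instead converged more
slowly per unit time). Skips add *post-block* features (the
pre-/post-activation choice is not fixed by the source description).
Inputs must be divisible by \(2^\text{depth}\); the desk shapes are.

## Metrics

SSIM follows the standard luminance/contrast/structure form with
\(c_1 = (0.01 L)^2\), \(c_2 = (0.03 L)^2\), \(L = 255\). Two modes:
Gaussian-windowed 11×11 (σ = 1.5, valid-region crop, population moments)
mean SSIM — the default, matching common practice — and a global mode
evaluating the formula once on whole-image statistics, which is the form
printed in the source description. Inputs are jointly min-max rescaled to
\([0, 255]\) (jointly, so the relative scale of the pair is preserved;
disable with `rescale = FALSE`). Identical images score exactly 1. Note
the often-quoted \((0,1)\) range holds for structurally related pairs,
not in general: anticorrelated windows can push SSIM negative
(the true range is \([-1,1]\)); the tests assert the positive range only
where it actually holds.

Detection scoring is Pascal-VOC style: greedy confidence-ordered matching
(ties by best IoU, then input order), one consumption per truth box,
class agreement required, IoU ≥ 0.5 at the default boundary ("exceeds
0.5" is read inclusively; a strict mode is provided). AP uses all-point
interpolation (area under the precision envelope), mAP averages over
classes present in the truth. The true-negative count defined in the
source text has no standard meaning in detection and is ignored. The
detector itself is external and pluggable; only label export and scoring
are in scope. The source work's per-class precisions (71.8% class 0,
>96% classes 1–3) and 91.0%/95% aggregate figures depend on external
imagery and trained detector weights and are documented as
non-reproducible context, not targets.

## Numerical choices and edge cases

- Phase conventions: fields use \(e^{+i\,\text{phase}}\) throughout; the
  mixed-sign notation of the source equations is absorbed into the
  definition of the recovered phase. All round-trip tests are
  convention-independent.
- \(\epsilon_\delta = 10^{-3}\) guards every division by \(\sin\delta\).
- `ar_from_reference()` errors on an all-zero reference frame.
- Composition at the frame edge: quantized YOLO half-extents are clamped
  downward (≤ 1 µ-unit) so boxes can never leave the unit square.
- Degenerate SSIM rescale (constant pair) leaves values untouched; the
  identical-image score is still exactly 1.
- PGM (8/16-bit) replaces PNG/TIFF for image exchange and JSON replaces
  YAML for the manifest: they are the formats expressible with the
  guaranteed dependency set, and equally standard.

## Known limitations

- Uniform-depth scenes are the default; multi-depth refocusing is
  exercised in tests by composing propagations manually, not by the
  dataset writer.
- The "paper" dataset profile triggers the sampling warning by
  construction (see above); it exists to mirror the stated geometry and
  the 9000/1000 split logic, not for quantitative recovery claims.
- The desk-scale learned-inversion score is a scaled-down reproduction of
  the full-scale result (512², 10,000 holograms, 300 cycles, 57 h GPU),
  which is explicitly out of desk reach.
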