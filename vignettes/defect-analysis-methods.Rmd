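---
title: "Measuring topological defects in active nematic cell monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring topological defects in active nematic cell monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematicdefects)
```

## The model

Confluent monolayers of elongated cells (myoblasts, retinal epithelial
cells, fibroblasts) behave as two-dimensional *active nematics*: cells
align locally along a director axis $\Theta(x, y)$ defined modulo $\pi$,
and the alignment field carries point singularities — topological defects
— characterized by their winding number $k$, the total director rotation
accumulated along a closed loop around the core divided by $2\pi$. In a
nematic, half-integer charges are allowed; the generic defects are the
comet-shaped $+1/2$ (one symmetry axis; a pointed "tail" where the
director is parallel to the axis and a rounded "head" where it is
perpendicular) and the three-fold symmetric $-1/2$. Because cells exert
active stresses, $+1/2$ defects self-propel; the direction of the core
flow relative to the comet axis diagnoses the sign of the active stress
(toward the tail in a contractile tissue, toward the head in an extensile
one). A biologically important subpopulation of $+1/2$ defects remains
*stationary* (tracked speed below 10 µm/h, versus roughly 20 µm/h for
motile defects); around those, flow persists only on the head side and
cell density accumulates at the head — the conditions under which a
monolayer locally splits into two stacked, perpendicularly oriented
layers.

This package implements the measurement chain for that physics on
time-lapse images, and a synthetic-scene generator that provides exact
ground truth for every stage, so the whole chain is verifiable without
any microscopy data.

## Measurement chain

**Director field.** The director is estimated per pixel from the gradient
structure tensor $J = G_{\sigma_w} * (\nabla I\, \nabla I^\top)$, with
Gaussian-derivative gradients (scale $\sigma_g$) and a Gaussian smoothing
window ($\sigma_w$). The texture orientation is the eigenvector of the
*smallest* eigenvalue of $J$ (perpendicular to the mean gradient), mapped
into $[0, \pi)$; coherency $(\lambda_1 - \lambda_2)/(\lambda_1 +
\lambda_2)$ quantifies how well-defined the orientation is. Defaults:
$\sigma_g = 1$ px, $\sigma_w = 8$ px. The small gradient scale is a
deliberate choice: on ridge-like cellular texture, thin gradients give
many statistically independent orientation samples per window, and on the
package's own synthetic textures this roughly halves the angular error
relative to $\sigma_g = 2$ px. Both scales are exposed as arguments.

All raster conventions follow TIFF storage order: origin at the top-left
pixel center, $x$ rightward, $y$ downward, angles measured by
`atan2(dy, dx)` in that frame; output tables are in µm with 0-based
frames.

**Order parameter and detection.** The windowed nematic order parameter
$$Q_\mathrm{local}(\Omega) = \sqrt{\langle\cos 2\Theta\rangle^2_\Omega +
\langle\sin 2\Theta\rangle^2_\Omega}$$ equals 1 for perfect local
alignment and drops to 0 at defect cores. The window is $\Omega$ = 27.8
µm, converted to the nearest odd pixel count. Defects are local minima of
$Q_\mathrm{local}$ below a threshold (default 0.5), suppressed to a
minimum separation (default $\Omega$), and localized to sub-pixel
precision by a separable quadratic fit of the minimum.

**Charge and axis.** The charge is measured by sampling the director on a
circular loop around the candidate core (64 points, tensor-bilinear
interpolation so the $\pi$-ambiguity never crosses an interpolation),
accumulating successive nematic differences reduced into $(-\pi/2,
\pi/2]$, and dividing by $2\pi$. The raw winding snaps to the nearest
multiple of $1/2$ within a tolerance of 0.1; loops of radius 5, 8 and 11
px vote by majority, which makes the measurement robust to the
discretization noise right at the core. Near the core of a defect of
charge $k$ the director is $\Theta \approx k\varphi + c$; the axis is
carried by the phase constant $c$. The default estimator demodulates the
loop samples, $m = \langle e^{i(2\Theta - 2k\varphi)}\rangle$, giving
$2c = \arg m$ — exact on the ideal single-defect solution, and unbiased
to second order under the perturbation of distant defects because the
harmonic cross-terms average out on a full circle (mean-value property).
An independent estimator based on the divergence of the nematic tensor
$Q_{ij}$, averaged over an annulus, is also provided and cross-checked in
the tests; the two agree to fractions of a degree. For $k = +1/2$ the
reported angle $\psi$ is the tail direction in $[0, 2\pi)$; for $k =
-1/2$ it is the canonical symmetry axis, the smallest of the three, in
$[0, 2\pi/3)$.

**Velocity.** Velocity fields come from single-pass window
cross-correlation PIV: 16-px windows with 50% overlap, normalized FFT
cross-correlation, 3-point Gaussian sub-pixel refinement, displacement
validity range $|d| < \mathrm{window}/3$. When the displaced windows
match exactly (overlap correlation 1), the integer peak is returned
unrefined — a perfect match cannot be improved, and this keeps pure
integer displacements exact. Vectors failing a normalized median test
against their 3×3 neighborhood (threshold 2.0, standard PIV practice) are
masked and optionally median-replaced. Pixel calibration and frame
interval are required inputs and are never guessed from data.

**Tracking and motility.** Observations are linked frame-to-frame by
greedy mutual-nearest-neighbor matching restricted to equal charge and a
maximum displacement; unmatched observations start new tracks and a
missed frame terminates a track (no gap closing). Defect counts are small
(of order 10 per field of view), so mutual-NN is adequate; crossing
tracks of equal charge within one linking gate are its documented failure
mode. Track speed is the mean frame-to-frame displacement rate after
centered box smoothing of the positions (default 5 frames, applied only
where the full window fits so that clean linear tracks are measured
exactly). Tracks observed for at least 2 h are classified *stationary*
below 10 µm/h and *motile* above; shorter tracks are *unclassified*.
Backward tracking from a reference frame is the same linking run on the
reversed frame order.

**Defect-frame averaging.** Each $+1/2$ observation is registered into a
canonical frame — core at the origin, tail along $+x$ — by translating,
rotating vectors by $-\psi$, and resampling the director through its
tensor components with the angle shifted by $-\psi$. Angles are never
averaged raw; the $\pi$-ambiguity makes raw angle means ill-defined, so
ensemble averages are taken on $(\cos 2\Theta, \sin 2\Theta)$ and
converted back through the half-angle. The axial velocity profile is the
mean $x$-component over a band $|y| \le 30$ µm, binned in $x$ with SEM
per bin (patch half-size default 150 µm; both exposed). Whether the
original profile used a band or the full transverse extent is not
determinable from published material; the band is this package's choice
and is configurable. The contractility diagnostic averages the axial
velocity over a core disc: positive (toward the tail) beyond a noise
floor is contractile, negative extensile; the antisymmetry of the
vorticity about the defect axis is reported alongside. Note the averaged
angle at the exact core node is meaningless (the tensor resultant
vanishes there), so angular comparisons mask nodes with resultant below
0.2.

**Cell density.** Density maps are sliding-window counts of nuclei
positions divided by the window area; the head-accumulation profile bins
nuclei in the defect frame along the axis, in the same band geometry as
the velocity profile.

**Focal adhesions.** Adhesion images are segmented by one global
threshold shared across all images of a comparison set, with
8-connectivity labeling. For real microscopy the images are
histogram-equalized first and the shared level is Otsu's threshold on the
pooled pixels; note that *perfect* equalization flattens the pooled
histogram, so on synthetic panels with calibrated absolute intensities
segmentation is run without equalization. Area is the pixel count times
the pixel area, with an open-interval gate at (1, 7) µm²: objects at
exactly 1 or 7 µm² are excluded. The perimeter uses a Cauchy–Crofton
estimator over four line directions,
$P = \tfrac{\pi}{8}\left[T_0 + T_{90} + (T_{45} + T_{135})/\sqrt 2\right]$
with $T_d$ the number of foreground/background transitions along the
digital line family in direction $d$ — a naive boundary-pixel count
biases circularity above 1 for small discs, whereas the Crofton estimate
keeps the discretization excess of $4\pi A / P^2$ below about 0.05 at a
10-px radius, shrinking with size. Orientation comes from second central
moments (major axis, nematic, $[0, \pi)$). Head and tail regions are the
half-planes $x < 0$ and $x > 0$ of the defect frame within a radius
limit. Region comparison reports mean ± SD of area and circularity, a
two-sided Mann–Whitney test on circularity (the quantity is bounded and
non-Gaussian, so a rank test; the published analysis names no test), and
nematic orientation histograms over $[-90°, 90°)$ with bins centered on
the defect axis. All adhesions are pooled across fields of view for the
test — a per-image hierarchical analysis is out of scope and the pooling
is flagged here deliberately.

## The synthetic generator, and what passing means

The generator produces every input the chain consumes, with exact truth:

* **Director fields** are harmonic superpositions $\Theta = \sum_i k_i
  \varphi_i + c_0$. For a single $+1/2$ defect, $\Theta = \varphi/2 +
  \psi/2$ places the tail along $\psi$; this sign convention was fixed
  once against the canonical comet geometry and is frozen in code and
  tests. With several defects a single global phase cannot realize every
  requested axis, so the generator honors the first defect's axis exactly
  and reports the *realized* axis of each defect — the effective local
  phase including all other defects' contributions at its core — in the
  truth table. Round-trip tests compare against realized truth.
* **Textures** are line-integral convolutions of white noise along the
  director: streaks about two stripe-periods long and one pixel thin,
  which guarantees a well-defined ground-truth structure tensor (drawing
  discrete cells would not). Limitations: orientation fidelity is best
  on-axis (RMS error ≈ 1.5°) and about twice worse along grid diagonals
  (≈ 4°), and streak contrast does not mimic phase-contrast halo
  artifacts. Textures are bit-reproducible given a seed; the base noise
  can be supplied explicitly, which is what the 90°-rotation oracle tests
  rotate.
* **Flows** are parametric, not active-gel solutions, because only the
  qualitative flow structure is constrained by observation. The
  motile-contractile fixture is $v = v_0 e^{-r/\ell}\hat x$ in the defect
  frame: core flow toward the tail, and its vorticity $-\partial_y v_x$
  automatically forms the two counter-rotating, axis-antisymmetric
  lobes. The stationary fixture is zero on the tail half-plane and
  $v_0 e^{-r/\ell}$ pointing toward the core on the head side. Defaults
  $v_0 = 20$ µm/h, $\ell = 60$ µm match the observed speed scale of
  motile defects and the ~100 µm extent of defect-centered flow
  structures.
* **Trajectories, adhesion panels, nuclei.** Tracks are linear motion
  plus Gaussian jitter (defaults: 15-min frames, 1 µm jitter). Adhesion
  panels are filled ellipses with prescribed area/aspect/orientation on
  a jittered grid (no accidental merging). Nuclei are homogeneous
  Poisson points plus an independent Poisson excess disc, so a fold-2
  hotspot has exactly twice the background intensity.

Passing the round-trip suite therefore shows that the measurement chain
is *correct* — charges exact, positions within $\Omega/2$, axes within a
fraction of a degree, 100% recall/precision at separations above
$3\Omega$ — under noise and texture statistics that the generator
controls. It does not show robustness to everything real microscopy adds
(uneven illumination, defocus, cell division events, defect creation and
annihilation during a movie, separations below $3\Omega$); those remain
the user's responsibility to validate on their data.

## Numerical choices and degenerate inputs

* Winding snap tolerance 0.1; candidates whose majority vote is not a
  non-zero half-integer with $|k| \le 1$ are dropped and logged.
* Loop radii {5, 8, 11} px for charge and axis; loops that would leave
  the field raise an error rather than extrapolate.
* Constant images give coherency 0 everywhere (orientation flagged
  unreliable); non-finite pixels are an error, not a warning.
* Flat PIV windows (zero variance) are masked as "no texture", never
  interpolated silently.
* The discrete odd $\Omega$-window cannot split a half/half field
  exactly evenly; the residual order parameter at the interface is
  exactly $1/w$ for window width $w$, and tests assert that value rather
  than pretending 0.
* Sub-node localization clamps the quadratic-fit offset to ±1 node.
* Degenerate generator inputs (defect cores closer than 2 px) are
  refused as "degenerate configuration".

## Problem sizes

The shipped tests and analysis scripts run on 128–300 px scenes, 50-scene
round-trip ensembles, 60–100 patch ensembles and 100-draw power
simulations; the full suite completes in well under a minute on one core.
These sizes were chosen because every measured quantity is already stable
at them (the acceptance summary varies by well under a percent across
seeds); all generators and operations scale to full-size microscopy
fields unchanged.

## Known limitations

* Mutual-NN linking can swap crossing equal-charge tracks within one
  gate radius.
* Integer-charge ($\pm 1$) defects are reported by winding but no axis
  convention is defined for them (and none is needed for the analyses
  here).
* The realized-axis bookkeeping means requested axes of second and later
  defects in a multi-defect scene are only approximate; the truth table
  is authoritative.
* Single-pass PIV limits trustworthy displacements to about a third of
  the window; larger motions need a shorter frame interval, not a larger
  threshold.
* Per-adhesion pooling across fields of view treats adhesions as
  exchangeable; image-level clustering is not modeled.
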