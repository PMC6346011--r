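---
title: "Shape-mode decomposition and single-cell creep rheology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-mode decomposition and single-cell creep rheology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcrheo)
```

## The measurement problem

In deformability cytometry a suspended cell is pushed through a narrow
microfluidic constriction (square cross-section of 20 or 30 µm, 300 µm
long) by a viscous, shear-thinning carrier. High-speed imaging
(2000–6000 frames/s at 0.34 µm/px over a 1280 × 80 px field of view)
captures the cell contour in every frame. The cell experiences two distinct
mechanical loads in one transit:

* a **stress peak at the channel inlet**, caused by the velocity gradient
  where the flow converges, which compresses the cell fore-aft
  symmetrically, and
* a **constant stress inside the channel**, which pushes the cell into the
  characteristic bullet shape.

Both responses are visible in the deformation trace
$d = 1 - c = 1 - 2\sqrt{\pi A}/P$ (circularity $c$; $A$ projected area, $P$
perimeter), but they overlap in time, so $d$ alone cannot be fitted by a
simple rheological model. The central idea implemented here is to separate
the two responses by the **parity of radial Fourier shape modes**.

## Shape modes

Each contour (the convex hull of the segmented cell outline) is linearly
interpolated with 49 points per edge, transformed into polar coordinates
$(r_n, \varphi_n)$ about its shoelace centroid, and decomposed as

$$a_k = \frac{1}{\pi}\sum_n r_n \cos(k\varphi_n)\,\Delta\varphi_n,\qquad
  b_k = \frac{1}{\pi}\sum_n r_n \sin(k\varphi_n)\,\Delta\varphi_n,$$

with trapezoid-type angular weights
$\Delta\varphi_n = \tfrac12(\varphi_{n+1}-\varphi_{n-1})$. The first ten
$a_k$ suffice to reconstruct cell shapes: $a_0$ is twice the mean radius,
$a_1$ eccentricity, $a_2$ ellipticity, higher orders star-like features.
The $b_k$ encode angular orientation; they average to zero for cells on the
channel axis but are carried through reconstruction because they matter for
off-center cells.

Even cosine modes ($a_2, a_4, a_6, a_8$) share the fore-aft symmetry of the
inlet compression; odd modes ($a_1 \ldots a_9$) share the asymmetry of the
bullet. Reconstructing the radius function from each parity subset
(together with $a_0$) and applying the deformation formula to the
reconstructed shape yields two clean traces per cell: $d_\text{even}$
(alias $d_\text{inlet}$), which peaks at the inlet and relaxes, and
$d_\text{odd}$ (alias $d_\text{channel}$), which rises from zero to a
plateau at the outlet. Because the odd trace starts at zero for *any*
initially symmetric shape, the method needs no assumption about the resting
geometry of the cell.

## Creep model

Both parity traces are fitted with the single-exponential creep law

$$d(t) = d_0 + \hat d\, e^{-t/\tau},$$

with the amplitude signed $+\hat d$ for the relaxing inlet trace and
$-\hat d$ for the saturating channel trace. Fits are gated by the
coefficient of correlation $r^2 = 1 - SS_\text{res}/SS_\text{tot} \ge 0.6$;
rejected cells are counted and reported, never silently dropped. Under a
Kelvin-Voigt interpretation of the channel response to its constant stress
$\sigma_\text{channel}$, the relaxation time satisfies
$\tau_\text{channel} = \eta/E$, so an apparent Young's modulus from the
steady-state deformation and a relaxation time from the fit give an
apparent viscosity $\eta = E\,\tau_\text{channel}$ per cell.

The mapping from steady-state channel deformation (and cell size) to $E$
depends on the full hydrodynamic stress distribution around the cell and is
supplied as a pluggable calibration look-up table; computing it is outside
the scope of this package. The FEM-derived mean surface stresses for the
three standard measurement conditions (142 Pa for a 30 µm channel at
8 nl/s, 216 Pa and 128 Pa for 20 µm channels at 4 nl/s) enter as
configuration constants, as do the matching mean shear rates (5100, 9700,
8600 s⁻¹). The carrier viscosity follows a power law
$\eta(\dot\gamma) = K(\dot\gamma/\dot\gamma_0)^{n-1}$ with
$K = 0.16$ Pa·s, $n = 0.74$ (0.6% methylcellulose) or $K = 0.60$ Pa·s,
$n = 0.64$ (1%), $\dot\gamma_0 = 1$ s⁻¹.

As an alternative material law the package also fits power-law (soft
glassy) rheology, $J(t) = \tfrac1E (t/t_0)^\beta$ with $t_0 = 1$ s, to the
channel creep compliance; the strain is approximated by scaling the
normalized deformation to a 10% peak surface displacement. Comparing the
residuals of the two fits on the same segment shows which material law the
data prefer.

## The synthetic-data generator

The simulator produces ground-truth cells so the whole chain can be
validated without an instrument. Its design choices:

* **Deformation is prescribed directly.** The generator specifies
  $d_\text{even}(t)$ as the Kelvin-Voigt response to a half-Gaussian
  stress peak ending at the inlet (the true inlet transient is an FEM
  result with no published closed form; the half-Gaussian is a documented
  stand-in, width 15 µm by default) and $d_\text{odd}(t)$ as
  $\hat d_\text{channel}(1 - e^{-t/\tau})$ with
  $\tau = \eta_\text{true}/E_\text{true}$. Deformation — not raw mode
  amplitude — is the observable the creep law is fitted to, and deformation
  is second order in mode amplitude, so prescribing amplitudes would not
  produce exponential deformation traces.
* **Convex shape families.** An area-preserving ellipse carries the even
  response (it has no odd content by symmetry); an egg curve
  $(x, y) = (a\cos u,\, b\sin u\,(1+\alpha\cos u))$ carries the odd
  response and stays convex up to $\alpha \approx 0.7$, which caps the
  odd-parity deformation of a convex cell near 0.04 — consistent with the
  small channel deformations of real cells.
* **Joint amplitude calibration.** Elongation and asymmetry couple in the
  measured parity deformations, so the generator tabulates the map
  $(\delta, \alpha) \mapsto (d_\text{even}, d_\text{odd})$ on a grid and
  inverts it per frame (alternating monotone 1-D inversions plus exact
  Newton refinement). The map is computed by generator-local geometry code
  — shoelace sums and a trapezoid-weighted DFT written independently of the
  analysis module — so that recovery tests compare two separate code paths.
  When the even target falls below the asymmetry-induced even leakage the
  elongation clamps at zero; the measured even trace therefore floors at
  that leakage level late in the channel, which mildly biases the *inlet*
  relaxation-time fit (a known limitation; the channel fit is unaffected
  because the ellipse leaks nothing into odd parity).
* **Rendering.** Contours are rasterized at 0.34 µm/px (configurable) by
  supersampled area coverage with a 50% threshold, giving binary frames.
  Contour noise is applied radially per vertex (i.i.d. Gaussian, before any
  convex-hull step), mimicking segmentation jitter.
* **Toy calibration.** For closed-loop studies the default look-up table
  implements $\hat d = c\sqrt{\sigma/E}$ with $c = 0.030$: a saturating
  deformation response (the real stress-to-shape model also saturates) that
  maps $E \in [0.1, 2]$ kPa at 142 Pa to $\hat d \in [0.008, 0.036]$ —
  inside the convex-bullet range and above the pixelation floor. A linear
  toy table $E = \sigma g/\hat d$ is also provided.

What the generator does **not** emulate: optical blur and camera noise,
cell rotation, non-convex shapes, cell-cell interactions, the true FEM
stress transient, and any dependence of the calibration on cell size. A
passing recovery study therefore validates the analysis mathematics and its
pixel-level robustness, not the hydrodynamic calibration itself.

## Imaging and tracking

Frames are binarized with a global Otsu threshold (a fixed threshold is
available in the configuration), connected components are labeled with
EBImage, and each component above 50 px² becomes the convex hull of its
boundary pixels. Because centers of boundary pixels sit systematically
inside the true edge — on average a quarter pixel for a 50%-coverage
binarization — the hull is dilated radially by 0.25 px. Tracking follows
the instrument's moving sub-ROI scheme: a 250 × 80 px window opens when a
cell appears in the inlet region and advances by 48% of its length whenever
the cell's center of mass passes 70% of the window (strictly greater than,
by a literal reading of the rule; both fractions are arguments). One cell
per ROI is enforced; collisions, stationary debris (net displacement below
20 px) and tracks shorter than 14 observations are excluded with recorded
reasons.

## Numerical choices

* Contour timestamps are `frame_index / fps`; no sub-frame interpolation.
* Polar angles are unwrapped along the traversal and the contour is rotated
  to start near $\varphi = -\pi$; the angular weights telescope to $2\pi$
  exactly. Non-star-shaped inputs are rejected.
* Reconstructions are sampled at 1000 uniform angles, making discretization
  error far below the ~1% reconstruction-fidelity budget; a reconstruction
  with non-positive radius is an error and the trace point is dropped
  (a trace with more than 20% dropped points is rejected).
* Deformation is clipped at zero where pixelation pushes circularity
  marginally above one.
* The creep fit uses bounded Levenberg-Marquardt least squares
  (`minpack.lm`), started at `d0` = last value, `d_hat` = |first − last|,
  `tau` = a third of the segment span, with `tau` bounded to
  `[dt/10, 100 × span]`; a bound-hitting `tau` is flagged. The inlet
  segment runs from the even-parity maximum to 40% of the channel length
  past the inlet; the channel segment from the first in-channel frame to
  the outlet (both configurable — the choice of cut points is a design
  decision, not part of the model).
* The channel amplitude $\hat d_\text{channel}$ is the fitted plateau
  `d0` minus the pre-channel baseline of the odd trace (median of the last
  pre-channel frames), so initially non-circular cells start from zero and
  the discrete sampling of the channel entry does not bias the amplitude.
  A trace ending before the plateau keeps the fitted `d0` and is flagged
  `no_plateau`.
* Coefficient normalization by $a_0$ is available for size-invariant
  reporting but never used for reconstruction, which needs length units.

## Validation studies and their problem sizes

`recovery_study()` encapsulates the closed-loop experiment: simulate cells
with known $(E, \eta)$, analyse them, compare. Its sampling design is fixed
a priori: the transit spans six relaxation times (velocity capped at
24 cm/s, the top speed cells reach in practice) so the plateau is well
constrained, the frame rate is eight frames per relaxation time clamped to
[2000, 20000] fps (stiff, low-viscosity cells relax in a fraction of a
millisecond and genuinely require sampling faster than the 2000–6000 fps
camera range — a physical requirement of the time scale, stated here once),
and each condition is summarized by the median over a small cohort whose
velocities and entry phases are jittered so that sub-pixel sampling
patterns decorrelate across cells. The cohort size balances total frames
per condition (about 600), between 2 cells for slow relaxers (over a
thousand frames each) and about 20 for fast ones.

The test suite runs this study on a 3 × 3 grid spanning
$E \in [0.1, 2]$ kPa and $\eta \in [0.5, 10]$ Pa·s from rendered binary
frames at the instrument resolution, and a 100-cell cohort with radial
contour noise of 2% of the cell radius on the contour path. Single-cell
estimates at the stiffest, least-deformed grid points carry ~10-15%
pixelation scatter per cell — which is why conditions are summarized by
cohort medians, exactly as instrument data are.

## Known limitations

* The inlet relaxation time is mildly biased when the odd response is
  strong, because the egg family leaks a small even component that the
  generator can only cancel while the prescribed even target exceeds the
  leakage (see above). Channel-side parameters ($E$, $\eta$,
  $\tau_\text{channel}$) are unaffected.
* At 0.34 µm/px a binary contour of a 9 µm cell quantizes the odd-parity
  deformation with a standard deviation near $10^{-3}$ per frame; channel
  amplitudes below ~0.008 (stiff cells at 142 Pa) approach this floor, and
  per-cell relaxation times there scatter by over 10%. Population medians
  absorb most, but not all, of this.
* The calibration look-up table is a seam: all moduli inherit its accuracy.
  The toy tables shipped with the package are for validation and teaching,
  not for interpreting instrument data.
* Linear mixed models, logistic classification and other population-level
  statistics are intentionally not implemented; per-cell results are
  exported as tidy CSV for external statistical software.
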