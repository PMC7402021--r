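---
title: "Modelling and inverting the orientation dependence of the gradient-echo frequency shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and inverting the orientation dependence of the gradient-echo frequency shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msai)
```

## The problem

The phase of the gradient-echo MR signal in brain white matter depends on
how the myelinated axons in a voxel are oriented with respect to the main
magnetic field $\hat B_0$.  Two very different tissue properties are
conflated in that dependence: the *microscopic* susceptibility anisotropy of
the myelin sheath (a marker of myelination) and the *voxel-scale* axon
orientation distribution (fiber crossings, fanning, dispersion).  A fiber
bundle running parallel to the field produces almost no frequency shift no
matter how heavily it is myelinated; a perpendicular bundle shows the full
microscopic shift.  `msai` separates these two effects: given the axon
orientation distribution function (ODF, estimated upstream from diffusion
MRI), it recovers the **microscopic frequency shift** $\omega_{A}(t)$ — the
frequency offset a single microdomain would exhibit if it were oriented
perpendicular to the field — per voxel and per echo time, unconfounded by
the orientational architecture.

## Forward model

A single microdomain (an axon segment) with orientation $u$ accrues, at
echo time $t$ relative to a short reference echo $t_0$, the frequency shift

$$\delta\omega(\theta, t) = \omega_A(t)\,\sin^2\theta,
\qquad \cos\theta = \langle \hat B_0, u\rangle ,$$

and thus contributes the unit phasor
$\exp\!\left(i\,\omega_A(t)\sin^2\theta\,(t - t_0)\right)$ to the voxel
signal.  Averaging over the voxel's orientation distribution $p(u)$ — a
non-negative, antipodally symmetric density integrating to one on the unit
sphere — gives the ensemble signal shift

$$\delta E(\hat B_0, t)
  = \int_{S^2} \exp\!\left(i\,\omega_A(t)\,[1 - \langle\hat B_0,u\rangle^2]\,(t-t_0)\right) p(u)\, du .$$

Two numerically equivalent evaluation routes are implemented:

* **quadrature** — summation over an antipodally paired sphere grid
  (`make_antipodal_grid()`, `ensemble_signal(method = "quadrature")`).
  Note the density convention: $p$ is a true density with
  $\int p\,du = 1$ and the quadrature weights carry the surface measure
  (they sum to $4\pi$).  A plain average of $\exp(\cdot)\,p(u_j)$ over $N$
  points is consistent only when $p$ is expressed relative to the uniform
  density; fixing $p$ as a true density and letting the weights carry
  $4\pi/N$ reproduces the integral without a $4\pi$ ambiguity.
* **spherical harmonics** — by the Funk–Hecke theorem a zonal kernel
  $f(\langle\hat B_0, u\rangle)$ acts diagonally per order on the SH
  coefficients of $p$, with per-order Legendre coefficients
  $\lambda_\ell = 2\pi\int_{-1}^1 f(c)P_\ell(c)\,dc$
  (`zonal_kernel_coefficients()`, `funk_hecke_convolve()`).  This route
  needs no sphere grid and is what the fitting code uses.

ODFs are carried as real, orthonormal, even-order spherical harmonics up to
order 8 (45 coefficients).  The ordering is orders ascending and degrees
$m = -\ell,\dots,\ell$ within an order, with $\sin$ terms at $m<0$, $\cos$
terms at $m>0$, and the Condon–Shortley phase inside the associated
Legendre functions.  This convention is fixed package-wide and recorded in
a JSON sidecar next to every coefficient volume written.

### Sphere grid and quadrature weights

The hemisphere point set is a deterministic spherical Fibonacci lattice,
mirrored through the origin so directions come in exact $(u, -u)$ pairs.
Plain equal weights $4\pi/N$ on such a lattice integrate order-16
polynomials only to about $10^{-2}$ relative accuracy, which is far too
coarse for checking an order-8 model against quadrature.  The weights
therefore receive a *minimal-norm correction* that makes all even
spherical harmonics up to order 16 integrate exactly — products of two
order-8 functions are then exact to machine precision — while remaining
strictly positive and summing to $4\pi$ (the correction perturbs the
uniform weights by well under a factor of two at $N = 500$).  If a very
small grid cannot support the full constraint set, the exactness order is
reduced automatically.

### Watson distributions and the band limit

Synthetic single-fiber ODFs are antipodally symmetric Watson densities
$\propto \exp(\kappa\langle\mu,u\rangle^2)$.  Because the density is zonal
about $\mu$, its SH coefficients are $\lambda_\ell(\kappa) Y_{\ell m}(\mu)$
with $\lambda_\ell$ a ratio of 1D integrals over the cosine; these are
evaluated by high-order Gauss–Legendre quadrature after shifting the
exponent ($e^{\kappa(t^2-1)}$), with the integration interval split near
$|t| = 1$ for large $\kappa$ so the $O(1/\sqrt\kappa)$ boundary layer is
resolved.  Normalisation therefore never touches confluent hypergeometric
functions and remains finite for arbitrarily large $\kappa$.

An order-8 representation cannot hold an arbitrarily sharp density.  At
$\kappa \approx 4.2$ the truncation error of the reconstructed density at
its peak reaches 1% and keeps growing; `watson_odf()` warns above this
documented cap.  Important nuance: the projection is *exact in every
retained order* at any $\kappa$ — only the pointwise band-limited density
degrades (it rings and can go negative).  Quantities that depend only on
low-order moments, notably the orientation weighting below, remain exact
for arbitrarily concentrated distributions.  The delta-like constructions
used to probe the parallel/perpendicular limits intentionally exceed the
cap for precisely this reason, and the phantom's "coherent fiber" classes
($\kappa = 100$) do as well.

### Orientation distribution weighting and dispersion entropy

The short-time sensitivity of the experiment to the microscopic shift is

$$\pi(\hat B_0) = \int_{S^2} \left(1 - \langle\hat B_0, u\rangle^2\right) p(u)\,du \in [0, 1],$$

0 when all axon segments run parallel to the field (no observable shift,
regardless of myelination) and 1 when all run perpendicular.  The kernel
is a degree-2 zonal polynomial, so only the order-0 and order-2
coefficients contribute; `orientation_weighting()` uses the exact
Funk–Hecke coefficients $8\pi/3$ and $-8\pi/15$.  The uniform distribution
gives exactly $2/3$.

`dispersion_entropy()` summarises orientational heterogeneity as the
relative entropy of $p$ with respect to the uniform density,
$\int p \ln(4\pi p)\,du$, computed by grid quadrature in nats (the natural
logarithm is a package convention; no particular base is canonical).  The
band-limited density is clipped at $10^{-12}$ inside the logarithm, and
densities below $-10^{-3}$ anywhere on the grid signal an invalid ODF
rather than being silently repaired.

## Frequency difference mapping

Per-echo phase volumes are converted to frequency shifts relative to the
reference echo on the complex circle,
$y = \mathrm{Arg}\!\left(e^{i(\varphi_t - \varphi_{t_0})}\right)/(t - t_0)$,
so any common $2\pi k$ offset cancels.  Remaining large-scale field
structure is removed by a masked least-squares 3D polynomial fit
(`remove_background()`, default order 2).  This detrending plays the role
of a variational field-removal step in a scanner pipeline; it is fully
specified, testable, and preserves the essential contract: because the
constant term belongs to the background, the residual is known only up to
a spatially constant offset $\phi_{\hat B_0, t}$ per field direction and
echo.  That constant is recovered later, jointly with the microscopic
shift.  Only odd-numbered echoes are analysed by default (a scheme-level
mask), since even echoes of a bipolar readout can differ in signal
formation.

## Estimation

### Phase-metric fit per voxel and echo

With measurements $y(\hat B_0, t)$ at one or more field directions, the
microscopic shift is the minimiser of

$$\sum_{\hat B_0} D\!\left\{\,e^{i y (t-t_0)},\ \mathrm{sgn}\,\delta E(\omega_A)\right\}^2,
\qquad D\{z_1, z_2\} = \arccos\!\big(\mathrm{Re}(z_1^* z_2)\big),$$

where $\mathrm{sgn}(z) = z/|z|$.  The magnitude attenuation of $\delta E$
under dispersion is computed and exposed but deliberately never used in the
objective — the estimator is a pure phase fit.  The objective is cheap,
one-dimensional, and multimodal under phase wrapping, so `fit_voxel()` uses
a deterministic dense grid scan (default 721 points) over the search
interval followed by bounded local refinement (`stats::optimize`), with
ties broken towards the smallest $|\omega_A|$.  Determinism makes every
result exactly reproducible.

Voxels whose orientation weighting is below $10^{-3}$ for *every* acquired
field direction are still fitted but flagged: with a single field
direction a perfectly parallel fiber population is uninformative, yet in
practice intravoxel dispersion almost always leaves some sensitivity,
which is why the fit is not refused outright.

### Wrap tracking across the echo train

At late echoes the accumulated phase $\omega_A (t - t_0)$ can exceed
$\pi$, making an isolated fit alias.  Assuming the microscopic shift
evolves smoothly in time, `track_echo_train()` fits echoes in increasing
order: the first fitted echo searches $[-\pi/t_1, +\pi/t_1]$ (centred at
zero), and echo $t_{k+1}$ searches an interval of half-width
$\pi/t_{k+1}$ centred on the previous estimate.  The half-width uses the
*absolute* echo time by default, the literal reading of the interval rule;
a `"relative"` mode using $t_{k+1} - t_0$ is provided for sensitivity
analyses, since the printed rule is ambiguous on this point.  Both modes
are deliberately exposed rather than resolving the ambiguity silently.

### Joint global-offset estimation

After background removal each (field direction, echo) measurement carries
an unknown spatially constant offset.  `estimate_offsets()` recovers these
jointly with the voxelwise shifts by alternating minimisation over an ROI:
(i) voxelwise tracking at fixed offsets; (ii) per-(position, echo) offset
update towards the circular mean of the per-voxel phase residuals,
accepted only if it lowers the total squared phase error, so the total
objective is non-increasing across iterations.  The iteration stops when
the decrease falls below $10^{-8}\,\mathrm{rad}^2$ or after 100 sweeps —
both are package choices, as is the acceleration: the plain alternation
contracts slowly along a near-degenerate direction that trades a common
offset against coordinated shifts in all voxels, so every third sweep the
offset sequence is extrapolated geometrically (Aitken), rolling back any
extrapolation that fails to lower the error.  On a noise-free 500-voxel
two-position phantom this converges in roughly a dozen sweeps where the
plain iteration needs hundreds.  At least two head orientations are
required; with one the decomposition is not identifiable, and the
function refuses with a clear error.  Offsets are parameterised in rad/s
and applied as $e^{i\phi(t-t_0)}$ on the measurement phasor, keeping the
comparison between unit phasors dimensionally coherent.

## Noise amplification

Linearising the fit around the estimate gives the g-factor
$g = (J^\top J)^{-1}$ with per-direction central differences

$$J_{\hat B_0} = \frac{D\{\mathrm{sgn}\,\delta E(\tilde\omega + \epsilon),\ \mathrm{sgn}\,\delta E(\tilde\omega - \epsilon)\}}{2\epsilon},$$

assuming i.i.d. Gaussian frequency noise of equal level across field
directions.  The default step is $\epsilon = 10^{-6} \cdot 2\pi/t$ (a
fixed fraction of the wrap-tracking interval width; a step-halving check
in the tests confirms the estimate is in the stable regime).  The
predicted estimator spread is $\sqrt{g}\,\sigma_y (t - t_0)$, which a
seeded Monte Carlo oracle (`monte_carlo_std()`) reproduces within 15% at
small noise.  $J^\top J$ is a sum of squares, so appending a head
orientation can never increase the unnormalised $g$; a second direction
at ~60° dramatically reduces amplification for fibers parallel to the
first — the geometric argument for acquiring at least two head positions.
A `normalize = TRUE` variant multiplies $g$ by the number of positions,
referencing it to plain signal averaging so acquisitions of different
scan time are comparable; the exact normalisation used for published
g-factor maps is not fully specified anywhere, so the raw
$(J^\top J)^{-1}$ is the default and the corrected variant is opt-in.

## The synthetic phantom

Because no public data accompany this kind of acquisition, every stage is
exercised against `build_phantom()`: a voxel grid with five tissue
archetypes (coherent fiber parallel to the standard field direction,
coherent perpendicular fiber, dispersed fiber at Watson $\kappa = 5$,
50/50 orthogonal crossing, isotropic tissue), each with a known
microscopic shift time course.  The default curves ramp linearly from 0
at the reference echo to $-3$ Hz at the last selected echo in the
white-matter-like classes and stay at 0 in the isotropic class — values
chosen as illustrative of the reported qualitative behaviour (the shift
in white matter grows more negative with echo time, at a few Hz by
~40 ms) since no ground-truth table exists; they are user-configurable
(`default_tissue_classes()`, or any `micro_shift_curve`).  The default
acquisition (`default_scheme()`) is the reference geometry: 11 echoes
from 4.5 ms at 4.5 ms spacing, odd echoes selected, reference at 4.5 ms,
and up to three head orientations ±29.9° about the left–right axis
(59.8° between extremes).

`simulate_measurements()` produces
$y = \mathrm{Arg}(\delta E)/(t - t_0) + \phi_{\hat B_0,t} + \text{background} + \varepsilon$
with i.i.d. Gaussian $\varepsilon$ on the *frequency* measurements
(matching the stated noise model; raw-phase noise, Rician magnitude
effects, coil combination, motion and distortion are deliberately not
emulated).  Passing tests on this phantom therefore demonstrates
correctness of the modelling and inversion chain, not robustness to every
artifact of scanner data.

```{r phantom-example}
scheme <- default_scheme(3)
phantom <- build_phantom(c(5, 5, 2), scheme)
data <- simulate_measurements(phantom)
odfs <- phantom_odfs(phantom)
fit <- track_echo_train(matrix(data$values[1, , ], nrow = 3),
                        odfs[[1]], scheme)
rbind(estimated_hz = fit$omega / (2 * pi),
      truth_hz = phantom_truth(phantom)[phantom$class_index[1], ] / (2 * pi))
```

## Numerical choices and limitations

* **Problem sizes.**  The shipped tests run the full pipeline on grids of
  50–500 voxels with the 721-point search grid; these sizes characterise
  the method completely because phantom classes are homogeneous.  Whole-
  brain volumes simply scale linearly in voxels.
* **Times and units.**  Echo times cross module boundaries in
  milliseconds and are converted to seconds exactly once; all internal
  phase arithmetic uses rad/s so $\omega (t - t_0)$ is dimensionless.
  Written maps are in Hz ($\omega/2\pi$), the displayed convention.
* **Gauss–Legendre orders.**  Zonal kernel expansion uses
  $2\,\ell_{\max} + 16$ nodes (ample for phase excursions up to $\pi$);
  the fitting profile uses 64 nodes, accurate for the several-$\pi$
  excursions reached during wrap tracking.
* **Degenerate inputs.**  Zero phasors are rejected by the phase metric;
  $\mathrm{sgn}$ is guarded where $|\delta E|$ passes through zero for
  strongly dispersed ODFs; vanishing $J^\top J$ yields an infinite
  g-factor with a warning rather than an error.
* **Out of scope.**  Raw-phase unwrapping, coil combination,
  registration between head positions, estimation of ODFs from diffusion
  data, variational (TGV-style) background-field removal, and
  compartmental myelin signal models.  ODFs are inputs here.
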