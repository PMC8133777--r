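---
title: "Models and methods behind epimech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epimech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

epimech quantifies tissue-scale patterning of cell morphology in a
pseudo-2D epithelium such as the *Drosophila* wing-disc pouch, and models
it with an active nematic continuum theory. This vignette explains the
science implemented in each module, the conventions and numerical choices
made where several were defensible, what the synthetic-data generator does
and does not emulate, and the known limitations.

## Nematic description of cell shape

All oriented quantities — cell elongation $Q$, the polarity cue $q$,
shear and normalized stress anisotropy — are traceless symmetric $2\times
2$ tensors with two independent components $(\cdot_{xx}, \cdot_{xy})$. A
nematic encodes an axis (not a direction) and a magnitude; rotating the
frame by $\theta$ rotates the components by $2\theta$. The radial
projection at polar angle $\phi$ is
$Q_{rr} = Q_{xx}\cos 2\phi + Q_{xy}\sin 2\phi$; negative $Q_{rr}$ means
tangential elongation.

## Triangle-method morphometry

Cell elongation is defined on the triangulation connecting centroids of
neighboring cells. Each triangle is described by the linear map $s$ taking
an equilateral reference triangle to the observed one, factored uniquely
as
$$s = \left(\frac{a}{a_0}\right)^{1/2} \exp(\tilde q)\, R(\theta),$$
an area ratio, a finite elongation (matrix exponential of a traceless
symmetric tensor) and a rotation. Tissue elongation over a patch is the
area-weighted mean of triangle elongations, which is exactly additive over
sub-patches. The reference triangle area is set to the frame's mean
triangle area: only ratios enter any downstream result.

**Curvature deprojection.** The pouch is slightly domed, so apical shapes
imaged in 2D projection are distorted. From a height map smoothed with a
Gaussian of width $\sigma = 2\,\mu m$ (and the gradient smoothed again
with the same kernel) we form, at each element center, the tilt factor
$\lambda = \sqrt{1 + |\nabla h|^2}$ and the tilt transformation
$N = R(\alpha)\,\mathrm{diag}(\lambda, 1)\,R(-\alpha)$ with $\alpha$ the
steepest-ascent angle; the deprojected state is $N s$ and the deprojected
area $a\lambda$. The factor $\sqrt{1+|\nabla h|^2}$ is the geometrically
exact one for a tilted plane and is used for both the tensor and the area;
for shallow domes the difference from the linearized form is second order.
Deprojection is exact on analytic tilted planes and accurate to the raster
and smoothing resolution on domes (the smoothing kernel slightly averages
the gradient where curvature varies).

**Center of the radial pattern.** The pattern center is assumed on the DV
boundary (the x axis). For a candidate position $x$ the tissue is split
into quadrants (numbered counter-clockwise from the top-right) and
$$F(x) = A_I\langle Q_{xy}\rangle_I - A_{II}\langle Q_{xy}\rangle_{II}
       + A_{III}\langle Q_{xy}\rangle_{III}
       - A_{IV}\langle Q_{xy}\rangle_{IV}.$$
For a tangential (or radial) pattern $F$ is a signed well whose minimum
sits where the dividing line passes through the center — there $Q_{xy}$
vanishes along the line, so $F$ is stationary. We therefore take the
scanned $x$ minimizing $F$ (default scan step $1\,\mu m$, ties broken
toward smallest $|x|$). Note that $F$ does *not* cross zero at the center
of an ideally mirror-symmetric pattern: every quadrant combination of
$Q_{xy}$ integrals is either independent of $x$ or non-vanishing there, so
a zero-crossing criterion would be ill-posed; the signed minimum is
well-posed. For spatially uniform elongation $F$ reduces to a
quadrant-area imbalance carrying no center information; this is flagged
degenerate (well depth below 2% of the available elongation scale). On an
exact tangential pattern the center is recovered within one scan step; on
fully synthetic tissues, where the measured elongation carries lattice
noise, the well is shallow and the center is localized to a few
micrometres — matching the precision one should expect from this
functional on real data.

**Region rules and averaging.** Cells within the 22-$\mu m$ stripe around
the DV boundary are labeled `DV_band` and excluded from radial profiles by
default, as are border (`excluded`) cells. Radial profiles bin by rounding
the distance to the center to the nearest 10 $\mu m$ and report mean cell
area and area-weighted $Q_{rr}$ with dispersions. Grid maps discard boxes
whose cell-area coverage is below 33% (border noise).

## Shear decomposition

Between tracked frames, coarse-grained tissue shear obeys
$\tilde v = DQ/Dt + R$: the co-rotational change of mean cell elongation
plus rearrangement-driven shear, the latter carrying T1, division,
extrusion and correlation contributions. Operationally, per interval:

* `total` — area-weighted mean of the per-triangle log-strain nematic of
  matched triangles (vertices matched through the lineage);
* `dQ` — co-rotational change of mean elongation over all triangles;
* `t1`, `cd`, `ex` — minus the jump in mean elongation carried by
  triangles destroyed/created at the corresponding events; triangles are
  labeled by fate with priority extrusion > division > T1 (rarest first);
* `corr` — the exact closure residual, lumping all correlation terms.

The closure identity holds to numerical precision by construction; the
scientific content is that the residual is *small* on homogeneous
event-free data (verified: zero for affine deformations and scripted
events). Matched pairs whose triangle orientation flips within an interval
(a degenerate tracking situation) are dropped from `total` defensively.
Event-free affine deformations reproduce the log-strain of the map to
$10^{-8}$; rigid rotations produce exact zeros.

For radial analyses every tensor is projected on the local radial axis
per-triangle before averaging. Cumulative curves apply a centered moving
average (kernel 11 frames), drop the adaption phase (first 2 hr by
default) and accumulate.

The isotropic (area-growth) decomposition is an exact log-partition:
extrusion $= \ln(A_{kept}/A)$, cell-area change $=$ the surviving cells'
log growth, division $=$ the remainder. This differs in convention from
rate-based bookkeeping in tracking databases but closes exactly and
reduces to the obvious answers in the limiting cases.

## ESCA: stress inference from circular ablation

A circular cut (radius $r_{cut} = 7\,\mu m$) relaxes to an inner and an
outer elliptical contour that encode the pre-cut stress, normalized by the
elastic constants: $\tilde s = \tilde\sigma/(2K)$, $p = P/\bar K$ and, at
the ensemble level, $\rho = 2K/\bar K$.

*Conventions.* Tension is positive; $p > 0$ means compression, so the
freed inner piece expands. Cells hit by the laser die, so the initial
inner radius is reduced by half a mean cell diameter:
$r_{eff} = r_{cut} - \sqrt{\bar a/\pi}$.

*Forward model.* The inner piece releases its elastic deformation
completely: semi-axes $r_{eff}\exp(p/2 \mp \tilde s)$, contracted along
the tension axis. The outer rim follows the classical traction-free
circular hole in an infinite 2D elastic sheet with Kolosov constant
$\kappa = 1 + \rho$:
$$u_r(\theta) = r_{cut}\left[c_0\,p + c_2\,\tilde s\cos 2(\theta -
\text{axis})\right],\qquad c_0 = -\left(\tfrac12 +
\tfrac1\rho\right),\quad c_2 = 2 + \rho,$$
with the rim displacement measured from the unstressed reference
configuration — the same reference against which the inner piece is
compared, which makes the pair of contours jointly interpretable. Both
coefficients are validated against an independent finite-element solution
of the annulus problem (energy minimization per Fourier mode with traction
boundary conditions) to better than 1%. Had the rim displacement instead
been referenced to the pre-cut stressed state, the coefficients would read
$-1/\rho$ and $1+\rho$; the convention only rescales the inferred $p$ and
$\tilde s$ jointly with $\rho$ and is self-consistent throughout the
package (forward model, inversion, generator).

*Inversion.* At fixed $\rho$ the six observables (inner log-size, inner
log-anisotropy nematic, outer mean-size change, outer anisotropy nematic)
are linear in $(p, \tilde s_{xx}, \tilde s_{xy})$, so each cut is solved
by linear least squares, weighting inner and outer residuals equally (the
published protocol does not state its weighting). The ensemble estimate of
$\rho$ minimizes the summed per-cut residuals over a grid of fixed ratios,
after excluding cuts whose best residual exceeds 3x the ensemble median
(eliminating non-elliptical outlines); uncertainty is the SD over 100
bootstrap subsets of 7 cuts. Identifiability of $\rho$ comes from the
overdetermination between inner (size) and outer (rim) responses and
requires non-zero stress.

*Position bookkeeping.* Distances measured on fixed tissue are rescaled by
$1/(1-0.15)$ for fixation shrinkage. Cuts within $7\,\mu m$ of the AP
boundary are excluded; a cut is `DV_band` if it protrudes at most
$1.4\,\mu m$ (20% of the radius) from the 22-$\mu m$ stripe, `outside` if
it intrudes at most that much, else `border_excluded`.

*Ellipse fitting.* Contours are fit by the direct algebraic least-squares
conic method constrained to ellipses, refined by minimizing the exact RMS
point-to-ellipse distance (per-point Newton on the support angle).

## Continuum model with mechanosensitive feedback

Constitutive relations: $\tilde\sigma = 2KQ + \zeta q$ and
$R = Q/\tau + \lambda q$. At steady state with vanishing shear and
rearrangement, $Q = -\tau\lambda q$: radially oriented rearrangements
sustain tangential elongation. Pressure follows cell area,
$P = -\bar K\ln(a/a_0)$, and radial force balance
$\partial_r P = \partial_r\tilde\sigma_{rr} + 2\tilde\sigma_{rr}/r$
links the stress profile to the area profile; the quadrature is adaptive
(about $10^{-10}$ relative accuracy) and matches closed forms for
constant and power-law stress profiles to $10^{-8}$.

Eliminating $q$ gives the per-ablation relation
$\tilde\sigma_{rr} = 2K^* Q_{rr} + 2(K - K^*)\tau R_{rr}$ with
$K^* = (1 - \zeta/(2K\tau\lambda))K$; a slope of 1 in
$\tilde\sigma/(2K)$ vs $Q$ corresponds to a tissue without a polarity
cue, and the relaxation time follows as
$\tau = \mathrm{intercept}/((1-\mathrm{slope})R_{rr})$.

**Feedback and pitchfork.** Polarity obeys
$\dot q = -q/\tau_q - \mu\tilde\sigma - \alpha|q|^2 q + D\nabla^2 q$.
Beyond $\mu_c = 1/(\tau_q(2K\tau\lambda - \zeta))$ the isotropic state
destabilizes and a polarized state of amplitude
$q_0^2 = (\tau_q\mu(2K\tau\lambda - \zeta) - 1)/(\alpha\tau_q)$ emerges.
The sign of the $-\mu\tilde\sigma$ coupling is fixed by requiring exactly
this amplitude to emerge from the coupled dynamics; time integration of
the homogeneous system (deSolve) reproduces it to $10^{-6}$ and confirms
the $\sqrt{\mu - \mu_c}$ scaling.

**Radial steady state.** In radial symmetry, substituting
$Q_{rr} = \tau(R_{rr} - \lambda q_{rr})$ yields
$$0 = \frac{D}{\alpha}\left(q'' + \frac{q'}{r} - \frac{4q}{r^2}\right)
 + q_0^2 q - q^3 - \frac{2K\mu\tau}{\alpha}R_{rr},$$
where the $-4q/r^2$ term is the tensor part of the nematic Laplacian. The
component norm $|q|^2 = q_{rr}^2 + q_{r\theta}^2$ is used with
$q_{r\theta}\equiv 0$ in the reduction; alternative norm conventions
rescale $\alpha$ and are absorbed by the fit. The solver marches from
$r_{in}$ with the two inner boundary values (classical RK4, substep
0.05 $\mu m$ by default); a damped-Newton collocation solver provides an
independent cross-check (agreement $10^{-4}$ at matched grids) and
handles long domains, where the march is exponentially unstable, or an
outer Neumann condition (used to verify the far-field plateau at $q_0$ to
the analytic $-4q/r^2$ correction). The cubic balance bounds the
admissible forcing: for $(2K\mu\tau/\alpha)R_{rr}$ beyond
$\tfrac{2}{3\sqrt3}q_0^3\,(\alpha/D)^{-1}\dots$ the marched solution
blows up in finite radius, which the solver reports rather than masking.

**Parameter fitting.** Only the identifiable combinations are fit:
$q_0^2$, $\lambda\tau$, $D/\alpha$ ($\mu m^2$), the forcing
$(2K\mu\tau/D)R_{rr}$ ($\mu m^{-2}$), and the two inner boundary values.
(The published composite grouping of the forcing parameter is
typographically ambiguous; the package parameterizes the forcing exactly
as it enters the reduced equation above.) Uncertainty intervals are the
10th/90th percentiles over 101 refits of profiles resampled uniformly
within the per-bin SD, each refit run with the same protocol (same
starting point) as the original fit so that poorly identified directions
scatter honestly. With six parameters against one radial curve the
problem is near-degenerate — wide intervals are the expected, correct
outcome, and the package reproduces that behavior on synthetic profiles.

## The synthetic-tissue generator

The generator provides ground truth for every analysis stage. Design:

* **Single frames** are concentric staggered rings of cell centroids whose
  local ring/arc spacings impose a target mean-area profile (default 3 to
  7 $\mu m^2$ from center to margin) and a target radial-elongation
  profile (default 0 at 10 $\mu m$ falling to $-0.1$ at 40 $\mu m$);
  triangulation between rings is built by an angular merge walk, so
  connectivity is exact ground truth. Ring-count mismatch between
  adjacent rings shears strip triangles and correlated ring phases would
  imprint a spiral shear; both artifacts are removed by damped
  neighbor-centroid relaxation, random ring phases, and a closed-loop
  calibration that re-measures the built tissue with the package's own
  morphometry and folds the residuals (radial profile, area profile, and
  residual $q_{r\theta}$ twist) back into the construction. The
  calibrated tissue matches the elongation targets within $\pm 0.01$ per
  10-$\mu m$ bin and the area targets within 10%.
* **Height fields** are paraboloid domes $h = h_0(1 - r^2/R^2)$ (default
  apex 15 $\mu m$), deterministic given the spec.
* **Timelapses** draw T1s and divisions as Poisson processes. A T1 spans
  two intervals, as it does at typical frame rates: the junction between
  the doomed pair shrinks (their opposite, soon-to-be-bonded centroids
  approach) in the interval where the event fires, and the topological
  flip plus a confined, area-preserving relaxation toward the isotropic
  rhombus happen in the next. "Bond" follows the junction convention
  (perpendicular to the centroid edge); the radial bias weights candidate
  flips by $\exp(b\cos 2(\theta - \theta_{radial}))$ on the junction axis,
  with $b = 2\,\mathrm{bias}/(1-\mathrm{bias})$ and bias 1 meaning the
  most radial candidate deterministically. The confined relaxation
  (extension fraction 0.82 of the free rhombus) plus a gentle per-frame
  neighbor-centroid smoothing — a stand-in for tissue elasticity — make
  the cumulative decomposition reproduce the structure seen in live
  imaging: a positive-radial T1 curve balanced by a negative (tangential)
  cell-elongation-change curve with small total shear. Event quartets are
  kept disjoint within a frame so triangle bookkeeping is exact; events
  that find no disjoint candidate carry over to the next frame, keeping
  totals Poisson. Divisions split a random interior cell's triangle fan
  along a uniform axis.
* **Ablation sets** apply the ESCA forward model at sampled positions
  under a prescribed stress field and emit noisy contour point clouds
  with stored truth.

What the generator does **not** emulate: a mechanical vertex model (no
force balance; elasticity is a kinematic smoothing surrogate), realistic
division-orientation statistics, the DV band's distinct mechanics,
peripodial tissue, or tissue-to-tissue biological variability. Passing
tests on synthetic data therefore demonstrate the correctness of the
estimators and bookkeeping — not that real discs satisfy the model; the
drift of mean elongation in long biased movies, for instance, is stronger
than in the real tissue because nothing saturates it.

## Problem sizes and numerical defaults

Test-suite and acceptance-script computations use: tissues of 25 to 50
$\mu m$ radius (roughly 450 to 1600 cells), movies of 50 frames at
$dt = 0.05$ hr (chosen well below both the Poisson-resolution bound
$dt \le 1/(10\,\mathrm{rate})$ and the per-frame packing capacity for
disjoint quartets), ablation ensembles of 14 to 24 cuts with 0.05 to 0.1
$\mu m$ contour noise on 60-point contours, a $\rho$ grid of 0.05 to 0.1
spacing, and 101 resamples for fit uncertainties. The finite-element
elasticity oracle uses 800 log-spaced elements to an outer radius of 40
cut radii (discretization + far-field truncation error below 1%).

## Known limitations

* The center-finding functional has a shallow minimum; on measured (as
  opposed to exact) elongation fields its precision is a few micrometres.
* The correlation term of the shear decomposition is defined as the exact
  closure residual; the analytic sub-terms of the underlying formalism
  are not reproduced individually.
* The per-cut ESCA inversion assumes the linear-response regime of the
  outer rim ($|c_2\tilde s| < 1$, $|p| < 1$) and equal inner/outer
  weighting.
* `reproduce_from_source_data()` requires local CSV exports of the
  published per-ablation, cumulative-shear and elongation tables; they
  are not redistributed with the package.
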