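---
title: "Methods: from channel flow to fiber orientation to directed invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from channel flow to fiber orientation to directed invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fiberflow)
library(dplyr)
```

fiberflow models a chain of three physical stages and the statistics used to
quantify them: (1) the depth-averaged laminar flow in a shallow microfluidic
channel around an immobilized tumor spheroid, (2) the orientation field that
rigid collagen fibers acquire while they polymerize in that flow, and (3)
the directed invasion of cells out of the spheroid by an anisotropic random
walk guided by the local fiber axis. A synthetic-image generator and a
local-gradient orientation estimator close the loop so that every stage can
be tested without microscopy data.

## The flow model

The channel is 3.8 mm wide, 17 mm long and 0.4 mm high and is driven at
0.2 µl/min, giving a depth-averaged speed
$U = Q/(wh) \approx 2.19\ \mu\mathrm{m/s}$ and a Reynolds number far below
one. Because the channel is shallow ($h \ll w$), the depth-averaged flow is
a Hele-Shaw flow. Around a rigid disk (the spheroid, treated as an
immobilized impermeable obstacle) two analytic solutions are provided:

* **Free slip (default).** The classical potential solution, a uniform
  stream plus a doublet. It is the exact Hele-Shaw limit, satisfies
  $\nabla\cdot v = 0$ and zero normal velocity on the disk, has stagnation
  points at the poles and tangential speed $2U$ at the disk's sides, and its
  velocity gradient is analytic (the flow is a complex-analytic field). This
  is the validation surface: the tests compare it against a brute-force
  finite-difference solve of the Laplace equation for the stream function.
* **No slip (`slip = "no_slip"`).** Depth-averaging the shallow-channel
  momentum equation leaves a drag term $12\mu u/h^2$, i.e. a Brinkman
  equation with screening length $h/\sqrt{12} \approx 115\ \mu$m. With
  no-slip on the disk the stream function is
  $\psi = U\sin\theta\,(r + A/r + B\,K_1(\lambda r))$ with $A$ and $B$ fixed
  by $f(a) = f'(a) = 0$. This variant has a shear layer of thickness
  $\sim h/\sqrt{12}$ hugging the obstacle — comparable to the obstacle
  radius here — which matters for fiber rotation (below). Its gradient is
  the analytic Hessian of $\psi$, traceless by construction.

Side-wall no-slip is neglected throughout (obstacle diameter ≈ 0.2–0.3 mm
versus a 3.8 mm channel width); cross-channel mass flux is therefore
conserved only to a few tenths of a percent over the finite width, which is
the tolerance the tests use. The flow axis convention is: origin at the
obstacle center, flow along $-y$, orientation angles axial in
$[0^\circ, 180^\circ)$ with $90^\circ$ along the flow axis.

## Rod dynamics and the orientation field

A collagen fiber (length 47.5 µm, width 5 µm) is advected as a rigid
slender rod: its center follows the velocity and its axis $p(\theta)$
follows the infinite-aspect-ratio limit of Jeffery's equations,
$\dot p = Lp - (p^\top L p)\,p$. The finite aspect ratio (~10) would add an
$O(1/r^2)$ tumbling correction; in the shear- and strain-dominated regions
that set the pattern the slender limit is adequate and keeps the dynamics
closed-form testable. Integration is fixed-step RK4 (`deSolve`); evaluation
points that would fall inside the disk are projected radially onto its
boundary, so rods slide along the obstacle rather than penetrating it.

`synthesize_orientation_field()` emulates polymerization under flow: rods
are released upstream on lanes across the field of view (plus a set of
near-axis lanes that resolve the stagnation region and the wake), with
normally distributed axial jitter (default sd 8°) around the flow axis —
real far-field fibers are spread around 90°, and the jitter also breaks the
unstable equilibrium of a rod riding the stagnation streamline at exactly
90°. Rod angles are recorded at every integration step ("polymerization
freeze" at uniform time sampling, since the freeze is not timed), and all
samples are deposited into square boxes of side $d = 103\ \mu$m. Because
sampling is uniform in time, slow regions (the stagnation caps) are
weighted by residence time, as fibers accumulating there are. Per-box
statistics use angle doubling: the axial mean is
$\tfrac12\,\mathrm{atan2}(\sum w\sin 2\theta, \sum w\cos 2\theta)$ and the
resultant length of the doubled vectors is reported as a coherence in
$[0, 1]$. Boxes with no samples (the spheroid interior) are filled from the
nearest sampled box and flagged — the invasion simulator needs a total
field.

Two choices deserve emphasis:

* **The no-slip flow drives the synthesis.** In the free-slip potential
  flow, off-axis streamlines accumulate only a finite strain, so the
  tangential/perpendicular band at the spheroid surface is only ~40 µm
  thick and a 103 µm box at the upstream face averages out flow-aligned.
  The no-slip (Brinkman) shear layer rotates fibers tangential over a
  box-scale band, reproducing the observed pattern: flow-aligned far field,
  tangential ring around the spheroid, perpendicular-to-flow at the
  upstream face, radial at the downstream face. The free-slip solution
  remains the default `flow_model()` and the validation surface for the
  flow criteria.
* **Grid anchoring.** `grid_spec_for_spheroid()` picks between the two
  symmetric grid anchorings so that the box row containing the spheroid
  surface is centered as close to the surface as possible; a box whose edge
  sits at the surface dilutes the near-surface band with far-field fibers.

```{r field, fig.height = 5}
model <- flow_model(obstacle = obstacle_spec(diameter = 300),
                    slip = "no_slip")
field <- synthesize_orientation_field(model, grid_spec_for_spheroid(150),
                                      seed = 1)
autoplot(field)
```

## The invasion model

Cells start on the spheroid (default: uniform over the disk of radius
150 µm — the spheroid is filled with cells; uniform-on-the-circle seeding is
kept for sensitivity checks). At each of $N$ steps per day every cell picks
one of four equiprobable moves: $\pm k_p$ along the local fiber axis
$\alpha$ (the angle of the cell's grid box) or $\pm k_v$ perpendicular to
it,
$$\Delta x = \pm k_p\cos\alpha,\quad \Delta y = \pm k_p\sin\alpha
\qquad\text{or}\qquad
\Delta x = \pm k_v\cos(\alpha+90^\circ),\quad
\Delta y = \pm k_v\sin(\alpha+90^\circ).$$
Cells are points, may overlap, do not proliferate, and the plane is
unbounded; outside the gridded field of view the nearest box supplies
$\alpha$. Step sizes come from day-scale calibration distances via the
diffusive normalization $k = r/\sqrt{N}$, so that an $N$-step $\pm k$ walk
has RMS displacement $r$ and fronts grow with $\sqrt{t}$. (The ballistic
alternative $k = r/N$ is exposed as `step_scaling = "linear"` but
contradicts the observed square-root growth.) With $k_v = 0$ a
perpendicular move is a null move that still consumes the time step; the
alternative (re-drawing) would double the effective parallel diffusivity
and is exposed as `redraw_null_moves`. $N$ is not critical under the
square-root scaling — the tests check that day-1 dispersal statistics agree
across $N \in \{25, 100, 400\}$ — and defaults to 100. The calibrated
parameters are $r_p = 220\ \mu$m/day (from the day-1 downstream front) and
$r_v = 0$, the value selected by the perpendicular-step sweep: reducing
$r_v$ over $\{220, 120, 60, 0\}$ monotonically increases the
downstream/upstream asymmetry, and complete blockage of cross-fiber
migration matches the observed shapes best.

```{r sim, fig.height = 4}
cfg <- sim_config(r_p = 220, r_v = 0, days = 3, n_cells = 1000,
                  radius = 150, seed = 1)
sim <- simulate_invasion(field, cfg)
glance(sim)
invasion_front_table(sim) |> filter(day == 1, sector %in% c(90, 270))
```

## Quantification

* **Sector fronts.** The invasion front in a direction is the mean distance
  beyond the initial spheroid boundary of the 10 cells that travelled
  furthest, among cells whose polar angle falls in the corresponding
  45° sector (downstream = 270° under flow-from-top). Distances are radial;
  ties at the 10th cell break by cell index for determinism; sectors with
  fewer than 10 cells use all of them and are flagged.
* **Degree of alignment.** Orientation histograms have 180 one-degree bins.
  The aligned window (90° ± 22°) is realized as the 46 integer bins
  68..113, so the uniform baseline is exactly 46/180 = 25.56%; the degree
  of alignment is the window mass divided by that baseline (1 = isotropic,
  maximum 180/46 ≈ 3.91). The closed interval 68°–112° would span 45 bins
  (25.0%); the printed 25.56% baseline is taken as normative.
* **Front-growth exponent.** Least-squares slope of log front distance
  versus log time; 1/2 for the diffusive model.
* **Shape mismatch.** RMS front difference over sectors, averaged over
  days — a scalar for comparing two invasion shapes in the sweep.

One caveat the tests quantify: the front is an extreme order statistic. With
1000 cells (~125 per sector) the mean of the top 10 of a centred Gaussian
radial displacement sits near 1.9 standard deviations, so the calibrated
model's day-1 downstream front computes to roughly 250–270 µm rather than
the 222 µm the calibration distance was read from — the front statistic of
a point-cloud walk is not the same functional that defined the day-scale
calibration in the source experiments (whose cell count and front
extraction are not stated). The upstream front (~115–130 µm) and the
downstream/upstream asymmetry (~2.1 at day 1) are reproduced.

## Image analysis

Fiber images are preprocessed by Gaussian smoothing, rolling-ball-style
background subtraction (grayscale morphological opening with a disk
element; invariant to constant offsets), and Otsu thresholding into a
foreground mask. Per-pixel orientation is the gradient direction (3×3
Sobel kernels) rotated by 90°, weighted by squared gradient magnitude over
the foreground — the local-gradient method of standard directionality
plugins. The exact smoothing sigma and rolling-ball radius used for the
original orientation analysis are not stated; the defaults (sigma 1 px,
radius 25 px) are package choices exposed as parameters.

## The synthetic-image generator

`render_fiber_image()` draws fibers as anti-aliased segments (length
normal around 47.5 µm, truncated at 5 µm) whose axial angle is the local
field angle plus von Mises jitter on the doubled angle (Best–Fisher
sampling — axial objects need a 180°-periodic jitter law), then applies a
Gaussian PSF and Gaussian or Poisson noise. Pixel size defaults to 1 µm/px
for arithmetic transparency; the true microscope scale is not stated and
nothing downstream depends on it beyond the recorded `pixel_size`. The
generator emulates the statistical structure the estimator assumes
(oriented line-like objects on a noisy background); it does not emulate
confocal z-sectioning, photobleaching, fiber crossings' intensity
saturation, or brightfield spheroid texture — so passing round-trip tests
validates the estimator's geometry, not its robustness to every real-world
artifact.

## Numerical choices and problem sizes

Rod integration uses RK4 at dt = 3–4 s with a 6000 s horizon; field
synthesis releases ~10 rods on each of ~150 lanes (a few seconds of
compute). The test suite runs the calibrated invasion at 1000 cells ×
100 steps/day with 10 replicate seeds, and the sweep at 4 × 10 replicates
over 3 days — sizes chosen so the full suite completes in a few minutes
while keeping replicate standard errors a few µm. All randomness flows
through explicit seeds (`withr::with_seed`); simulations are
bit-reproducible given their configuration.

## Known limitations

* The depth-averaged 2D flow ignores the imaging plane's position in z and
  any 3D flow structure around the spheroid.
* Slender-rod advection has no fiber–fiber interactions, network
  elasticity, or matrix remodeling; the synthesized field is a proxy for
  the measured one, adequate at the 103 µm box scale.
* The invasion model deliberately omits finite cell volume, cell–cell
  adhesion, jamming, and proliferation; deviations concentrate in the
  sectors adjacent to downstream, as expected when crowding effects are
  ignored.
* The spheroid is rigid and immobile in the flow stage and invisible (not
  an obstacle) in the walk stage.
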