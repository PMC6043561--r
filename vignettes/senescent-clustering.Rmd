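---
title: "Model and methods: senescence-nucleated 3D tumor-cell clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: senescence-nucleated 3D tumor-cell clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sencluster)
```

## The phenomenon being modeled

In dense monolayers of highly motile breast-cancer cells, occasional
cells enter senescence: permanent cycle arrest with dramatic lateral
spreading into a "fried-egg" shape — a bulged nuclear core surrounded by
a very thin, actin-rich body that can reach thousands of square microns.
Live imaging shows that such a senescent cell acts as an aggregation
center: when a neighboring tumor cell divides, it transiently rounds up
and loses adhesion to the substrate (mitotic cell-rounding), and the
newly divided daughters climb onto the senescent cell's body and migrate
to its core, where a three-dimensional cell cluster accumulates — a
premature, locally triggered 2D-to-3D transition.

The package implements a 3D cellular Potts model (CPM) of this process,
together with the motility statistics used to characterize the cells
(anomalous mean-squared displacement, two-tiered directional
persistence, radial velocity) and synthetic-trajectory generators that
stand in for the unavailable live-imaging tracks.

## The lattice model

Space is a `Lx x Ly x Lz` lattice at 1 µm spacing (one lattice site is
1 µm³). Each site holds a cell id; a cell is the set of sites sharing
its id. Five types exist: culture medium, the senescent core, the
senescent body (an aggregate of small domains forming the thin sheet
around the core), tumor cells, and the substrate ("matrix", a frozen
one-site-thick floor). The box is periodic in x and y; the floor and the
top plane are fixed.

The energy has three parts. Volume and surface elasticity constrain each
cell to its targets,

$$H_\text{constraints} = \sum_\sigma \left[\lambda_V (v_\sigma - V_t)^2
  + \lambda_P (P_\sigma - P_t)^2\right],$$

interface adhesion sums type-pair energies over all unlike order-2
neighbor pairs,

$$H_\text{interaction} = \sum_{\text{interface}(i,j)}
  J(\tau_{\sigma_i}, \tau_{\sigma_j}) (1 - \delta_{\sigma_i \sigma_j}),$$

and chemotaxis biases tumor-cell moves along the gradient of a secreted
field $\omega$ through a move-difference term
$\Delta H_\text{chemotaxis} = \mu\,(\omega(x') - \omega(x))$, where $x'$
is the site the tumor cell extends into and $x$ the site it extends
from. With $\mu < 0$ (the package default) up-gradient extension lowers
the energy; this term exists only as a move difference and has no
total-energy counterpart.

Dynamics are Metropolis copy kinetics: a random site and a random
neighbor (order-2, i.e. the 18-site face+edge stencil) are drawn, and
the neighbor's id is copied into the site with probability 1 if
$\Delta H < 0$ and $e^{-\Delta H / T}$ otherwise, at temperature
$T = 100$. One Monte Carlo step — as many attempts as there are lattice
sites — represents one second. Substrate sites are never copy sources or
targets, and a copy that would erase a cell's last site is rejected, so
cells never vanish. $\Delta H$ is always evaluated incrementally from
the local stencil; the package keeps a separate brute-force
`total_hamiltonian()` in pure R whose differences the incremental path
must match to $10^{-9}$ in the tests.

### Interaction energies

`default_J()` carries the eleven resting adhesion energies
(core–body −170, core–tumor −10, core–medium 10, core–matrix −70,
body–medium 4, body–body −120, body–tumor −2, tumor–tumor −6,
tumor–medium −4, tumor–matrix −20, medium–matrix 10). More negative
means contact is preferred. Two consequences worth noting:

* the body domains cohere to each other (−120) and to the core (−170)
  with no extra tethering — the "tightly connected aggregate" emerges
  from adhesion alone;
* at rest, two tumor cells separated by a film of medium are *lower*
  energy than the same cells in contact (two tumor–medium face pairs at
  −4 beat one tumor–tumor pair at −6), so resting cells do not
  spontaneously aggregate. Daughter-pair cohesion is supplied by the
  rounding schedule below. The tests assert this computed ordering
  directly on constructed lattices.

### Mitotic cell-rounding

At each division onset $t_0$ the dividing cell's adhesion becomes
time-dependent: tumor–tumor switches from −6 to
$-6 - 110\,e^{-(t - t_0)/100}$ and tumor–matrix from −20 to
$-20 - 110\,e^{-(t-t_0)/500}$, both relaxing back to rest (time
constants 100 s and 500 s). `adhesion_at()` evaluates these formulas
verbatim as its default (`rounding_sign = "as_printed"`).

The sign of the 110-amplitude term is the one genuinely ambiguous point
of the model: as written, the transient makes both energies *more
negative*, i.e. the rounding cell binds its neighbors and the substrate
*more* strongly, while the biological description of mitotic rounding —
and the observed climbing itself — requires the cell to *release* the
substrate. Both modes are provided. The simulation scenarios default to
`rounding_sign = "weakening"` (the transient is added with a plus sign,
so tumor–matrix rises to +90 at onset and decays back), because with the
as-printed sign a freshly divided cell is glued to the floor at −130 and
no cluster can form; with weakening, substrate release is exactly what
lets daughters pop out of the plane and climb. The schedule is truncated
to rest beyond ten times the slower constant (5000 s). When two rounding
cells touch, the more recent onset governs their pair energy.

Division itself is clock-driven: each tumor cell draws its next cycle
length from a truncated normal with mean 5000 s and sd 1000 s. At
division the cell's sites are split by a vertical plane through its
centroid with uniformly random horizontal azimuth (division axes are
co-planar with the substrate); one half keeps the id, the other becomes
a new cell; both daughters keep the 400 µm³ target, get fresh clocks,
rounding onset $t_0$, and an incremented generation counter — which is
how first-generation and replicated cells are distinguished afterwards.
Founders start at uniformly random phases of their first cycle
(asynchronous seeding), so founder first-divisions are excluded from
inter-division-interval statistics.

### The chemoattractant field

The senescent core secretes a diffusible attractant (a stand-in for a
SASP factor) obeying
$\partial\omega/\partial t = p - d\,\omega + D\nabla^2\omega$ with
$p = 2\ \mu\text{m}^{-3}\text{s}^{-1}$ at core sites only,
$d = 0.02\ \text{s}^{-1}$ and $D = 2\ \mu\text{m}^2\text{s}^{-1}$
everywhere outside the substrate. The solver is explicit forward Euler
with the 7-point Laplacian; the number of substeps per second is chosen
from the stability bound $D\,\Delta t/\Delta x^2 \le 1/6$ (12 substeps
at the defaults) and violating configurations are rejected before a run
starts. Substrate sites are no-flux with $\omega = 0$; x and y are
periodic; the z faces are no-flux. One field step of one second is
interleaved after each MCS's copy attempts. The field starts at zero and
is pre-equilibrated for a 500 s burn-in before the lattice moves, which
removes the start-up transient from the chemotactic drive (the field's
global relaxation time is $1/d = 50$ s). At steady state the total
field satisfies the balance $\Sigma\omega = p\,V_\text{core}/d$, which
the tests verify to 1%, along with exact mass conservation when
$p = d = 0$ and the homogeneous-decay and variance-growth limits.

We diffuse $\omega$ through all non-substrate sites, including those
occupied by cells; whether the attractant should penetrate cell bodies
is not constrained by the observations, and an occlusion model would add
a parameter the data cannot fix.

### Initial layout and geometry

`gen_initial_lattice()` builds the starting configuration: the substrate
floor; a central core as a half-ellipsoid standing on the floor, its
height solved so the discrete volume matches the 1800 µm³ target; the
body as an annular sheet around the core split into equal angular
wedges (600 µm³ each); and tumor cells as near-cubic blocks placed
greedily in the medium near the body rim with one site of clearance.
Target surfaces come from the dimensionless "asperity" (0.8 for core and
body, 1.4 for tumor cells), which we read as the ratio of the target
surface to the surface of the sphere of the same volume — asperity 1 is
sphere-like, larger values leave slack for rougher, more deformable
boundaries. Surfaces are counted as exposed faces (6-connectivity).

Two named configurations exist. `sim_config()` is the full published
geometry: 200 × 200 × 50 µm, 48 body domains, 20 tumor cells, 8800 MCS.
`reduced_config()` is the down-scaled counterpart used by the tests,
examples and analysis scripts: 64 × 64 × 20 µm with 12 body domains and
6 tumor cells, all physical parameters unchanged. 64 (not 60) in x and y
is the smallest even box in which the 12-wedge body annulus still leaves
a ring of medium wide enough to seed the tumor blocks without contact.
The reduced run keeps the published 8800 s duration, under which most
founders divide at least once.

## Calibration of the unprinted parameters

$\lambda_V$, $\lambda_P$, $\mu$ and the field burn-in have no published
values (the original sensitivity was "finely tuned" without printing the
result), so they are package defaults calibrated once against two
qualitative requirements: cell volumes must track their targets, and
only cells in the rounding phase may climb the body. The defaults are
$\lambda_V = 1$, $\lambda_P = 0.1$, $\mu = -150$, burn-in 500 s. At
these values, reduced-scenario volumes stay within a few percent of
target over 8800 MCS; a control run with divisions disabled shows no
cell leaving the substrate over 6000 MCS (selectivity is supplied by the
resting tumor–matrix adhesion, which chemotaxis at this $\mu$ cannot
overcome, rather than by gating $\mu$ itself); and with divisions
enabled, clusters of several cells form on the core within the published
timescale. The chemotactic sensitivity is constant in time — selectivity
comes from the adhesion schedule, not from boosting $\mu$ during
rounding (though both knobs are exposed in the configuration).

## Motility statistics

`compute_msd()` is the time-and-ensemble averaged squared displacement
over all overlapping pairs at each lag, by default in the imaging plane
(x, y). `fit_msd_exponent()` fits log MSD on log lag by OLS over lags in
[2 frames, T/4] — short lags are dominated by localization-scale noise
and the long tail by vanishing statistics. The slope is the anomalous
exponent $\alpha$ (1 diffusive, 2 ballistic).

`direction_autocorr()` defines the heading at time $s$ as the unit
displacement over one frame interval (the observable closest to "the
direction the cell is heading" without an arbitrary smoothing window)
and returns $\langle\cos\theta(t)\rangle$ with its per-lag spread.
`fit_two_exponential()` fits $A e^{-t/\tau} + B e^{-t/\tau_0}$ with
$A, B \ge 0$, multi-start over a grid of time-constant pairs, selecting
the best-residual fit satisfying the identifiability constraint
$\tau \ge 2\tau_0$; $\tau$, the slow component, is the reported
directional persistence time. The fit then refits once on the
signal-bearing window $t \le 2.5\,\hat\tau$: beyond a few slow time
constants the model value lies below the sampling noise of the curve,
and including that tail only injects noise-driven bias into $\tau$ (on
noise-free curves the two-pass fit still inverts the forward model to
machine precision; the window factor can be disabled). Fits whose slow
constant is unresolved — pure noise input — are flagged via the
parameter covariance.

`radial_velocity()` regresses each track's distance-to-center on time
and reports minus the mean slope (positive = inward), and
`cluster_metrics()` quantifies the end state: the number of tumor cells
whose centroid lies in the core's x–y footprint above the body's median
top surface, the tallest contiguous tumor-occupied z-extent there, and
the boolean "cluster formed" (at least two cells on the core).

## Synthetic track generators

The experimental tracks are not deposited, so generators with known
ground truth stand in for them; they are first-class, tested code.

**Two-population persistent walkers** (`gen_persistent_tracks()`)
realize the two-tiered heading autocorrelation as a mixture: a fraction
$A/(A+B)$ of constant-speed walkers decorrelate with the slow constant
$\tau$ (Wiener heading angle, increment variance $2\,dt/\tau$), the rest
with $\tau_0$, and every reported heading carries independent angular
jitter solved from $1-(A+B)$ — the fitted amplitudes summing below one
is exactly an instantaneous decorrelated component. The ensemble curve
is then $A e^{-t/\tau} + B e^{-t/\tau_0}$ by construction, which the
tests verify at below 0.03 RMS. Defaults: speed 30 µm/hr and
dt = 0.25 hr, resembling aggregated phase-contrast imaging cadence.

**Fractional Brownian tracks** (`gen_fbm_tracks()`) draw exact
fractional Gaussian noise increments per axis by multiplying i.i.d.
Gaussians with the Cholesky factor of the analytic fGn covariance, so
the ensemble MSD exponent is exactly $2H$; $H = 0.71$ reproduces the
observed super-diffusive exponent 1.42. The realized covariance is
checked against the closed form, and displacement variances scale as
$k^{2H}$ across frame lags.

What the generators deliberately do not emulate: cell–cell collisions
and jamming, spatially varying speed, haptotactic guidance along the
senescent boundary, and segmentation/tracking noise. Passing recovery
tests on these ensembles therefore shows the *estimators* are correct
and well-conditioned at the published parameter values — not that real
confluent-monolayer tracks satisfy the generative assumptions.

## Numerical and design notes

* Determinism: all lattice kinetics flow from one integer seed through a
  dedicated xorshift generator (R's RNG stream is used only for
  R-level draws such as layout phases), so identical configurations
  reproduce bit-identical trajectories; the tests assert this.
* Copy attempts draw sites independently and uniformly (not a
  permutation sweep), the standard Metropolis choice.
* $\Delta H = 0$ moves are accepted with probability one ($e^0 = 1$);
  the zero-temperature limit accepts exactly the non-positive moves, and
  total energy is then non-increasing, which the tests check per MCS.
* Domain connectivity is not enforced; cells can in principle fragment.
  Volume/surface bookkeeping stays exact regardless (audited against
  recomputation), and the near-even daughter-volume distribution of
  centroid-plane splits is checked statistically.
* Degenerate division planes (all sites on one side of the centroid
  plane, possible for strongly non-convex cells) fall back to an
  index-order split; cells below 2 sites defer division by one MCS.
* The interface sum weights all order-2 neighbor pairs equally; no
  distance weighting is applied (none is specified for the model).
* Problem sizes in the tests — the reduced 64 × 64 × 20 scenario, 500
  synthetic tracks for persistence, 200 for fBm, ten seeds for the
  replicate table — were chosen as the smallest ensembles at which the
  recovery bands are comfortably resolved.

## Known limitations

* The body's thin-sheet geometry is maintained by adhesion and surface
  elasticity only; over long runs body domains partially drape onto the
  core dome, raising the "body top" reference that the cluster metric is
  measured against. The metric is defined relative to that (emergent)
  surface rather than a fixed height for exactly this reason.
* With the as-printed rounding sign, the model as configured does not
  produce clusters; the weakening mode is a modeling judgment, made for
  the mechanistic reasons above, not a fitted choice.
* One lattice unit = 1 µm is an interpretation of the printed grid size;
  target volumes then map to plausible site counts, but no independent
  length calibration exists.
* The full-scale 200 × 200 × 50 configuration is provided and its layout
  is tested, but the analysis scripts run the reduced scenario; the
  full-scale run is a matter of patience, not of different code.
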