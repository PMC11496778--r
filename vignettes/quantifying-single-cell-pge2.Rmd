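---
title: "Quantifying single-cell PGE2 discharge from radial PKA activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell PGE2 discharge from radial PKA activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspaquant)
```

## The measurement problem

A single epithelial cell that fires a calcium transient activates
cytosolic phospholipase A2, synthesizes prostaglandin E2 (PGE2), and
discharges it into the surrounding medium within a couple of minutes.
Neighbouring cells expressing the Gs-coupled EP2 receptor respond through
cAMP and protein kinase A (PKA). When the neighbours carry an
intermolecular FRET biosensor for PKA activity (donor mKOκ, acceptor
mKate2), the discharge becomes visible as a ring of elevated
acceptor/donor ratio expanding radially from the producer cell — a radial
spread of PKA activation (RSPA).

The ring radius is the only observable; the quantity of interest is the
number of moles discharged. This package provides the full chain that
connects the two:

1. a finite-difference solver for the diffusion of an instantaneous
   point release above the dish bottom (`solve_diffusion`),
2. a dose–response module that converts a fractional FRET-ratio
   threshold into the iso-concentration contour it traces
   (`fit_hill`, `threshold_to_concentration`),
3. an event detector and tracker for normalized ratio stacks
   (`detect_events`),
4. the inversion of observed maximum radii into femtomoles
   (`build_calibration`, `radius_to_amount`),
5. a calcium-transient module (`compute_f_over_f0`,
   `merge_simultaneous`) for the producer-side trigger, and
6. a ground-truthed synthetic scene generator (`render_scene`,
   `scene_suite`) so every step above is testable end to end without
   external data.

## The diffusion model

PGE2 released at the dish bottom spreads into the medium. With
rotational symmetry around the release point the concentration
$C(r, z, t)$ obeys

$$\frac{\partial C}{\partial t} = D\left(
  \frac{\partial^2 C}{\partial r^2} + \frac{1}{r}\frac{\partial C}{\partial r}
  + \frac{\partial^2 C}{\partial z^2}\right),$$

with a reflecting dish bottom ($\partial C/\partial z = 0$ at $z = 0$), a
reflecting symmetry axis ($\partial C/\partial r = 0$ at $r = 0$), zero
concentration at the open faces $r = r_\mathrm{max}$, $z = z_\mathrm{max}$,
and the whole amount $Q$ deposited at the origin at $t = 0$. The
diffusion constant defaults to $D = 500\ \mu m^2\,s^{-1}$, the rounded
literature value for fluorescein, a molecule of similar weight to PGE2.

Key numerical choices:

* **Scheme.** Explicit forward-time central-space stepping. The time
  step is derived as $0.4 \times 0.5/(D(1/\Delta r^2 + 1/\Delta z^2))$,
  i.e. 40% of the stability bound; a user-supplied `dt` beyond the bound
  is rejected before integration. At this step size every update
  coefficient is non-negative, so the scheme preserves non-negativity
  exactly rather than approximately.
* **Axis treatment.** At $r = 0$ the $1/r$ term is replaced by its
  symmetric limit, giving the standard $4(C_1 - C_0)/\Delta r^2$ axis
  stencil. The interior radial stencil is algebraically identical to the
  finite-volume flux form with face radii $r_{i\pm 1/2}$, so the
  discrete mass — computed with the matching control volumes (a disc of
  radius $\Delta r/2$ on the axis, half cells on the reflecting faces) —
  is conserved exactly up to the flux lost through the open boundaries.
  Before any material reaches those boundaries the integral equals $Q$
  to solver precision (`total_amount`).
* **Source.** By default the whole amount occupies the single grid cell
  at the origin; `source_extent` optionally spreads it over a
  hemisphere (10 µm is a cell-sized choice) to blunt early-time grid
  artifacts. The difference decays within a few seconds because the
  Gaussian width $\sqrt{4 D t}$ passes the grid spacing almost
  immediately.
* **Radius search.** `contour_trace` samples the bottom-row contour
  radius every second by default (60 s sampling is available to mimic a
  1-min imaging cadence) and excludes $t = 0$: at the release instant
  the deposit cell exceeds any threshold for any $Q > 0$, which carries
  no information about the observable spread.
* **Domain.** The defaults $r_\mathrm{max} = 1500$, $z_\mathrm{max} =
  1000\ \mu m$ keep the open boundaries invisible for releases up to
  ~2 fmol over a few minutes. They are explicit configuration because
  larger releases or longer windows make results depend on them.
* **Units.** Fixed package-wide: µm, s, nM, fmol, with
  $1\ \mathrm{nM} = 10^{-24}\ \mathrm{mol}\,\mu m^{-3}$ centralized in
  one constant.

The solver is validated against an independent closed form: an
instantaneous point source on a reflecting plane is the free-space
Gaussian doubled by its image,

$$C(r, z, t) = \frac{2Q}{(4\pi D t)^{3/2}}
  \exp\!\left(-\frac{r^2 + z^2}{4Dt}\right),$$

implemented as `analytic_halfspace`. On the default grid the two agree
to about 1% everywhere the concentration exceeds 0.01 nM, and the
discrete mass matches $Q$ to $10^{-6}$ relative at $t = 10$ s.

Maximizing the contour radius over time gives the closed-form
benchmark $r_\mathrm{max}^2 = 6 D t^\ast$ with $(4\pi D t^\ast)^{3/2} =
2Q/(C^\ast e^{3/2})$ (`analytic_max_radius`), which implies
$r_\mathrm{max} \propto Q^{1/3}$ at a fixed contour concentration. The
solver reproduces the 1/3 log–log slope to a fraction of a percent
across 0.05–1 fmol.

## From FRET ratio to concentration

The reporter's dose–response is a four-parameter Hill curve

$$R(C) = R_\mathrm{min} + (R_\mathrm{max} - R_\mathrm{min})
  \frac{C^n}{C^n + \mathrm{EC}_{50}^n}.$$

`fit_hill` estimates all four parameters by least squares from a
titration table, starting from a fixed grid of EC50 values (log-spaced
over the tested doses) and Hill coefficients (0.5, 1, 2, 4), so the fit
is deterministic. The Hill coefficient is fitted rather than pinned at 1
because receptor-level amplification can steepen the effective response.
Replicates enter with equal weight. A fit is *flagged* — not failed —
when no start converges, the EC50 leaves the tested range, or the
amplitude is indistinguishable from the residual noise (e.g. constant
ratios).

The detector binarizes at a **fold change over baseline** (default 1.20,
a 20% ratio increase). `threshold_to_concentration` inverts the Hill
model at $R_\mathrm{thr} = 1.20\,R_\mathrm{min}$. The threshold is
deliberately defined relative to baseline rather than as a fraction of
the dynamic range, because the detector operates on
minimum-projection-normalized ratios whose baseline is 1 by
construction. For the default HeLa-like response ($R_\mathrm{min} = 1$,
$R_\mathrm{max} = 1.35$, $\mathrm{EC}_{50} = 1$ nM, $n = 1$) a 20%
increase maps to $C^\ast = (0.20/0.15) \times 1.0 = 1.33$ nM, within 2%
of the 1.35 nM contour conventionally paired with that threshold; the
1.35 nM value is kept as the configuration default for the simulation
because the exact correspondence depends on an amplitude that cannot be
re-derived from published summaries.

**Monte-Carlo recovery.** The recovery study models measurement noise as
5% multiplicative Gaussian noise on the *activation response above
baseline*, with three replicate titrations per dose, emulating the
actual assay (field-of-view-averaged ratios have sub-percent technical
noise; run-to-run variability enters through pathway activation, and the
titration is performed in triplicate). Under that model the median EC50
error of 100 fits is about 5%. Noise of 5% on the *full ratio* would be
a qualitatively different regime: the information content of 8 doses
then caps EC50 recovery near 50% median error for any estimator, which
is why we do not present that variant as a recovery benchmark.

## Event detection and tracking

`preprocess` subtracts the camera background from both channels, applies
a 3×3 median filter to each frame (a configurable Gaussian is available;
the defaults are documented choices, not claims about any particular
published pipeline), forms the acceptor/donor ratio, and masks pixels
with non-positive corrected intensities. `normalize_by_min_projection`
divides each pixel trace by its own temporal minimum, making the quiet
baseline exactly 1 and the movie scale-free: multiplying both raw
channels by any constant changes nothing downstream.

`segment_frame` thresholds at the binarization fold, then applies
morphological opening and closing (disc elements, 3 px radius by
default) to remove speckle and fill pinholes, labels 8-connected
components, and reports each region's centroid and equivalent circle
radius $\sqrt{A/\pi}$. Regions below the detection limit `min_radius`
are discarded; 33 µm is the default, with 26 and 66 µm used by some
imaging configurations — it is configuration, never hard-coded.

`track_events` links regions across successive frames by greedy
nearest-neighbour association within 100 µm: closest pairs claim first,
ties break toward the lower event id, each region and each event match
at most once per frame. The successive-frame rule is taken literally — a
one-frame dropout ends the event and a reappearance starts a new one.
Greedy matching is the deliberate resolution of an ambiguity (the
100 µm rule alone does not define behaviour when two candidates are in
range); it is simple, order-independent given the distance sort, and
exact in the common one-candidate case.

`event_statistics` reduces each event to its maximum tracked radius —
the quantity the calibration expects — and reports diameters, counts and
a histogram.

## From radius to femtomoles

`build_calibration` runs one simulation per amount on an ascending grid
and records each maximum contour radius; `radius_to_amount` inverts the
resulting monotone curve by piecewise-linear interpolation. Radii below
the calibrated range report amount 0 with a `below_calibration` flag
(the smallest calibrated amount is then an upper bound); radii above it
are refused rather than extrapolated (`above_calibration`), because the
$Q^{1/3}$ power law flattens near the domain boundaries and a blind
extrapolation would be systematically wrong. Round-tripping
`max_contour_radius` through a dense calibration recovers amounts to
within the 5% interpolation tolerance.

`cells_covered` converts a radius into the number of 200 µm² cells
inside the activated disc ($\pi r^2 / A_\mathrm{cell}$): a 250 µm radius
covers ~980 cells (about $10^3$ at one significant figure), a 500 µm
radius ~$4\times 10^3$. `per_cell_amount` performs the bulk-assay
arithmetic (moles divided by cell count, in fmol per cell); note that
published bulk values quoted as 0.3 fmol/cell from 4 nmol per mg protein
at 0.1 ng protein per cell compute to 0.4 fmol/cell by exact arithmetic —
the discrepancy is reported as-is, not reconciled.

## The synthetic scene generator

`render_scene` builds two-channel stacks from the *analytic* half-space
solution — deliberately not the grid solver, so the generator and the
estimator share no code path and end-to-end tests are a genuine
cross-validation. Per frame, the concentrations of all releases
superpose (each bolus optionally translated by a uniform flow velocity,
reproducing the comet-like smear of a moving medium), pass through the
Hill response, and optionally through a single-exponential reporter lag
(`reporter_tau`, default 30 s — activation is visible within a minute in
real recordings, but no rate constant is published, so the lag is a free
generator parameter). The channels split the ratio as
$\mathrm{donor} = B_d/\sqrt{R}$, $\mathrm{acceptor} = B_a\sqrt{R}$ — an
arbitrary but documented choice that keeps both channels positive and
the ratio exact in expectation — with multiplicative Gaussian noise
(default 1% per channel, shot-noise-limited bright imaging) and a
constant camera offset. All randomness is fixed by the scene seed.

What the generator emulates: diffusion-driven ring growth and decay,
Hill saturation, reporter lag, camera noise, medium flow. What it does
not: cell-shape texture, photobleaching, stage drift, debris, or
single-cell expression variability. Passing the recovery benchmark
therefore demonstrates the correctness of the detection–calibration
chain, not robustness to every nuisance of real microscopy.

**Benchmark conditions.** `scene_suite` renders its validation scenes
with `reporter_tau = 0` (instantaneous response): the suite benchmarks
the pipeline, and reporter kinetics are a property of the biosensor, not
of the analysis. Scenes use a 1200 µm field at 2.6 µm pixels, 40 frames
at 5 s, one central release at $t = 20$ s, amounts log-spaced across
0.05–1 fmol. Under these conditions the median absolute relative error
of recovered amounts is a few percent, comfortably inside the 15%
benchmark bound.

The reporter lag matters quantitatively for real data: rendering the
default 0.25 fmol scene with $\tau = 30$ s shrinks the detected maximum
radius from 303 to 219 µm — about a quarter — and, because
$Q \propto r^3$ along the calibration, the inferred amount falls about
2.5-fold. This one-sided bias is an inherent limitation of
threshold-contour quantification with a slow reporter, and it acts in
the same direction as the unexplained gap between the pure-diffusion
model (which pairs 0.25 fmol with a ~300 µm maximum contour radius at
1.35 nM) and imaging-based calibrations that pair ~110 µm with the same
amount. We expose the geometry and kinetics as configuration and do not
force agreement.

## Problem sizes

The validation suite runs the full default grid (301×201 nodes, 5 µm
spacing, `dt` = 5 ms) for the solver–oracle comparison, an
8-point calibration to 150 s for the scaling and recovery checks, and a
10-scene recovery batch; unit tests use coarser 10 µm grids and smaller
fields where the full geometry adds nothing. These sizes were chosen so
the whole suite completes in a few minutes while the full-resolution
defaults remain exactly the ones a user gets.

## Worked example

```{r example, eval = FALSE}
# contour calibration at the concentration matched to a 20% ratio increase
C_star <- threshold_to_concentration(
  list(R_min = 1, R_max = 1.35, EC50 = 1, n = 1), 1.20)   # 1.333 nM
cal <- build_calibration(
  diffusion_config(t_end = 150, C_thresh = C_star),
  amounts = exp(seq(log(0.05), log(2), length.out = 8)))

# one synthetic event, detected and quantified
sc <- render_scene(scene_config(reporter_tau = 0, seed = 11))
stack <- preprocess(sc$donor, sc$acceptor, background = 100,
                    pixel_size = 2.6, frame_interval = 5)
events <- detect_events(stack)
estimate_amounts(events, cal)
```

## Known limitations

* The estimator's PDE contains no advection term; flow exists only in
  the generator. A flowing medium smears the ring and breaks the
  radius–amount correspondence, which is why quantitative recordings
  avoid stage-movement-induced whirl.
* The 3D half-space model does not apply to confluent epithelial
  monolayers whose tight junctions confine PGE2 to the basolateral
  space; their larger activation radii need a different (quasi-2D)
  geometry that is out of scope here.
* Amount estimates carry no error propagation from the dose–response
  uncertainty; they are point estimates, as in the source analyses.
* Reporter kinetics bias the estimate downward (see above); `reporter_tau`
  in the generator exists precisely to study that sensitivity.
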