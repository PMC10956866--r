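---
title: "Automated sorting-gate generation: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated sorting-gate generation: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortgate)
```

## The problem

High-throughput CRISPR knock-in workflows produce arrayed libraries of cell
pools in which only a subpopulation carries the fluorescent edit, at an
abundance and brightness that differ gene by gene. Isolating the edited
cells by FACS therefore needs a *different* sorting gate for every sample: a
closed polygon on the (fluorescence, back-scatter) plane that selects a
user-defined top fraction of the profiled events — routinely the brightest
1% — which is then sorted until a fixed number of cells (1,200 in the
default protocol) has been collected into a 96-well rescue plate.

`sortgate` implements the data-driven gating algorithm, a desk-scale
simulation of the sorter session around it, and the batch orchestration
that ties both to a worklist, so the whole pipeline can be developed,
tested and audited without an instrument.

## The gating algorithm

For a profiled sample the gate is constructed in four steps.

**1. Density estimation.** Events are binned on a `grid_size` × `grid_size`
histogram (default 256) over the data range of each gating axis padded by
5% per side, then smoothed with a separable Gaussian kernel
(`smoothing_bandwidth`, default 2 bins) and normalised to unit mass. The
defaults give smooth, simple contour rings for the 10^4–10^5 events of a
typical profile; both are configuration items. Samples below 100 events are
refused (`sortgate_error_insufficient_events`) because no usable density
exists, and a zero-variance axis is rejected as degenerate.

**2. Highest-density-region contours.** The "α% contour" is interpreted as
the boundary of the highest-density region (HDR) holding α of total event
mass — the convention of cytometry probability-contour plots, as opposed to
percent-of-peak levels. The threshold is found exactly by ranking grid
cells by smoothed density and accumulating mass; no iterative search is
needed. One numerical subtlety: if the accumulated mass is the *smoothed*
mass, kernel smoothing pushes the region outward and the enclosed fraction
of actual events overshoots α (about +0.016 at α = 0.8 with the default
bandwidth at n = 50,000). The level is therefore calibrated against the
raw histogram mass, with cells still ranked by smoothed density: the
region's shape comes from the smoothed field, its level from the data.
Iso-contours at the threshold are traced by marching squares
(`grDevices::contourLines`); contours running into the grid boundary are
closed along it, keeping the closure that encloses more event mass.
Multimodal samples yield several rings; the gate derives from the main
component, the ring enclosing the most mass (ties broken by area).

**3. Template construction.** Two mass levels shape the gate: the 80%
contour sets its vertical (back-scatter) extent `[y_lo, y_hi]`, and the
25% contour sets the shape of its sides. Concretely, the left boundary of
the gate is the *bright-edge arc* of the 25% contour — the ring split at
its back-scatter extremes, keeping the high-fluorescence side, made
y-monotone — extended to `[y_lo, y_hi]` with constant-fluorescence
segments (by HDR nesting the 25% ring never exceeds the 80% ring's
extent, so in practice this is an extension, not a clip). The right
boundary is the left one translated brighter by the fluorescence span of
the 25% contour; top and bottom edges join the curves. Each side curve is
resampled by arc length to half the vertex budget with endpoints kept, so
the closed ring has at most `max_vertices` (default 60) vertices and its
vertical extent is preserved exactly. The width choice and the bright-edge
arc are design decisions: they make the gate hug the main population's
bright flank, matching how an experienced operator draws these gates, and
both are configurable.

**4. Fitting.** The template is translated along the fluorescence axis
until it captures the target fraction. On the bright tail capture is
non-increasing in rightward shift, so the fit brackets the target with a
coarse right-to-left scan and then bisects the translation; the bisection
runs to bracket collapse and keeps the translation whose capture is
closest to the target (stopping at the first in-tolerance value would bias
the achieved fraction toward the approach side). Membership uses the
even-odd rule with boundary points counted inside — a fixed tie-break;
boundary hardware behaviour is not modelled. If translation alone cannot
reach the target within `fraction_tolerance` (default 0.001, about 50
events of a 50,000-event profile, finer than sampling noise at the 1%
target), a golden-section search over a rotation about the gate centroid
(±`max_rotation`, default 15°) re-runs the translation fit at each
candidate angle. Rotation is applied in axis-standardised coordinates
(each axis divided by the event standard deviation): degrees are not
meaningful between axes of incommensurate units. The whole search is
deterministic; an unreachable target returns the best gate flagged
unconverged rather than raising, and the orchestrator escalates it as a
warning.

Fitted gates can be exported as a plain-text vertex file (17 significant
digits, exact round-trip) — an open re-implementation of the vertex
hand-off that a vendor tool would perform.

## Transform conventions

Gating operates on a compressed fluorescence scale. The default is
`asinh(x / 150)` — defined at and below zero, unlike a log display — with
back-scatter kept linear; `log10(x + 1)` and pure linear scales are
available. Every event table records a per-channel transform tag, gates
record the tags they were fitted in, and capture refuses mismatched
spaces. Which scale the real instrument exports is not assumed; the
transform is a configuration item recorded in every exported gate.

## The synthetic data generator

The generator is the package's stand-in for instrument profiling data and
defines the study conditions used throughout the tests. Each sample is a
mixture of bivariate Gaussians on the transformed plane — the minimal
model for the unimodal blobs with bright tails seen in edited-pool
profiles. The default panel emulates a 12-sample sorting batch:

* unedited majority: fluorescence mean 0.5, sd 0.25 (asinh scale,
  autofluorescence near zero), back-scatter mean 5×10^5, sd 7.5×10^4
  (linear instrument units), correlation 0.2;
* edited subpopulation: fraction spanning 2–60% and fluorescence mean
  spanning 1.2–5.0 (dim to bright) across the panel, sd 0.4, sharing the
  unedited back-scatter distribution (tagging does not change cell size);
* 50,000 events per sample at a nominal 2×10^6 cells/mL.

Events are shuffled so no downstream step can rely on population blocks,
and every draw is reproducible from the spec's seed. What the generator
deliberately omits: doublets and debris, spectral spillover, acquisition
drift, and any non-Gaussian back-scatter shape — so green tests show the
algorithm is correct under the generative model, not that it is robust to
every artifact of real instrument data.

## The simulated sorter session

The session model reduces the instrument to a linear fluidic law: sample
flow is `flow_per_pressure × pressure` (mL/s), so at true concentration
`c` the event rate is `eps = c × flow_per_pressure × pressure`. The
concentration estimate inverts this from the observed profiling rate. The
pressure controller is the minimal law with the stated fixed point — a
clamped multiplicative proportional update
`p × (eps_target / eps_observed)^gain` — which reaches the fixed point in
a single unclamped step on a noiseless plant at gain 1; the default gain
0.5 trades speed for stability under Poisson rate noise. A zero observed
rate (empty line) drives the pressure to its maximum with a warning.
Arrival noise is Poisson per controller tick (1 s default) and is the only
randomness, governed by the session seed. Per-sample timing is split into
the five categories of an automated sort — profiling, sorting, transport,
gating, control — with the sample-independent three as configuration
constants (defaults 40, 12 and 30 s); absolute wall-clock fidelity to any
particular hardware is a non-goal.

With the default panel (50,000 stored events) a 1% gate holds ~500
in-gate events, so a 1,200-cell sort plan ends in an honest shortfall:
`completed = FALSE`, a warning notification, and the count achieved. This
is the intended behaviour of the model under those conditions, not an
error; sessions on samples with sufficient in-gate events stop at exactly
`n_sort`.

## Orchestration and reporting

`run_batch()` validates the worklist (18-tube housing, 96 plate wells
A1–H12, uniqueness of names/positions/wells), then runs each sample
through profile → gate → sort. Failures are isolated per sample and
surfaced through a pluggable notification sink; error notifications always
name the sample and phase. The end-of-run artifacts are a multi-page PDF
(batch table plus one contour-and-gate panel per sample) and a JSON
summary; both are byte-deterministic given identical inputs when
timestamps are disabled (the PDF's embedded dates are neutralised in
place, preserving cross-reference offsets). Pause/resume/stop are modelled
as explicit state transitions so the control surface is testable without a
keyboard listener. The optional control-sample prompt of the deployed
workflow is represented by simply gating a designated sample first and
reusing its configuration; re-queueing of samples that fail mid-sort is
left to the caller, as no fidelity claim is possible there.

## Problem sizes and verification

The test-suite study conditions are: a 12-sample panel at 50,000 events
per sample for gate-fraction fidelity and the end-to-end run; 50,000-event
isotropic Gaussian samples for HDR mass/nesting checks against the
analytic region (the α-HDR of an isotropic bivariate normal is the disc of
radius σ·sqrt(−2 ln(1−α)), e.g. 1.794σ at α = 0.8); 10,000 random
point/polygon trials against an independent winding-number oracle; and
60-step controller simulations. These sizes keep every statistical check
well inside its tolerance (binomial noise at the 1% target with n = 50,000
is ~4.5×10^-4, half the 10^-3 fit tolerance) while the full suite runs in
about a minute.

## Known limitations

* The density model is a fixed-bandwidth histogram KDE; heavily skewed or
  very sparse profiles may need a different `grid_size`/bandwidth, and
  adaptive estimation is out of scope.
* Percent-of-peak contour semantics, offered by some acquisition software,
  are intentionally not the default interpretation; the HDR reading is
  logged in every fit.
* The instrument model is linear in pressure with a proprietary reality
  behind it; its constants are stand-ins, and only relative behaviour
  (fixed point, stability, clamping) is asserted.
* FCS support covers single-dataset list-mode files with float/double
  storage — enough for fixtures and common exports, not a general FCS
  toolkit; keyword preservation, compensation and spectral unmixing are
  non-goals.
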