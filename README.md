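# sortgate

Automated sorting-gate generation and cell-sorter run simulation for flow
cytometry, in R.

High-throughput CRISPR knock-in pipelines produce arrayed libraries of
cell pools in which a fluorescent edited subpopulation of variable
abundance and brightness sits on top of a non-fluorescent majority. Each
pool needs its own FACS sorting gate — a closed polygon on the
(fluorescence, back-scatter) plane capturing a user-defined top fraction
of events, routinely the brightest 1% — drawn consistently, sample after
sample, with no operator in the loop. `sortgate` implements that gating
algorithm and the automation logic around it at desk scale, for people
building or validating automated sorting workflows: algorithm developers,
cytometry core facilities, and anyone who wants a reproducible, auditable
alternative to hand-drawn gates.

## The algorithm

For each profiled sample:

1. **Density** — 2D histogram of the events on the gating plane
   (256 × 256, 5% range padding), Gaussian-smoothed (2-bin bandwidth),
   normalised to unit mass.
2. **Contours** — highest-density-region (HDR) contours: the α-contour is
   the boundary of the smallest region holding α of total event mass,
   traced by marching squares. The level is calibrated against raw event
   mass so the enclosed fraction is unbiased.
3. **Template gate** — the 80% contour fixes the gate's vertical
   (back-scatter) extent; the bright-edge arc of the 25% contour shapes
   its sides; the side curve translated by the 25% contour's fluorescence
   span closes the polygon, resampled to at most 60 vertices.
4. **Fit** — the template is translated along the fluorescence axis
   (bisection to bracket collapse), and rotated (golden-section, ±15°)
   only if translation cannot reach the target, until the gate captures
   the target fraction (default 1% ± 0.1 percentage point).

Around the gate sits a simulated sorter session — Poisson event arrivals,
concentration estimation from the observed event rate, a clamped
multiplicative pressure controller holding a target rate, sort termination
at a fixed cell count (default 1,200) — and a worklist-driven batch
orchestrator (18-tube housing, 96-well destination plate) with error
isolation, pluggable notifications, a multi-page PDF report and a JSON
summary. A synthetic-data module generates edited-pool samples so the
whole pipeline runs without an instrument. Event I/O covers minimal
FCS 3.0/3.1 and a fixed CSV dialect.

## Worked example

```r
library(sortgate)

# a synthetic edited pool: 10% edited cells, moderately bright tag
spec <- panel_sample_spec("demo", edit_fraction = 0.10,
                          edited_fluo_mean = 3, n_events = 50000, seed = 7)
tab <- simulate_sample(spec)
tab
#> <event_table> sample 'demo': 50000 events x 2 channels
#>   channels: FL1 [asinh], BSC [linear]

# density -> 80%/25% HDR contours -> template -> fitted gate
g <- auto_gate(tab)
g$fit
#> <gate_fit> captured 0.0100 (target met: TRUE), translation 2.865, rotation 0.00 deg, 77 evaluations
g$fit$gate
#> <gate_polygon> 60 vertices, axes FL1 (asinh) x BSC (linear)

# simulate the sort session with the default protocol (1,200 cells)
res <- run_session(tab, sort_plan(g$fit$gate), seed = 7)
res
#> <sort_result> 'demo': profiled 10000, sorted 386 (shortfall), est. conc 2.03e+06 cells/mL, 107.8 s
```

Reading the output: the fitted gate captures exactly 1.00% of the 50,000
profiled events (500 cells), sitting 2.87 asinh units brighter than the
template position on the main population, with no rotation needed. The
session profiles 10,000 events, estimates the loading concentration at
2.03×10⁶ cells/mL from the observed event rate (true value 2×10⁶), and
then sorts; a 50,000-event sample holds only ~500 in-gate cells, so the
1,200-cell protocol ends in a reported shortfall rather than an error —
on an instrument this is the point where the operator is notified.

Batch processing works from a worklist (`parse_worklist()`,
`run_batch()`), and a thin command-line front end with `simulate`,
`gate`, `run` and `report` subcommands lives in `inst/cli/sortgate.R`.

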