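# traplife

Simulation and analysis of trap-array yeast replicative-aging experiments.

## The problem

Microfluidic trap arrays dock single mother cells of budding yeast in
bowl-shaped traps under laminar perfusion; every matured daughter is
sheared off hydrodynamically, so one chip run tracks hundreds of mothers
through their entire reproductive lives by time-lapse imaging. The two
core readouts are the **replicative lifespan** (RLS) — the number of
daughters a mother produces before death — and the **budding time
interval** (BTI) — the time between successive budding events. Neither is
imaged directly: per trap and per frame the data are just the visible
objects (mother, buds) and their sizes.

traplife is for people building or validating such analysis pipelines. It
provides:

* a **synthetic experiment generator** with full ground truth — array
  geometry and upstream ordering, initial trapping and self-filling of
  empty traps by daughters dissected upstream, mother-loss and
  extra-capture artifacts, and per-cell budding/dissection timelines with
  first-generation BTI extension, terminal BTI elongation and age-growing
  variability;
* the **sequential two-digit event coder**: each frame transition is coded
  `(delta_n, delta_t)` where `delta_n` is the net change in visible bud
  count (+1 bud appeared, -1 daughter dissected) and `delta_t = 1` flags a
  same-interval handoff (old daughter removed *and* new bud appeared
  between two consecutive frames, inferred from a fractional size drop).
  RLS = #(delta_n = 1) + #(delta_t = 1); BTI_g = (frame of budding event
  g+1 - frame of event g) x frame interval;
* the **cohort statistics**: viability curves, mean RLS under both
  standard-error conventions (between-run SD/sqrt(runs) and per-cell
  SD/sqrt(n)), capture-time-binned RLS with a linear fit, birth- and
  death-aligned BTI profiles with the first-generation extension, and
  RLS-ordered BTI kymographs with 5-generation period labels.

## Worked example

Simulate three independent 220-trap runs at study-condition defaults
(10-min frames, 60-h run, 70.5% initial occupancy, mean lifespan 24.29
generations, 9% first-generation BTI extension), encode every cell, and
summarize the cells captured in the first 10 hours:

```r
library(traplife)

lay <- build_layout(array_layout(n_subarrays = 1L))   # one 220-trap subarray
co  <- simulate_cohort(lay, aging_params(), seed = 42, n_runs = 3)
summarize_cohort(co$records[co$records$capture_min <= 600, ])
#> Cohort summary: 419 cells in 3 run(s)
#>   mean RLS 21.74 +/- 2.82 (paper SE; conventional 0.24)
#>   capture-time slope -0.667 generations/h
#>   first-generation BTI extension 9.97%
```

419 complete records survive the default screening (lost, contaminated and
censored cells are excluded). The mean RLS sits below the configured 24.29
because a 60-h run can only *call* a death that leaves a full 600-min
budding-free gap before run end — long-lived cells are censored, a
right-truncation real runs of this design share. The recovered
first-generation extension (9.97%) matches the configured 9% within
sampling error, and the negative capture-time slope reflects the shortened
lifespans of daughters captured from old mothers.

The coding arithmetic on a single cell:

```r
m <- representative_matrix()   # synthetic 23-generation reference sequence
rls_from_matrix(m)
#> [1] 23
head(btis_from_matrix(m))
#> [1] 100  90  90  90  90  90
```

A command-line driver wraps the same pipeline
(`simulate`, `encode`, `analyze`, `report`):

```sh
Rscript inst/cli/traplife.R simulate --config config.yaml --out sim/
```

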