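---
title: "Methods: simulating and decoding trap-array yeast aging experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding trap-array yeast aging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In a microfluidic trap array, single mother cells of budding yeast are
docked in bowl-shaped traps under continuous medium perfusion. Each matured
daughter is sheared off hydrodynamically, so a mother can be imaged every
few minutes for days while its successive daughters are produced and
removed. Two quantities summarize the aging process: the **replicative
lifespan** (RLS), the number of daughters produced before death, and the
**budding time interval** (BTI), the time between successive budding
events. Neither is observed directly — what the microscope records is, per
trap and per frame, which objects (mother, buds) are visible and how large
they are. traplife implements the whole chain from such object tables to
cohort statistics, together with a ground-truthed generator of synthetic
experiments, so that every inference step can be tested against known
truth.

```{r}
library(traplife)
```

## The event coder

Between two consecutive frames the visible bud count can stay, rise or
fall, which is captured by a two-digit code per transition:

* `delta_n` — the net change in bud count: `+1` a new bud appeared, `-1` a
  daughter was dissected, `0` no change;
* `delta_t` — set to `1` when the counts are equal and positive but the
  matched bud shrank by more than a threshold fraction (default 0.5): the
  old daughter was removed *and* a new bud appeared between the same two
  frames, without an observable bud-free gap.

The RLS of a cell is the total number of `1`s among the `delta_n` digits
plus the `1`s among the `delta_t` digits; BTI~g~ is the frame difference
between budding events g+1 and g times the frame interval. An
*oscillogram* — the cumulative-generation staircase — makes the count
visual, and its final level always equals the RLS computed from the same
matrix.

```{r}
m <- representative_matrix()   # synthetic 23-generation reference sequence
rls_from_matrix(m)
head(btis_from_matrix(m))
```

Three motifs arise at a 10-min sampling interval and are all handled by the
code pair: an observable bud-free gap (`-1` then later `+1`), an overlap in
which the next bud appears before the previous daughter detaches (a frame
shows two buds), and the same-interval handoff flagged by `delta_t`.

Choices the underlying papers of this field leave open, and how they are
resolved here (all switchable):

* **Handoff inference.** Visually a handoff is "a big bud disappeared and a
  small bud appeared". We formalize it as a fractional size drop of the
  count-matched bud exceeding 0.5. With deterministic rendering a mature
  bud is near 4 um and a fresh one near 1 um, so the drop (~0.7) is well
  separated from growth noise; the threshold is a tuning parameter for real
  segmentations.
* **Bud matching.** When a frame holds two buds, identities are matched by
  nearest size, largest first; survivors keep the older bud's identity.
  Compound transitions not covered by the motif set (e.g. one removal plus
  two appearances in one interval) are coded as the net `delta_n` with
  `delta_t = 1` and logged as a warning.
* **Bud at capture.** A cell trapped while already budded carries its first
  daughter; by default that bud counts as generation 1 through a synthetic
  leading `(1, 0)` code (`capture_bud_as_gen1 = FALSE` disables it).
* **Death calling.** Death leaves no direct image signature, so it is
  called when no budding event occurred within `death_gap` (default 600
  min) before the series ends. A mother that vanishes *after* a full death
  gap of quiescence is recorded `death_called` — a dead mother dragged from
  its trap is a complete record — whereas mid-life disappearance terminates
  the record as `lost`. Cells still budding at run end are `censored`.
  Lost, contaminated and censored records are excluded from cohort
  statistics by default, and no survival-curve compensation or imputation
  is applied; inclusion flags exist for sensitivity analyses.
* **Contamination.** A frame showing three or more buds, or a second
  adult-size object (>= 4.5 um), terminates the record as `contaminated` at
  that frame.

## The synthetic experiment generator

The generator emulates the study conditions of a long-term trap-array run:
a 1100-trap chip (5 subarrays of 10 x 22; one 220-trap subarray is the unit
used for characterization cohorts), imaged every 10 min for 60 h, initial
occupancy 70.5%.

**Occupancy.** Traps fill independently at time 0, then empty traps refill
by *self-filling*: each daughter dissected upstream of an empty trap gives
it an independent chance `refill_coupling` to be caught that frame
(`P(fill) = 1 - (1 - c)^k` with k upstream dissections in the frame).
Occupied traps lose their mother with a per-frame hazard and acquire an
extra cell with another; `trap_profile()` ships presets expressing the
bowl-length trade-off between the two artifact rates. The coupling constant
is the one free parameter; `scripts/calibrate_refill.R` sweeps it, and the
shipped default (0.025) makes a 220-trap run rise from ~70% to ~92-93%
occupancy within 4 h, the self-filling behaviour reported for this chip
class. The hazards (3e-4 per frame each at default) are presets of
plausible magnitude, not measured rates — only endpoint percentages are
reported for the real device.

**Per-cell timelines.** A cell captured at time t draws a generation target
from a Gaussian (rounded, floored at 1; a gamma option exists) with mean
24.29 and SD 6.32, minus `daughter_penalty_per_hour` x t/60 — daughters
dissected from old mothers inherit shortened lifespans, and the penalty
(0.22 gen/h) is set so the mean lifespan of cells captured at ~45 h is
about 59% of the 0-2 h value, matching the reported endpoint ratio. The SD
derives from the reported 24.29 +/- 3.65 under the between-run convention
SE = SD/sqrt(runs) with 3 runs (3.65 x sqrt(3) = 6.32); whether that
printed spread is an SE or a per-cell dispersion is ambiguous in this
literature, and this is the reading consistent with the stated statistics
convention. Inter-budding intervals start from a 90-min baseline (typical
diploid budding at 30 C; not printed for the source device), times 1.09 for
the first interval (the reported 9% first-generation extension), times a
terminal ramp rising linearly to 2.0 over the last 5 intervals ("rises
dramatically in the last generations" given a concrete, configurable form),
times lognormal noise whose coefficient of variation grows by 0.01 per
generation — the de-synchronization mechanism: cohorts stay synchronized
for the first ~10 generations and spread out later. Each interval's
dissection/appearance relation is drawn among the three motifs with
probabilities 0.2 (overlap) and 0.1 (handoff); the remainder leave a ~1.5
frame bud-free gap. Events past run end are truncated and the cell flagged
censored.

**Rendering.** Buds are visible over the half-open window [appearance,
dissection) and grow linearly from 1 to 4 um; the mother is a constant 5 um
until lost; a contaminating cell renders as a second adult from its capture
onward. Sizes are deterministic given event times (noise off by default) so
the coder's size-drop rule is exactly testable; a warning is emitted if a
maturation is no longer than the frame interval, where handoff detection
becomes unreliable.

What the generator does **not** emulate: pixel-level imaging (observations
are object tables, not micrographs), segmentation error in sizes, any fluid
mechanics (flow fields, forces on buds), position-dependent artifact rates,
or biological correlations between a mother's BTI and its daughters'.
Passing round-trip tests therefore show the *coder* is exact under the
stated observation model — not that segmentation of real micrographs would
be.

## Cohort statistics

`summarize_cohort()` assembles, from per-cell records: the viability curve
(fraction with RLS >= g; its discrete tail sum equals the mean RLS, an
identity the tests check exactly), the mean RLS with both standard-error
conventions (the between-run convention SD/sqrt(runs), reported alongside
the conventional SD/sqrt(n)), capture-time bins (2-h default) with an
ordinary least-squares fit through the bin means (slope in generations per
hour), birth-aligned BTI means with the first-generation extension relative
to generations 2-6, death-aligned BTI means indexed by generations before
death, and the RLS-ordered BTI kymograph with 5-generation period labels.
The interval from capture to the first budding event is exposed separately
as `bti0` and excluded from the aligned profiles, whose generation 1 is the
first *inter*-budding interval — on synthetic data that is the convention
the generator's extension parameter targets.

## Numerical choices and degenerate inputs

Frame indices are global (frame f at f x 10 min); captures are snapped to
frame times, since filling is detected at frames. Bud visibility windows
are half-open so a bud dissected exactly at a frame time is absent from
that frame. With all noise switched off, intervals are exactly the baseline
— degenerate cases short-circuit the lognormal sampler rather than taking
log(0). Measured BTIs are quantized to frame multiples and differ from the
true intervals by strictly less than one frame interval. Single-bin
cohorts raise on regression; single-cell runs report an undefined (NA)
between-run SE rather than a fabricated one. Ties in the kymograph row
order are broken by cell id, and upstream-rank ties by row then subarray,
so all orderings are total and runs are bitwise reproducible: every
stochastic function takes an explicit `rng_stream`, and one experiment seed
fans out to named substreams.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script cohorts use 3 independent runs of one
220-trap subarray (the 3-runs-of-220-traps protocol used for
characterization experiments on this chip class), which yields ~400-450
complete first-10-h records per cohort; round-trip checks use ~1000 clean
cells across three seeds; the distribution-recovery check uses 10,000
draws. These sizes make every Monte-Carlo band in the tests at least ~3
standard errors wide at the effect sizes being recovered.

## Known limitations

* A 60-h run right-truncates the observable lifespan distribution: a death
  can only be *called* if a full death gap of quiescence fits before run
  end, so cells needing more than ~50 h are censored and excluded under the
  default policy. Observed cohort means therefore sit 2-3 generations below
  the configured distribution mean — visible in the simulated cohorts, and
  inherent to the study design rather than a coding artifact.
* For the same reason, complete records from captures after ~20 h are
  scarce; capture-delay effects are better read from the binned regression
  slope than from late-bin means.
* The observed capture-time slope is steeper than the configured penalty
  because censoring removes long-lived late captures preferentially — a
  selection effect real analyses of this design share.
* Artifact hazards are memoryless and uniform across the array; real
  mother loss concentrates on senescent cells with upstream buds.
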