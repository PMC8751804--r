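---
title: "From sensor log to exposure index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sensor log to exposure index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2sindex)
```

## The problem

Hydrogen sulphide (H2S) harms acutely: brief peaks of tens to hundreds of
ppm matter far more than the day's average, yet the conventional 8-h
time-weighted average (TWA) compresses a shift with a 100-ppm excursion into
a number that can sit below 0.1 ppm. Wastewater work is the archetype:
exposure is zero for most of the shift and concentrated in short episodic
tasks — opening a pump sump, flushing a line — during which concentrations
rise almost instantaneously and decay within minutes.

Direct-reading personal monitors produce long regular-interval logs of such
shifts. `h2sindex` turns one log into a single dimensionless exposure index
that combines three things the TWA cannot: how *often* peaks occurred (peak
counts in four concentration bands), how *long* the worker was exposed
(durations in two bands), and how *bad* it got (the shift maximum). The TWA
is computed alongside for comparison with the occupational exposure limit
(OEL).

## The pipeline

For a validated series of readings $x_1,\dots,x_n$ (ppm) at logging
interval $\Delta$ seconds:

1. **Segmentation.** Compute a 3-min centred moving average (CMA). An
   *exposure task* is a maximal run of samples with CMA $> 0$; runs whose
   separating all-zero-CMA gap is shorter than the separation time
   (default 3 min) are merged. Distinct tasks therefore represent distinct
   work episodes, separated by genuinely unexposed time.
2. **Peak detection.** Within each task, sample $i$ is a *peak* iff
   $x_i > x_{i-1}$ and $x_i > x_{i+1}$ (strict local maximum; shift-boundary
   samples compare only against the neighbour that exists) **and**
   $x_i \ge 1.25\,\mathrm{CMA}_{1\min}(i)$. If no sample in a task satisfies
   both, one *forced* peak is emitted at the earliest sample attaining the
   task maximum: every task has at least one peak.
3. **Classification and accumulation.** Peak apexes are classified into
   $(0,1]$, $(1,5]$, $(5,10]$, $(10,\infty)$ ppm, giving counts
   $c_{01}, c_1, c_5, c_{10}$. Each raw-positive sample contributes $\Delta$
   seconds to $d_{01}$ (readings in $(0,5]$) or $d_5$ (readings above 5);
   both are expressed in minutes.
4. **Index.** With $m$ the maximum raw reading of the measurement,

   $$\mathrm{index} = 0.1\,c_{01} + 0.1\,d_{01} + c_1 + 5\,c_5 + 5\,d_5 +
     10\,c_{10} + m.$$

5. **TWA.** The dose is $\sum_i x_i \Delta$ (ppm-minutes);
   `mean_measured` divides by measured time, `twa_8h` by the 8-h reference,
   treating unmeasured time as unexposed.

```{r example}
ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") +
  seq(0, by = 10, length.out = 2880)
x <- numeric(2880)
x[1440] <- 8.0                       # one 8-ppm sample in an 8-h shift
analyze_shift(gas_series(ts, x))
```

One task, one peak in the $(5,10]$ band, 10 s above 5 ppm:
$5 + 5\cdot\tfrac{1}{6} + 8 \approx 13.83$.

## Conventions and their rationale

Several details of the method are not forced by its verbal description;
this package fixes them as follows, and exposes the tunables through
`algorithm_params()`.

**CMA parity and edges.** The window in samples is
$w = \mathrm{round}(\mathrm{window}/\Delta)$, incremented by one when even,
so the average is truly centred. At the series edges the window shrinks to
the available samples and the divisor is the actual count: zero-padding
would fabricate unexposed time at shift boundaries and could suppress or
split tasks there.

**Positivity is strict.** Task support uses `CMA > 0` on the unquantized
average. Sums of exact zeros are exact zeros in floating point (the
cumulative-sum implementation subtracts identical partial sums), so the
strict test is reliable.

**Merge semantics.** The gap that decides whether two positive-CMA runs are
one task is the duration of the all-zero-CMA run between them. With the
default 3-min window and 3-min separation the CMA already bridges raw gaps
up to about the window length, so merging mostly matters when the two
parameters are set independently — e.g. a 1-min window with a 3-min
separation.

**The ratio criterion.** "25% above the 1-min CMA" is implemented as the
dimensionless test $x_i \ge 1.25\,\mathrm{CMA}_{1\min}(i)$, with the CMA
window centred at and including the apex. The ratio form is the only
scale-free reading, which is what makes peak detection invariant under
positive rescaling of the readings; `ratio` is a parameter so alternatives
can be explored. The CMA at a candidate apex can never be zero (its own
positive reading lies in its window), so the test needs no special case.

**Plateaus and ties.** "Larger than" is strict: a flat-topped excursion has
no strict local maximum and is handled by the forced-peak rule rather than
by relaxing strictness. When a task maximum is attained at several samples,
the forced peak goes to the earliest, for determinism.

**Interval boundaries.** All bands are half-open on the left, $(lo, hi]$.
At 0.1-ppm instrument resolution this reproduces the conventional labels
"up to 1.0", "1.1–5.0", "5.1–10.0", "10.1 and higher".

**Durations exclude zero readings.** $d_{01}$ counts samples in $(0, 5]$
only. Counting zeros at 0.1/min would award an unexposed 8-h shift an index
of 48; excluding them keeps the invariant that index 0, TWA 0 and "no
positive reading" coincide.

**Durations are in minutes.** Hours would make the duration terms
negligible against single peaks; seconds would let them dominate everything
else. Minutes put a typical task's duration on the same scale as its peak
count, which is what the weighting presupposes.

**The maximum is raw and global.** $m$ is the maximum unsmoothed reading of
the whole measurement, not a per-task or smoothed value.

**TWA reference.** `twa_8h` divides the dose by 8 h, treating unmeasured
time as unexposed; this is the number to set against an 8-h OEL when
measurement covered the active work. `mean_measured` (dose over measured
time) is reported alongside, since both conventions are in use.

## Parameters

| parameter         | default | unit    | meaning                                   |
|-------------------|---------|---------|-------------------------------------------|
| `cma_window`      | 180     | s       | segmentation CMA window                    |
| `separation`      | 180     | s       | minimum unexposed time between tasks       |
| `peak_cma_window` | 60      | s       | peak-validation CMA window                 |
| `ratio`           | 1.25    | —       | required apex-to-CMA ratio                 |
| `reference_hours` | 8       | h       | TWA reference period                       |
| `quantize`        | off     | —       | snap readings to 0.1 ppm before analysis   |

The 3-min separation suits wastewater work, where inspections at successive
pumping stations can be less than 5 min apart; other work patterns may need
other values, and shortening or lengthening it only re-partitions tasks —
it does not change the index, which depends on peaks and durations, not on
task boundaries (merging two tasks can reduce the peak count only through
the forced-peak rule, when neither fragment had a qualifying peak).

## The synthetic generator

`generate_shift()` emulates the structure of shift logs from episodic H2S
work: a zero background over a few hours at 10-s logging; a handful of
tasks, each one to three pulses with instantaneous rise and exponential
decay (time constant 30 s, matching peaks that are very steep and last
minutes); lognormal apex amplitudes with geometric mean 1.8 ppm and
geometric standard deviation 9.3 (the scale and spread typical of exposed
readings in this kind of work); quantization to the 0.1-ppm instrument
grid; and guaranteed gaps of at least `separation + cma_window` seconds of
zeros between tasks, so segmentation can be tested against an exact
expected count. Pulse spacing within a task is uniform, since no empirical
spacing distribution is available.

Two accounting subtleties are deliberate:

* **Realized vs nominal tasks.** A lognormal apex occasionally falls below
  half the quantization step and disappears from the quantized series. The
  ground truth therefore records the *realized* task windows — those with
  at least one positive sample — which is what any algorithm could recover.
  Clipping apexes upward instead would bias the amplitude distribution by
  roughly 10% in GM and defeat the distributional checks.
* **Ground truth comes from the oracle.** `oracle_elements()` is a literal,
  loop-based restatement of the whole method (window means computed sample
  by sample, explicit run collection and merging, both peak criteria
  re-evaluated at every sample). It shares no code with the production
  pipeline, so exact agreement between the two routes on generated shifts
  is a genuine two-implementation check, not a tautology.

What the generator does **not** emulate: sensor drift and negative
baselines, cross-sensitivity, alarm-triggered sensor shutdowns, varying
logging intervals within a file, and the shape variety of real releases
(plateaus from standing in a plume, slow ventilation decays). Passing tests
on synthetic data therefore demonstrate algorithmic correctness — the
implementation computes the defined quantities exactly — not field validity
of the index itself. One field-data feature follows directly: pooled
positive readings of a generated cohort have a lower GM than the apex
distribution (decay tails contribute many small readings), as in real logs
where most exposed samples sit well below their peak.

## Numerical choices

* Durations are computed by counting samples per band and converting to
  minutes once (`count * interval / 60`), in both the pipeline and the
  oracle, so the two routes agree bit-exactly rather than to rounding.
* JSON reports serialize numbers at 17 significant digits; reading a report
  back reproduces every numeric field exactly.
* CSV output writes readings at 4 decimals; the read–write round trip is
  the identity for any series quantized at least that coarsely (including
  everything at instrument resolution).
* Interval validation tolerates ±5% jitter on the logging interval; logger
  clocks drift, and the analysis windows are defined in wall time.
* Short dropped-sample gaps can be repaired by linear interpolation
  (`fill_short_gaps()`), flagged in the series metadata; long gaps remain a
  hard validation error. How missing samples were handled in the original
  field datasets is not documented anywhere we know of; interpolation over
  a bounded gap is a conservative repair, not a reconstruction.

## Known limitations

* **Monotonicity has edge cases.** Raising one reading "should" never
  lower the index, and in randomized tests over generated shifts it never
  does. It is not a theorem, though: raising a reading adjacent to a
  *marginal* apex (one barely at `ratio` times its 1-min CMA) can push that
  apex below the ratio criterion — or tie it and destroy the strict local
  maximum — without creating a qualifying peak at the raised sample,
  removing one peak's weight. Constructing this requires two comparable
  apexes within a window of each other, a configuration episodic
  pulse-decay data rarely produces.
* **Merged tasks are not CMA-connected.** When `separation` exceeds the
  CMA window's bridging range, a merged task contains interior zero-CMA
  samples; per-task duration then includes that interior time.
* **Apex-interval counts are resolution-dependent at band edges.** A true
  concentration of 5.04 ppm quantized to 5.0 classifies as $(1,5]$;
  enabling `quantize` changes band membership for readings within half a
  step of a boundary. This is inherent to the printed band labels.
* The index weights are fixed by convention (`index_weights()`); any
  re-weighting changes the meaning of the number and would need fresh
  validation against manually assessed data.

## Problem sizes used by the test suite

The suite checks two-route (pipeline vs oracle) agreement on 200 seeded
3-h shifts at 10-s logging, segmentation properties on 50 shifts across a
grid of separation times, 1000 single-reading perturbation trials for
monotonicity, and amplitude-distribution recovery on 10,000 draws; the
whole suite runs in well under a minute. These sizes give each property
multiple independent chances to fail per class of input while keeping the
suite fast enough to run on every change.
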