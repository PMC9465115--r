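---
title: "Designing dia-PASEF isolation-window schemes from precursor density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dia-PASEF isolation-window schemes from precursor density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diawin)
```

## The design problem

On a trapped-ion-mobility quadrupole TOF, data-independent acquisition
is synchronized with the ion-mobility elution (dia-PASEF): during each
TIMS ramp, ions elute from high to low reduced mobility (1/K~0~), and
the quadrupole steps through a sequence of m/z isolation windows, each
transmitted during a segment of the ramp. An isolation window is
therefore a rectangle in the m/z-1/K~0~ plane, and an acquisition
scheme is a set of `n_scans * windows_per_scan` such rectangles
visited over one cycle.

Peptide precursors occupy diagonal, charge-stratified bands in this
plane: within a charge state, mobility rises roughly linearly with
m/z, and higher charges sit on lower bands. A scheme with fixed-width
m/z windows spanning a rectangular region wastes quadrupole time on
empty corners of the plane and leaves dense regions under-sampled.
diawin instead:

1. **bins the precursors at equal density along m/z**, so each
   isolation window fragments about the same number of precursors;
2. **models the scanned region as a trapezoid** — the lower and upper
   1/K~0~ limits are linear functions of m/z, parameterized by their
   four corner values;
3. **assigns the bins diagonally to scans**: scan 1 starts at the
   highest-m/z bin in the top mobility strip, and each subsequent scan
   starts one bin lower, following the cloud's diagonal. With bins
   indexed `1..W` from low m/z, scan `j` carries bin
   `W - (s - 1) * n_scans - (j - 1)` in strip `s`;
4. **extends the outer strips** to the instrument mobility limits, so
   the topmost window of each scan reaches the upper 1/K~0~ limit and
   the bottommost the lower limit — precursors straggling above or
   below the trapezoid at the right m/z are still acquired;
5. **optimizes the four trapezoid corners** to maximize the covered
   fraction of library precursors, with a Gaussian-process surrogate.

The result is exported as a plain CSV window table
(`write_method_file()`), and any such table — including ones describing
an instrument's existing method — can be re-imported and scored
against a library (`run_evaluate()`).

## Geometry details and conventions

**Quadrupole transitions.** Within a scan the quadrupole jumps once
per strip boundary, so the boundary must be a single 1/K~0~ value, but
the trapezoid's interior line at height `(k - s)/k` varies with m/z.
We evaluate it at the mean of the two adjacent bins' m/z centers,
which balances the two windows symmetrically against the diagonal. Any
fixed choice between the two bin centers would bias one window's
overlap with the cloud; the midpoint is the neutral choice.

**Half-open windows.** m/z intervals are half-open `[start, end)`,
except the window carrying the highest bin, which is closed so the
upper range limit itself is not lost. A precursor sitting exactly on a
shared edge therefore belongs to exactly one window — the one whose
`mz_start` equals the edge — and per-window counts add up to the
number of covered precursors exactly when overlap is zero (the
default; the package never adds overlaps unless asked).

**Equal-density edges.** Interior edges are placed midway between the
order statistics flanking rank `i * n / n_bins`. For continuous data
this guarantees per-bin counts differ by at most one; ties that
collapse edges are reported as errors rather than silently merged,
because a collapsed edge means the library cannot support that many
distinct windows.

**Cycle time.** Each frame (MS1 or dia-PASEF) lasts the TIMS ramp time
plus a fixed transfer overhead:
`(n_scans + ms1_frames) * (ramp_time + frame_overhead)`. The defaults
are a 100 ms ramp and a 6.15 ms overhead, chosen so that the standard
12-scan method reports 1.38 s; with 8 and 25 scans the same timing
yields 0.96 s and 2.76 s. The overhead is a single configurable
constant — real instruments may vary transfer time slightly with frame
content, which this model ignores.

**Coverage population.** Coverage defaults to precursors of charge
2-4 inside the method's configured m/z and mobility ranges,
unweighted. Singly charged ions are dominated by non-peptide
background and are excluded from library searches anyway; intensity
weighting is available (`intensity_weighted = TRUE`) but off by
default, so one abundant precursor cannot dominate the objective.

## The optimizer

The objective — covered fraction as a function of the four corner
values — is piecewise constant (it changes only when a window boundary
crosses a precursor), mildly multimodal, and cheap (a few milliseconds
for 2 x 10^4^ precursors). The m/z bin edges depend only on the
library, so they are computed once and held fixed; only the
ion-mobility geometry is searched.

`optimize_scan_area()` runs seeded evaluations first (if given), then
`n_initial_random` uniform draws over the corner box, then proposals
from a Gaussian-process surrogate: a squared-exponential kernel on
corners rescaled to the unit box (fixed length-scale 0.25, nugget
10^-6^), with the next candidate maximizing expected improvement over
a random candidate pool of 1000 points plus 200 local perturbations of
the incumbent (sd 0.05). Corner orderings with the top edge at or
below the bottom edge score 0 rather than erroring, which keeps the
search space a plain box. The proposer is swappable: `"random"` gives
pure random search, and any function `(bounds, X, y) -> next point` is
accepted. All randomness flows from one seed, so trial histories are
bit-reproducible.

The default budget of 200 trials is far more than the 4-dimensional
problem needs on the clouds we generate — on the trapezoid-recovery
fixture below the search typically reaches the optimum within a few
dozen trials — but matches common practice for this optimizer family
and costs only seconds. `grid_search_oracle()` exhaustively evaluates
a corner lattice (7^4^ = 2401 candidates by default) as an independent
check; the surrogate search is expected to match or beat the grid
within 0.02 coverage.

## What the synthetic generator does and does not emulate

`cloud_model()` emulates the charge-stratified band structure of a
tryptic digest: mixture weights 0.66/0.27/0.07 for charges 2+/3+/4+,
per-charge linear mobility trends (e.g. `0.40 + 0.0009 * mz` for 2+)
with Gaussian residual sd 0.045, and a lognormal m/z marginal with
median 700 Th (log-sd 0.30), truncated to the method box by rejection.
These constants were chosen once to visually mimic published
proteome-wide density maps; they are free parameters of the generator,
not measured values. Phospho mode translates the whole cloud by
(+80 Th, +0.03 1/K~0~) and moves the box to 400-1400 Th, mimicking the
mass and conformation shift of phosphopeptide enrichment.

The generator does **not** emulate: intensity structure (all
intensities are 1), retention time, missed cleavages and modification
fine structure within a band, detector saturation, or the
heavier-tailed mobility residuals of real libraries. Consequently,
passing tests demonstrate correct geometry, counting, and optimizer
behavior — not that any particular coverage percentage will be
attained on a real instrument library, which tends to have tighter
bands (and hence higher attainable coverage) than this conservative
generator.

`generate_within_trapezoid()` is a deliberately idealized fixture: a
cloud confined to a known steep trapezoid whose diagonal rise over
half the m/z range exceeds its height. For such a cloud a 2-window
scheme built on the generating trapezoid covers every point, so the
optimizer has a known feasible optimum at coverage 1.0 to recover.

```{r recovery}
area <- scan_area(0.7, 1.1, 0.85, 1.25)
trap <- generate_within_trapezoid(area, c(300, 1200), 2000, seed = 3)
res <- optimize_scan_area(
  trap, optimization_config(n_trials = 60, seed = 42),
  n_scans = 12, windows_per_scan = 2, charges = 2:3)
res$best_value
```

## Numerical choices and degenerate inputs

* Window membership uses exact comparisons with a 10^-9^ guard only to
  identify the highest-m/z window across printed-precision round
  trips; coverage itself involves no tolerance.
* Method files print 1/K~0~ with four decimals and m/z with two;
  re-reading and re-writing a file reproduces its body byte-for-byte,
  so files diff cleanly across runs and machines.
* Empty filter results warn and return an empty library (a crash would
  make range exploration from the CLI tedious); an empty *input*
  library is an error everywhere downstream.
* Rejection sampling aborts when the acceptance rate falls below 2%
  after 10^4^ draws — a model whose box excludes 98% of its own cloud
  is a misconfiguration, not something to wait out.
* Libraries deduplicate on (sequence, charge) when sequences are
  present — library exports often repeat a precursor per fragment row —
  otherwise on (mz, im, charge); the first occurrence wins.

## Problem sizes

The shipped tests design and score schemes against synthetic libraries
of 10^3^-10^4^ precursors and run the optimizer with 25-100 trials;
the acceptance script uses 2 x 10^4^-precursor libraries and 200
trials. These sizes give sub-precursor-level stable coverage
percentages for the generator's clouds while keeping a full run in the
tens of seconds on one core. Real libraries of 10^5^-10^6^ rows are
well within reach: coverage evaluation is vectorized over windows and
linear in library size.

## Known limitations

* One trapezoid per method: no retention-time-segmented or per-sample
  adaptive schemes.
* The single-overhead cycle-time model cannot reproduce every printed
  combination of scan count and cycle time for real instruments;
  the 12-scan timing anchors the default.
* Coverage is a geometric proxy: it counts precursors inside windows,
  not identifications — spectral complexity within a window, fragment
  interference, and points-per-peak effects are out of scope.
* The GP surrogate uses a fixed length-scale rather than marginal
  likelihood optimization; for this 4-dimensional box it finds the
  optimum reliably, and the grid oracle in the test suite guards
  against regressions.
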