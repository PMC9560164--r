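---
title: "Empirical-histogram cell-fate simulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical-histogram cell-fate simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfatesim)
```

## The data model

Long-term live-cell imaging with single-cell tracking produces a
*cell-lineage database*: one record per cell, where a cell begins at its
birth (selection as a progenitor at time 0, or production by a division or a
fusion) and ends with one of five outcomes — bipolar division (BD),
tripolar or tetrapolar division (MD3/MD4, jointly "multipolar division"),
cell death (CD), cell fusion (CF), or censoring at the end of the
observation window (NONE). A lineage is a progenitor plus all of its
progeny; a database is a forest of lineages.

`LineageDB` stores this forest with a validity layer split in two: the S4
validity checks structure (columns, types), while `validateLineageDB()`
checks the biology-level invariants — division arity (BD has exactly two
children, MD3 three, MD4 four), fusion symmetry (both partners end in CF at
the same time, the pair has exactly one joint child), time consistency, and
the forest property — returning violations as a table rather than an error,
so a defective file can be inspected.

Two conventions deserve justification because the data alone do not decide
them:

* **Aliveness is half-open, [birth, end).** At the frame on which a cell
  divides, the children are counted and the parent is not. This keeps the
  accounting identity
  `alive(t) = progenitors + Σ_divisions (arity − 1) − deaths − fusion pairs`
  exact at every sampled time, which the test suite asserts on every
  generated and simulated database. Censored cells are counted through
  their end time, since no event removed them.
* **Fusion is normalised to a forest.** Both fusing cells end with CF at
  the fusion time; one of them carries the merged cell as its child while
  the partner reference preserves traceability. The fusion time is the
  first merged frame.

Times are stored as real minutes throughout; the native TSV dialect writes
them with 17 significant digits so that save/load is the identity.

## Operation data: the empirical model

`extractOperationData()` decomposes every cell into a unit bounded by its
start and end events and accumulates two histogram collections:

* **Operation data-Time** — the distribution of the interval ("Ltime")
  between the two events, one histogram per start/end class (`FIRST`,
  `BDBD`, `BDMD`, `BDCD`, `BDCF`, `MDBD`, `MDMD`, `MDCD`, `MDCF`,
  `DIVCFDIV`, `BDCFCD`, `MDCFCD`, `NONDIVCD`);
* **Operation data-Events** — the frequency of each end event per start
  context (`FIRST_LIST`, `BD_LIST`, `MD_LIST`, `BDCF_LIST`, `MDCF_LIST`),

plus the **recovery percentage**: the share of all bipolar divisions
falling in the final fraction of the tracking window (default 0.2, i.e.
3200–4000 min of a 4000-min tracking), which the simulator uses to let
non-growing cells re-enter proliferation, and the tripolar/tetrapolar
split among multipolar divisions.

Extraction choices made where the procedure is underdetermined:

* Censored cells contribute nothing, except censored progenitors, which
  are counted as `NONDIV` in `FIRST_LIST` (the first-event list must cover
  every progenitor).
* A fusion pair contributes **one** observation — consistent with
  `countEvents()`, where a fusion pair is one CF event — using the
  interval of the member that carries the merged cell.
* `NONDIVCD` records the death times of cells not born of a division
  (progenitor deaths), which is exactly the array the simulator's
  non-dividing branch consumes; the same intervals also appear in `FIRST`.

## Simulation arrays

Sampling follows the flat-array construction: a time histogram bin
`20 : 4` expands to the sequence `20, 20, 20, 20`, and a uniform draw over
the expanded array is the count-weighted empirical draw. Interpolated
(real-valued) counts are apportioned by largest remainder at expansion
time only, so the arrays stay faithful to the weights without re-rounding
the model itself.

Each event list becomes an array of exactly 100 symbols. Counts are first
converted to percentages **of the divisions (BD + MD) recorded in that
list**; because the list also holds non-division events the total exceeds
100 and is scaled back to 100 before largest-remainder rounding (ties go
to the earlier symbol, so 1:1:1 becomes 34/33/33). A list without
divisions falls back to its own total, and a shortfall below 100 entries
is padded with `NONDIV` symbols, read as "no further event". With the
within-list denominator a BD child that is observed again almost always
divides again — which is what sustained exponential expansion of an
unstressed culture requires — whereas a global-denominator reading would
assign a large spurious non-dividing mass to every context. An empty list
or histogram yields an empty array, the "no data" signal for the fallback
rules below.

## The assignment cycle

`simulateCellFates()` seeds progenitors, assigns each a first event and
Ltime, and then repeatedly finalises every cell whose pending event falls
inside the horizon, spawning and assigning its children, until only
horizon-crossing assignments remain; those cells are censored as `NONE`
at the horizon (an assignment is never truncated into a fabricated
event). Cells are processed in (lineage, cell) order and all randomness
comes from one seeded R stream, so identical configurations produce
record-identical databases.

The assignment rules, with their fallbacks when an array is empty:

* **First events.** Ltime from the `FIRST` array; a draw equal to the
  tracking time is replaced by ±30% of the tracking time. The event comes
  from `FIRST_LIST`; a CD draw re-times from `NONDIVCD`. With no interval
  data the mean BD time ±25% is used; with no event data at all the cell
  divides bipolarly (with an empty list but interval data it is
  non-dividing — the all-`NONDIV` model must leave the population
  constant).
* **Non-dividing cells** get one recovery chance: with probability equal
  to the recovery percentage they re-enter growth via BD with an Ltime of
  80–100% of the tracking time (applied at most once per cell); otherwise
  they die with probability equal to the CD share of total divisions
  (Ltime from `NONDIVCD`), else idle to the horizon.
* **BD/MD children** draw from `BD_LIST`/`MD_LIST`. Division intervals
  come from `BDBD` (BD children, for both BD and MD draws) or `MDMD` (MD
  children); deaths from `BDCD`/`MDCD`; fallbacks use the mean division
  or death time pooled over the corresponding arrays.
* **The parent/child restraint.** A BD-born cell that divides bipolarly
  and whose parent was itself a BD-born bipolar divider redraws its Ltime
  until within ±10% (configurable) of the parent's, clamping to the
  nearest bound after a bounded number of attempts (default 100) so
  disjoint supports terminate. This is what lets fast lineages stay fast.
* **Fusion.** A CF draw pairs the cell with its first sibling (cell-id
  order) that is neither already paired nor dead, overriding that
  sibling's assignment if it has one; the pair shares the shorter of two
  `BDCF`/`MDCF` draws, and the merged cell is born at the common end as
  the child of the lower-numbered member. At most one pair forms per
  cohort (later draws exclude CF), and a CF draw with no available
  sibling becomes cell death at the mean death time. Fusion between
  non-siblings is never generated. With pairs counted once at extraction,
  the override rule reproduces the model's CF frequency on a
  simulate-then-extract round trip to O(p²); a
  rule restricted to unassigned siblings would halve it.
* **Merged cells** are reassigned from `BDCF_LIST`/`MDCF_LIST` according
  to the fusing cells' pre-fusion class; divisions re-time from
  `DIVCFDIV`, deaths from `BDCFCD`/`MDCFCD`; an empty list (and a CF
  draw, which has no partner for a merged cell) falls back to death.

## Modes

* **standard** — one population, one model.
* **dose** — the model is first built by bin-wise linear interpolation
  between two reference models:
  `c_x = c_a + (c_b − c_a)/(d_b − d_a) · (d_x − d_a)`,
  applied to every histogram bin, every event-list count and the recovery
  percentage, clamped at zero. Interpolating raw counts (not normalised
  frequencies) reproduces the worked reference values (10 and 1 at doses
  2 and 5 give 7 at dose 3) and keeping the results real-valued makes the
  endpoints exact identities.
* **mixed** — each population runs with its own model and its records
  carry a `population` tag; populations never interact (no
  cross-population fusion), which matches the intended use — tracking
  population proportions — and is a stated modelling limit.
* **switch / mixed_switch** — at the switch time every assignment that
  would complete after it is voided and redrawn under the second model,
  with birth state and the once-only recovery flag preserved; completed
  events are untouched. Because the redraw is unconditioned, crossing
  events can land earlier than the voided ones, so switching to an
  *identical* model is not exactly distribution-preserving: with
  realistic models the final population shifts by roughly 2–3%, well
  inside the seed-to-seed envelope for practical use but detectable with
  many replicates. The test suite asserts the honest bound (means within
  5%) rather than exact indistinguishability.

## The synthetic-data generator

`generateSyntheticDB()` is a branching process, independent of the
simulator's machinery, with known per-birth-class event probabilities and
interval families (fixed, uniform, lognormal). Its defaults emulate an
unstressed p53-proficient culture tracked for 4000 min: doubling times
around 38–40 h (lognormal, ~10% spread), progenitors mid-cycle at
selection, and rare multipolar division, death and fusion; multipolar
progeny mostly die. `makePaperLikeFixtures()` tunes two parameter sets so
the per-frame event chances approximate 0.54/0.001/0.004/0.004 (control-
like) and 0.54/0.014/0.037/0.023 (silenced-like) per 100 lineages, with
the cell-death probability ratio fixed at 9.25; 2000 lineages per fixture
keep the rare-event counts stable.

What the generator deliberately does **not** emulate: spatial positions
and motility, cell-cycle correlations beyond the parent/child restraint,
non-sibling fusion, and any dose-response mechanism. Tests passing on
synthetic data therefore validate the machinery — extraction, sampling,
bookkeeping, round trips — not the biological fidelity of any particular
empirical database.

## Numerical choices and degenerate inputs

* Largest-remainder rounding everywhere an integer composition is needed;
  ties break toward the earlier symbol — deterministic and
  mass-conserving.
* Empty arrays signal "no data" (`NULL` from `sampleArray()`), never 0.
* Mean-time fallbacks pool the relevant arrays (division times for the
  mean BD time, death times for the mean CD time) and degrade to half the
  tracking time when nothing is available.
* The resampling bound plus clamp guarantees termination of the ±10%
  restraint when the interval support is disjoint from the parent's
  window.
* A safety cap (`maxCells`, default 2·10⁶) aborts runaway simulations
  with a clear error instead of exhausting memory.
* Extraction from data with censoring straddling a generation
  under-represents long intervals (short intervals finish inside the
  window more often); this is a property of censored observation itself,
  shared with empirical tracking, and is why the round-trip tests use
  models whose generations either complete or censor as a whole.

## Problem sizes used in the checks

The test suite runs entirely on generated data: round-trip parameter
recovery simulates 2500 progenitors over a 4000-min horizon (roughly
10⁴ cells); determinism, validity and accounting checks use tens of seeds
at 30–200 progenitors; the variance-envelope check compares 5-seed
coefficients of variation at 100 vs 900 progenitors. These sizes put
every statistical assertion at 3-standard-error resolution while the
whole suite completes in a few minutes on one CPU.

## Known limitations

* Positions are not simulated; density maps apply only to tracked data
  with a positions table.
* Mixed cultures are independent populations — no competition, contact
  effects or cross-population fusion.
* The dose mode assumes event counts vary linearly in dose between the
  two reference models; outside the bracket it refuses to extrapolate.
* Bit-compatibility with any other random-number stream is a non-goal;
  the contract is distributional fidelity plus within-package
  determinism.
```{r session}
sessionInfo()
```
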