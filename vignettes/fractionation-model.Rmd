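---
title: "Fractionation after whole genome doubling: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractionation after whole genome doubling: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractionator)
```

## The deletion process

After a whole genome doubling every gene `g_1, ..., g_N` is present in
two copies.  Fractionation is modelled as a sequence of deletion
events: at each step a gene that is still double-copy is chosen
uniformly at random, a length `X` is drawn from a geometric law on
{1, 2, ...} with mean `µ ≥ 1`,

    P(X = a) = (1/µ) (1 − 1/µ)^(a−1),

and the next `X` *double-copy* genes from the start position onward are
converted to single-copy.  Genes that are already single-copy are
skipped: once a fragment has been excised the chromosome is rejoined,
so the fragment is invisible to later deletion events, which simply run
past it.  An observer, however, still sees the deleted genes — one copy
survives on the homeologous chromosome — so what accumulates on the
genome is a pattern of maximal runs: single-copy runs (whose length
distribution we call `ψ_t`) interleaved with double-copy runs (length
distribution `ρ_t`, mean `ν_t`).

`µ = 1` makes every event convert exactly one gene and never overlap
anything: the *functional*, gene-by-gene regime, under which the
deleted set is a uniformly random subset.  `µ > 1` is the *structural*
regime of segmental excision; overlapping events concatenate, so a
single-copy run is the footprint of one or more events.

### Assumptions baked into the model

* Deletions hit one and the same homeolog; the two-sided variant with a
  chromosome-choice probability is out of scope.
* Both copies of a gene are never lost (deleting the last copy is
  assumed lethal or invisible to the duplicate-pair bookkeeping).
* No rearrangement: run structure, once created, is only modified by
  further deletion.
* `N` is large enough that chromosome ends do not matter.  Rather than
  approximating this, the default topology is a **circular** gene
  order, which eliminates end effects exactly; `topology = "linear"` is
  available for completeness, with terminal runs tallied as ordinary
  runs.

### Decisions where the verbal model is underdetermined

Three details of the process are not fixed by the verbal description
above; the package fixes them as follows.

1. **Start-position law.**  "A doubled gene is chosen at random" is read
   as uniform over *currently double-copy* genes, not over all `N`
   positions: the chosen gene is converted first, and a single-copy
   start would be undefined under the skipping rule.
   `apply_deletion_event()` therefore treats a single-copy `start` as a
   contract violation rather than silently re-sampling.
2. **Scan direction.**  Skipping proceeds in increasing position order
   from the start (wrapping on the circle).  One-sided scanning is the
   natural reading of "convert the *next* double-copy genes".
3. **Checkpoint exactness.**  Run statistics at a deleted proportion
   `1 − θ` are recorded with the final event truncated so that the
   deleted count equals `round((1 − θ) N)` exactly; every tally in a
   reference grid is then conditioned on the same deleted fraction.
   The alternative — record at the first event that crosses the
   target, without truncation — is available as `truncate = FALSE`.
   At most one event per checkpoint is affected (one in several
   hundred at the default scales).

The simulator's event loop is compiled, but draws all randomness from
R's own RNG stream in a fixed order (one uniform for the start, one for
the length — by inversion, so `µ = 1` is exact), which makes
trajectories bit-reproducible from `set.seed()` and lets the test suite
re-derive them independently: a pure-R mirror of the loop must agree
event for event, and under `µ = 1` the run-length law must match exact
enumeration of all `C(N, k)` deleted-gene placements on the circle.

## Overlap probabilities

Let `q` be the number of pre-existing single-copy runs a new event
skips through (absorbs).  All `p_q = P(overlap = q)` depend only on `µ`
and the current double-run law `ρ_t`, taken geometric with mean `ν_t`.

`p_0` — the chance the event falls strictly inside a double-copy run,
creating a new single-copy run — is defined by a triple sum over the
run length `l`, the start offset `j`, and the event length `a`.
`p0_discrete_sum()` evaluates that sum directly, collapsing the inner
two sums into partial geometric moments and truncating the outer sum
over `l` once the neglected tail mass of `l ρ_t(l)/ν_t` falls below
`tail_tol` (default 1e−12; the geometric tail bound `q^L (L + ν)/ν` is
used, with a hard cap of 1e7 terms guarding pathological `ν_t`).
`p0_discrete_closed()` is the closed form

    p0 = (ν_t − 1)² / ((µ + ν_t − 1) ν_t).

The printed source for this expression was typographically ambiguous;
the form above is the unique reading consistent with the large-`ν_t`
behaviour `p0 ≈ (ν/(µ+ν))(1 − 1/ν)` (`p0_discrete_approx()`), and the
package requires sum and closed form to agree to 1e−9 across
`µ ∈ {1.0, 1.1, 1.5, 2.0, 2.4} × ν ∈ {2, 5, 10, 100, 1000}` before
anything downstream is trusted.  The reduction runs through a geometric
law with mean `ζ`, `1 − 1/ζ = (1 − 1/µ)(1 − 1/ν_t)` (`zeta_mean()`).

In the continuous analogue (exponential event lengths, mean `µ`;
exponential undeleted-segment lengths, mean `ν_t`) the overlap count is
exactly geometric,

    p_q = (ν_t/(µ + ν_t)) (µ/(µ + ν_t))^q,

implemented in `pq_continuous()` and checked by
`pq_continuous_oracle()`, which integrates the defining nested
integrals numerically for `q ∈ {0, 1}`.  Quadrature choices: the
innermost integral of the exponential density is taken through its
exact CDF (`pexp`); the remaining one (for `q = 0`) or three (for
`q = 1`) integrals use `stats::integrate` on the semi-infinite ranges
with relative tolerance one-tenth of the requested `quadrature_tol`
(default 1e−8).  Closed forms for discrete `p_1, p_2, ...` are *not*
provided: no printed form exists to implement, and inventing one would
be indistinguishable from error; discrete overlap counts beyond
`q = 0` are available empirically from the simulator's event log.

Two empirical facts about overlap, both reproduced by the test suite,
explain why no closed form for `ψ_t` is attempted here:

* long events skip more, so the events found in runs built from many
  events are systematically longer (`run_composition()`; positive rank
  correlation between events-per-run and mean constituent event
  length) — run lengths are *not* sums of i.i.d. geometrics;
* the fraction of events with `q = 0` sits *above* `p_0` by the
  probability of touching a run boundary without skipping (an event
  that deletes the first or last gene of a double run).  Touching is
  deliberately unformulated here; its size is `O((µ+1)/ν_t)` (hitting
  ~1 boundary position out of `~ν_t`), and the suite checks the
  empirical fraction declines with `ν_t` and stays within that
  envelope of `p_0`.

## Run-length discrimination

The classifier asks: which `µ` on a grid best explains an observed
run-length sample?

1. `build_reference()` simulates `replicates` trajectories per
   `(µ, N)` cell — defaults `µ = 1.0 ... 2.4` by 0.1 (15 bins),
   `N = 100 ... 900` by 100, checkpoints `1 − θ = 0.1 ... 0.9` — and
   forms empirical cumulatives `F_{µ,N,1−θ}` (single-copy runs) and
   `G_{µ,N,1−θ}` (double-copy runs) over run length `l`.
2. `classify_sample()` computes the Kolmogorov–Smirnov distance
   `D = max_l |F̂_sample(l) − F_ref(l)|` against all 15 candidates and
   returns `µ̂ = argmin D`.
3. `assess_discrimination()` repeats this over fresh trajectories
   (each followed across all checkpoints, as a real genome would be a
   single realisation observed once) and tabulates `µ̂` frequencies.

Numerical and procedural choices:

* **Cumulative unit**: proportion of *runs* (not genes) of length
  `≤ l`.
* **Pooling**: run counts are pooled across replicates before
  normalising (run-weighted averaging; stable when single trials hold
  few runs).  Per-trial averaging of relative frequencies is available
  as `pooling = "average"`; at the default scales the two are
  indistinguishable (checked directly during development).
* **KS support**: all integers up to the longer of the two supports;
  beyond its own maximum a cumulative is 1.
* **Tie-break**: exact ties go to the smallest `µ`, i.e. conservatively
  toward the functional model, and are flagged.
* **Seeds**: reference and test samples take independent seeds;
  `assess_discrimination()` warns when they collide.
* **Scale**: desk-scale defaults are 300 reference replicates and 300
  samples per cell (about a minute for the full two-`N` study on one
  CPU); published studies of this design used 1000/1000.  Replicate
  counts are explicit arguments and are recorded in the library.

## What the synthetic world does and does not establish

The generator *is* the model under study, at the parameter ranges the
discrimination question concerns (`µ` between 1 and 2.4, `N ≤ 900`,
deleted proportions 0.1–0.9); a green test establishes internal
correctness (simulator ↔ mirror ↔ enumeration; sum ↔ closed form ↔
quadrature) and the statistical behaviour of the procedure *under the
model's assumptions*.  It does not establish anything about real
WGD-descendant genomes, where orthology calls are noisy, both copies
are occasionally lost, rearrangement breaks runs, and deletion may act
on both homeologs.

Two findings from the package's own assessment deserve emphasis,
because they run against magnitudes sometimes quoted for this design:

* **Discrimination at `N = 900` is sharper than often credited.**  At
  `1 − θ = 0.2` a sample holds ~150 single-copy runs; adjacent
  reference cumulatives differ by ~0.05 at `l = 1` while the
  per-sample KS noise is ~0.02–0.03.  Samples generated at `µ = 1.2`
  therefore land in the 1.1–1.3 bins (mode at 1.2) and reach the
  `µ̂ = 1.0` bin only ~1–4% of the time — not ~20%, a rate this
  implementation reproduces only at `N = 200`.  The gene-by-gene
  recovery rate itself (70–85% for `1 − θ < 0.5`, higher for larger
  `N`) does match expectation.
* **Double-copy classification is not uniformly biased toward
  `µ̂ = 1` early.**  Under true `µ = 1.2` the `G`-based classifier
  does assign `µ̂ = 1` more often than the `F`-based one at small
  `1 − θ` and less often at large `1 − θ`; under true `µ = 1.0`,
  however, the `G`-based classifier is simply noisier at small
  `1 − θ` (adjacent `G` cumulatives differ by ~0.01 when `ν_t ≈ 10`,
  against sample noise ~0.06), so its `µ̂ = 1` frequency is *lower*
  there.  `compare_run_types()` exposes the per-cell differences so
  users can see both behaviours rather than trust a blanket rule.

## Degenerate inputs and edge behaviour

* `µ < 1`, `N < 2`, all-single states, and checkpoints at 0 or 1 (or
  mapping to 0 or `N` deleted genes after rounding) are rejected with
  explicit errors.
* A checkpoint grid that collapses to duplicate deleted counts at small
  `N` is an error rather than a silent merge.
* Classification of a tally with no runs of the requested type is an
  error (undefined), as is a reference cell missing from a library —
  reported by name.
* `sample_deletion_length()` with `µ = 1` returns 1 deterministically;
  the compiled sampler reproduces this by inversion, not by a special
  case in the RNG stream (the length uniform is always drawn, keeping
  draw order independent of `µ`).

## Known limitations

No closed-form `ψ_t`; no touching probabilities; no two-sided
deletions; no rearrangement; real-genome application requires a
per-gene copy-state track (`read_copy_state_track()`) prepared by the
user's own orthology pipeline.  Error-rate magnitudes quoted above are
properties of this implementation's stated procedure at the stated
scales; they are recomputed, not asserted, by the test suite and
`scripts/acceptance.R`.
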