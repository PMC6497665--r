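---
title: "Scoring dyadic encounters: the five behaviour indices and the MBI cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dyadic encounters: the five behaviour indices and the MBI cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoindex)
```

## The assay and its data

Standardised one-on-one encounter assays place two ant workers in a small
neutral arena and score the behaviour of each worker once per second on an
ordinal scale running from the most peaceful to the most aggressive
behaviour. `ethoindex` uses the adapted scale

| score | behaviour |
|------:|-----------|
| +5 | killing (absorbing: observation stops, remaining time is killing) |
| +4 | fighting with gaster flexion |
| +3 | fighting without gaster flexion |
| +2 | mandible threatening |
| +1 | avoiding |
|  0 | ignoring |
| -1 | being next to each other without touching |
| -2 | antennation |
| -3 | allogrooming |
| -4 | trophallaxis |

so that positive values mean aggression and negative values peace. A scored
encounter lasts `t_obs = 170` s per worker; the package assumes the
acclimatisation window at the start of an assay was already removed
upstream, and seconds are 1-based. Data coded on the older 0..7 scale are
mapped onto this one by `ds3_scale()` (0→0, 1→-1, 2→-2, 3→-3, 4→+1, 5→+2,
6→+3, 7→+4; the old scale collapses allogrooming and trophallaxis, so -4 is
unreachable from it).

Because every index below depends only on how long each score was displayed,
not on the order of behaviours, the package reduces each worker's series to
a *duration profile* (`to_profile()`): a map score → total seconds. Killing
order does matter, but it is folded into the profile by the absorbing-state
rule before reduction.

## The five indices

For one worker profile with duration $t_i$ at score $s_i$:

* **AI** (Aggression Index), `ai()`: the duration-weighted mean score over
  seconds of tactile interaction,
  $AI = \sum_i s_i t_i \,/\, T$ with $T = \sum_{s_i \neq 0} t_i$.
  Ignoring (score 0) is not an interaction and is excluded from numerator
  and denominator; every other behaviour — including avoiding (+1), sitting
  next to each other (-1) and killing seconds — is included. This
  denominator convention is what makes a pure-aggression scenario average to
  the mean allowed score (2.5 for scores 1..4) and an ignoring+aggression
  scenario stay there rather than being dragged toward 0; both behaviours of
  the published simulation means are reproduced only under this convention.
  An encounter consisting entirely of ignoring has no defined AI; the
  package reports `NA` (never 0) and drops such encounters from means,
  counting them in `n_ai_missing`.
* **MMAI / MMPI**, `mmai()` / `mmpi()`: the highest, respectively lowest,
  score displayed for at least one second. "Mean" in their names refers to
  the later averaging over workers and replicates. MMAI can be negative
  (purely peaceful encounter), MMPI positive (purely aggressive one).
* **MBI aggressive / peaceful**, `mbi()`: the Mean Behaviour Index buffers
  the two extreme-value indices against episodic behaviour with a time
  threshold $t$ (seconds). Per encounter: if a kill occurred the MBI is 5.
  Otherwise, with $d_{agg}$ = total seconds at score > 0 and $d_{pcf}$ =
  total seconds at score < 0: aggression dominating
  ($d_{agg} > t \ge d_{pcf}$) gives the encounter maximum; peace dominating
  ($d_{pcf} > t \ge d_{agg}$) gives the encounter minimum; neither
  exceeding $t$ gives 0; both exceeding $t$ gives the midrange
  (max+min)/2. All comparisons are strict, exactly as the cascade is
  defined; with $t$ equal to the encounter length every kill-free encounter
  is neutral, and at $t = 0$ a single non-ignoring second decides the
  branch. Aggression and peace cannot cancel each other here, unlike in the
  AI.

Indices are computed per worker, averaged with equal weight over the (1 or
2) workers of an encounter, and then averaged over the replicate encounters
of a colony pairing (`pairing_means()`); in a balanced design this equals
the pooled mean. The package rejects encounters with more than two workers.

## Choosing the MBI thresholds

`MBI_agg` and `MBI_pcf` are the cascade evaluated at two thresholds chosen
empirically per data set, on internest encounters only: scan every integer
$t$ from 0 to `t_obs` (`threshold_scan()`), count the encounters whose MBI
classifies aggressive (> 0) resp. peaceful (< 0), and take the lowest $t$
at which each count attains its maximum (`threshold_select()`). This is a
plain first-argmax — no smoothing or formal inflection-point estimation —
and ties therefore resolve toward smaller $t$ by construction. The counts
need not be monotone in $t$. Classification happens at the encounter level
(after worker averaging, before replicate averaging), matching a count of
*encounters*. When a class never occurs (e.g. no aggressive encounter in a
purely peaceful data set) the maximum count is 0 for every $t$; the package
returns the convention $t = 0$ with a warning. Downstream values are
insensitive to this choice in exactly those situations: when no aggressive
second exists, every $t \le t_{obs} - 1$ yields the same MBI.

The central entry point `index_analysis()` performs this estimation (unless
fixed thresholds are supplied), computes both index tables, and returns a
fitted-analysis object with `print`, `summary`, `coef` (the two
thresholds) and `plot` (scan curve and index distributions) methods.

## The encounter simulator

`simulate_dataset()` generates encounters under eight scenarios that allow
different slices of the scale: P (-4..-1), P+I (-4..0), P+I+A (-4..4),
P+I+A+K (-4..5), I+A (0..4), I+A+K (0..5), A (1..4), A+K (1..5). One batch
is 10,000 *averaged encounters*, each the index-mean of 5 independent
single-worker encounters of 170 s — averaging index values, not profiles,
exactly as for observed replicates. Per encounter, behaviours are drawn
uniformly *without replacement* from the allowed set; each drawn behaviour
receives a random duration; drawing stops when (i) all seconds are
assigned (later behaviours get 0 s), (ii) a single behaviour remains (it
receives the remainder), or (iii) killing is drawn, which immediately
absorbs all remaining seconds.

The duration draw itself is under-determined by the verbal description
("between one and 170 seconds" even when fewer seconds remain), so the
package exposes two rules behind `rule=`:

* `"remaining"` (default): duration ~ U{1, ..., remaining seconds};
* `"capped"`: duration ~ U{1, ..., 170}, truncated to the remaining budget.

The default was fixed once by calibration against the published simulation
grand means: under `"remaining"` the scenario-A batch averages
MMAI ≈ 3.94 / AI ≈ 2.50 / MMPI ≈ 1.05 and the symmetric-scale batch
averages ±3.34 for the extremes (published: 3.92 / 2.50 / 1.08 and ±3.35),
whereas `"capped"` concentrates too much time in the first draw and misses
the extreme-value means by ≈ 0.35. AI means are insensitive to the rule:
scores are drawn exchangeably, so a scenario without score 0 has
E[AI] equal to the mean allowed score under *any* duration rule that
ignores score values — a useful generator-robust check.

Simulated encounters use one virtual worker (indices are worker means
anyway) and are all labelled internest: the simulations make no
intranest/internest distinction, and labelling them internest lets the
threshold scan consume them directly. A single RNG stream with an explicit
seed makes batches reproducible.

What the generator emulates is the *composition* of encounters — which
behaviours occur and for how long, including killing absorption — under a
neutral, species-free null. What it does not emulate: temporal bout
structure within an encounter (beyond killing), behavioural correlation
between the two real workers, between replicates of a pairing, or across
assay days, and any species-specific behaviour frequencies. Tests passing
on simulated batches therefore validate the index arithmetic and the
threshold machinery, not biological realism.

A note on extreme scenarios: in a pure-aggression batch nearly every
encounter keeps $d_{agg} > t$ for all practical $t$, so the cascade returns
the encounter maximum and the MBI mean tracks the MMAI mean (≈ 3.9), not
the AI mean. The published table lists 2.50 for those MBI cells, which the
verbatim cascade cannot produce for any $t < 170$; the package implements
the cascade as defined and does not treat those cells as targets.

## Numerical and interface choices

* Strict (`>`) comparisons throughout the cascade; exactly-0 index values
  classify as neutral and count toward neither curve.
* The near-tie statistic `near_tie_fraction()` uses a strict
  `|d_agg - d_pcf| < 10` s window by default — the width used when
  reporting how often aggressive and peaceful time nearly cancel in AI.
* Killing seconds count as aggressive time and enter the AI numerator and
  denominator; a killed encounter has MMAI 5.
* Non-absorbing killing in input files is an error naming the offending
  row, not a silent repair; `repair_kill = TRUE` opts into forward-filling.
* Typographic minus signs (U+2212, U+2013) in CSV score columns are
  normalised to ASCII on input; output is always ASCII.
* Statistical comparisons (`compare_indices()`) are nonparametric
  throughout: Spearman rank correlation between pairing-level index values
  and two-sided Wilcoxon–Mann–Whitney tests of the mean differences, exact
  for small tie-free samples and tie-corrected normal approximation
  otherwise, with Bonferroni–Holm correction within each 10-pair block.
  Mixed-effects modelling of nest or day effects is deliberately out of
  scope — it is off-the-shelf machinery orthogonal to the indices — so the
  report states rank correlations rather than mixed-model p-values.

## Problem sizes

The test suite validates the cascade by exhaustive enumeration (all
profiles over scores {-1, 0, 1} up to 12 s at every threshold), threshold
selection against a brute-force double loop on 200 random small data sets,
and the simulator at the full study size of 10,000 × 5 × 170 s per
scenario, which takes a few seconds per batch. Interactive examples in this
vignette and the README use smaller batches purely for display.

```{r example}
fit <- index_analysis(simulate_dataset("P+I+A", n_averaged = 50, seed = 1))
summary(fit)
```

## Limitations

* Only 1 or 2 workers per encounter are supported; unbalanced worker counts
  are treated as data errors.
* The index report drops all within-encounter sequence information except
  killing; analyses of bout order need the raw series.
* Threshold estimation needs internest encounters; purely intranest data
  must supply fixed thresholds.
* Published per-data-set threshold values cannot be used for validation
  (their printed form is ambiguous), so the selection rule is validated
  synthetically instead.
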