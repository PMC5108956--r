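---
title: "Methods: need probabilities, forgetting curves, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: need probabilities, forgetting curves, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactmem)
```

## The model

`contactmem` treats social memory as an information-retrieval problem: when
an animal meets a group mate it must retrieve what it knows about that
partner, so the useful quantity is the **need probability** — the probability
that a given dyad will be in contact on the next observation day. The package
estimates that probability from the environment in two complementary ways and
then asks which functional law describes it:

* as a function of **frequency**: the count `n` of contact days in a
  15-day history, modelled linearly, `P = a + b·n`;
* as a function of **recency**: the number of days `t` since the last
  contact, modelled by a power law `P = c·t^−d` or an exponential
  `P = c·e^−dt`.

On the memory side, retention accuracy in delayed matching-to-sample (DMTS)
tasks is fitted with the same two decay families, and the ACT-R base-level
equation `A = ln Σ_k t_k^−d = ln(p/(1−p))` links an encounter history
directly to a retrieval probability. The scientific claim the pipeline is
built to examine is a structural match: if contact recency decays as a power
law, a rationally tuned memory should too.

## Scoring contact, no-contact and missing

The raw record is scan sampling: at fixed intervals an observer lists every
individual present in the followed party. For a dyad on a day:

* **contact** — the pair appears together in at least one scan;
* **no contact** — the pair never appears together *and* at least one member
  was recorded in at least 70% of that day's scans, so an encounter would
  almost certainly have been seen;
* **missing** — otherwise, and always when the day falls outside either
  member's community-membership interval (membership masking overrides
  everything else).

Three scoring choices deserve comment because the field protocol
underdetermines them:

* "Observed for at least 70% of the day" is operationalised as the fraction
  of the day's scans containing the individual. Scans occur at fixed
  (15-minute) intervals, so the scan fraction is the natural proxy for the
  time fraction; the threshold is a parameter (`threshold`, default 0.70).
* Membership is a single `[first_day, last_day]` interval per individual;
  emigration-and-return cycles are out of scope.
* Days with no scans at all are missing for every dyad, and day indices are
  dense 1-based integers — calendar dates are labels, not structure.

Missing is a first-class third state: it is never conflated with no-contact
in any downstream count, and `summarize_matrix()` accounts for every cell as
either complete or missing.

## Windows, recency runs, and what "one missing value" means

Frequency windows slide one day at a time along each dyad's row. A window of
16 consecutive matrix columns is usable when (i) at most one of its 16 cells
is missing and (ii) the final cell — the outcome — is observed; together
these place the tolerated missing day strictly in the 15-day history. The
frequency is the raw count of observed contact days in the history (no
rescaling for the missing day, since the quantity of interest is a count).
Two further interpretation choices: windows are defined over consecutive
*matrix columns* (observation days), and bins pool raw success/trial counts
across all dyads rather than averaging per-dyad proportions — pooled counts
are what a binomial confidence interval and a binomial likelihood require.

Recency events are anchored at the last *observed* contact: for an observed
day `D`, the unique candidate lag is the distance `t` to the nearest prior
contact day, and the event is emitted when the strictly intervening days are
all no-contact apart from at most one missing day and `t ≤ 15`. A missing
day can never anchor an event, and each `(dyad, day)` contributes at most one
event, so recency bins partition the observed outcome days. Both
enumerations are validated cell-for-cell against brute-force oracles in the
test suite.

Binomial proportions carry **Wilson score intervals** (default 95%), chosen
over the Wald interval because tail recency bins can hold few trials and
proportions near 0 or 1, where Wilson keeps honest coverage.

## Likelihood, AICc, and the two granularities

Curve fitting maximises a binomial likelihood on the binned data over
`(c, d)` with `c ∈ (0, 1]`, `d ∈ [0, 10]`, using bounded quasi-Newton
(`L-BFGS-B`) from a deterministic 3 × 3 grid of starts
(`c ∈ {0.2, 0.5, 0.8}`, `d ∈ {0.1, 0.5, 1.5}`); no randomness enters the
optimiser, so refits are bit-reproducible. Predictions are clipped to
`[1e−9, 1 − 1e−9]` inside the likelihood only — reported parameters and
predictions are unclipped.

Two likelihood granularities are exposed:

* `"bin"` — each bin contributes a single cross-entropy term at its observed
  proportion. Every bin counts equally, and the AICc sample size is the
  number of bins.
* `"event"` — each bin contributes its full binomial log-pmf for
  `successes/trials`, so bins are weighted by the data they contain, and the
  AICc sample size is the total trial count.

The analysis scripts and acceptance checks use `"event"`: it is the
statistically standard likelihood when trial counts are known, it is
invariant (up to data-only constants) to how bins are split, and it yields
AICc values on the customary scale for this literature. The `"bin"` variant
is retained as the function default for continuity with curve-fitting on
pre-averaged proportions, where trial counts are unavailable.

Model comparison uses `AICc = 2·NLL + 2k + 2k(k+1)/(n−k−1)` (undefined and
rejected when `n ≤ k + 1`), Akaike weights `w_i ∝ exp(−Δ_i/2)`, and the
evidence ratio `exp(ΔAICc/2)`. Fits carry a fingerprint of the data and
granularity they were computed on, and `compare_fits()` refuses to compare
fits with different fingerprints.

## Retention

DMTS observations (`delay`, `correct`, `trials`) flow through exactly the
same machinery by mapping delays to bins; `fit_retention()` is a thin
delegation to `fit_curve_mle()`, and pooling across studies merges identical
delays by summing counts. Two-alternative DMTS has a 0.5 guessing floor; the
default fit is nevertheless the raw `P = c·t^−d`, matching standard practice
for these comparisons, with an optional `floor` argument
(`P = f + (c − f)·t^−d`) for sensitivity analyses.

## What the generators emulate — and what they do not

The synthetic-data module defines the package's study conditions; its
defaults were chosen once, on field realism, and are not tuned.

* `simulate_fission_fusion()`: a community (default 45 individuals — a
  mid-sized chimpanzee community — over 250 days) whose subgroups evolve by
  individual switches, binomial splits, and pairwise merges, in that fixed
  within-day order (a documented constant; defaults
  `p_split = p_merge = 0.25`, `p_switch = 0.05`, 6 initial subgroups).
  Contact is same-subgroup co-membership.
* `simulate_hazard_contacts()`: independent dyads following a semi-Markov
  renewal process — the daily contact probability depends only on the time
  since the last contact, `min(1, c·t^−d)` (or `c·e^−dt`). This is the
  minimal process with the recency structure the estimators target. The
  reference regime is `c = 0.55`, `d = 0.4`, 500 dyads × 1000 days. A
  50-day burn-in removes the synchronized start for the (recurrent) power
  hazard. The exponential hazard is *transient* — `Σ_t c·e^−dt` converges,
  so every dyad eventually falls out of contact forever; exponential runs
  therefore keep the day-0 contact (`burn_in = 0`) and their information is
  concentrated in the early spells. That transience is itself the
  substantive contrast: a power-law environment keeps old partners relevant,
  an exponential one does not.
* `simulate_scan_samples()`: one followed subgroup per day (the largest, ties
  to the lowest label), 28 scans/day (15-minute scans across a ~7-hour
  follow), per-member detection probability 0.9. Observer-scored contacts
  are provably a subset of true co-membership days.
* `inject_missingness()`: whole-day masking (default 0.30) plus independent
  cell masking (default 0.857), giving an expected missing fraction of
  `0.30 + 0.70 × 0.857 ≈ 0.90` — the sparsity of multi-year party-level
  follow data.
* `simulate_dmts()`: binomial accuracy around a power forgetting curve,
  default 8 delays spanning 2–256 s, 200 trials per delay, `c = 0.95`,
  `d = 0.12` — the scale of pooled chimpanzee DMTS experiments.

Every generator takes a `seed` and is a pure function of its configuration:
identical seeds give identical outputs, byte-for-byte on disk.

Real field data differ from these generators in ways that bound what passing
tests demonstrate: no demography (births, deaths, immigration) beyond static
membership intervals, no seasonal or ranging structure, no sex/age
association preferences, dyads in the hazard model are mutually independent
(real subgroup co-membership correlates dyads), and observer effort is
uniform rather than biased toward gregarious individuals. Validation on
synthetic data shows the estimators are correct and well-calibrated under
the assumed structure; it does not by itself establish the empirical result
on any field dataset.

## Problem sizes and numerical checks

The test suite validates, among other things: enumeration equivalence with
brute-force oracles on 200 random ternary matrices (up to 10 dyads × 60
days); Wilson intervals against the closed form to 1e−9; AICc and
evidence-ratio formulas against direct arithmetic; parameter recovery and
family selection over 20 seeded replicates per family of the reference
500-dyad × 1000-day hazard regime (median relative error on `c` and `d`
within 5%, correct family selected in ≥ 19/20); flat-curve calibration under
memoryless (i.i.d. Bernoulli) contact, where ≥ 90% of bin intervals must
cover the generating probability; and power-vs-exponential selection on 100
seeded DMTS replicates. These sizes were chosen to give the property checks
sharp statistical power while keeping a full run comfortably
interactive.

Degenerate inputs are rejected loudly rather than silently repaired: zero
trials for an interval, fewer than three distinct bins for a two-parameter
fit, `t = 0` under a power curve, AICc at `n ≤ k + 1`, empty encounter
histories, and comparisons across mismatched data all raise errors.

## Known limitations

* Reproducing the archived 143-chimpanzee analyses requires the deposited
  matrix file; the package ships only its reader and the surrounding
  pipeline, and the corresponding checks fail visibly when the file is
  absent.
* Pooled binning ignores dyad heterogeneity; there are no per-dyad random
  effects, and no bootstrap uncertainty on fitted curve parameters.
* Only the base-level ACT-R equation is implemented — no activation noise,
  spreading activation, or latency mapping.
* The moving-window estimator treats consecutive matrix columns as
  consecutive days; if observation days are calendar-sparse, recency lags
  are in observation-day units.
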