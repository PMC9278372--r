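---
title: "Generalized cost-effectiveness analysis: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized cost-effectiveness analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcea)
```

## The model

Generalized cost-effectiveness analysis (GCEA) evaluates every intervention
scenario against a common *null* — the counterfactual in which none of the
interventions is delivered, the point (0, 0) on the cost-effectiveness
plane. Because all scenarios share one comparator, ratios are comparable
across disease programmes and packages can be assembled across the whole
health sector rather than within one programme at a time.

Each scenario is summarised by two numbers: its present-value cost over the
analytic horizon, in 2010 international dollars (I$), and the healthy life
years (HLYs) it gains versus the null. Costs and health are discounted
differentially: the headline convention is 3% per year on costs and 0% on
health effects over a 100-year horizon (`discount_spec()`), with the
health-effect rate configurable because symmetric 3%/3% variants are also in
use. Two ratios drive everything:

* **ACER** (average cost-effectiveness ratio): `cost / hly` against the
  null, the ranking statistic for league tables.
* **ICER** (incremental cost-effectiveness ratio):
  `(cost2 - cost1) / (hly2 - hly1)` between two package points, the ranking
  statistic along an expansion path.

### Combining scenarios

Costs and benefits are assumed additive *across* disease programmes.
*Within* a programme they generally are not: a scenario added after another
in the same programme gains less health (part of the burden is already
averted) and costs less (shared delivery infrastructure). When explicit
joint cost/benefit records exist for a co-implemented subset they are used
directly; otherwise `combine_within_programme()` applies a sequential
overlap model in ascending ACER order, with the k-th scenario contributing
`hly_k (1 - beta)^(k-1)` health and `cost_k (1 - gamma)^(k-1)` cost. Every
programme also carries a fixed support cost — planning, supervision,
surveillance — which enters once whenever any of its scenarios is
delivered. We treat this support cost as a present value entering once per
programme per package (not re-discounted, not annualised separately),
because delivering *any* part of a programme requires supporting the whole
programme.

There are no established empirical magnitudes for `beta` (benefit overlap)
and `gamma` (cost synergy); the generator defaults of 0.2 and 0.1 are
placeholders for exercising the machinery, and analyses of real data should
set them (or better, supply explicit combination records) from local
evidence. With `beta = gamma = 0` and zero support costs the combination
rules collapse to plain addition.

## The expansion path

`build_expansion_path()` implements the greedy construction: adopt the
scenario with the lowest ACER first, then repeatedly evaluate every
remaining candidate as an addition to the current package — combination
rules within programmes, additive across, a higher coverage rung replacing
the currently adopted rung of its ladder — and adopt the candidate with the
lowest ICER against the current point. Construction stops when no candidate
adds health. Three bookkeeping rules shape the result:

* **Strict dominance** (`strict_dominance = TRUE`, the default): after each
  adoption, any remaining candidate offering no more health for no less
  cost than the adopted step (one comparison strict) is permanently
  excluded — dominated interventions cannot enter the package. Their
  would-be ICERs are retained in the `excluded` table because near-ties may
  still be perfectly reasonable real-world choices even though the
  mathematically optimized path drops them.
* **Coverage supersession**: lower rungs of an adopted ladder that can no
  longer add health are recorded as `superseded_coverage`.
* **Extended dominance** (`extended_dominance = TRUE`): if a new step's
  ICER undercuts the previous step's, the previous step is spliced out
  (`extended_dominated`) and the new step's increment is recomputed against
  the earlier point, keeping the ICER sequence non-decreasing — the
  standard frontier cleanup.

### The two dominance modes, and what is provable

The default mode mirrors the published procedure, where dominated options
are removed as the path grows. The alternative `strict_dominance = FALSE`
(*frontier mode*) never permanently excludes a still-beneficial candidate.
The two modes answer slightly different questions. A pairwise-dominated
scenario is a bad *alternative* to its dominator, but in an additive world
it can still be a worthwhile *addition* once everything better has been
adopted; frontier mode keeps it available and therefore traces the complete
efficiency frontier, while the default mode reproduces the stricter
published reading in which such options are off the table.

In the additive limit (`beta = gamma = 0`, zero support costs), frontier
mode provably traces the lower convex hull of all feasible package points:
candidate increments are static, the minimum-slope move from a hull vertex
is the next hull edge, and allowing direct jumps to any higher ladder rung
covers non-convex ladders. The same argument shows extended dominance never
fires in that limit. The test suite enforces both facts against
`oracle_frontier()`, an exhaustive enumerator (independent down to its own
inline combination arithmetic) that evaluates every feasible selection and
returns the hull: frontier mode must match the hull of all selections, and
the default mode must match the hull of the pairwise-dominance-filtered
scenario set, each exactly, over 100 random instances per run.

### Numerical choices and degenerate inputs

* Discounting uses start-of-year timing (the first year is undiscounted);
  the convention matters for reproducibility and is fixed package-wide.
* Ties in ICER comparisons within a relative `tie_epsilon` (default 1e-9)
  are broken by ascending scenario id, so paths are bitwise reproducible.
* Cost-saving candidates (positive health, non-positive incremental cost)
  are adopted before any ratio comparison, in descending health order: they
  belong in any rational package and would corrupt a ratio sort. With
  positive costs and `gamma = 0` they cannot arise mid-path; with cost
  synergies they can (an addition may cheapen enough co-programme
  scenarios to pay for itself), in which case the ICER sequence is
  non-decreasing within each run of ratio-ranked steps, with each
  cost-saving adoption resetting the baseline.
* Scenarios identical to the null (zero cost *and* zero health) are
  rejected at validation; zero-health scenarios are accepted as data but
  cannot be ranked (ACER undefined) and never enter a path.
* Under fixed support costs or overlap parameters, extended dominance can
  splice out a scenario that still carries positive net benefit; this is a
  known limitation of expressing the cleanup as single-scenario exclusion
  and is confined to non-additive configurations.

## League tables and banding

`build_league_table()` presents all rankable scenarios, not just the
optimized path: entries are stratified by delivery platform (population,
community, first-level clinical, referral — the last defined as everything
outside the primary-healthcare set), banded by order of magnitude of the
ACER, and de-duplicated so each coverage ladder or overlapping bundle
contributes only its lowest-ACER member. Band membership uses the
*unrounded* ACER on half-open intervals `[edge, 10*edge)`; this is why a
published table that rounds for display can print two "$100" entries in
adjacent bands, and why the packaged transcription of such a table keeps
the as-printed placement (`band_source = "as_printed"`) instead of silently
re-banding reference data. Each league entry's ACER includes its
programme's support cost, since a league row is a standalone comparison
with the null.

`package_summary()` totals a selection under the combination rules and
converts the present-value cost to a per-capita annual cost. The default
*equivalent annual cost* convention divides the PV by the annuity factor of
the cost rate over the horizon — the long-run yearly price of sustaining
the package — because "long run" is otherwise ambiguous; a `steady_state`
alternative (final-year undiscounted cost over population) is exposed for
comparison. `apply_budget_constraint()` walks a path accumulating
per-capita annual cost and keeps the largest affordable prefix; steps are
indivisible by default, with optional linear pro-rating of the first
unaffordable step.

## What the synthetic generator emulates — and what it does not

`generate_interventions()` produces datasets with the features the analysis
assumes: ACERs drawn log-uniformly over `[10^-0.5, 10^4.5]` I$/HLY so that
every order-of-magnitude band is populated (log-uniform rather than
lognormal precisely to cover the tails); lognormal PV costs
(`meanlog = log(1e8)`, `sdlog = 1.5`, spanning roughly 1e6-1e10 I$ —
plausible 100-year programme costs for a region of 1e8 people); coverage
ladders whose rung totals have geometrically decaying health increments
(ratio 0.5) against slower-decaying cost increments (ratio 0.8), giving
strictly rising incremental ICERs; and per-programme support costs at 10%
of mean scenario cost. Generation is deterministic given the seed, and a
truth record (true ACERs, ladder structure, overlap parameters) accompanies
every dataset for recovery tests.

The generator does *not* simulate disease natural history, intervention
effect sizes, epidemiological correlation between programmes, or costing
detail — it draws cost/HLY endpoints directly. Passing tests therefore
demonstrate that the *pipeline* (validation, combination, banding, path
construction, budget truncation, costing) is correct on data with the right
statistical shape; they say nothing about the realism of any particular
cost or effect estimate, which in real applications comes from
disease-specific models and local adaptation.

## Problem sizes used in the test suite

The suite validates frontier equivalence on 100 random instances of up to
12 scenarios per dominance mode (exhaustive enumeration is exponential, so
the oracle is capped there), path invariants on 1000 fuzzed instances with
random overlap parameters and ladder densities, and the ACER-spread
property on a single 10^4-scenario draw. These sizes give dense coverage of
the combinatorics while keeping the default test run fast; the algorithms
themselves have no such limits (the path construction is quadratic in the
number of scenarios).

## Known limitations

* The optimized path is greedy with local cleanup; under strong
  non-additivity (large `beta`/`gamma`, large fixed costs) it is a
  heuristic, not a guaranteed optimum — the provable-optimality statements
  hold in the additive limit.
* No uncertainty propagation: ratios are point estimates, and there are no
  stochastic league tables or acceptability curves.
* No age-weighting or time-varying discount rates.
* Budget truncation is a prefix rule on the optimized path, not a knapsack
  optimisation over arbitrary subsets.
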