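# gcea

Sector-wide **generalized cost-effectiveness analysis** (GCEA) for health
benefit package design.

Health ministries assembling a universal-health-coverage benefit package
face one pooled budget and hundreds of candidate interventions across
disease programmes. GCEA makes them comparable by measuring every
intervention scenario against the same *null* scenario (no intervention:
zero cost, zero benefit), summarising each as a present-value cost `C` (2010
international dollars, costs discounted at 3%/yr over a 100-year horizon)
and a health gain `E` in healthy life years (HLYs, undiscounted by
default). Two ratios organise the analysis:

* the **average cost-effectiveness ratio** `ACER = C / E` against the null,
  used to rank interventions in league tables banded by order of magnitude
  (`<$10`, `$10-$100`, `$101-$1000`, `$1001+` per HLY) and stratified by
  delivery platform (population, community, first-level clinical,
  referral);
* the **incremental cost-effectiveness ratio**
  `ICER = (C2 - C1) / (E2 - E1)` between package points, used to build the
  **expansion path**: starting from the null, repeatedly adopt the
  candidate with the lowest ICER against the current package — additive
  across programmes, overlap-adjusted within them, higher coverage rungs
  replacing lower ones — while excluding dominated options (less health for
  more cost) and splicing out extended-dominated steps so the ICER sequence
  is non-decreasing. The cumulative points of the path trace the efficiency
  frontier on the cost-effectiveness plane.

The package provides the full pipeline: CSV readers with validation,
discounting and ratio arithmetic, within/across-programme combination rules
(explicit joint records or a sequential overlap model, plus per-programme
fixed support costs), expansion-path construction with strict and extended
dominance, per-capita budget truncation, league tables, equivalent-annual
per-capita package costing, the standard figures (log-log isoquant scatter,
expansion path, platform comparison), a synthetic-data generator, and an
exhaustive-enumeration frontier oracle used to validate the path algorithm.
A transcription of a published Eastern sub-Saharan Africa league table
ships as reference data (`load_table1_fixture()`).

## Worked example

```r
library(gcea)

sim  <- generate_interventions(synth_config(n_programmes = 6, seed = 7))
sim$clusters
#> <cluster_set> 6 programme(s), 32 scenario(s)

path <- build_expansion_path(sim$clusters, path_config(beta = 0.2, gamma = 0.1))
path
#> <expansion_path> 6 step(s), 26 excluded
#>   first ACER 0.5441, final ICER 80.57, total (7.71e+08 I$, 979800000 HLY)
#>
#>  strictly_dominated superseded_coverage
#>                  25                   1

head(path$steps[, c("rank", "scenario_id", "delta_cost", "delta_hly", "icer")], 4)
#>   rank scenario_id delta_cost delta_hly      icer
#> 1    1     P006S01  311584644 572685116 0.5440767
#> 2    2     P006S02  232192844 332978832 0.6973201
#> 3    3     P006S05  130699771  51598576 2.5330112
#> 4    4   P003S04R2   66198316  19211229 3.4458137
```

The first adopted scenario is the one with the lowest ACER (I$0.54 per
HLY); each later step is the cheapest next addition per HLY, so the `icer`
column rises monotonically. 25 scenarios were excluded as strictly
dominated (their would-be ICERs are kept in `path$excluded`) and one
coverage rung was superseded by a higher rung of the same ladder.

Applying a per-capita budget and costing the result:

```r
cfg <- path_config(budget_per_capita = 1, region_population = 1e8,
                   beta = 0.2, gamma = 0.1)
apply_budget_constraint(build_expansion_path(sim$clusters, cfg), cfg)
#> <benefit_package> 5 scenario(s)
#>   total PV cost : 771,015,538 I$
#>   total HLY     : 979,842,578
#>   per capita    : 0.24 I$/person/year (population 1e+08)
```

The per-capita figure is the equivalent annual cost: the total present
value spread over the 100-year horizon with the 3% annuity factor, divided
by the population — the long-run yearly price of sustaining the package.

League tables rank everything, not just the optimized path:

```r
build_league_table(sim$clusters)
#> <league_table> 24 entries, 4 platform(s) [bands computed]
#>      platform band_label scenario_id     name       acer programme
#> 1  population       <$10     P006S01  P006S01  0.5440767      P006
#> 2  population       <$10     P003S02  P003S02  0.8577561      P003
#> ...
```

and `plot_isoquant()`, `plot_expansion()`, `plot_platform_stack()` draw the
three standard figures.

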