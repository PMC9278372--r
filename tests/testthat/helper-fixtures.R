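# Builders for small in-code fixtures used across the suite.

make_scenarios <- function(ids, cost, hly, programme,
                           platform = "community", group = NA_character_,
                           name = ids) {
  data.frame(id = ids, name = name, programme = programme,
             platform = platform, exclusivity_group = group,
             cost_pv = cost, hly = hly, population_in_need = NA_real_,
             stringsAsFactors = FALSE)
}

# three independent scenarios in three programmes: the canonical worked
# example (A cheapest, B next on the frontier, C dominated by A pairwise)
abc_clusters <- function() {
  as_cluster_set(make_scenarios(
    ids = c("A", "B", "C"), cost = c(100, 200, 150), hly = c(10, 15, 8),
    programme = c("p1", "p2", "p3")))
}

# a small random instance under additive conditions (no overlap, no fixed
# support costs), suitable for exhaustive enumeration
rand_instance <- function(seed, ladder_prob = 0.4) {
  cfg <- synth_config(n_programmes = 2 + seed %% 2,
                      scenarios_per_programme = c(1, 3),
                      coverage_ladder_prob = ladder_prob,
                      fixed_support_cost_fraction = 0,
                      beta = 0, gamma = 0, seed = seed)
  generate_interventions(cfg)$clusters
}

path_points <- function(path) {
  unname(as.matrix(path$steps[, c("cum_cost", "cum_hly")]))
}

frontier_points <- function(frontier) {
  unname(as.matrix(frontier[-1, c("cost", "hly")])) # drop the null
}

expect_same_points <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  expect_equal(a, b, tolerance = tol)
}

# TRUE when ICERs are non-decreasing within every maximal run of ratio-ranked
# steps; cost-saving adoptions (possible under cost synergies) are dominance
# moves, not ratio moves, and reset the ordering baseline
ratio_runs_monotone <- function(path, tol = 1e-9) {
  run <- cumsum(path$steps$cost_saving)
  ok <- TRUE
  for (r in unique(run)) {
    icers <- path$steps$icer[run == r & !path$steps$cost_saving]
    if (length(icers) > 1 &&
        any(diff(icers) < -tol * pmax(1, abs(icers[-1]))))
      ok <- FALSE
  }
  ok
}
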