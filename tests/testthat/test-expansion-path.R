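test_that("a single scenario yields a one-step path with ICER = ACER", {
  cl <- as_cluster_set(make_scenarios("s", 100, 10, "p"))
  path <- build_expansion_path(cl)
  expect_equal(nrow(path$steps), 1)
  expect_equal(path$steps$icer, 10)
  expect_equal(path$steps$cum_cost, 100)
  expect_equal(nrow(path$excluded), 0)
})

test_that("strict dominance excludes costlier, less effective candidates", {
  path <- build_expansion_path(abc_clusters(),
                               path_config(strict_dominance = TRUE))
  expect_equal(path$steps$scenario_id, c("A", "B"))
  expect_equal(path$steps$icer, c(10, 200 / 15))
  expect_equal(path$excluded$scenario_id, "C")
  expect_equal(path$excluded$reason, "strictly_dominated")
  # the excluded candidate keeps its would-be ICER for reporting
  expect_equal(path$excluded$would_be_icer, 150 / 8)
})

test_that("frontier mode adopts every beneficial scenario in hull order", {
  path <- build_expansion_path(abc_clusters(),
                               path_config(strict_dominance = FALSE))
  expect_equal(path$steps$scenario_id, c("A", "B", "C"))
  expect_equal(path$steps$icer, c(10, 200 / 15, 150 / 8))
  expect_true(all(diff(path$steps$icer) >= 0))
  expect_equal(path$steps$cum_cost[3], 450)
  expect_equal(path$steps$cum_hly[3], 33)
})

test_that("a cheaper higher coverage rung supersedes the lower rung", {
  sc <- make_scenarios(c("r1", "r2"), c(10, 12), c(1, 20), "p", group = "g")
  path <- build_expansion_path(as_cluster_set(sc))
  expect_equal(path$steps$scenario_id, "r2")
  expect_equal(path$excluded$scenario_id, "r1")
  expect_equal(path$excluded$reason, "superseded_coverage")
})

test_that("coverage upgrades appear as steps with incremental values", {
  sc <- make_scenarios(c("r1", "r2"), c(10, 30), c(10, 15), "p", group = "g")
  path <- build_expansion_path(as_cluster_set(sc))
  expect_equal(path$steps$scenario_id, c("r1", "r2"))
  expect_equal(path$steps$delta_cost, c(10, 20))
  expect_equal(path$steps$delta_hly, c(10, 5))
  expect_equal(path$steps$icer, c(1, 4))
  # the final package holds only the top rung, but totals telescope
  expect_setequal(path$adopted, "r2")
  expect_equal(path$steps$cum_cost[2], 30)
  expect_equal(path$steps$cum_hly[2], 15)
})

test_that("extended dominance splices out steeper earlier steps", {
  sc <- rbind(make_scenarios("X", 50, 1, "q0"),
              make_scenarios(c("a", "b"), c(1, 1), c(1, 1), "q1"))
  cl <- as_cluster_set(sc, fixed_support_costs = c(q1 = 100))
  path <- build_expansion_path(
    cl, path_config(strict_dominance = FALSE, extended_dominance = TRUE))
  # adopting b after a makes a's step (ICER 101 incl. support cost) look
  # steep next to b's (ICER 1); the cleanup resplices b against X directly
  expect_equal(path$steps$scenario_id, c("X", "b"))
  expect_equal(path$steps$icer, c(50, 101))
  expect_equal(path$excluded$scenario_id, "a")
  expect_equal(path$excluded$reason, "extended_dominated")
  expect_true(all(diff(path$steps$icer) >= 0))
})

test_that("cost-saving candidates are adopted before any ratio comparison", {
  sc <- make_scenarios(c("free", "paid"), c(0, 100), c(2, 50), "p")
  path <- build_expansion_path(as_cluster_set(sc))
  expect_equal(path$steps$scenario_id[1], "free")
  expect_true(path$steps$cost_saving[1])
  expect_false(path$steps$cost_saving[2])
})

test_that("a path needs at least one health-gaining scenario", {
  sc <- make_scenarios("dead", 10, 0, "p")
  expect_error(build_expansion_path(as_cluster_set(sc)), "gains health")
})

test_that("adding a strictly dominated scenario changes only the excluded set", {
  base <- make_scenarios(c("A", "B"), c(100, 200), c(10, 15), c("p1", "p2"))
  with_dom <- rbind(base, make_scenarios("C", 150, 8, "p3"))
  p1 <- build_expansion_path(as_cluster_set(base))
  p2 <- build_expansion_path(as_cluster_set(with_dom))
  expect_equal(p1$steps, p2$steps)
  expect_equal(p2$excluded$scenario_id, "C")
})

test_that("budget truncation keeps the largest affordable prefix", {
  sc <- make_scenarios(c("x", "y", "z"), c(1, 1.5, 3.5), c(10, 11, 12),
                       programme = c("q1", "q2", "q3"))
  cfg <- function(budget, partial = FALSE)
    path_config(budget_per_capita = budget, region_population = 1,
                allow_partial = partial,
                discount = discount_spec(cost_rate = 0, horizon = 1))
  path <- build_expansion_path(as_cluster_set(sc), cfg(3))
  # cumulative per-capita costs along the path: 1.0, 2.5, 6.0
  pkg <- apply_budget_constraint(path, cfg(3))
  expect_setequal(pkg$scenario_ids, c("x", "y"))
  expect_equal(pkg$total_cost, 2.5)

  full <- apply_budget_constraint(path, cfg(Inf))
  expect_setequal(full$scenario_ids, c("x", "y", "z"))

  expect_warning(empty <- apply_budget_constraint(path, cfg(0)),
                 "below the cost of the first step")
  expect_length(empty$scenario_ids, 0)
  expect_equal(empty$total_cost, 0)

  partial <- apply_budget_constraint(path, cfg(3, partial = TRUE))
  expect_setequal(partial$scenario_ids, c("x", "y", "z"))
  expect_equal(partial$total_cost, 3)
  expect_equal(partial$total_hly, 21 + 12 * (0.5 / 3.5))
})

test_that("a larger budget never yields a smaller package", {
  # without coverage ladders the packages are literally nested sets
  cl <- rand_instance(99, ladder_prob = 0)
  cfg <- function(budget)
    path_config(budget_per_capita = budget, region_population = 1e6)
  path <- build_expansion_path(cl, cfg(1))
  prev <- character(0)
  for (budget in c(0.01, 0.1, 1, 10, 100, 1e4, Inf)) {
    pkg <- suppressWarnings(apply_budget_constraint(path, cfg(budget)))
    expect_true(all(prev %in% pkg$scenario_ids),
                info = paste("budget", budget))
    prev <- pkg$scenario_ids
  }

  # with ladders a scenario may be replaced by a higher rung of its own
  # exclusivity group, but coverage never shrinks
  cl <- rand_instance(98, ladder_prob = 0.6)
  sc <- scenario_table(cl)
  path <- build_expansion_path(cl, cfg(1))
  prev <- character(0)
  for (budget in c(0.01, 0.1, 1, 10, 100, 1e4, Inf)) {
    pkg <- suppressWarnings(apply_budget_constraint(path, cfg(budget)))
    for (id in setdiff(prev, pkg$scenario_ids)) {
      g <- sc$exclusivity_group[match(id, sc$id)]
      expect_false(is.na(g))
      rungs <- sc$id[!is.na(sc$exclusivity_group) & sc$exclusivity_group == g]
      upgraded <- intersect(rungs, pkg$scenario_ids)
      expect_true(length(upgraded) == 1 &&
                    sc$hly[match(upgraded, sc$id)] >= sc$hly[match(id, sc$id)],
                  info = paste("budget", budget, "scenario", id))
    }
    prev <- pkg$scenario_ids
  }
})

test_that("paths satisfy accounting identities under fuzzing", {
  set.seed(202)
  for (i in 1:30) {
    cfg <- synth_config(
      n_programmes = sample(2:4, 1), scenarios_per_programme = c(1, 4),
      coverage_ladder_prob = runif(1, 0, 0.5),
      fixed_support_cost_fraction = runif(1, 0, 0.3),
      beta = runif(1, 0, 0.4), gamma = runif(1, 0, 0.3),
      seed = sample.int(1e6, 1))
    cl <- generate_interventions(cfg)$clusters
    path <- build_expansion_path(
      cl, path_config(beta = cfg$beta, gamma = cfg$gamma))
    all_ids <- c(path$steps$scenario_id, path$excluded$scenario_id)
    expect_setequal(all_ids, scenario_table(cl)$id)
    expect_false(anyDuplicated(all_ids) > 0)
    expect_equal(path$steps$cum_cost, cumsum(path$steps$delta_cost))
    expect_equal(path$steps$cum_hly, cumsum(path$steps$delta_hly))
    expect_true(ratio_runs_monotone(path))
  }
})
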