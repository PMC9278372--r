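test_that("present value follows start-of-year discounting", {
  expect_equal(present_value(rep(1, 5), rate = 0), 5)
  expect_equal(present_value(rep(0, 10), rate = 0.03), 0)
  expect_error(present_value(rep(1, 5), rate = -0.01), "non-negative")

  # closed-form annuity-due: sum_{t=0}^{99} 1.03^{-t}
  closed_form <- (1 - 1.03^(-100)) / 0.03 * 1.03
  expect_equal(present_value(rep(1, 100), rate = 0.03), closed_form,
               tolerance = 1e-12)
  expect_equal(annuity_factor(0.03, 100), closed_form, tolerance = 1e-12)
  expect_equal(annuity_factor(0, 100), 100)

  # PV is non-increasing in the rate for non-negative streams
  stream <- c(3, 0, 2, 5, 1, 1)
  pv <- vapply(seq(0, 0.2, by = 0.01), function(r) present_value(stream, r),
               numeric(1))
  expect_true(all(diff(pv) <= 0))
})

test_that("ACER is cost per HLY against the null and is scale-invariant", {
  expect_equal(acer(100, 10), 10)
  expect_equal(acer(0, 5), 0)
  expect_equal(acer(23, 100), 0.23)
  expect_error(acer(10, 0), "undefined")
  expect_error(acer(-1, 5), ">= 0")

  for (s in c(0.5, 2, 1000)) {
    expect_equal(acer(s * 37, s * 4.2), acer(37, 4.2))
  }
})

test_that("ICER handles the null reference, cost saving and dominance", {
  expect_equal(as.numeric(icer(100, 10, 200, 15)), 20)
  expect_equal(as.numeric(icer(0, 0, 100, 10)), acer(100, 10))
  cs <- icer(100, 10, 90, 12)
  expect_equal(as.numeric(cs), -5)
  expect_true(attr(cs, "cost_saving"))
  expect_false(attr(icer(100, 10, 200, 15), "cost_saving"))
  expect_error(icer(100, 10, 200, 10), class = "gcea_dominance_error")
  expect_error(icer(100, 10, 200, 8), class = "gcea_dominance_error")
})

test_that("within-programme combination applies joint data, overlap and fixed costs", {
  sc <- make_scenarios(c("a", "b"), c(100, 100), c(10, 6), "p")
  cl <- programme_cluster("p", sc, fixed_support_cost = 7)

  # singleton: own values plus the programme support cost
  pt <- combine_within_programme("a", cl)
  expect_equal(pt$cost, 107)
  expect_equal(pt$hly, 10)
  # empty selection is the null, with no support cost
  expect_equal(combine_within_programme(character(0), cl)$cost, 0)

  # additive limit: exact sums plus one fixed support cost
  pt <- combine_within_programme(c("a", "b"), cl)
  expect_equal(pt$cost, 207)
  expect_equal(pt$hly, 16)

  # explicit joint data overrides the model
  cl2 <- programme_cluster("p", sc,
                           combinations = data.frame(member_ids = "a;b",
                                                     cost_pv = 180, hly = 14))
  pt <- combine_within_programme(c("b", "a"), cl2)
  expect_equal(pt$cost, 180)
  expect_equal(pt$hly, 14)

  # sequential overlap in ascending ACER order: a (ACER 10) before b (16.7)
  pt <- combine_within_programme(c("a", "b"), cl, beta = 0.2, gamma = 0.1)
  expect_equal(pt$hly, 10 + 6 * 0.8)
  expect_equal(pt$cost, 7 + 100 + 100 * 0.9)

  # mutually exclusive scenarios cannot be combined
  sc$exclusivity_group <- "g"
  cl3 <- programme_cluster("p", sc)
  expect_error(combine_within_programme(c("a", "b"), cl3), "exclusivity")
})

test_that("cross-programme combination is additive and permutation-invariant", {
  expect_equal(combine_across_programmes(list())$cost, 0)
  pts <- list(cost_effect_point(100, 10), cost_effect_point(50, 2))
  tot <- combine_across_programmes(pts)
  expect_equal(tot$cost, 150)
  expect_equal(tot$hly, 12)

  set.seed(11)
  pts <- lapply(1:6, function(i)
    cost_effect_point(runif(1, 0, 100), runif(1, 0, 50)))
  ref <- combine_across_programmes(pts)
  for (i in 1:5) {
    perm <- sample(pts)
    got <- combine_across_programmes(perm)
    expect_equal(got$cost, ref$cost)
    expect_equal(got$hly, ref$hly)
  }
  # associativity: combining a combined pair equals combining all three
  ab <- combine_across_programmes(pts[1:2])
  abc <- combine_across_programmes(list(ab, pts[[3]]))
  direct <- combine_across_programmes(pts[1:3])
  expect_equal(abc$cost, direct$cost)
  expect_equal(abc$hly, direct$hly)
})

test_that("with no overlap and no fixed costs, within equals across", {
  sc <- make_scenarios(c("a", "b", "c"), c(5, 10, 20), c(1, 4, 2), "p")
  cl <- programme_cluster("p", sc, fixed_support_cost = 0)
  within <- combine_within_programme(c("a", "b", "c"), cl)
  across <- combine_across_programmes(lapply(seq_len(3), function(i)
    cost_effect_point(sc$cost_pv[i], sc$hly[i])))
  expect_equal(within$cost, across$cost)
  expect_equal(within$hly, across$hly)
})

test_that("per-capita annual cost follows the equivalent-annual-cost convention", {
  expect_equal(per_capita_annual_cost(0, 100), 0)
  expect_equal(
    per_capita_annual_cost(1000, 10,
                           discount_spec(cost_rate = 0, horizon = 100)),
    1)
  # inverse construction: a PV engineered to cost $19.80 per person per year
  spec <- discount_spec()
  pop <- 5e7
  pv <- 19.80 * annuity_factor(spec$cost_rate, spec$horizon) * pop
  expect_equal(per_capita_annual_cost(pv, pop, spec), 19.80)
  # steady-state convention divides the final-year cost by the population
  expect_equal(per_capita_annual_cost(1e9, 100, spec,
                                      convention = "steady_state",
                                      final_year_cost = 500), 5)
  expect_error(per_capita_annual_cost(10, 0), "positive")
})
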