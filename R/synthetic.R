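#' Synthetic intervention-set configuration
#'
#' Parameters of the synthetic generator, chosen to emulate the statistical
#' structure of sector-wide cost-effectiveness datasets: ACERs spread
#' log-uniformly over several orders of magnitude (so every league-table
#' band is populated), lognormal programme-level present-value costs,
#' coverage ladders with strictly diminishing marginal health gain per rung,
#' and per-programme fixed support costs.
#'
#' The overlap parameters `beta` and `gamma` have no empirically established
#' magnitudes in this literature; the defaults (0.2, 0.1) are placeholders
#' for testing the combination machinery and should be replaced with local
#' estimates in any real application.
#'
#' @param n_programmes number of disease programmes.
#' @param scenarios_per_programme length-2 integer range (min, max) of
#'   scenarios per programme.
#' @param acer_log10_range interval of log10(ACER) from which true ACERs are
#'   drawn uniformly (default \[-0.5, 4.5\]: about I$0.3 to I$30000 per HLY).
#' @param cost_meanlog,cost_sdlog parameters of the lognormal present-value
#'   cost draw (defaults log(1e8) and 1.5: 100-year PV costs for a region of
#'   ~1e8 people, spanning roughly 1e6 to 1e10 I$).
#' @param beta benefit-overlap proportion in \[0, 1).
#' @param gamma cost-synergy proportion in \[0, 1).
#' @param fixed_support_cost_fraction programme support cost as a fraction of
#'   the programme's mean scenario cost.
#' @param coverage_ladder_prob probability that a scenario is expanded into a
#'   2-3 rung coverage ladder.
#' @param region_population persons.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_programmes = 20,
                         scenarios_per_programme = c(2, 8),
                         acer_log10_range = c(-0.5, 4.5),
                         cost_meanlog = log(1e8), cost_sdlog = 1.5,
                         beta = 0.2, gamma = 0.1,
                         fixed_support_cost_fraction = 0.1,
                         coverage_ladder_prob = 0.3,
                         region_population = 1e8,
                         seed = 1L) {
  if (length(scenarios_per_programme) == 1)
    scenarios_per_programme <- rep(scenarios_per_programme, 2)
  stopifnot(n_programmes >= 1,
            length(scenarios_per_programme) == 2,
            scenarios_per_programme[1] >= 1,
            scenarios_per_programme[2] >= scenarios_per_programme[1],
            length(acer_log10_range) == 2,
            acer_log10_range[2] > acer_log10_range[1],
            cost_sdlog >= 0, region_population > 0)
  for (p in c(beta, gamma, fixed_support_cost_fraction, coverage_ladder_prob))
    if (p < 0 || p >= 1)
      stop("proportions must be in [0, 1)", call. = FALSE)
  structure(
    list(n_programmes = as.integer(n_programmes),
         scenarios_per_programme = as.integer(scenarios_per_programme),
         acer_log10_range = acer_log10_range,
         cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
         beta = beta, gamma = gamma,
         fixed_support_cost_fraction = fixed_support_cost_fraction,
         coverage_ladder_prob = coverage_ladder_prob,
         region_population = region_population,
         seed = as.integer(seed)),
    class = "synth_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic intervention dataset
#'
#' Draws intervention scenarios with the structure the analysis assumes:
#' per-scenario ACERs log-uniform over the configured range, lognormal
#' costs, health gain `hly = cost / acer`. With probability
#' `coverage_ladder_prob` a scenario becomes a 2-3 rung coverage ladder
#' (an exclusivity group). Rung values are totals at that coverage level,
#' with monotone cost and health gain and strictly diminishing incremental
#' health per rung, so higher rungs have strictly higher ACERs and rising
#' incremental ICERs. Each programme receives a fixed support cost equal to
#' `fixed_support_cost_fraction` times its mean scenario cost.
#'
#' Alongside the clusters a truth record is returned (true per-scenario
#' ACERs, ladder structure, overlap parameters, population) for parameter-
#' recovery tests.
#'
#' @param config a [synth_config()].
#' @return A list with elements `clusters` (a [as_cluster_set()] object) and
#'   `truth` (list: `acers` data.frame of id/true_acer, `ladders`, `beta`,
#'   `gamma`, `region_population`, `seed`).
#' @examples
#' sim <- generate_interventions(synth_config(n_programmes = 3, seed = 42))
#' sim$clusters
#' @export
generate_interventions <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  pick <- function(x) x[sample.int(length(x), 1)] # safe for length-1 x
  with_seed(config$seed, {
    id_l <- list()
    grp_l <- list()
    prog_l <- list()
    plat_l <- list()
    cost_l <- list()
    hly_l <- list()
    ladders <- list()
    fixed <- numeric(0)
    k <- 0L
    for (p in seq_len(config$n_programmes)) {
      prog <- sprintf("P%03d", p)
      n <- pick(seq(config$scenarios_per_programme[1],
                    config$scenarios_per_programme[2]))
      prog_costs <- numeric(0)
      for (s in seq_len(n)) {
        acer_true <- 10^stats::runif(1, config$acer_log10_range[1],
                                     config$acer_log10_range[2])
        cost <- stats::rlnorm(1, config$cost_meanlog, config$cost_sdlog)
        hly <- cost / acer_true
        platform <- pick(gcea_platforms)
        base_id <- sprintf("%sS%02d", prog, s)
        is_ladder <- stats::runif(1) < config$coverage_ladder_prob
        k <- k + 1L
        if (!is_ladder) {
          id_l[[k]] <- base_id
          grp_l[[k]] <- NA_character_
          cost_l[[k]] <- cost
          hly_l[[k]] <- hly
        } else {
          n_rungs <- pick(2:3)
          grp <- paste0(base_id, "G")
          # rung r adds cost * 0.8^(r-1) and hly * 0.5^(r-1) on top of the
          # previous total: increments shrink faster in health than in cost,
          # so incremental ICERs rise strictly along the ladder
          d_cost <- cost * 0.8^(seq_len(n_rungs) - 1)
          d_hly <- hly * 0.5^(seq_len(n_rungs) - 1)
          ids <- sprintf("%sR%d", base_id, seq_len(n_rungs))
          id_l[[k]] <- ids
          grp_l[[k]] <- rep(grp, n_rungs)
          cost_l[[k]] <- cumsum(d_cost)
          hly_l[[k]] <- cumsum(d_hly)
          ladders[[grp]] <- ids
        }
        prog_l[[k]] <- rep(prog, length(id_l[[k]]))
        plat_l[[k]] <- rep(platform, length(id_l[[k]]))
        prog_costs <- c(prog_costs, cost_l[[k]])
      }
      fixed[prog] <- config$fixed_support_cost_fraction * mean(prog_costs)
    }
    scenarios <- data.frame(
      id = unlist(id_l), name = unlist(id_l), programme = unlist(prog_l),
      platform = unlist(plat_l), exclusivity_group = unlist(grp_l),
      cost_pv = unlist(cost_l), hly = unlist(hly_l),
      population_in_need = NA_real_, stringsAsFactors = FALSE)
    clusters <- as_cluster_set(scenarios, fixed_support_costs = fixed)
    truth <- list(
      acers = data.frame(id = scenarios$id,
                         true_acer = scenarios$cost_pv / scenarios$hly,
                         stringsAsFactors = FALSE),
      ladders = ladders,
      beta = config$beta, gamma = config$gamma,
      fixed_support_costs = fixed,
      region_population = config$region_population,
      seed = config$seed)
    list(clusters = clusters, truth = truth)
  })
}

#' Exhaustive-enumeration frontier oracle
#'
#' Test oracle for [build_expansion_path()]: enumerates every feasible
#' selection of scenarios (at most one member per exclusivity group),
#' evaluates each selection with its own inline combination arithmetic
#' (sequential overlap in ACER order within programmes, additive across;
#' deliberately independent of [combine_within_programme()]), and returns
#' the efficient frontier — the lower convex hull of all feasible package
#' points, i.e. exactly the cumulative points reachable from the null by a
#' non-decreasing-ICER path. The null (0, 0) is always the first frontier
#' point.
#'
#' Intended for small instances only; the enumeration is exponential.
#'
#' @param clusters a [as_cluster_set()] object.
#' @param limit maximum total number of scenarios (default 12).
#' @param beta,gamma,include_fixed combination parameters matching the path
#'   configuration under test.
#' @param exclude_dominated drop scenarios pairwise strictly dominated by
#'   another scenario (less health for more cost, one strict) before
#'   enumerating — the static counterpart of the path's stepwise
#'   strict-dominance exclusion.
#' @return A data.frame of frontier points (`cost`, `hly`) sorted by cost,
#'   with the achieving selections in attribute `selections`.
#' @export
oracle_frontier <- function(clusters, limit = 12, beta = 0, gamma = 0,
                            include_fixed = TRUE, exclude_dominated = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"))
  sc <- scenario_table(clusters)
  if (nrow(sc) > limit)
    stop("instance too large for exhaustive enumeration (", nrow(sc), " > ",
         limit, " scenarios)", call. = FALSE)

  if (exclude_dominated && nrow(sc) > 1) {
    dominated <- vapply(seq_len(nrow(sc)), function(j) {
      any(sc$cost_pv <= sc$cost_pv[j] & sc$hly >= sc$hly[j] &
            (sc$cost_pv < sc$cost_pv[j] | sc$hly > sc$hly[j]))
    }, logical(1))
    sc <- sc[!dominated, , drop = FALSE]
  }

  # choice sets: each exclusivity group contributes one-of-(none, rungs);
  # ungrouped scenarios are independent in/out choices
  choice_sets <- list()
  grouped <- !is.na(sc$exclusivity_group)
  for (g in unique(sc$exclusivity_group[grouped]))
    choice_sets[[length(choice_sets) + 1L]] <-
      c(NA_character_, sc$id[grouped & sc$exclusivity_group == g])
  for (id in sc$id[!grouped])
    choice_sets[[length(choice_sets) + 1L]] <- c(NA_character_, id)

  grid <- expand.grid(choice_sets, stringsAsFactors = FALSE)
  selections <- apply(grid, 1, function(row) row[!is.na(row)],
                      simplify = FALSE)

  # independent evaluation of one selection
  eval_sel <- function(ids) {
    if (length(ids) == 0) return(c(0, 0))
    cost <- 0
    hly <- 0
    for (prog in unique(sc$programme[match(ids, sc$id)])) {
      m <- match(intersect(ids, sc$id[sc$programme == prog]), sc$id)
      r <- ifelse(sc$hly[m] > 0, sc$cost_pv[m] / sc$hly[m], Inf)
      ord <- order(r, sc$id[m])
      k <- seq_along(ord) - 1
      hly <- hly + sum(sc$hly[m][ord] * (1 - beta)^k)
      cost <- cost + sum(sc$cost_pv[m][ord] * (1 - gamma)^k)
      if (include_fixed) cost <- cost + sc$fixed_support_cost[m[1]]
    }
    c(cost, hly)
  }
  pts <- t(vapply(selections, eval_sel, numeric(2)))
  df <- data.frame(cost = pts[, 1], hly = pts[, 2])

  # lower convex hull from the null outward: sort by hly, keep the cheapest
  # point per hly, then a monotone-chain scan keeping right turns
  ord <- order(df$hly, df$cost)
  df <- df[ord, ]
  selections <- selections[ord]
  keep_first <- !duplicated(df$hly)
  df <- df[keep_first, ]
  selections <- selections[keep_first]

  hull <- integer(0)
  for (i in seq_len(nrow(df))) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]
      b <- hull[length(hull)]
      # pop b unless a -> b -> i turns counterclockwise (slopes strictly
      # rising); collinear middles are popped so only hull vertices remain
      t1 <- (df$hly[b] - df$hly[a]) * (df$cost[i] - df$cost[a])
      t2 <- (df$cost[b] - df$cost[a]) * (df$hly[i] - df$hly[a])
      if (t1 - t2 <= 1e-9 * (abs(t1) + abs(t2))) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  # with non-negative costs the hull slopes from the null are >= 0 and
  # non-decreasing, so this is the efficient frontier sorted by cost
  out <- df[hull, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selections") <- selections[hull]
  out
}
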