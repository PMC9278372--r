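#' Expansion-path configuration
#'
#' Controls for [build_expansion_path()] and [apply_budget_constraint()].
#'
#' `strict_dominance` selects between the two published-path readings of
#' dominance handling. With `TRUE` (default), each adoption permanently
#' excludes any remaining candidate offering less health for more cost than
#' the adopted step — dominated interventions cannot enter the package. With
#' `FALSE`, no still-beneficial candidate is ever permanently excluded and
#' the path's cumulative points provably trace the lower convex hull of all
#' feasible package points in the additive limit (zero overlap parameters and
#' zero fixed support costs); this is the frontier mode validated against the
#' exhaustive-enumeration oracle.
#'
#' @param extended_dominance after each adoption, splice out earlier steps
#'   whose ICER exceeds the new step's (standard frontier cleanup), keeping
#'   the ICER sequence non-decreasing (default `TRUE`).
#' @param strict_dominance permanently exclude candidates strictly dominated
#'   by an adopted step (default `TRUE`).
#' @param tie_epsilon relative ICER tolerance for ties; tied candidates are
#'   broken by ascending scenario id.
#' @param budget_per_capita optional per-capita annual budget (I$/person/yr).
#' @param region_population region population; required when a budget is set.
#' @param allow_partial pro-rate the first unaffordable step linearly when
#'   applying a budget (default `FALSE`).
#' @param beta,gamma within-programme overlap parameters (see
#'   [combine_within_programme()]).
#' @param include_fixed include programme support costs in package points.
#' @param discount a [discount_spec()] used for per-capita annualisation.
#' @return An object of class `path_config`.
#' @export
path_config <- function(extended_dominance = TRUE, strict_dominance = TRUE,
                        tie_epsilon = 1e-9, budget_per_capita = NULL,
                        region_population = NULL, allow_partial = FALSE,
                        beta = 0, gamma = 0, include_fixed = TRUE,
                        discount = discount_spec()) {
  if (tie_epsilon < 0) stop("`tie_epsilon` must be >= 0", call. = FALSE)
  if (!is.null(budget_per_capita) && is.null(region_population))
    stop("`region_population` is required when a budget is set", call. = FALSE)
  structure(
    list(extended_dominance = extended_dominance,
         strict_dominance = strict_dominance,
         tie_epsilon = tie_epsilon,
         budget_per_capita = budget_per_capita,
         region_population = region_population,
         allow_partial = allow_partial,
         beta = beta, gamma = gamma, include_fixed = include_fixed,
         discount = discount),
    class = "path_config")
}

new_expansion_path <- function(steps, excluded, adopted, adopted_after,
                               config) {
  structure(
    list(steps = steps, excluded = excluded, adopted = adopted,
         config = config),
    adopted_after = adopted_after,
    class = "expansion_path")
}

#' @export
print.expansion_path <- function(x, ...) {
  cat(sprintf("<expansion_path> %d step(s), %d excluded\n",
              nrow(x$steps), nrow(x$excluded)))
  if (nrow(x$steps) > 0) {
    cat(sprintf("  first ACER %s, final ICER %s, total (%s I$, %s HLY)\n",
                format(signif(x$steps$icer[1], 4)),
                format(signif(x$steps$icer[nrow(x$steps)], 4)),
                format(signif(x$steps$cum_cost[nrow(x$steps)], 4)),
                format(signif(x$steps$cum_hly[nrow(x$steps)], 4))))
  }
  if (nrow(x$excluded) > 0)
    print(table(x$excluded$reason))
  invisible(x)
}

#' Build the optimized expansion path
#'
#' Greedy construction of the cross-programme expansion path from the null
#' scenario outward. The scenario with the lowest ACER is adopted first; at
#' every subsequent step each remaining candidate is evaluated as an
#' addition to the current package (within-programme combination rules for
#' same-programme additions, additive across programmes, a higher coverage
#' rung replacing the currently adopted rung of its exclusivity group) and
#' the candidate with the lowest ICER against the current point is adopted.
#' Cost-saving candidates (positive health gain at non-positive incremental
#' cost) are adopted before any ratio comparison, in descending health-gain
#' order, since they enter any rational package.
#'
#' Candidates made obsolete along the way are recorded with a reason:
#' `strictly_dominated` (less health for more cost than an adopted step;
#' only with `strict_dominance = TRUE`, or any candidate that can no longer
#' add health), `superseded_coverage` (a lower rung of a coverage ladder
#' whose higher rung was adopted), or `extended_dominated` (an earlier step
#' spliced out because a later addition achieved health more cheaply per
#' HLY). Near-tie candidates that remain excluded keep their would-be ICER
#' in the `excluded` table so reports can surface them.
#'
#' The construction stops when no candidate adds health. Every input
#' scenario appears exactly once across `steps` and `excluded`. After
#' extended dominance cleanup the ICER sequence is non-decreasing within
#' every run of ratio-ranked steps; a cost-saving adoption (possible
#' mid-path when cost synergies make an addition reduce total programme
#' cost) is a dominance move rather than a ratio move and resets that
#' ordering baseline.
#'
#' @param clusters a [as_cluster_set()] object with at least one scenario
#'   with positive health gain.
#' @param config a [path_config()].
#' @return An object of class `expansion_path` with elements `steps` (rank,
#'   scenario_id, delta_cost, delta_hly, icer, cum_cost, cum_hly,
#'   cost_saving), `excluded` (scenario_id, reason, would_be_icer), `adopted`
#'   (final package scenario ids) and `config`.
#' @examples
#' sc <- data.frame(
#'   id = c("a", "b"), name = c("a", "b"), programme = c("p1", "p2"),
#'   platform = "community", exclusivity_group = NA,
#'   cost_pv = c(100, 200), hly = c(10, 15), population_in_need = NA)
#' build_expansion_path(as_cluster_set(sc))
#' @export
build_expansion_path <- function(clusters, config = path_config()) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(config, "path_config"))
  sc <- scenario_table(clusters)
  if (!any(sc$hly > 0))
    stop("no scenario gains health: the expansion path is empty",
         call. = FALSE)

  eval_point <- function(ids) {
    selection_point(ids, clusters, beta = config$beta, gamma = config$gamma,
                    include_fixed = config$include_fixed)
  }

  adopted <- character(0)
  current <- cost_effect_point(0, 0)
  steps <- list()
  adopted_after <- list()
  excluded <- data.frame(scenario_id = character(), reason = character(),
                         would_be_icer = numeric(), stringsAsFactors = FALSE)

  exclude <- function(id, reason, would_be) {
    excluded[nrow(excluded) + 1L, ] <<- list(id, reason, would_be)
  }

  candidate_ids <- function() {
    setdiff(sc$id, c(adopted, excluded$scenario_id,
                     vapply(steps, `[[`, character(1), "scenario_id")))
  }

  # evaluate all candidates against the current package point
  eval_candidates <- function(ids) {
    if (length(ids) == 0)
      return(data.frame(id = character(), delta_cost = numeric(),
                        delta_hly = numeric()))
    res <- lapply(ids, function(id) {
      g <- sc$exclusivity_group[match(id, sc$id)]
      sel <- adopted
      if (!is.na(g)) {
        rival <- adopted[sc$exclusivity_group[match(adopted, sc$id)] %in% g]
        sel <- setdiff(sel, rival)
      }
      pt <- eval_point(c(sel, id))
      c(pt$cost - current$cost, pt$hly - current$hly)
    })
    data.frame(id = ids,
               delta_cost = vapply(res, `[`, numeric(1), 1),
               delta_hly = vapply(res, `[`, numeric(1), 2),
               stringsAsFactors = FALSE)
  }

  adopt <- function(id, delta_cost, delta_hly, icer_val, cost_saving) {
    g <- sc$exclusivity_group[match(id, sc$id)]
    if (!is.na(g)) {
      rival <- adopted[sc$exclusivity_group[match(adopted, sc$id)] %in% g]
      adopted <<- setdiff(adopted, rival)
    }
    adopted <<- c(adopted, id)
    pt <- eval_point(adopted)
    steps[[length(steps) + 1L]] <<- list(
      scenario_id = id, delta_cost = delta_cost, delta_hly = delta_hly,
      icer = icer_val, cost_saving = cost_saving)
    adopted_after[[length(adopted_after) + 1L]] <<- adopted
    current <<- pt
  }

  repeat {
    cand <- eval_candidates(candidate_ids())
    if (nrow(cand) == 0) break
    beneficial <- cand$delta_hly > 0
    if (!any(beneficial)) {
      # nothing left can add health: classify and stop
      for (i in seq_len(nrow(cand))) {
        g <- sc$exclusivity_group[match(cand$id[i], sc$id)]
        reason <- if (!is.na(g) &&
                      any(sc$exclusivity_group[match(adopted, sc$id)] %in% g))
          "superseded_coverage" else "strictly_dominated"
        exclude(cand$id[i], reason, NA_real_)
      }
      break
    }

    saving <- beneficial & cand$delta_cost <= 0
    if (any(saving)) {
      pick <- which(saving)[order(-cand$delta_hly[saving],
                                  cand$id[saving])][1]
      adopt(cand$id[pick], cand$delta_cost[pick], cand$delta_hly[pick],
            cand$delta_cost[pick] / cand$delta_hly[pick], cost_saving = TRUE)
      next
    }

    ratio <- ifelse(beneficial, cand$delta_cost / cand$delta_hly, Inf)
    best <- min(ratio)
    tol <- config$tie_epsilon * max(1, abs(best))
    tied <- which(ratio <= best + tol)
    pick <- tied[order(cand$id[tied])][1]
    adopted_id <- cand$id[pick]
    dc <- cand$delta_cost[pick]
    dh <- cand$delta_hly[pick]
    adopt(adopted_id, dc, dh, dc / dh, cost_saving = FALSE)

    # lower rungs of the adopted scenario's ladder can never add health now
    g <- sc$exclusivity_group[match(adopted_id, sc$id)]
    if (!is.na(g)) {
      for (i in setdiff(which(!is.na(sc$exclusivity_group) &
                                sc$exclusivity_group == g), 0)) {
        id_i <- sc$id[i]
        if (id_i %in% cand$id && id_i != adopted_id &&
            sc$hly[i] <= sc$hly[match(adopted_id, sc$id)]) {
          j <- match(id_i, cand$id)
          wb <- if (cand$delta_hly[j] > 0)
            cand$delta_cost[j] / cand$delta_hly[j] else NA_real_
          exclude(id_i, "superseded_coverage", wb)
        }
      }
    }

    # paper rule: candidates with less health and more cost than the adopted
    # step are out of the running for good
    if (config$strict_dominance) {
      remaining <- setdiff(candidate_ids(), adopted_id)
      for (id_j in intersect(remaining, cand$id)) {
        j <- match(id_j, cand$id)
        if (cand$delta_hly[j] <= dh && cand$delta_cost[j] >= dc &&
            (cand$delta_hly[j] < dh || cand$delta_cost[j] > dc)) {
          wb <- if (cand$delta_hly[j] > 0)
            cand$delta_cost[j] / cand$delta_hly[j] else NA_real_
          exclude(id_j, "strictly_dominated", wb)
        }
      }
    }

    # extended dominance: splice out earlier, steeper steps
    if (config$extended_dominance) {
      repeat {
        k <- length(steps)
        if (k < 2) break
        last <- steps[[k]]
        prev <- steps[[k - 1]]
        if (last$cost_saving || prev$cost_saving) break
        tol <- config$tie_epsilon * max(1, abs(prev$icer))
        if (last$icer >= prev$icer - tol) break
        # remove the previous step and recompute the last step's increment
        adopted <- setdiff(adopted, prev$scenario_id)
        exclude(prev$scenario_id, "extended_dominated", prev$icer)
        base <- if (k >= 3) adopted_after[[k - 2]] else character(0)
        pt_base <- eval_point(base)
        pt_new <- eval_point(adopted)
        dC <- pt_new$cost - pt_base$cost
        dH <- pt_new$hly - pt_base$hly
        steps[[k - 1]] <- steps[[k]]
        steps[[k]] <- NULL
        adopted_after[[k - 1]] <- adopted
        adopted_after[[k]] <- NULL
        if (dH <= 0) {
          # degenerate resplice (possible only under combination records):
          # the new step itself no longer adds health
          bad <- steps[[k - 1]]$scenario_id
          adopted <- setdiff(adopted, bad)
          exclude(bad, "strictly_dominated", NA_real_)
          steps[[k - 1]] <- NULL
          adopted_after[[k - 1]] <- NULL
          current <- eval_point(adopted)
          break
        }
        steps[[k - 1]]$delta_cost <- dC
        steps[[k - 1]]$delta_hly <- dH
        steps[[k - 1]]$icer <- dC / dH
        current <- pt_new
      }
    }
  }

  if (length(steps) == 0)
    stop("no scenario could be adopted: the expansion path is empty",
         call. = FALSE)

  steps_df <- do.call(rbind, lapply(steps, function(s)
    data.frame(scenario_id = s$scenario_id, delta_cost = s$delta_cost,
               delta_hly = s$delta_hly, icer = s$icer,
               cost_saving = s$cost_saving, stringsAsFactors = FALSE)))
  steps_df$cum_cost <- cumsum(steps_df$delta_cost)
  steps_df$cum_hly <- cumsum(steps_df$delta_hly)
  steps_df <- data.frame(rank = seq_len(nrow(steps_df)), steps_df)
  steps_df <- steps_df[, c("rank", "scenario_id", "delta_cost", "delta_hly",
                           "icer", "cum_cost", "cum_hly", "cost_saving")]

  # accounting identity: every scenario exactly once
  all_ids <- sort(c(steps_df$scenario_id, excluded$scenario_id))
  stopifnot(identical(all_ids, sort(sc$id)))

  new_expansion_path(steps_df, excluded, adopted, adopted_after, config)
}

#' Truncate an expansion path at a per-capita budget
#'
#' Walks the path in order, converting the cumulative present-value cost to
#' an equivalent annual cost per capita, and returns the largest prefix whose
#' per-capita cost does not exceed the budget. With
#' `allow_partial = TRUE` the first unaffordable step is pro-rated linearly
#' (its cost and health scaled by the affordable fraction); by default steps
#' are indivisible.
#'
#' @param path an [build_expansion_path()] result.
#' @param config a [path_config()] with `budget_per_capita` and
#'   `region_population` set (defaults to the path's own config).
#' @return A [benefit_package()]. An unaffordable first step yields an empty
#'   package with a warning.
#' @export
apply_budget_constraint <- function(path, config = path$config) {
  stopifnot(inherits(path, "expansion_path"))
  budget <- config$budget_per_capita
  pop <- config$region_population
  if (is.null(budget) || is.null(pop))
    stop("`budget_per_capita` and `region_population` must be set",
         call. = FALSE)
  af <- annuity_factor(config$discount$cost_rate, config$discount$horizon)
  per_cap <- path$steps$cum_cost / af / pop
  tol <- 1e-9 * max(1, budget)
  k <- max(c(0L, which(per_cap <= budget + tol)))
  if (k == 0L) {
    if (!config$allow_partial || nrow(path$steps) == 0 ||
        path$steps$delta_cost[1] <= 0) {
      if (budget < per_cap[1])
        warning("budget below the cost of the first step: empty package")
      return(benefit_package(character(0), 0, 0, 0, pop))
    }
  }
  adopted_after <- attr(path, "adopted_after")
  ids <- if (k > 0) adopted_after[[k]] else character(0)
  cost <- if (k > 0) path$steps$cum_cost[k] else 0
  hly <- if (k > 0) path$steps$cum_hly[k] else 0
  if (config$allow_partial && k < nrow(path$steps)) {
    dc <- path$steps$delta_cost[k + 1]
    dh <- path$steps$delta_hly[k + 1]
    if (dc > 0) {
      frac <- (budget * af * pop - cost) / dc
      frac <- max(0, min(1, frac))
      if (frac > 0) {
        cost <- cost + frac * dc
        hly <- hly + frac * dh
        ids <- c(ids, path$steps$scenario_id[k + 1])
      }
    }
  }
  benefit_package(ids, cost, hly,
                  per_capita_annual_cost(cost, pop, config$discount), pop)
}
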