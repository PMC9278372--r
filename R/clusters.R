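#' Delivery platforms
#'
#' The four service-delivery levels used to stratify league tables:
#' population-level policy, community/outreach services, first-level clinical
#' services, and referral care (everything outside the primary-healthcare
#' definition).
#'
#' @export
gcea_platforms <- c("population", "community", "first_level_clinical", "referral")

#' A cost-effect point
#'
#' A point on the cost-effectiveness plane: present-value cost (I$) and
#' healthy life years gained, both measured against the null scenario, which
#' is the point (0, 0).
#'
#' @param cost present-value cost, >= 0 (I$).
#' @param hly healthy life years gained, >= 0.
#' @return An object of class `cost_effect_point` (a named list).
#' @export
cost_effect_point <- function(cost, hly) {
  stopifnot(length(cost) == 1, length(hly) == 1)
  if (is.na(cost) || is.na(hly) || cost < 0 || hly < 0)
    stop("cost and hly must be non-negative", call. = FALSE)
  structure(list(cost = as.numeric(cost), hly = as.numeric(hly)),
            class = "cost_effect_point")
}

#' @export
print.cost_effect_point <- function(x, ...) {
  cat(sprintf("<cost_effect_point> cost = %s I$, hly = %s\n",
              format(x$cost), format(x$hly)))
  invisible(x)
}

# Validate and normalise a scenario data.frame. Errors name the offending
# column or row so CSV problems are actionable.
validate_scenarios <- function(scenarios) {
  required <- c("id", "name", "programme", "platform", "exclusivity_group",
                "cost_pv", "hly", "population_in_need")
  missing_cols <- setdiff(setdiff(required, c("population_in_need", "name")),
                          names(scenarios))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"name" %in% names(scenarios)) scenarios$name <- scenarios$id
  if (!"population_in_need" %in% names(scenarios))
    scenarios$population_in_need <- NA_real_

  scenarios$id <- as.character(scenarios$id)
  scenarios$name <- as.character(scenarios$name)
  scenarios$programme <- as.character(scenarios$programme)
  scenarios$platform <- as.character(scenarios$platform)
  scenarios$exclusivity_group <- as.character(scenarios$exclusivity_group)
  scenarios$exclusivity_group[!is.na(scenarios$exclusivity_group) &
                                scenarios$exclusivity_group == ""] <- NA_character_
  scenarios$cost_pv <- as.numeric(scenarios$cost_pv)
  scenarios$hly <- as.numeric(scenarios$hly)
  scenarios$population_in_need <- as.numeric(scenarios$population_in_need)

  if (anyDuplicated(scenarios$id)) {
    dup <- scenarios$id[duplicated(scenarios$id)][1]
    stop("duplicate scenario id: ", dup, call. = FALSE)
  }
  bad <- which(is.na(scenarios$cost_pv) | scenarios$cost_pv < 0)
  if (length(bad) > 0)
    stop("negative or missing cost_pv at row ", bad[1], call. = FALSE)
  bad <- which(is.na(scenarios$hly) | scenarios$hly < 0)
  if (length(bad) > 0)
    stop("negative or missing hly at row ", bad[1], call. = FALSE)
  bad <- which(scenarios$cost_pv == 0 & scenarios$hly == 0)
  if (length(bad) > 0)
    stop("scenario identical to the null (cost_pv = 0 and hly = 0) at row ",
         bad[1], call. = FALSE)
  bad <- which(!scenarios$platform %in% gcea_platforms)
  if (length(bad) > 0)
    stop("unknown platform '", scenarios$platform[bad[1]], "' at row ", bad[1],
         "; must be one of: ", paste(gcea_platforms, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(scenarios$population_in_need) &
                 scenarios$population_in_need <= 0)
  if (length(bad) > 0)
    stop("population_in_need must be > 0 at row ", bad[1], call. = FALSE)

  grp <- scenarios$exclusivity_group[!is.na(scenarios$exclusivity_group)]
  singleton <- names(which(table(grp) < 2))
  if (length(singleton) > 0)
    stop("exclusivity_group '", singleton[1],
         "' has a single member; groups must have >= 2 scenarios",
         call. = FALSE)
  rownames(scenarios) <- NULL
  scenarios[, required]
}

#' Disease-programme cluster
#'
#' A disease programme's intervention scenarios, its fixed programme-support
#' cost (a present value incurred once whenever any of the programme's
#' scenarios are delivered), and optional combination records giving joint
#' cost and benefit when specific scenario subsets are co-implemented.
#'
#' @param programme programme identifier.
#' @param scenarios data.frame of the programme's scenarios (columns `id`,
#'   `name`, `programme`, `platform`, `exclusivity_group`, `cost_pv`, `hly`,
#'   `population_in_need`).
#' @param fixed_support_cost present-value programme-support cost (I$, >= 0).
#' @param combinations optional data.frame with columns `member_ids`
#'   (semicolon-joined, sorted scenario ids), `cost_pv`, `hly`, giving joint
#'   values for co-implemented subsets. Joint benefit must not exceed the sum
#'   of member benefits (overlap only reduces benefit).
#' @param check_economies if `TRUE`, additionally require joint cost <= sum
#'   of member costs (economies of scale).
#' @return An object of class `programme_cluster`.
#' @export
programme_cluster <- function(programme, scenarios, fixed_support_cost = 0,
                              combinations = NULL, check_economies = FALSE) {
  scenarios <- validate_scenarios(scenarios)
  if (!all(scenarios$programme == programme))
    stop("all scenarios must belong to programme '", programme, "'",
         call. = FALSE)
  if (length(fixed_support_cost) != 1 || is.na(fixed_support_cost) ||
      fixed_support_cost < 0)
    stop("`fixed_support_cost` must be a single non-negative number",
         call. = FALSE)
  if (!is.null(combinations)) {
    stopifnot(all(c("member_ids", "cost_pv", "hly") %in% names(combinations)))
    combinations$member_ids <- vapply(
      strsplit(as.character(combinations$member_ids), ";", fixed = TRUE),
      function(ids) paste(sort(trimws(ids)), collapse = ";"), character(1))
    for (i in seq_len(nrow(combinations))) {
      ids <- strsplit(combinations$member_ids[i], ";", fixed = TRUE)[[1]]
      if (!all(ids %in% scenarios$id))
        stop("combination row ", i, " references scenario(s) outside ",
             "programme '", programme, "'", call. = FALSE)
      m <- match(ids, scenarios$id)
      if (combinations$hly[i] > sum(scenarios$hly[m]) + 1e-9)
        stop("combination row ", i, ": joint hly exceeds the sum of member ",
             "hly values (benefit can only overlap, not amplify)",
             call. = FALSE)
      if (check_economies &&
          combinations$cost_pv[i] > sum(scenarios$cost_pv[m]) + 1e-9)
        stop("combination row ", i, ": joint cost exceeds the sum of member ",
             "costs despite the economies-of-scale flag", call. = FALSE)
    }
  }
  structure(
    list(programme = programme, fixed_support_cost = fixed_support_cost,
         scenarios = scenarios, combinations = combinations),
    class = "programme_cluster"
  )
}

#' @export
print.programme_cluster <- function(x, ...) {
  cat(sprintf("<programme_cluster> %s: %d scenario(s), support cost %s I$%s\n",
              x$programme, nrow(x$scenarios), format(x$fixed_support_cost),
              if (is.null(x$combinations)) ""
              else sprintf(", %d combination record(s)", nrow(x$combinations))))
  invisible(x)
}

#' Build a cluster set from a scenario table
#'
#' Groups a validated scenario data.frame by programme into
#' [programme_cluster()] objects. Row order within each programme is
#' preserved so downstream tie-breaking is deterministic.
#'
#' @param scenarios data.frame of scenarios across programmes.
#' @param combinations optional data.frame with columns `programme`,
#'   `member_ids`, `cost_pv`, `hly`.
#' @param fixed_support_costs optional named numeric vector of programme
#'   support costs (names are programme ids; missing programmes get 0).
#' @return An object of class `cluster_set`: a named list of
#'   `programme_cluster` objects.
#' @export
as_cluster_set <- function(scenarios, combinations = NULL,
                           fixed_support_costs = NULL) {
  scenarios <- validate_scenarios(scenarios)
  programmes <- unique(scenarios$programme)
  clusters <- lapply(programmes, function(p) {
    comb <- NULL
    if (!is.null(combinations) && nrow(combinations) > 0) {
      comb <- combinations[combinations$programme == p,
                           c("member_ids", "cost_pv", "hly"), drop = FALSE]
      if (nrow(comb) == 0) comb <- NULL
    }
    fixed <- 0
    if (!is.null(fixed_support_costs) && p %in% names(fixed_support_costs))
      fixed <- unname(fixed_support_costs[[p]])
    programme_cluster(p, scenarios[scenarios$programme == p, , drop = FALSE],
                      fixed_support_cost = fixed, combinations = comb)
  })
  names(clusters) <- programmes
  structure(clusters, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  n <- sum(vapply(x, function(cl) nrow(cl$scenarios), integer(1)))
  cat(sprintf("<cluster_set> %d programme(s), %d scenario(s)\n", length(x), n))
  invisible(x)
}

#' Flatten a cluster set to one scenario table
#'
#' @param clusters a [as_cluster_set()] object.
#' @return A data.frame of all scenarios with a `fixed_support_cost` column
#'   carrying each programme's support cost.
#' @export
scenario_table <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  out <- do.call(rbind, lapply(clusters, function(cl) {
    df <- cl$scenarios
    df$fixed_support_cost <- cl$fixed_support_cost
    df
  }))
  rownames(out) <- NULL
  out
}

#' Combine scenarios within one programme
#'
#' Joint cost and health gain when a set of a programme's scenarios is
#' co-implemented. If the cluster carries an explicit combination record for
#' exactly this set, its joint values are used. Otherwise a sequential
#' overlap model is applied in ascending ACER order: the k-th scenario added
#' contributes `hly_k * (1 - beta)^(k-1)` health and `cost_k * (1 - gamma)^(k-1)`
#' cost, reflecting that later additions gain less (some benefit was already
#' obtained) and cost less (economies of scale). The programme's fixed
#' support cost enters once for any non-empty selection.
#'
#' @param selected character vector of scenario ids (at most one per
#'   exclusivity group).
#' @param cluster a [programme_cluster()].
#' @param beta benefit-overlap proportion in \[0, 1).
#' @param gamma cost-synergy proportion in \[0, 1).
#' @param include_fixed include the programme-support cost (default `TRUE`).
#' @return A [cost_effect_point()].
#' @examples
#' cl <- programme_cluster("p", data.frame(
#'   id = c("a", "b"), name = c("a", "b"), programme = "p",
#'   platform = "community", exclusivity_group = NA,
#'   cost_pv = c(100, 100), hly = c(10, 6), population_in_need = NA))
#' combine_within_programme(c("a", "b"), cl)  # additive: (200, 16)
#' @export
combine_within_programme <- function(selected, cluster, beta = 0, gamma = 0,
                                     include_fixed = TRUE) {
  stopifnot(inherits(cluster, "programme_cluster"))
  if (length(beta) != 1 || beta < 0 || beta >= 1)
    stop("`beta` must be in [0, 1)", call. = FALSE)
  if (length(gamma) != 1 || gamma < 0 || gamma >= 1)
    stop("`gamma` must be in [0, 1)", call. = FALSE)
  selected <- unique(as.character(selected))
  if (length(selected) == 0) return(cost_effect_point(0, 0))
  sc <- cluster$scenarios
  if (!all(selected %in% sc$id))
    stop("selected ids not in programme '", cluster$programme, "': ",
         paste(setdiff(selected, sc$id), collapse = ", "), call. = FALSE)
  m <- match(selected, sc$id)
  grp <- sc$exclusivity_group[m]
  if (anyDuplicated(grp[!is.na(grp)]))
    stop("selection contains two scenarios from exclusivity group '",
         grp[!is.na(grp)][duplicated(grp[!is.na(grp)])][1], "'",
         call. = FALSE)

  fixed <- if (include_fixed) cluster$fixed_support_cost else 0

  key <- paste(sort(selected), collapse = ";")
  if (!is.null(cluster$combinations)) {
    hit <- match(key, cluster$combinations$member_ids)
    if (!is.na(hit)) {
      return(cost_effect_point(cluster$combinations$cost_pv[hit] + fixed,
                               cluster$combinations$hly[hit]))
    }
  }

  # sequential overlap model, applied in ascending ACER order (ties by id)
  cost_i <- sc$cost_pv[m]
  hly_i <- sc$hly[m]
  ratio <- ifelse(hly_i > 0, cost_i / hly_i, Inf)
  ord <- order(ratio, sc$id[m])
  k <- seq_along(ord) - 1
  hly <- sum(hly_i[ord] * (1 - beta)^k)
  cost <- fixed + sum(cost_i[ord] * (1 - gamma)^k)
  cost_effect_point(cost, hly)
}

#' Combine package points across programmes
#'
#' Costs and benefits are assumed additive across distinct disease
#' programmes, so the package point is the component-wise sum. The empty
#' list is the null scenario (0, 0). The sum is permutation-invariant,
#' associative and commutative.
#'
#' @param points list of [cost_effect_point()] objects.
#' @return A [cost_effect_point()].
#' @export
combine_across_programmes <- function(points) {
  if (length(points) == 0) return(cost_effect_point(0, 0))
  stopifnot(all(vapply(points, inherits, logical(1), "cost_effect_point")))
  cost_effect_point(sum(vapply(points, `[[`, numeric(1), "cost")),
                    sum(vapply(points, `[[`, numeric(1), "hly")))
}

# Evaluate an arbitrary cross-programme selection of scenario ids:
# within-programme combination rules per programme, additive across.
selection_point <- function(selected, clusters, beta = 0, gamma = 0,
                            include_fixed = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (length(selected) == 0) return(cost_effect_point(0, 0))
  points <- lapply(clusters, function(cl) {
    ids <- intersect(selected, cl$scenarios$id)
    combine_within_programme(ids, cl, beta = beta, gamma = gamma,
                             include_fixed = include_fixed)
  })
  found <- unlist(lapply(clusters, function(cl)
    intersect(selected, cl$scenarios$id)))
  if (length(found) != length(unique(selected)))
    stop("selection contains unknown scenario id(s): ",
         paste(setdiff(selected, found), collapse = ", "), call. = FALSE)
  combine_across_programmes(points)
}
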