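#' Build a platform-stratified league table
#'
#' Ranks every rankable scenario by average cost-effectiveness ratio, groups
#' entries by delivery platform and order-of-magnitude band, and sorts
#' ascending by ACER (ties by id) within each band. Overlaps from coverage
#' ladders or overlapping bundles are de-duplicated: within each exclusivity
#' group only the member with the lowest ACER is listed. Each scenario's
#' ACER is computed standalone against the null, with its programme's fixed
#' support cost added to its cost first (delivering any part of a programme
#' requires supporting the programme).
#'
#' Scenarios with zero health gain cannot be ranked and are dropped with a
#' warning.
#'
#' @param clusters a [as_cluster_set()] object.
#' @param scheme a [band_scheme()].
#' @param include_fixed add each programme's support cost to its scenarios'
#'   costs before computing ACERs (default `TRUE`).
#' @return A `league_table` data.frame with columns `platform`, `band_label`,
#'   `scenario_id`, `name`, `acer`, plus `programme`.
#' @export
build_league_table <- function(clusters, scheme = band_scheme(),
                               include_fixed = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(scheme, "band_scheme"))
  sc <- scenario_table(clusters)

  unrankable <- sc$hly <= 0
  if (any(unrankable)) {
    warning(sum(unrankable), " scenario(s) with hly = 0 cannot be ranked ",
            "and were dropped from the league table")
    sc <- sc[!unrankable, , drop = FALSE]
  }
  if (nrow(sc) == 0) {
    return(new_league_table(
      data.frame(platform = character(), band_label = character(),
                 scenario_id = character(), name = character(),
                 acer = numeric(), programme = character()),
      scheme = scheme))
  }

  fixed <- if (include_fixed) sc$fixed_support_cost else 0
  sc$acer <- acer(sc$cost_pv + fixed, sc$hly)

  # de-duplicate coverage ladders / bundles: lowest ACER per group wins
  keep <- rep(TRUE, nrow(sc))
  grouped <- !is.na(sc$exclusivity_group)
  for (g in unique(sc$exclusivity_group[grouped])) {
    members <- which(grouped & sc$exclusivity_group == g)
    best <- members[order(sc$acer[members], sc$id[members])][1]
    keep[setdiff(members, best)] <- FALSE
  }
  sc <- sc[keep, , drop = FALSE]

  sc$band_label <- assign_band(sc$acer, scheme)
  band_rank <- match(sc$band_label, scheme$labels)
  platform_rank <- match(sc$platform, gcea_platforms)
  ord <- order(platform_rank, band_rank, sc$acer, sc$id)
  sc <- sc[ord, , drop = FALSE]

  out <- data.frame(platform = sc$platform, band_label = sc$band_label,
                    scenario_id = sc$id, name = sc$name, acer = sc$acer,
                    programme = sc$programme, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new_league_table(out, scheme = scheme)
}

#' Benefit package constructor
#'
#' @param scenario_ids character vector of the scenarios in the package.
#' @param total_cost total present-value cost (I$).
#' @param total_hly total healthy life years gained.
#' @param per_capita_annual_cost equivalent annual cost per person
#'   (I$/person/year).
#' @param region_population persons.
#' @return An object of class `benefit_package`.
#' @export
benefit_package <- function(scenario_ids, total_cost, total_hly,
                            per_capita_annual_cost, region_population) {
  if (per_capita_annual_cost < 0)
    stop("per-capita annual cost must be >= 0", call. = FALSE)
  structure(
    list(scenario_ids = as.character(scenario_ids),
         total_cost = total_cost, total_hly = total_hly,
         per_capita_annual_cost = per_capita_annual_cost,
         region_population = region_population),
    class = "benefit_package")
}

#' @export
print.benefit_package <- function(x, ...) {
  cat(sprintf(paste0(
    "<benefit_package> %d scenario(s)\n",
    "  total PV cost : %s I$\n",
    "  total HLY     : %s\n",
    "  per capita    : %s I$/person/year (population %s)\n"),
    length(x$scenario_ids), format(x$total_cost, big.mark = ","),
    format(x$total_hly, big.mark = ","),
    format(round(x$per_capita_annual_cost, 2)),
    format(x$region_population, big.mark = ",")))
  invisible(x)
}

#' Summarise a scenario selection as a benefit package
#'
#' Totals the selection under the programme combination rules (fixed support
#' costs once per programme, overlap model or explicit combination records
#' within programmes, additive across programmes) and converts the total
#' present-value cost to an equivalent annual cost per capita.
#'
#' By default the selection is every scenario in the clusters, reduced to one
#' member per exclusivity group (the lowest-ACER member, matching league
#' table de-duplication). Pass `ids` to cost a specific selection, e.g. one
#' platform's league-table entries.
#'
#' @param clusters a [as_cluster_set()] object.
#' @param ids optional character vector of scenario ids.
#' @param population region population (> 0).
#' @param spec a [discount_spec()].
#' @param beta,gamma overlap-model parameters (see
#'   [combine_within_programme()]).
#' @param include_fixed include programme support costs.
#' @return A [benefit_package()].
#' @export
package_summary <- function(clusters, ids = NULL, population,
                            spec = discount_spec(), beta = 0, gamma = 0,
                            include_fixed = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (is.null(ids)) {
    sc <- scenario_table(clusters)
    sc <- sc[sc$hly > 0, , drop = FALSE]
    fixed <- if (include_fixed) sc$fixed_support_cost else 0
    ratio <- (sc$cost_pv + fixed) / sc$hly
    keep <- rep(TRUE, nrow(sc))
    grouped <- !is.na(sc$exclusivity_group)
    for (g in unique(sc$exclusivity_group[grouped])) {
      members <- which(grouped & sc$exclusivity_group == g)
      best <- members[order(ratio[members], sc$id[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
    ids <- sc$id[keep]
  }
  pt <- selection_point(ids, clusters, beta = beta, gamma = gamma,
                        include_fixed = include_fixed)
  benefit_package(
    ids, pt$cost, pt$hly,
    per_capita_annual_cost(pt$cost, population, spec),
    population)
}
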