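#' Average cost-effectiveness ratio
#'
#' Cost per healthy life year (HLY) gained of a scenario measured against the
#' null (zero cost, zero benefit) scenario: `acer = cost / hly`. Defined only
#' for scenarios with positive health gain; a free intervention (zero cost,
#' positive gain) has ACER 0.
#'
#' Vectorised over `cost` and `hly`.
#'
#' @param cost present-value cost vs the null (I$), >= 0.
#' @param hly healthy life years gained vs the null, > 0.
#' @return ACER in I$ per HLY.
#' @examples
#' acer(100, 10) # 10
#' acer(23, 100) # 0.23
#' @export
acer <- function(cost, hly) {
  if (length(cost) != length(hly))
    stop("`cost` and `hly` must have the same length", call. = FALSE)
  if (any(is.na(cost)) || any(is.na(hly)))
    stop("ACER inputs must not be NA", call. = FALSE)
  if (any(hly <= 0))
    stop("ACER is undefined for scenarios with hly <= 0; ",
         "such scenarios cannot be ranked", call. = FALSE)
  if (any(cost < 0)) stop("`cost` must be >= 0", call. = FALSE)
  cost / hly
}

#' Incremental cost-effectiveness ratio
#'
#' Additional cost per additional HLY when moving from one package point to a
#' larger one: `(cost_to - cost_from) / (hly_to - hly_from)`. Requires the
#' destination to gain health; moving to a point with no extra health is a
#' dominance question, not a ratio, and raises an error of class
#' `gcea_dominance_error`. A negative ratio (the larger package saves money)
#' is returned with attribute `cost_saving = TRUE` rather than treated as an
#' error, because cost-saving moves must not be ranked by ratio.
#'
#' @param cost_from,hly_from the current package point (the null is 0, 0).
#' @param cost_to,hly_to the candidate package point.
#' @return The ICER in I$ per HLY, with a logical `cost_saving` attribute.
#' @examples
#' icer(100, 10, 200, 15)  # 20
#' icer(0, 0, 100, 10)     # equals acer(100, 10)
#' @export
icer <- function(cost_from, hly_from, cost_to, hly_to) {
  stopifnot(length(cost_from) == 1, length(hly_from) == 1,
            length(cost_to) == 1, length(hly_to) == 1)
  d_hly <- hly_to - hly_from
  d_cost <- cost_to - cost_from
  if (is.na(d_hly) || is.na(d_cost))
    stop("ICER inputs must not be NA", call. = FALSE)
  if (d_hly <= 0) {
    stop(structure(
      class = c("gcea_dominance_error", "error", "condition"),
      list(message = paste0(
             "destination gains no health (delta hly = ", format(d_hly),
             "): treat as dominated or tied, not as a ratio"),
           call = sys.call(-1))))
  }
  structure(d_cost / d_hly, cost_saving = d_cost < 0)
}
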