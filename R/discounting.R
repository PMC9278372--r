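#' Discounting specification
#'
#' Differential discounting convention for costs and health effects: a rate
#' for costs, a (usually lower) rate for health benefits, and an analytic
#' horizon in years. The headline convention in sector-wide generalized
#' cost-effectiveness work is 3% per year on costs, 0% on health effects,
#' over a 100-year horizon; health-effect discounting is configurable because
#' 3%/3% variants are also in common use.
#'
#' @param cost_rate annual discount rate applied to costs, in \[0, 1).
#' @param health_rate annual discount rate applied to health effects, in
#'   \[0, 1).
#' @param horizon number of years in the analytic horizon (>= 1).
#' @return An object of class `discount_spec`.
#' @examples
#' discount_spec()                    # 3% costs, 0% health, 100 years
#' discount_spec(health_rate = 0.03)  # symmetric discounting variant
#' @export
discount_spec <- function(cost_rate = 0.03, health_rate = 0, horizon = 100) {
  stopifnot(length(cost_rate) == 1, length(health_rate) == 1,
            length(horizon) == 1)
  if (is.na(cost_rate) || cost_rate < 0 || cost_rate >= 1)
    stop("`cost_rate` must be in [0, 1)", call. = FALSE)
  if (is.na(health_rate) || health_rate < 0 || health_rate >= 1)
    stop("`health_rate` must be in [0, 1)", call. = FALSE)
  if (is.na(horizon) || horizon < 1)
    stop("`horizon` must be >= 1 year", call. = FALSE)
  structure(
    list(cost_rate = cost_rate, health_rate = health_rate,
         horizon = as.integer(horizon)),
    class = "discount_spec"
  )
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf(
    "<discount_spec> costs %.1f%%/yr, health %.1f%%/yr, horizon %d yr\n",
    100 * x$cost_rate, 100 * x$health_rate, x$horizon))
  invisible(x)
}

#' Annual stream of amounts
#'
#' A yearly series of amounts (costs or health effects), one value per year
#' of the horizon, starting at `start_year`. Payments are dated at the start
#' of each year, so the first element is never discounted.
#'
#' @param values numeric vector, one amount per year (length >= 1).
#' @param start_year first calendar year of the stream.
#' @return An object of class `stream_series`.
#' @export
stream_series <- function(values, start_year = 2010) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("a stream needs at least one year", call. = FALSE)
  if (anyNA(values)) stop("stream values must not be NA", call. = FALSE)
  structure(list(values = values, start_year = as.integer(start_year)),
            class = "stream_series")
}

#' Present value of an annual stream
#'
#' Discounted sum of a yearly stream with payments at the start of each year
#' (annuity-due timing): `PV = sum_t x_t / (1 + rate)^t` for
#' `t = 0 ... n - 1`. With `rate = 0` this is the plain sum.
#'
#' @param stream a [stream_series()] or a bare numeric vector of yearly
#'   amounts.
#' @param rate annual discount rate, >= 0.
#' @return The present value (scalar).
#' @examples
#' present_value(rep(1, 5), rate = 0)      # 5
#' present_value(rep(1, 100), rate = 0.03) # approx 32.55
#' @export
present_value <- function(stream, rate) {
  if (inherits(stream, "stream_series")) stream <- stream$values
  stream <- as.numeric(stream)
  if (length(rate) != 1 || is.na(rate) || rate < 0)
    stop("`rate` must be a single non-negative number", call. = FALSE)
  if (length(stream) == 0) return(0)
  t <- seq_along(stream) - 1
  sum(stream / (1 + rate)^t)
}

#' Annuity factor under start-of-year timing
#'
#' Present value of a unit amount paid at the start of each year over the
#' horizon: `sum_{t=0}^{h-1} (1 + rate)^{-t}`. Used to convert a lump-sum
#' present value into an equivalent annual cost.
#'
#' @param rate annual discount rate, >= 0.
#' @param horizon number of years.
#' @return The annuity factor (scalar); equals `horizon` when `rate = 0`.
#' @export
annuity_factor <- function(rate, horizon) {
  if (length(rate) != 1 || is.na(rate) || rate < 0)
    stop("`rate` must be a single non-negative number", call. = FALSE)
  if (length(horizon) != 1 || is.na(horizon) || horizon < 1)
    stop("`horizon` must be >= 1", call. = FALSE)
  if (rate == 0) return(as.numeric(horizon))
  (1 - (1 + rate)^(-horizon)) / rate * (1 + rate)
}

#' Per-capita annual cost of a package
#'
#' Converts a package's total present-value cost into an annual cost per
#' person. The default `"annuity"` convention spreads the present value over
#' the horizon as an equivalent annual cost (PV divided by the annuity
#' factor of the cost rate), then divides by the population: the long-run
#' yearly price of sustaining the package. The `"steady_state"` convention
#' instead divides a supplied final-year undiscounted cost by the
#' population.
#'
#' @param cost_pv total present-value cost of the package (I$).
#' @param population region population (> 0).
#' @param spec a [discount_spec()].
#' @param convention `"annuity"` (default) or `"steady_state"`.
#' @param final_year_cost undiscounted cost in the final year; required for
#'   the `"steady_state"` convention.
#' @return Annual cost per person (I$/person/year).
#' @examples
#' per_capita_annual_cost(1000, 10, discount_spec(cost_rate = 0, horizon = 100)) # 1
#' @export
per_capita_annual_cost <- function(cost_pv, population,
                                   spec = discount_spec(),
                                   convention = c("annuity", "steady_state"),
                                   final_year_cost = NULL) {
  convention <- match.arg(convention)
  if (length(population) != 1 || is.na(population) || population <= 0)
    stop("`population` must be a single positive number", call. = FALSE)
  if (cost_pv < 0) stop("`cost_pv` must be >= 0", call. = FALSE)
  if (convention == "annuity") {
    cost_pv / annuity_factor(spec$cost_rate, spec$horizon) / population
  } else {
    if (is.null(final_year_cost))
      stop("`final_year_cost` is required for the steady_state convention",
           call. = FALSE)
    final_year_cost / population
  }
}
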