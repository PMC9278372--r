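#' Order-of-magnitude banding scheme
#'
#' Bands the cost-effectiveness axis into decades of the ACER. Each band is
#' the half-open interval `[edge_k, edge_{k+1})`; the last band is open
#' above; values below the first edge fold into the lowest band. Consecutive
#' edges must differ by exactly a factor of ten, so consecutive bands tile
#' the positive axis in orders of magnitude.
#'
#' The default mirrors the published league-table headers: `<$10`,
#' `$10-$100`, `$101-$1000`, `$1001+`. A finer scheme that splits out the
#' sub-dollar decade (as on isoquant plots) is
#' `band_scheme(c(1, 10, 100, 1000), split_below_one = TRUE)`.
#'
#' @param edges strictly ascending numeric vector of band edges, each 10x the
#'   previous.
#' @param labels one label per band (same length as `edges`).
#' @param split_below_one prepend a `<$1` band below the first edge.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(edges = c(1, 10, 100, 1000),
                        labels = c("<$10", "$10-$100", "$101-$1000", "$1001+"),
                        split_below_one = FALSE) {
  edges <- as.numeric(edges)
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be strictly ascending", call. = FALSE)
  if (any(edges <= 0)) stop("`edges` must be positive", call. = FALSE)
  if (length(edges) > 1) {
    ratio <- edges[-1] / edges[-length(edges)]
    if (any(abs(ratio - 10) > 1e-9))
      stop("each edge must be 10 times the previous (order-of-magnitude bands)",
           call. = FALSE)
  }
  if (split_below_one) {
    if (abs(edges[1] - 1) > 1e-12)
      stop("`split_below_one` requires the first edge to be 1", call. = FALSE)
    edges <- c(0.1, edges)
    labels <- c("<$1", sub("^<\\$10$", "$1-$10", labels))
  }
  if (length(labels) != length(edges))
    stop("need exactly one label per band (", length(edges), ")",
         call. = FALSE)
  structure(list(edges = edges, labels = as.character(labels)),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Assign ACERs to order-of-magnitude bands
#'
#' Classifies unrounded ACER values into the scheme's half-open bands
#' `[edge_k, edge_{k+1})`; values below the first edge map to the lowest
#' band. Negative values (cost-saving) are not banded — they are reported
#' separately — and raise an error.
#'
#' @param acer numeric vector of ACER values, >= 0.
#' @param scheme a [band_scheme()].
#' @return Character vector of band labels (factor-ordered by the scheme).
#' @examples
#' assign_band(c(3, 11, 10, 100), band_scheme())
#' @export
assign_band <- function(acer, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  acer <- as.numeric(acer)
  if (anyNA(acer)) stop("ACER values must not be NA", call. = FALSE)
  if (any(acer < 0))
    stop("negative ACER (cost-saving) entries are listed separately, not banded",
         call. = FALSE)
  idx <- findInterval(acer, scheme$edges)
  idx[idx == 0] <- 1 # below the first edge -> lowest band
  scheme$labels[idx]
}
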