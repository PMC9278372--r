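#' Isoquant plot of cost-effectiveness ratios
#'
#' Scatter of interventions on log-log axes — health gain (HLY) horizontal,
#' present-value cost vertical — with constant-ACER diagonals at the banding
#' scheme's edges. Points on one diagonal share a cost-effectiveness ratio;
#' each diagonal is an order of magnitude apart. Lower points are cheaper,
#' points further right gain more health at the same ratio. Scenarios with
#' non-positive cost or health gain cannot be drawn on log axes and are
#' dropped with a warning.
#'
#' @param clusters a [as_cluster_set()] object (or a scenario data.frame with
#'   `cost_pv`, `hly`, `programme` columns).
#' @param scheme a [band_scheme()] supplying the diagonal ACER levels.
#' @param file optional output path; the plot is written with
#'   [ggplot2::ggsave()].
#' @param width,height device size in inches when `file` is given.
#' @return The ggplot object, invisibly when `file` is written.
#' @export
plot_isoquant <- function(clusters, scheme = band_scheme(), file = NULL,
                          width = 7, height = 5) {
  df <- if (inherits(clusters, "cluster_set")) scenario_table(clusters)
        else as.data.frame(clusters)
  stopifnot(all(c("cost_pv", "hly", "programme") %in% names(df)))
  bad <- df$cost_pv <= 0 | df$hly <= 0
  if (any(bad)) {
    warning(sum(bad), " scenario(s) with non-positive cost or hly dropped ",
            "from the log-log isoquant plot")
    df <- df[!bad, , drop = FALSE]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hly, y = .data$cost_pv)) +
    ggplot2::geom_abline(
      intercept = log10(scheme$edges), slope = 1,
      linetype = "dashed", colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$programme),
                        alpha = 0.8, size = 1.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Healthy life years gained (vs null)",
                  y = "Present-value cost (I$)",
                  colour = "Programme",
                  title = "Cost-effectiveness isoquants",
                  subtitle = paste("Diagonals: ACER =",
                                   paste(scheme$edges, collapse = ", "),
                                   "I$/HLY")) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Plot an expansion path
#'
#' Cumulative health gain (horizontal) against cumulative present-value cost
#' (vertical) from the null outward; the slope of each segment is that
#' step's ICER, so a mathematically optimized path bends upward, ending in a
#' near-vertical final segment.
#'
#' @param path an [build_expansion_path()] result.
#' @param file optional output path.
#' @param width,height device size in inches when `file` is given.
#' @return The ggplot object, invisibly when `file` is written.
#' @export
plot_expansion <- function(path, file = NULL, width = 7, height = 5) {
  stopifnot(inherits(path, "expansion_path"))
  if (nrow(path$steps) == 0) stop("empty path", call. = FALSE)
  df <- rbind(data.frame(cum_hly = 0, cum_cost = 0),
              path$steps[, c("cum_hly", "cum_cost")])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cum_hly,
                                        y = .data$cum_cost)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Cumulative healthy life years gained",
                  y = "Cumulative present-value cost (I$)",
                  title = "Optimized expansion path") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Platform comparison of benefit packages
#'
#' Side-by-side bars of total health gain and per-capita annual cost for a
#' set of per-platform benefit packages, showing which service level drives
#' health gain.
#'
#' @param packages named list of [benefit_package()] objects (names are
#'   platform labels).
#' @param file optional output path.
#' @param width,height device size in inches when `file` is given.
#' @return The ggplot object, invisibly when `file` is written.
#' @export
plot_platform_stack <- function(packages, file = NULL, width = 7,
                                height = 5) {
  stopifnot(length(packages) >= 1,
            all(vapply(packages, inherits, logical(1), "benefit_package")))
  if (is.null(names(packages)))
    names(packages) <- paste0("package_", seq_along(packages))
  df <- do.call(rbind, lapply(names(packages), function(nm) {
    pk <- packages[[nm]]
    data.frame(platform = nm,
               metric = c("Total HLY gained",
                          "Per-capita annual cost (I$)"),
               value = c(pk$total_hly, pk$per_capita_annual_cost))
  }))
  df$platform <- factor(df$platform, levels = names(packages))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$platform,
                                        y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Benefit packages by delivery platform") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
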