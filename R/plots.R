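# ggplot2 views of the result types.

link_colors <- c(V = "#d7191c", T = "#fdae61", Hp = "#2c7bb6",
                 Hap = "#00a6ca", X = "#5e3c99")

#' Plot crosslink populations over time
#'
#' Time courses of the five crosslink-type counts of a census.
#'
#' @param object an `mt_census`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mt_census <- function(object, ...) {
  long <- tidyr::pivot_longer(object[c("time", link_types)],
                              -"time", names_to = "type", values_to = "count")
  long$type <- factor(long$type, levels = link_types)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$count,
                                     colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = link_colors) +
    ggplot2::labs(x = "time (s)", y = "crosslinks", colour = "link type")
}

#' Plot a phase-space scan
#'
#' Classified scan points in a chosen coordinate pair; asters in dark red,
#' graded states on the blue (P = 0.5) to red (P = 1) gradient.
#'
#' @param points scan table from [run_scan()]
#' @param coords `"ratio"`, `"difference"` or `"raw"`
#' @return a ggplot
#' @export
plot_phase_space <- function(points, coords = "ratio") {
  uv <- scan_coordinates(points, coords)
  df <- dplyr::mutate(points, u = uv$u, w = uv$w,
                      fill_val = ifelse(.data$label == "aster", 1,
                                        pmin(pmax(.data$P, 0.5), 1)))
  lab <- switch(coords,
    ratio = c("motors per filament", "vg / vm"),
    difference = c("motors per filament", "vg - vm (um/s)"),
    raw = c("motor number", "vg (um/s)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$w, .data$u)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$fill_val),
                        shape = 21, size = 4, stroke = 0.2) +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                 limits = c(0.5, 1), name = "P (aster = 1)") +
    ggplot2::labs(x = lab[2], y = lab[1])
}

#' Plot a single-filament motor profile
#'
#' Side- and end-bound motor numbers and their ratio against time.
#'
#' @param object a `motor_profile` from [integrate_profile()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.motor_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object[c("t", "ns", "ne", "ratio")], -"t",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Histogram of per-filament velocity-polarity correlations
#' @param object a `vp_sample` from [compute_vp()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.vp_sample <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$vp)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = attr(object, "mean"), colour = "red") +
    ggplot2::labs(x = expression(hat(v) %.% hat(p)), y = "filaments")
}
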