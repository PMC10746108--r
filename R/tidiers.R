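# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @rdname tidiers
#' @param x A `fricke_kinetics`, `fricke_scan` or `fricke_mi` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble (time course or scan rows); `glance()`
#'   a one-row summary.
#' @export
tidy.fricke_kinetics <- function(x, ...) x$kinetics

#' @rdname tidiers
#' @export
glance.fricke_kinetics <- function(x, ...) {
  tibble::tibble(let = x$meta$beam$let,
                 cystamine_conc = x$meta$cystamine_conc,
                 mi_probability = x$meta$mi_probability,
                 G200 = x$G200, G200_se = x$G200_se,
                 replicates = x$meta$replicates,
                 mean_particles = x$meta$mean_particles)
}

#' Tidiers for frickeirt result objects
#'
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.fricke_scan <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.fricke_scan <- function(x, ...) {
  tibble::tibble(n_points = nrow(x), lets = length(unique(x$let)),
                 conc_min = min(x$conc), conc_max = max(x$conc),
                 replicates = attr(x, "meta")$replicates)
}

#' @rdname tidiers
#' @export
tidy.fricke_mi <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.fricke_mi <- function(x, ...) {
  tibble::tibble(let = attr(x, "meta")$let,
                 mi_probability = attr(x, "meta")$mi_probability,
                 max_rel_reduction = max(x$rel_reduction),
                 min_rel_reduction = min(x$rel_reduction))
}

#' Plot methods
#'
#' `autoplot.fricke_kinetics` draws G(Fe3+) against time (log axis) with the
#' per-reaction extents; `autoplot.fricke_scan` the 200-s yield against
#' cystamine concentration per LET; `autoplot.fricke_mi` the paired MI
#' comparison.
#'
#' @param object A result object.
#' @param channels Show the per-reaction ferric extents?
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-frickeirt
NULL

#' @rdname autoplot-frickeirt
#' @export
autoplot.fricke_kinetics <- function(object, channels = TRUE, ...) {
  p <- ggplot2::ggplot(object$kinetics, ggplot2::aes(.data$t_s, .data$G)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "G(Fe3+) (molecules / 100 eV)",
                  colour = "reaction")
  if (channels) {
    keep <- dplyr::filter(object$channels, .data$dG > 1e-4)
    p <- p + ggplot2::geom_line(
      data = keep,
      ggplot2::aes(y = .data$dG, colour = .data$reaction),
      linetype = "dashed")
  }
  p
}

#' @rdname autoplot-frickeirt
#' @export
autoplot.fricke_scan <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     conc_plot = pmax(.data$conc, 1e-7))
  ggplot2::ggplot(d, ggplot2::aes(.data$conc_plot, .data$G200,
                                  colour = factor(.data$let))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[cystamine] (M)", y = "G(Fe3+) at 200 s",
                  colour = "LET (keV/um)")
}

#' @rdname autoplot-frickeirt
#' @export
autoplot.fricke_mi <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("G_off", "G_on"), names_to = "arm",
                           values_to = "G200")
  ggplot2::ggplot(d, ggplot2::aes(pmax(.data$conc, 1e-7), .data$G200,
                                  linetype = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[cystamine] (M)", y = "G(Fe3+) at 200 s",
                  linetype = NULL)
}

#' @export
plot.fricke_kinetics <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.fricke_scan <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.fricke_mi <- function(x, ...) print(autoplot(x, ...))
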