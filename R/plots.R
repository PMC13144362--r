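#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial ring profile
#'
#' Normalised (if present) or raw per-ring means, one line per channel,
#' with scaling-segment boundaries marked.
#'
#' @param object A [ring_profile()] / [piecewise_minmax()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  has_norm <- "normalised" %in% names(object)
  y <- if (has_norm) "normalised" else "raw"
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$ring, y = .data[[y]], colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "ring (anchor → edge)",
                  y = if (has_norm) "min–max scaled intensity" else
                    "mean intensity", colour = NULL) +
    ggplot2::theme_minimal()
  split <- attr(object, "split")
  if (!is.null(split) && split < max(object$ring)) {
    p <- p + ggplot2::geom_vline(xintercept = split + 0.5, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot a normalised FRAP recovery curve
#'
#' @param object A [normalize_frap()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_curve
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$normalised)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = attr(object, "n_prebleach") + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "frame", y = "normalised intensity") +
    ggplot2::theme_minimal()
}

#' Plot an aggregated FRAP mean +/- SD band
#'
#' @param object An [aggregate_curves()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot frap_aggregate
#' @export
autoplot.frap_aggregate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frame", y = "normalised intensity (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot per-line displacement measurements
#'
#' Histogram of accepted signed peak displacements with the mean marked.
#'
#' @param object A [measure_displacements()] tibble.
#' @param binwidth_nm Histogram bin width.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot displacement_measurement
#' @export
autoplot.displacement_measurement <- function(object, binwidth_nm = 10, ...) {
  acc <- dplyr::filter(object, .data$accepted)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$delta_nm)) +
    ggplot2::geom_histogram(binwidth = binwidth_nm, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(acc$delta_nm), colour = "firebrick") +
    ggplot2::labs(x = "displacement (nm, + = towards nucleolar interior)",
                  y = "lines") +
    ggplot2::theme_minimal()
}

#' Plot ranked per-gene screen values
#'
#' Genes ordered by ascending value, top-`k` rounding hits highlighted,
#' and the control reference marked.
#'
#' @param summary A [summarize_screen()] result.
#' @param k Number of highlighted top genes.
#' @return A ggplot.
#' @export
plot_screen_ranking <- function(summary, k = 20L) {
  g <- summary$genes |>
    dplyr::filter(!.data$excluded) |>
    dplyr::arrange(.data$value, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  hit = .data$rank <= k)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$rank, y = .data$value,
                                  colour = .data$hit)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = summary$control_reference,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "magenta3"),
                                 guide = "none") +
    ggplot2::labs(x = "gene rank (rounder → left)",
                  y = "per-gene median aspect ratio") +
    ggplot2::theme_minimal()
}
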