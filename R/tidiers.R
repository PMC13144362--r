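#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-Gaussian profile fit
#'
#' @param x A [fit_gaussian()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "mean_nm", "sigma_nm"),
    estimate = c(x$amplitude, x$mean_nm, x$sigma_nm)
  )
}

#' Glance at a single-Gaussian profile fit
#'
#' @param x A [fit_gaussian()] result.
#' @param ... Unused.
#' @return One-row tibble (`r.squared`, `converged`, `nobs`).
#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, converged = x$converged, nobs = x$n)
}

#' Tidy a chromatic-offset calibration
#'
#' @param x A [bead_chromatic_offset()] result.
#' @param ... Unused.
#' @return Tibble with one row per axis (`axis`, `offset_px`, `offset_nm`,
#'   `dispersion_nm`).
#' @method tidy chromatic_offset
#' @export
tidy.chromatic_offset <- function(x, ...) {
  tibble::tibble(
    axis = c("y", "x"),
    offset_px = unname(x$offset_px),
    offset_nm = unname(x$offset_nm),
    dispersion_nm = unname(x$dispersion_nm)
  )
}

#' Tidy a screen summary
#'
#' @param x A [summarize_screen()] result.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @method tidy screen_summary
#' @export
tidy.screen_summary <- function(x, ...) x$genes

#' Glance at a screen summary
#'
#' @param x A [summarize_screen()] result.
#' @param ... Unused.
#' @return One-row tibble with gene/well counts and the control reference.
#' @method glance screen_summary
#' @export
glance.screen_summary <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_excluded = sum(x$genes$excluded),
    n_control_wells = nrow(x$control_wells),
    control_reference = x$control_reference
  )
}
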