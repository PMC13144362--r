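#' Raw FRAP trace
#'
#' Per-frame mean intensities of the bleached region, a reference region
#' elsewhere in the cell, and a background region outside the cell.
#'
#' @param frame Frame indices.
#' @param bleach,reference,background Per-frame region means.
#' @param n_prebleach Number of pre-bleach frames (>= 1); the bleach event
#'   occurs between frame `n_prebleach` and `n_prebleach + 1`.
#' @return A `"frap_trace"` tibble with attribute `n_prebleach`.
#' @export
frap_trace <- function(frame, bleach, reference, background, n_prebleach) {
  stopifnot(length(frame) == length(bleach),
            length(bleach) == length(reference),
            length(reference) == length(background),
            n_prebleach >= 1L, length(frame) > n_prebleach)
  out <- tibble::tibble(frame = frame, bleach = bleach,
                        reference = reference, background = background)
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  class(out) <- c("frap_trace", class(out))
  out
}

#' Double-normalise a FRAP trace
#'
#' Computes `N(t) = [(B(t) - G(t)) / (R(t) - G(t))] / c`, where `B`, `R`
#' and `G` are the bleach, reference and background traces and `c` is the
#' pre-bleach mean of the same ratio — double normalisation, which cancels
#' acquisition photobleaching (it affects `B` and `R` equally) and pins
#' the pre-bleach level at 1. The plateau is the mean of the final
#' `plateau_frames` frames, and the apparent recovery fraction is
#' `(plateau - floor) / (1 - floor)` with the floor taken from the first
#' post-bleach frame.
#'
#' @param trace A [frap_trace()].
#' @param plateau_frames Number of final frames averaged for the plateau.
#' @return A `"recovery_curve"` tibble (`frame`, `normalised`) with
#'   attributes `plateau`, `postbleach_floor`, `recovery_fraction`,
#'   `n_prebleach`.
#' @export
normalize_frap <- function(trace, plateau_frames = 20L) {
  n_pre <- attr(trace, "n_prebleach")
  stopifnot(!is.null(n_pre))
  denom <- trace$reference - trace$background
  if (any(denom <= 0)) {
    stop("reference - background is non-positive at frame(s) ",
         paste(utils::head(trace$frame[denom <= 0], 5L), collapse = ", "))
  }
  ratio <- (trace$bleach - trace$background) / denom
  pre <- mean(ratio[seq_len(n_pre)])
  if (pre <= 0) stop("non-positive pre-bleach ratio")
  nrm <- ratio / pre
  n <- length(nrm)
  plateau <- mean(nrm[(n - min(plateau_frames, n - n_pre) + 1L):n])
  floor_ <- nrm[n_pre + 1L]
  out <- tibble::tibble(frame = trace$frame, normalised = nrm)
  attr(out, "plateau") <- plateau
  attr(out, "postbleach_floor") <- floor_
  attr(out, "recovery_fraction") <-
    if (floor_ < 1) (plateau - floor_) / (1 - floor_) else NA_real_
  attr(out, "n_prebleach") <- n_pre
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Recovery fraction of a normalised curve
#' @param curve A [normalize_frap()] result.
#' @return Scalar apparent recovery (mobile) fraction.
#' @export
recovery_fraction <- function(curve) attr(curve, "recovery_fraction")

#' Aggregate recovery curves into a mean +/- SD curve
#'
#' Curves on different time bases are resampled onto the first curve's
#' frame grid by linear interpolation before pointwise aggregation.
#'
#' @param curves Non-empty list of [normalize_frap()] results.
#' @return A `"frap_aggregate"` tibble (`frame`, `mean`, `sd`, `n`).
#' @export
aggregate_curves <- function(curves) {
  if (length(curves) == 0L) stop("no curves to aggregate")
  grid <- curves[[1L]]$frame
  vals <- vapply(curves, function(cv) {
    if (identical(cv$frame, grid)) cv$normalised
    else stats::approx(cv$frame, cv$normalised, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  out <- tibble::tibble(
    frame = grid,
    mean = rowMeans(vals),
    sd = apply(vals, 1L, stats::sd),
    n = ncol(vals)
  )
  class(out) <- c("frap_aggregate", class(out))
  out
}

#' Optional single-exponential recovery fit
#'
#' Fits `N(tau) = floor + span (1 - exp(-k tau))` to the post-bleach
#' segment. Provided for exploratory use; the standard normalisation
#' pipeline reports raw recovery curves only.
#'
#' @param curve A [normalize_frap()] result.
#' @return A list (`floor`, `span`, `rate_per_frame`, `plateau`) or `NULL`
#'   if the fit fails.
#' @export
fit_recovery_exponential <- function(curve) {
  n_pre <- attr(curve, "n_prebleach")
  post <- curve[(n_pre + 1L):nrow(curve), ]
  tau <- post$frame - post$frame[1L] + 1
  df <- data.frame(tau = tau, v = post$normalised)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ fl + sp * (1 - exp(-k * tau)), data = df,
                      start = list(fl = df$v[1L],
                                   sp = max(df$v) - df$v[1L], k = 0.05)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  list(floor = unname(co["fl"]), span = unname(co["sp"]),
       rate_per_frame = unname(co["k"]),
       plateau = unname(co["fl"] + co["sp"]))
}
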