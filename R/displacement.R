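#' Two-channel intensity line profile
#'
#' Intensities sampled along an oriented axis running from outside the
#' nucleolus towards its interior, so positive peak displacements point
#' into the nucleolus.
#'
#' @param positions_nm Strictly increasing sample positions (nm); at least
#'   10 samples.
#' @param intensities Numeric matrix, one named column per channel.
#' @param pixel_size_nm Pixel size used for sampling.
#' @param width_px Perpendicular averaging width used at extraction.
#' @param direction Unit `(dy, dx)` image-space direction of the axis.
#' @param id Line identifier.
#' @param true_peaks_nm Optional named true peak positions (synthetic
#'   fixtures).
#' @return A `"line_profile"` object.
#' @export
line_profile <- function(positions_nm, intensities, pixel_size_nm,
                         width_px = 2L, direction = c(0, 1), id = 1L,
                         true_peaks_nm = NULL) {
  stopifnot(length(positions_nm) >= 10L, all(diff(positions_nm) > 0),
            is.matrix(intensities), nrow(intensities) == length(positions_nm),
            !is.null(colnames(intensities)))
  structure(
    list(positions_nm = as.numeric(positions_nm), intensities = intensities,
         pixel_size_nm = pixel_size_nm, width_px = width_px,
         direction = direction / sqrt(sum(direction^2)), id = id,
         true_peaks_nm = true_peaks_nm, normalised = FALSE),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile #%s> %d samples, %.0f-%.0f nm, channels: %s\n",
              x$id, length(x$positions_nm), min(x$positions_nm),
              max(x$positions_nm), paste(colnames(x$intensities), collapse = ", ")))
  invisible(x)
}

#' Reverse the orientation of a line profile
#'
#' Reverses the sampling order and flips the axis direction; measured
#' displacements change sign exactly.
#'
#' @param profile A [line_profile()].
#' @return The reversed profile.
#' @export
reverse_profile <- function(profile) {
  n <- length(profile$positions_nm)
  p0 <- profile$positions_nm[1]
  profile$positions_nm <- rev(max(profile$positions_nm) - profile$positions_nm) + p0
  profile$intensities <- profile$intensities[n:1, , drop = FALSE]
  profile$direction <- -profile$direction
  if (!is.null(profile$true_peaks_nm)) {
    profile$true_peaks_nm <- max(profile$positions_nm) + p0 - profile$true_peaks_nm
  }
  profile
}

#' Extract a line profile from a scene
#'
#' Samples each channel at 1 px steps along the segment from `p_out`
#' (outside the nucleolus) to `p_in` (inside) by bilinear interpolation,
#' averaging over `width_px` parallel lines offset perpendicular to the
#' segment at 1 px spacing.
#'
#' @param scene An [image_scene()].
#' @param p_out,p_in `(y, x)` endpoints in px; at least 10 px apart.
#' @param width_px Perpendicular averaging width in px.
#' @param roles Channels to sample.
#' @param id Line identifier.
#' @return A [line_profile()].
#' @export
extract_line_profile <- function(scene, p_out, p_in, width_px = 2L,
                                 roles = names(scene$channel_roles), id = 1L) {
  p_out <- as.numeric(p_out); p_in <- as.numeric(p_in)
  len <- sqrt(sum((p_in - p_out)^2))
  if (len < 10) stop("endpoints must be at least 10 px apart")
  u <- (p_in - p_out) / len
  v <- c(-u[2], u[1])
  t_steps <- seq(0, floor(len))
  offsets <- (seq_len(width_px) - (width_px + 1) / 2)
  ny <- dim(scene$pixels)[1]; nx <- dim(scene$pixels)[2]
  pts_y <- outer(t_steps * u[1], offsets * v[1], "+") + p_out[1]
  pts_x <- outer(t_steps * u[2], offsets * v[2], "+") + p_out[2]
  if (any(pts_y < 1) || any(pts_y > ny) || any(pts_x < 1) || any(pts_x > nx)) {
    stop("line (including its perpendicular averaging width) leaves the image")
  }
  vals <- vapply(roles, function(role) {
    img <- scene_channel(scene, role)
    rowMeans(matrix(bilinear_at(img, as.vector(pts_y), as.vector(pts_x)),
                    nrow = length(t_steps)))
  }, numeric(length(t_steps)))
  line_profile(positions_nm = t_steps * scene$pixel_size_nm,
               intensities = vals, pixel_size_nm = scene$pixel_size_nm,
               width_px = width_px, direction = u, id = id)
}

# Bilinear interpolation of matrix `img` at fractional (y, x) positions.
bilinear_at <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L); x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]; i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  i00 * (1 - fy) * (1 - fx) + i01 * (1 - fy) * fx +
    i10 * fy * (1 - fx) + i11 * fy * fx
}

#' Background-subtract and sum-normalise a line profile
#'
#' Per channel: subtracts the channel minimum (background correction) and
#' divides by the sum of the subtracted values, so each channel sums to 1.
#' A constant channel has no defined normalisation and raises an error
#' (the profile is rejected).
#'
#' @param profile A [line_profile()].
#' @return The normalised profile.
#' @export
normalize_profile <- function(profile) {
  ints <- profile$intensities
  for (ch in colnames(ints)) {
    v <- ints[, ch] - min(ints[, ch])
    s <- sum(v)
    if (s == 0) stop("channel '", ch, "' is constant; profile rejected")
    ints[, ch] <- v / s
  }
  profile$intensities <- ints
  profile$normalised <- TRUE
  profile
}

#' Fit a single Gaussian to one profile channel
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2))` (no constant
#' offset: profiles are background-subtracted first, so the baseline is
#' ~0). Initialisation is deterministic: `mu0` at the argmax, `A0` at the
#' maximum, `sigma0` from the half-width at half-maximum divided by 1.177.
#'
#' @param positions_nm Sample positions.
#' @param values Channel values (normalised).
#' @return A `"gaussian_fit"` with amplitude, `mean_nm`, `sigma_nm`,
#'   `r_squared` and a `converged` flag.
#' @export
fit_gaussian <- function(positions_nm, values) {
  i_max <- which.max(values)
  mu0 <- positions_nm[i_max]; a0 <- values[i_max]
  above <- which(values >= a0 / 2)
  hwhm <- max(diff(range(positions_nm[above])) / 2,
              mean(diff(positions_nm)) / 2)
  sigma0 <- hwhm / 1.177
  df <- data.frame(x = positions_nm, v = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
                      start = list(A = a0, mu = mu0, sig = sigma0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, mean_nm = NA_real_,
                          sigma_nm = NA_real_, r_squared = NA_real_,
                          converged = FALSE, n = length(values)),
                     class = "gaussian_fit"))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((values - mean(values))^2)
  structure(
    list(amplitude = unname(co["A"]), mean_nm = unname(co["mu"]),
         sigma_nm = abs(unname(co["sig"])),
         r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
         converged = TRUE, n = length(values)),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.1f nm, sigma = %.1f nm, R2 = %.4f (%s)\n",
              x$mean_nm, x$sigma_nm, x$r_squared,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Measure the signed peak displacement between two channels
#'
#' Normalises the profile, fits a single Gaussian per channel and reports
#' `delta_nm = mean(channel a) - mean(channel b)` along the
#' outside-to-inside axis (positive = channel a displaced towards the
#' nucleolar interior). When a bead-derived [chromatic offset]
#' [bead_chromatic_offset()] is supplied, its 2D mean offset projected
#' onto the line direction is subtracted. The measurement is accepted only
#' when both fits converge with `r_squared >= r2_min` and both sigmas lie
#' inside `sigma_band_px * pixel size` — the automated stand-in for manual
#' rejection of badly fitted profiles.
#'
#' @param profile A [line_profile()].
#' @param role_a,role_b Channel names in the profile.
#' @param correction Optional `"chromatic_offset"` for the (a, b) pair.
#' @param r2_min Minimum per-channel goodness of fit.
#' @param sigma_band_px Acceptable sigma range in pixel-size multiples.
#' @return A one-row `"displacement_measurement"` tibble.
#' @export
measure_displacement <- function(profile, role_a = "a", role_b = "b",
                                 correction = NULL, r2_min = 0.8,
                                 sigma_band_px = c(0.5, 10)) {
  reason <- NA_character_
  norm <- tryCatch(normalize_profile(profile), error = function(e) NULL)
  if (is.null(norm)) {
    fit_a <- fit_b <- structure(list(amplitude = NA_real_, mean_nm = NA_real_,
                                     sigma_nm = NA_real_, r_squared = NA_real_,
                                     converged = FALSE, n = 0L),
                                class = "gaussian_fit")
    reason <- "constant_channel"
  } else {
    fit_a <- fit_gaussian(norm$positions_nm, norm$intensities[, role_a])
    fit_b <- fit_gaussian(norm$positions_nm, norm$intensities[, role_b])
  }
  delta <- fit_a$mean_nm - fit_b$mean_nm
  corr_nm <- 0
  if (!is.null(correction) && is.finite(delta)) {
    stopifnot(inherits(correction, "chromatic_offset"))
    corr_nm <- sum(correction$offset_nm * profile$direction)
    delta <- delta - corr_nm
  }
  sig_lo <- sigma_band_px[1] * profile$pixel_size_nm
  sig_hi <- sigma_band_px[2] * profile$pixel_size_nm
  if (is.na(reason)) {
    if (!fit_a$converged || !fit_b$converged) reason <- "no_convergence"
    else if (fit_a$r_squared < r2_min || fit_b$r_squared < r2_min) reason <- "poor_fit"
    else if (fit_a$sigma_nm < sig_lo || fit_a$sigma_nm > sig_hi ||
             fit_b$sigma_nm < sig_lo || fit_b$sigma_nm > sig_hi) reason <- "sigma_band"
  }
  out <- tibble::tibble(
    line_id = profile$id, mu_a_nm = fit_a$mean_nm, mu_b_nm = fit_b$mean_nm,
    sigma_a_nm = fit_a$sigma_nm, sigma_b_nm = fit_b$sigma_nm,
    r2_a = fit_a$r_squared, r2_b = fit_b$r_squared,
    delta_nm = delta, correction_nm = corr_nm,
    accepted = is.na(reason), reason = reason
  )
  class(out) <- c("displacement_measurement", class(out))
  out
}

#' Measure displacements for a list of line profiles
#'
#' @param profiles List of [line_profile()] objects.
#' @inheritParams measure_displacement
#' @return A `"displacement_measurement"` tibble, one row per line.
#' @export
measure_displacements <- function(profiles, role_a = "a", role_b = "b",
                                  correction = NULL, r2_min = 0.8,
                                  sigma_band_px = c(0.5, 10)) {
  out <- purrr::map_dfr(profiles, measure_displacement, role_a = role_a,
                        role_b = role_b, correction = correction,
                        r2_min = r2_min, sigma_band_px = sigma_band_px)
  class(out) <- c("displacement_measurement", class(out))
  out
}

#' Aggregate accepted displacement measurements
#'
#' Pools accepted lines (the convention for reporting `mean +/- SD, n`).
#'
#' @param measurements A [measure_displacements()] tibble.
#' @return One-row tibble (`n_lines`, `n_accepted`, `mean_delta_nm`,
#'   `sd_delta_nm`).
#' @export
summarize_displacement <- function(measurements) {
  acc <- dplyr::filter(measurements, .data$accepted)
  tibble::tibble(
    n_lines = nrow(measurements), n_accepted = nrow(acc),
    mean_delta_nm = mean(acc$delta_nm), sd_delta_nm = stats::sd(acc$delta_nm)
  )
}

#' Bead-based chromatic offset between two channels
#'
#' Detects beads as local intensity maxima in each channel, refines their
#' positions to sub-pixel accuracy by the intensity-weighted centroid of a
#' 5x5 window (after subtracting the window minimum), matches mutually
#' nearest pairs within `match_radius_px`, and reports the mean `(dy, dx)`
#' offset of channel a relative to channel b with its per-axis dispersion.
#' At least `min_beads` matched pairs are required.
#'
#' @param bead_scene Two-channel bead [image_scene()].
#' @param role_a,role_b Channel roles.
#' @param match_radius_px Maximum pairing distance.
#' @param min_beads Minimum number of matched pairs.
#' @return A `"chromatic_offset"` object with `offset_px`, `offset_nm`,
#'   `dispersion_nm` and `n_beads`.
#' @export
bead_chromatic_offset <- function(bead_scene, role_a, role_b,
                                  match_radius_px = 3, min_beads = 5L) {
  pa <- detect_peaks(scene_channel(bead_scene, role_a))
  pb <- detect_peaks(scene_channel(bead_scene, role_b))
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("bead detection failed (", nrow(pa), " / ", nrow(pb), " peaks)")
  }
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  nearest_b <- apply(d2, 1L, which.min)
  nearest_a <- apply(d2, 2L, which.min)
  mutual <- which(nearest_a[nearest_b] == seq_len(nrow(pa)))
  keep <- mutual[sqrt(d2[cbind(mutual, nearest_b[mutual])]) <= match_radius_px]
  if (length(keep) < min_beads) {
    stop("only ", length(keep), " matched bead pair(s); at least ",
         min_beads, " required")
  }
  d <- pa[keep, , drop = FALSE] - pb[nearest_b[keep], , drop = FALSE]
  structure(
    list(roles = c(role_a, role_b),
         offset_px = colMeans(d),
         offset_nm = colMeans(d) * bead_scene$pixel_size_nm,
         dispersion_nm = apply(d, 2L, stats::sd) * bead_scene$pixel_size_nm,
         n_beads = length(keep),
         pixel_size_nm = bead_scene$pixel_size_nm),
    class = "chromatic_offset"
  )
}

#' @export
print.chromatic_offset <- function(x, ...) {
  cat(sprintf("<chromatic_offset %s-%s> (dy, dx) = (%.1f, %.1f) nm from %d beads\n",
              x$roles[1], x$roles[2], x$offset_nm[1], x$offset_nm[2], x$n_beads))
  invisible(x)
}

# Local-maximum bead detection with 5x5 weighted-centroid refinement.
detect_peaks <- function(img, border = 3L) {
  ny <- nrow(img); nx <- ncol(img)
  thr <- stats::median(img) + 0.25 * (max(img) - stats::median(img))
  is_max <- img >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy); xs <- max(1, 1 + dx):min(nx, nx + dx)
    shifted[ys - dy, xs - dx] <- img[ys, xs]
    is_max <- is_max & (img >= shifted)
  }
  is_max[c(seq_len(border), ny - seq_len(border) + 1L), ] <- FALSE
  is_max[, c(seq_len(border), nx - seq_len(border) + 1L)] <- FALSE
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0L) return(matrix(numeric(0), 0, 2))
  t(apply(peaks, 1L, function(p) {
    ys <- (p[1] - 2L):(p[1] + 2L); xs <- (p[2] - 2L):(p[2] + 2L)
    w <- img[ys, xs] - min(img[ys, xs])
    s <- sum(w)
    if (s == 0) return(as.numeric(p))
    c(sum(row_grid(5L, 5L) * w), sum(col_grid(5L, 5L) * w)) / s - 3 + as.numeric(p)
  }))
}
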