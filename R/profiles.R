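#' Chromatin enrichment ratios in interior, rim and nucleoplasm
#'
#' For each nucleus, the mean channel intensity of every child nucleolus's
#' interior (and rim) is averaged across the nucleolar children first, and
#' the average is then divided by the mean intensity in the parent
#' nucleus's nucleoplasm. Ratios are 1 for a uniform image by
#' construction. Nuclei whose interior or rim is empty, or whose
#' nucleoplasm mean is zero, are flagged and get `NA` ratios.
#'
#' @param partition A [make_partition()] result.
#' @param scene An [image_scene()].
#' @param role Channel role to quantify (e.g. `"chromatin"`).
#' @return Tibble (`nucleus`, `channel`, `interior_ratio`, `rim_ratio`,
#'   `nucleoplasm_mean`, `flag`).
#' @export
enrichment <- function(partition, scene, role) {
  stopifnot(inherits(partition, "region_partition"))
  img <- scene_channel(scene, role)
  stopifnot(all(dim(img) == dim(partition$interior_labels)))
  int_means <- label_means(partition$interior_labels, img)
  rim_means <- label_means(partition$rim_labels, img)
  np_means <- label_means(partition$nucleoplasm_labels, img)
  parent_of <- partition$parent_of
  nuclei <- sort(unique(unname(parent_of)))
  purrr::map_dfr(nuclei, function(p) {
    children <- names(parent_of)[parent_of == p]
    im <- int_means[names(int_means) %in% children]
    rm_ <- rim_means[names(rim_means) %in% children]
    np <- if (as.character(p) %in% names(np_means)) np_means[[as.character(p)]] else NA_real_
    flag <- NA_character_
    if (length(im) == 0L || length(rm_) == 0L) flag <- "empty_region"
    if (is.na(np) || np == 0) flag <- paste(stats::na.omit(c(flag, "zero_nucleoplasm")),
                                            collapse = ";")
    ok <- is.na(flag)
    tibble::tibble(
      nucleus = p, channel = role,
      interior_ratio = if (ok) mean(im) / np else NA_real_,
      rim_ratio = if (ok) mean(rm_) / np else NA_real_,
      nucleoplasm_mean = np, flag = flag
    )
  })
}

#' Concentric edge-conforming ring map
#'
#' Assigns every pixel of `region_mask` to one of `n_rings` concentric
#' rings running from an anchor point (ring 1) to the mask edge (ring
#' `n_rings`). The normalised radial coordinate of pixel `p` is
#' `f(p) = D_a(p) / (D_a(p) + D_e(p))`, where `D_a` is the Euclidean
#' distance to the anchor and `D_e` the Euclidean distance to the nearest
#' non-mask pixel; the ring index is `min(n_rings, floor(f n_rings) + 1)`.
#' For irregular masks the rings conform to the mask edge instead of being
#' circular.
#'
#' @param anchor `(y, x)` anchor, which must lie inside the mask.
#' @param region_mask Logical matrix.
#' @param n_rings Number of rings (>= 2).
#' @return Integer matrix of ring indices (0 outside the mask).
#' @export
ring_map <- function(anchor, region_mask, n_rings = 50L) {
  stopifnot(n_rings >= 2L)
  region_mask <- region_mask != 0
  ay <- anchor[1]; ax <- anchor[2]
  ai <- round(c(ay, ax))
  if (ai[1] < 1 || ai[1] > nrow(region_mask) || ai[2] < 1 ||
      ai[2] > ncol(region_mask) || !region_mask[ai[1], ai[2]]) {
    stop("anchor must lie inside the region mask")
  }
  Y <- row_grid(nrow(region_mask), ncol(region_mask))
  X <- col_grid(nrow(region_mask), ncol(region_mask))
  d_a <- sqrt((Y - ay)^2 + (X - ax)^2)
  d_e <- distance_in_mask(region_mask)
  f <- d_a / (d_a + d_e)
  ring <- matrix(0L, nrow(region_mask), ncol(region_mask))
  ring[region_mask] <- as.integer(pmin(n_rings, floor(f[region_mask] * n_rings) + 1))
  ring
}

#' Per-ring mean intensities
#'
#' Measures the mean raw intensity of each channel within each ring of a
#' ring-index image. Rings containing no pixels are reported as missing
#' (`NA`), not zero, so later min-max scaling is not distorted.
#'
#' @param ring_image Integer ring-index matrix from [ring_map()].
#' @param scene An [image_scene()].
#' @param roles Channel roles to measure.
#' @return A `"radial_profile"` tibble (`ring`, `channel`, `raw`, `n_px`).
#' @export
ring_profile <- function(ring_image, scene, roles = names(scene$channel_roles)) {
  n_rings <- max(ring_image)
  stopifnot(n_rings >= 1L)
  counts <- tabulate(ring_image[ring_image > 0L], nbins = n_rings)
  out <- purrr::map_dfr(roles, function(role) {
    img <- scene_channel(scene, role)
    sums <- vapply(seq_len(n_rings), function(r) sum(img[ring_image == r]),
                   numeric(1))
    tibble::tibble(ring = seq_len(n_rings), channel = role,
                   raw = ifelse(counts > 0, sums / counts, NA_real_),
                   n_px = counts)
  })
  class(out) <- c("radial_profile", class(out))
  out
}

#' Piecewise min-max scaling of a radial profile
#'
#' Rescales each channel's ring means to `[0, 1]` independently within the
#' segment of rings `1..split` and the segment `split+1..n` (the
#' convention for 50-ring profiles is `split = 15`: rings 1-15 around the
#' chromatin focus, rings 16-50 around the nucleolar rim). A constant
#' segment maps to all zeros; missing rings are excluded from the min/max
#' and stay missing. Applying the scaling twice is a no-op.
#'
#' @param profile A [ring_profile()] tibble.
#' @param split Last ring of the first scaling segment (`1 <= split`);
#'   a split at or beyond the last ring leaves a single segment.
#' @return The profile with columns `segment` and `normalised` added.
#' @export
piecewise_minmax <- function(profile, split = 15L) {
  stopifnot(split >= 1L)
  out <- profile |>
    dplyr::mutate(segment = ifelse(.data$ring <= split, 1L, 2L)) |>
    dplyr::group_by(.data$channel, .data$segment) |>
    dplyr::mutate(normalised = minmax_scale(.data$raw)) |>
    dplyr::ungroup()
  class(out) <- unique(c("radial_profile", class(out)))
  attr(out, "split") <- split
  out
}

minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1])) return(rep(NA_real_, length(x)))
  if (diff(r) == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - r[1]) / diff(r)
}

#' Centre-to-edge radial profile of one nucleolus
#'
#' Divides a nucleolar mask into `n_bins` concentric bins from its
#' centroid to the mask edge (the same edge-conforming construction as
#' [ring_map()]), measures per-bin channel means, and min-max scales each
#' channel over the whole profile. If the centroid falls outside the mask
#' (crescent shapes) the anchor snaps to the nearest mask pixel and the
#' profile is flagged.
#'
#' @param nucleoli A [label_map()] (or label matrix).
#' @param label Nucleolus label to profile.
#' @param scene An [image_scene()].
#' @param n_bins Number of radial bins.
#' @param roles Channel roles to measure.
#' @return A `"radial_profile"` tibble with attribute `anchor_snapped`.
#' @export
sector_profile <- function(nucleoli, label, scene, n_bins = 10L,
                           roles = names(scene$channel_roles)) {
  nl <- label_matrix(nucleoli)
  mask <- nl == label
  if (!any(mask)) stop("label ", label, " is empty")
  idx <- which(mask, arr.ind = TRUE)
  anchor <- c(mean(idx[, 1]), mean(idx[, 2]))
  ai <- round(anchor)
  snapped <- FALSE
  if (!mask[ai[1], ai[2]]) {
    d2 <- (idx[, 1] - anchor[1])^2 + (idx[, 2] - anchor[2])^2
    anchor <- as.numeric(idx[which.min(d2), ])
    snapped <- TRUE
  }
  rings <- ring_map(anchor, mask, n_rings = n_bins)
  prof <- ring_profile(rings, scene, roles = roles) |>
    piecewise_minmax(split = n_bins)
  attr(prof, "anchor_snapped") <- snapped
  attr(prof, "anchor") <- anchor
  prof
}

#' Pearson correlation of two channels within a mask
#'
#' @param scene An [image_scene()].
#' @param role_a,role_b Channel roles.
#' @param mask Logical matrix of pixels to correlate (e.g. a nucleolar
#'   mask).
#' @return Tibble (`channel_a`, `channel_b`, `n_px`, `r`, `flag`); `r` is
#'   `NA` (flagged) when either channel is constant in the mask.
#' @export
pearson_in_mask <- function(scene, role_a, role_b, mask) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  a <- scene_channel(scene, role_a)[mask]
  b <- scene_channel(scene, role_b)[mask]
  constant <- stats::sd(a) == 0 || stats::sd(b) == 0
  tibble::tibble(
    channel_a = role_a, channel_b = role_b, n_px = sum(mask),
    r = if (constant) NA_real_ else stats::cor(a, b),
    flag = if (constant) "constant_channel" else NA_character_
  )
}
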