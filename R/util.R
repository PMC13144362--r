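# Low-level image helpers shared across modules.

# Otsu threshold on a numeric vector of intensities. Values are binned into
# `n_bins` equal-width bins over their range; returns the bin-edge threshold
# maximising between-class variance. Constant input returns NA.
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(n_bins, floor((values - rng[1]) / diff(rng) * n_bins) + 1L),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# Three-class Otsu: the pair of thresholds (t1 < t2) maximising
# between-class variance over three classes; returns t1 (the cut below
# the middle class). Used for channels whose foreground contains a very
# bright substructure (e.g. a chromatin channel with a bright
# peri-nucleolar rim), where two-class Otsu would segment only the bright
# mode: the middle and upper classes together form the foreground.
otsu_threshold3 <- function(values, n_bins = 128L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(n_bins, floor((values - rng[1]) / diff(rng) * n_bins) + 1L),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  cw <- c(0, cumsum(p)); cm <- c(0, cumsum(p * centers))
  best <- -Inf; best_t1 <- 1L
  for (t1 in 1:(n_bins - 2L)) {
    w0 <- cw[t1 + 1L]
    if (w0 <= 0) next
    m0 <- cm[t1 + 1L] / w0
    t2 <- (t1 + 1L):(n_bins - 1L)
    w1 <- cw[t2 + 1L] - cw[t1 + 1L]
    w2 <- 1 - cw[t2 + 1L]
    m1 <- (cm[t2 + 1L] - cm[t1 + 1L]) / w1
    m2 <- (cm[n_bins + 1L] - cm[t2 + 1L]) / w2
    mt <- cm[n_bins + 1L]
    v <- w0 * (m0 - mt)^2 + w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2
    v[!is.finite(v)] <- -Inf
    if (max(v) > best) { best <- max(v); best_t1 <- t1 }
  }
  rng[1] + best_t1 / n_bins * diff(rng)
}

# Connected-component labelling with 8-connectivity. EBImage::bwlabel uses
# 4-connectivity, so diagonally adjacent 4-components are merged afterwards.
label_components <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) vs (i+1, j+1) and (i+1, j) vs (i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  for (pr in list(cbind(as.vector(a1), as.vector(b1)),
                  cbind(as.vector(a2), as.vector(b2)))) {
    keep <- pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2]
    if (any(keep)) {
      pairs <- unique(pr[keep, , drop = FALSE])
      for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# Exact Euclidean distance (in px) from every pixel to the nearest TRUE
# pixel of `mask`; 0 on the mask itself. Implemented with EBImage's exact
# Euclidean distance map of the complement.
distance_to_mask <- function(mask) {
  m <- matrix(as.numeric(mask == 0), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

# Distance from every mask pixel to the nearest non-mask pixel (>= 1 on the
# mask, 0 off it).
distance_in_mask <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

#' Binary erosion and dilation by a Euclidean disc
#'
#' Distance-threshold morphology, the "shrink/expand" primitive of the
#' partition algebra: erosion keeps mask pixels strictly farther than `k`
#' from the background, dilation adds background pixels within `k` of the
#' mask. Equivalent to a disc structuring element and exactly testable
#' against a brute-force distance transform.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param k Radius in px.
#' @return Logical matrix.
#' @export
erode_disc <- function(mask, k) {
  distance_in_mask(mask) > k
}

#' @rdname erode_disc
#' @export
dilate_disc <- function(mask, k) {
  mask != 0 | distance_to_mask(mask) <= k
}

fill_holes <- function(mask) {
  as.matrix(EBImage::fillHull(matrix(as.numeric(mask != 0), nrow(mask),
                                     ncol(mask)))) != 0
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma_px))
}

# Sub-pixel translation by (dy, dx) px via the Fourier shift theorem.
fourier_shift <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  phase <- exp(-2i * pi * (outer(fy * dy, fx * dx, "+")))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nr * nc)
}

# Per-label means of `values` over a label image; returns named numeric
# vector indexed by label.
label_means <- function(labels, values) {
  idx <- labels > 0L
  if (!any(idx)) return(stats::setNames(numeric(0), character(0)))
  tapply(values[idx], labels[idx], mean)
}

# Pixel coordinate grids (1-based pixel centres).
row_grid <- function(nr, nc) matrix(seq_len(nr), nr, nc)
col_grid <- function(nr, nc) matrix(seq_len(nc), nr, nc, byrow = TRUE)
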