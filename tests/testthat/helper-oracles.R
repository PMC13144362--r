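# Brute-force oracles, independent of the package's implementation paths.

# Per-pixel Euclidean distance from every mask pixel to the nearest
# non-mask pixel (in-image), by exhaustive pairwise search.
bf_dist_in <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Distance from every pixel to the nearest mask pixel.
bf_dist_to <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(nrow(bg))) {
    out[bg[i, 1], bg[i, 2]] <-
      sqrt(min((fg[, 1] - bg[i, 1])^2 + (fg[, 2] - bg[i, 2])^2))
  }
  out
}

# Brute-force ring binning: f = D_a / (D_a + D_e) per pixel.
bf_ring_map <- function(anchor, mask, n_rings) {
  d_in <- bf_dist_in(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    da <- sqrt((fg[i, 1] - anchor[1])^2 + (fg[i, 2] - anchor[2])^2)
    f <- da / (da + d_in[fg[i, 1], fg[i, 2]])
    out[fg[i, 1], fg[i, 2]] <- as.integer(min(n_rings, floor(f * n_rings) + 1))
  }
  out
}

bf_erode <- function(mask, k) mask & bf_dist_in(mask) > k
bf_dilate <- function(mask, k) mask | bf_dist_to(mask) <= k

# Gaussian blur with zero padding (mass near the border leaves the frame,
# as in a real defocused acquisition).
blur_zero <- function(img, sigma) {
  brush <- EBImage::makeBrush(2 * ceiling(3 * sigma) + 1, "gaussian",
                              sigma = sigma)
  pmax(as.matrix(EBImage::filter2(img, brush, boundary = 0)), 0)
}

# Rasterise a Fourier-perturbed boundary (circle for no irregularity) as
# a logical mask.
raster_shape <- function(center, r0, irregularity = list(), ny = 96, nx = 96) {
  Y <- matrix(seq_len(ny), ny, nx); X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  dy <- Y - center[1]; dx <- X - center[2]
  th <- atan2(dy, dx)
  r <- rep(1, length(th))
  for (m in irregularity) r <- r + m[2] * cos(m[1] * th + m[3])
  matrix(sqrt(dy^2 + dx^2) <= r0 * r, ny, nx)
}

raster_ellipse <- function(center, ay, ax, ny = 128, nx = 128, angle = 0) {
  Y <- matrix(seq_len(ny), ny, nx); X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  dy <- Y - center[1]; dx <- X - center[2]
  u <- dy * cos(angle) - dx * sin(angle)
  v <- dy * sin(angle) + dx * cos(angle)
  (u / ay)^2 + (v / ax)^2 <= 1
}

# A random small mask for oracle comparisons: disc, ellipse or
# Fourier-irregular blob, away from the image border.
random_mask <- function(seed, ny = 72, nx = 72) {
  set.seed(seed)
  kind <- sample(c("disc", "ellipse", "fourier"), 1)
  c0 <- c(runif(1, 30, ny - 30), runif(1, 30, nx - 30))
  if (kind == "disc") {
    raster_shape(c0, runif(1, 10, 20), ny = ny, nx = nx)
  } else if (kind == "ellipse") {
    raster_ellipse(c0, runif(1, 8, 16), runif(1, 12, 22), ny = ny, nx = nx,
                   angle = runif(1, 0, pi))
  } else {
    raster_shape(c0, runif(1, 10, 18),
                 irregularity = list(c(sample(2:5, 1), runif(1, 0.05, 0.25),
                                       runif(1, 0, 2 * pi))),
                 ny = ny, nx = nx)
  }
}

# Plain bilinear interpolation, written independently of the package's
# sampling code.
bilinear_at_oracle <- function(img, y, x) {
  vapply(seq_along(y), function(i) {
    y0 <- floor(y[i]); x0 <- floor(x[i])
    fy <- y[i] - y0; fx <- x[i] - x0
    img[y0, x0] * (1 - fy) * (1 - fx) + img[y0, x0 + 1] * (1 - fy) * fx +
      img[y0 + 1, x0] * fy * (1 - fx) + img[y0 + 1, x0 + 1] * fy * fx
  }, numeric(1))
}

# Single-channel scene wrapper around a plain matrix.
matrix_scene <- function(img, roles = c(chromatin = 1L), pixel_size_nm = 40) {
  image_scene(array(img, c(nrow(img), ncol(img), 1L)), pixel_size_nm, roles)
}

# Standard segmentation front-end used across tests: nuclei from the
# chromatin channel (three-class Otsu: the rim band is much brighter than
# the nucleoplasm), nucleoli from the fill channel, children linked.
segment_standard <- function(scene) {
  nuclei <- segment_regions(scene, "chromatin", min_area_px = 1000L,
                            window_px = 101L, kind = "nucleus",
                            otsu_classes = 3L)
  nucleoli <- segment_regions(scene, "nucleolus", min_area_px = 200L,
                              window_px = 51L, kind = "nucleolus")
  list(nuclei = nuclei, nucleoli = assign_children(nucleoli, nuclei))
}
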