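test_that("ring map equals the brute-force oracle pixel for pixel", {
  # disc with centre anchor: ring boundaries at radii i*R/n within 1 px
  disc <- raster_shape(c(36, 36), 25, ny = 72, nx = 72)
  rm_ <- ring_map(c(36, 36), disc, n_rings = 5L)
  Y <- matrix(1:72, 72, 72); X <- t(Y)
  r <- sqrt((Y - 36)^2 + (X - 36)^2)
  for (i in 1:5) {
    sel <- rm_ == i
    expect_gte(min(r[sel]), (i - 1) * 25 / 5 - 1)
    expect_lte(max(r[sel]), i * 25 / 5 + 1)
  }
  # partition: each mask pixel in exactly one ring
  expect_identical(sum(rm_ > 0L), sum(disc))
  expect_identical(rm_ > 0L, disc)

  for (seed in 1:8) {
    mask <- random_mask(seed)
    idx <- which(mask, arr.ind = TRUE)
    anchor <- idx[sample.int(nrow(idx), 1L), ]
    expect_identical(ring_map(anchor, mask, 50L),
                     bf_ring_map(anchor, mask, 50L))
  }

  expect_error(ring_map(c(1, 1), disc, 10L), "anchor")
})

test_that("anchor on the mask edge still yields a gapless ring partition", {
  for (seed in 1:5) {
    disc <- raster_shape(c(36, 36), runif(1, 12, 20), ny = 72, nx = 72)
    idx <- which(disc & !bf_erode(disc, 1.5), arr.ind = TRUE)  # edge pixels
    set.seed(seed)
    anchor <- idx[sample.int(nrow(idx), 1L), ]
    rm_ <- ring_map(anchor, disc, 20L)
    # f ~ 0 only at the anchor itself: ring 1 is exactly the anchor pixel
    expect_identical(which(rm_ == 1L),
                     unname((anchor[2] - 1L) * 72L + anchor[1]))
    # one pixel away from the anchor f >= 1/3 already (De is 1-Lipschitz
    # in Da), so rings 2..n/3 are structurally empty; the mask edge
    # attains the final ring and the partition is complete
    occupied <- sort(unique(rm_[rm_ > 0L]))
    expect_identical(occupied[1], 1L)
    expect_gte(occupied[2], 20L %/% 3L)
    expect_identical(max(occupied), 20L)
    expect_identical(sum(rm_ > 0L), sum(disc))
  }
})

test_that("ring profiles average raw intensities and keep empty rings missing", {
  disc <- raster_shape(c(36, 36), 20, ny = 72, nx = 72)
  rm_ <- ring_map(c(36, 36), disc, 10L)
  sc <- matrix_scene(matrix(7.5, 72, 72))
  prof <- ring_profile(rm_, sc)
  expect_equal(prof$raw, rep(7.5, 10))

  # synthetic shell at the boundary peaks in the expected ring
  shell <- exp(-(sqrt((matrix(1:72, 72, 72) - 36)^2 + (t(matrix(1:72, 72, 72)) - 36)^2) - 20)^2 / 8)
  sp <- ring_profile(rm_, matrix_scene(shell))
  # geometry oracle: boundary pixels have f ~ Da/(Da+De) ~ 1 -> last ring
  expect_lte(abs(sp$ring[which.max(sp$raw)] - 10), 2)

  # a ring index with no pixels stays missing
  rm2 <- rm_; rm2[rm_ == 4L] <- 3L
  p2 <- ring_profile(rm2, sc)
  expect_true(is.na(p2$raw[p2$ring == 4]))
  expect_identical(p2$n_px[p2$ring == 4], 0L)
})

test_that("piecewise min-max scaling hits 0 and 1 per segment and is idempotent", {
  prof <- tibble::tibble(ring = 1:6, channel = "chromatin",
                         raw = c(2, 4, 6, 3, 3, 3), n_px = 10L)
  class(prof) <- c("radial_profile", class(prof))
  out <- piecewise_minmax(prof, split = 3L)
  expect_equal(out$normalised[1:3], c(0, 0.5, 1))
  expect_equal(out$normalised[4:6], c(0, 0, 0))   # constant segment

  set.seed(5)
  for (i in 1:20) {
    p <- tibble::tibble(ring = 1:50,
                        channel = rep(c("a", "b"), each = 25)[sample.int(50)],
                        raw = runif(50), n_px = 5L)
    class(p) <- c("radial_profile", class(p))
    o <- piecewise_minmax(p, split = 15L)
    sums <- dplyr::summarise(dplyr::group_by(o, .data$channel, .data$segment),
                             lo = min(.data$normalised), hi = max(.data$normalised))
    expect_true(all(sums$lo == 0 & sums$hi == 1))
    # idempotence on already-scaled values
    o2 <- o; o2$raw <- o$normalised
    o3 <- piecewise_minmax(o2, split = 15L)
    expect_equal(o3$normalised, o$normalised)
  }

  # missing rings are excluded from min/max and stay missing
  pm <- tibble::tibble(ring = 1:4, channel = "a", raw = c(1, NA, 3, 5), n_px = 1L)
  class(pm) <- c("radial_profile", class(pm))
  om <- piecewise_minmax(pm, split = 4L)
  expect_equal(om$normalised, c(0, NA, 0.5, 1))
})

test_that("sector profiles run centre to edge with centroid snapping for crescents", {
  disc <- raster_shape(c(36, 36), 20, ny = 72, nx = 72)
  sc <- matrix_scene(matrix(3, 72, 72))
  prof <- sector_profile(label_map(disc, "nucleolus"), 1L, sc)
  expect_equal(unique(prof$raw), 3)
  expect_false(attr(prof, "anchor_snapped"))

  # radial gradient increasing outward -> strictly increasing profile
  Y <- matrix(1:72, 72, 72); X <- t(Y)
  grad <- sqrt((Y - 36)^2 + (X - 36)^2)
  pg <- sector_profile(label_map(disc, "nucleolus"), 1L, matrix_scene(grad))
  expect_true(all(diff(pg$normalised) > 0))
  expect_equal(range(pg$normalised), c(0, 1))

  # crescent: centroid outside the mask snaps to the nearest mask pixel
  crescent <- disc & !raster_shape(c(36, 30), 16, ny = 72, nx = 72)
  pc <- sector_profile(label_map(crescent, "nucleolus"), 1L, sc, n_bins = 8L)
  expect_true(attr(pc, "anchor_snapped"))
  rm_c <- ring_map(attr(pc, "anchor"), crescent, 8L)
  expect_identical(sum(rm_c > 0L), sum(crescent))  # still a full partition
})

test_that("masked Pearson correlation behaves at its analytic anchors", {
  set.seed(9)
  a <- matrix(runif(72 * 72), 72, 72)
  sc2 <- image_scene(array(c(a, 1 - a), c(72, 72, 2)), 40,
                     c(marker_a = 1L, marker_b = 2L))
  mask <- raster_shape(c(36, 36), 20, ny = 72, nx = 72)
  self <- pearson_in_mask(
    image_scene(array(c(a, a), c(72, 72, 2)), 40,
                c(marker_a = 1L, marker_b = 2L)), "marker_a", "marker_b", mask)
  expect_lt(abs(self$r - 1), 1e-12)
  neg <- pearson_in_mask(sc2, "marker_a", "marker_b", mask)
  expect_lt(abs(neg$r + 1), 1e-12)

  const <- image_scene(array(c(a, matrix(2, 72, 72)), c(72, 72, 2)), 40,
                       c(marker_a = 1L, marker_b = 2L))
  fc <- pearson_in_mask(const, "marker_a", "marker_b", mask)
  expect_true(is.na(fc$r))
  expect_identical(fc$flag, "constant_channel")

  # independent channels: |r| < 0.05 in at least 95% of 60 seeds
  hits <- vapply(1:60, function(s) {
    set.seed(s + 100)
    x <- matrix(rnorm(100 * 100), 100, 100)
    y <- matrix(rnorm(100 * 100), 100, 100)
    sc <- image_scene(array(c(x - min(x), y - min(y)), c(100, 100, 2)), 40,
                      c(marker_a = 1L, marker_b = 2L))
    abs(pearson_in_mask(sc, "marker_a", "marker_b",
                        matrix(TRUE, 100, 100))$r) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("enrichment is exactly 1 on a uniform scene and recovers the generator factors", {
  # identity scene: all channels equal constants
  u <- matrix(5, 96, 96)
  sc <- image_scene(array(c(u, u), c(96, 96, 2)), 40,
                    c(chromatin = 1L, nucleolus = 2L))
  disc <- raster_shape(c(48, 48), 22, ny = 96, nx = 96)
  nl <- label_map(disc, "nucleolus"); nl$parent_of <- c("1" = 1L)
  part <- make_partition(nl, label_map(matrix(1L, 96, 96), "nucleus"), 5L)
  e <- enrichment(part, sc, "chromatin")
  expect_identical(e$interior_ratio, 1)
  expect_identical(e$rim_ratio, 1)

  # zero nucleoplasm -> flagged undefined
  z <- u; z[] <- 0; z[disc] <- 5
  sz <- image_scene(array(z, c(96, 96, 1)), 40, c(chromatin = 1L))
  ez <- enrichment(part, sz, "chromatin")
  expect_true(is.na(ez$interior_ratio))
  expect_match(ez$flag, "zero_nucleoplasm")

  # generator recovery at the standard study conditions
  gs <- generate_scene(scene_params(seed = 3L))
  seg <- segment_standard(gs$scene)
  pa <- make_partition(seg$nucleoli, seg$nuclei, 5L)
  er <- enrichment(pa, gs$scene, "chromatin")
  expect_lt(abs(er$rim_ratio - gs$truth$true_ratio_rim) /
              gs$truth$true_ratio_rim, 0.15)
  expect_lt(abs(er$interior_ratio - gs$truth$true_ratio_interior) /
              gs$truth$true_ratio_interior, 0.15)
})

test_that("the full radial pipeline reproduces the interface ordering", {
  gs <- generate_scene(scene_params())
  seg <- segment_standard(gs$scene)
  foci <- segment_intranucleolar_foci(gs$scene, seg$nucleoli)
  sm <- shape_metrics(foci)
  expanded <- bf_dilate(seg$nucleoli$labels == foci$parent_of[["1"]], 5)
  rings <- ring_map(c(sm$centroid_y[1], sm$centroid_x[1]), expanded, 50L)
  prof <- piecewise_minmax(ring_profile(rings, gs$scene), split = 15L)

  peak <- function(ch, seg_i) {
    p <- prof[prof$channel == ch & prof$segment == seg_i, ]
    p$ring[which.max(p$normalised)]
  }
  # around the focus: the marker coats the chromatin focus surface
  expect_gt(peak("marker_a", 1L), peak("chromatin", 1L))
  # at the nucleolar periphery: marker inside the chromatin rim peak,
  # nucleolar fill decreasing across the marker peak
  expect_lt(peak("marker_a", 2L), peak("chromatin", 2L))
  fill <- prof[prof$channel == "nucleolus", ]
  mk_pk <- peak("marker_a", 2L)
  expect_gt(fill$raw[fill$ring == mk_pk - 3], fill$raw[fill$ring == mk_pk + 3])
  expect_true(all(diff(fill$raw[fill$ring %in% mk_pk:(mk_pk + 4)]) < 0))
  # scaling attains 0 and 1 within each segment
  rng <- dplyr::summarise(dplyr::group_by(prof, .data$channel, .data$segment),
                          lo = min(.data$normalised, na.rm = TRUE),
                          hi = max(.data$normalised, na.rm = TRUE))
  expect_true(all(rng$lo == 0 & rng$hi == 1))
})
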