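test_that("adaptive Otsu segmentation recovers synthetic regions", {
  gs <- generate_scene(scene_params(noise = no_noise()))
  sc <- gs$scene; tr <- gs$truth
  nl <- segment_regions(sc, "nucleolus", min_area_px = 200L, window_px = 51L,
                        kind = "nucleolus")
  expect_identical(n_labels(nl), 2L)
  covered <- spill <- 0
  for (i in 1:2) {
    truth_mask <- tr$nucleolus_masks[[i]]
    jac <- vapply(1:2, function(l) {
      m <- nl$labels == l
      sum(m & truth_mask) / sum(m | truth_mask)
    }, numeric(1))
    expect_gte(max(jac), 0.90)
    l <- which.max(jac); m <- nl$labels == l
    expect_gte(sum(m & truth_mask) / sum(truth_mask), 0.95)
    expect_lte(sum(m & !truth_mask) / sum(truth_mask), 0.05)
  }

  # constant image -> empty map with a warning, not an exception
  blank <- matrix_scene(matrix(7, 64, 64))
  expect_warning(empty <- segment_regions(blank, "chromatin"), "blank")
  expect_identical(n_labels(empty), 0L)

  # two disjoint bright discs -> exactly two labels
  img <- matrix(10, 96, 96)
  img[raster_shape(c(30, 30), 10, ny = 96, nx = 96)] <- 100
  img[raster_shape(c(65, 65), 8, ny = 96, nx = 96)] <- 100
  two <- segment_regions(matrix_scene(img), "chromatin", min_area_px = 20L,
                         window_px = 51L)
  expect_identical(n_labels(two), 2L)
})

test_that("labelling uses 8-connectivity", {
  img <- matrix(0, 24, 24)
  img[cbind(5:10, 5:10)] <- 100       # diagonal chain of pixels
  lab <- segment_regions(matrix_scene(img), "chromatin", min_area_px = 1L,
                         window_px = 23L)
  expect_identical(n_labels(lab), 1L)
})

test_that("children are linked to parents by plurality overlap", {
  parent <- label_map(matrix(0L, 20, 20), "nucleus")
  parent$labels[1:20, 1:8] <- 1L
  parent$labels[1:20, 13:20] <- 2L

  child <- matrix(0L, 20, 20)
  child[2:4, 2:4] <- 1L                 # fully inside nucleus 1
  child[6, 6:10] <- 2L                  # 3 px on nucleus 1, 2 px background
  child[10, 6:15] <- 3L                 # 3 px n1, 4 px bg, 3 px n2 -> dropped
  cm <- label_map(child, "nucleolus")

  expect_message(out <- assign_children(cm, parent), "dropping 1")
  expect_identical(unname(out$parent_of), c(1L, 1L))
  expect_identical(n_labels(out), 2L)
  # exhaustive pixel-count oracle for the dropped child
  counts <- table(parent$labels[child == 3L])
  expect_true(counts[["0"]] > max(counts[names(counts) != "0"]))
})

test_that("QC excludes abnormal nuclei by mean +/- 2 SD and marker floor", {
  lab <- matrix(0L, 140, 300)
  centers <- cbind(rep(c(35, 105), each = 5), rep(seq(30, 270, by = 60), 2))
  for (i in 1:9) lab[raster_shape(centers[i, ], 10, ny = 140, nx = 300)] <- i
  lab[raster_shape(centers[10, ], 22.4, ny = 140, nx = 300)] <- 10L  # ~5x area
  nuclei <- label_map(lab, "nucleus")
  marker <- matrix(50, 140, 300)
  marker[lab == 3L] <- 1            # insufficient nucleolar marker signal
  sc <- image_scene(array(marker, c(140, 300, 1)), 40, c(nucleolus = 1L))

  qc <- qc_filter_nuclei(nuclei, sc, "nucleolus", marker_min = 10)
  # hand-computed mean +/- 2 SD on the areas flags only the big nucleus
  areas <- tabulate(lab[lab > 0L])
  out_area <- areas < mean(areas) - 2 * sd(areas) |
    areas > mean(areas) + 2 * sd(areas)
  expect_identical(which(out_area), 10L)
  expect_false(qc$included[10])
  expect_match(qc$reasons[10], "area")
  expect_false(qc$included[3])
  expect_match(qc$reasons[3], "marker")
  expect_true(all(qc$included[c(1:2, 4:9)]))

  # idempotence: re-running on the included subset changes nothing
  keep <- qc$nucleus[qc$included]
  lab2 <- lab; lab2[!lab %in% keep] <- 0L
  qc2 <- qc_filter_nuclei(label_map(lab2, "nucleus"), sc, "nucleolus",
                          marker_min = 10)
  expect_true(all(qc2$included))

  # identical nuclei: SD = 0, equality passes
  qc3 <- qc_filter_nuclei(nuclei, sc, "nucleolus", marker_min = 0)
  same <- qc3[qc3$nucleus %in% 1:2, ]
  expect_true(all(same$included))

  # fewer than 3 nuclei: shape/area exclusion skipped with a warning
  lab4 <- matrix(0L, 60, 60)
  lab4[raster_shape(c(20, 20), 8, ny = 60, nx = 60)] <- 1L
  lab4[raster_shape(c(45, 45), 4, ny = 60, nx = 60)] <- 2L
  sc4 <- image_scene(array(50, c(60, 60, 1)), 40, c(nucleolus = 1L))
  expect_warning(qc4 <- qc_filter_nuclei(label_map(lab4, "nucleus"), sc4,
                                         "nucleolus"),
                 "fewer than 3")
  expect_true(all(qc4$included))
})

test_that("partition matches the brute-force distance-transform oracle exactly", {
  k <- 5L
  for (seed in 1:6) {
    mask <- random_mask(seed)
    nuclei <- label_map(matrix(1L, nrow(mask), ncol(mask)), "nucleus")
    nl <- label_map(mask, "nucleolus")
    nl$parent_of <- c("1" = 1L)
    part <- make_partition(nl, nuclei, k)
    expect_identical(part$interior_labels > 0L, bf_erode(mask, k))
    dil <- bf_dilate(mask, k)
    expect_identical(part$rim_labels > 0L, dil & !bf_erode(mask, k))
    expect_identical(part$nucleoplasm_labels > 0L, !dil)
  }
})

test_that("partition masks are disjoint, contained, and carry rim provenance", {
  gs <- generate_scene(scene_params())
  seg <- segment_standard(gs$scene)
  part <- make_partition(seg$nucleoli, seg$nuclei, 5L,
                         pixel_size_nm = gs$scene$pixel_size_nm)
  int_ <- part$interior_labels > 0L
  rim <- part$rim_labels > 0L
  np <- part$nucleoplasm_labels > 0L
  expect_false(any(int_ & rim)); expect_false(any(int_ & np))
  expect_false(any(rim & np))
  nucleus_mask <- seg$nuclei$labels > 0L
  expect_true(all(nucleus_mask[int_ | rim | np]))
  # interior and rim within the expanded nucleoli; nucleoplasm outside them
  expanded <- bf_dilate(seg$nucleoli$labels > 0L, 5)
  expect_true(all(expanded[int_ | rim]))
  expect_false(any(expanded & np))
  expect_equal(part$rim_halfwidth_nm, 200)   # 5 px at 40 nm/px

  # disc example: interior an r-15 disc, rim a 15-25 annulus (+/- 1 px)
  disc <- raster_shape(c(36, 36), 20, ny = 72, nx = 72)
  nl <- label_map(disc, "nucleolus"); nl$parent_of <- c("1" = 1L)
  pd <- make_partition(nl, label_map(matrix(1L, 72, 72), "nucleus"), 5L)
  Y <- matrix(1:72, 72, 72); X <- t(Y)
  r <- sqrt((Y - 36)^2 + (X - 36)^2)
  expect_true(all(abs(r[pd$interior_labels > 0L]) <= 16))
  expect_true(all(r[pd$interior_labels > 0L] <= 16))
  expect_gte(min(r[pd$rim_labels > 0L]), 14)
  expect_lte(max(r[pd$rim_labels > 0L]), 26)

  expect_error(make_partition(nl, label_map(matrix(1L, 72, 72), "nucleus"), 0L),
               "k_px")
})

test_that("a nucleolus vanishing under erosion is flagged with empty interior", {
  small <- raster_shape(c(20, 20), 3, ny = 40, nx = 40)
  nl <- label_map(small, "nucleolus"); nl$parent_of <- c("1" = 1L)
  part <- make_partition(nl, label_map(matrix(1L, 40, 40), "nucleus"), 5L)
  expect_false(any(part$interior_labels > 0L))
  expect_identical(part$flags$flag, "interior_empty")
})

test_that("foci detection finds planted foci and applies strict filters", {
  gs <- generate_scene(scene_params(seed = 2L))
  seg <- segment_standard(gs$scene)
  foci <- segment_intranucleolar_foci(gs$scene, seg$nucleoli)
  expect_identical(n_labels(foci), 1L)
  sm <- shape_metrics(foci)
  truth_c <- gs$truth$foci_centers_px
  expect_lt(sqrt((sm$centroid_y - truth_c[1, "y"])^2 +
                   (sm$centroid_x - truth_c[1, "x"])^2), 2)
  # the small nucleolus's sub-region vanishes under the 20 px erosion
  expect_identical(attr(foci, "flags")$flag, "subregion_empty")

  # strict "above 15 px" area and "above 0.7" circularity semantics on a
  # noise-free fixture with components of exactly known size
  ny <- 120; nx <- 120
  nl_mask <- raster_shape(c(60, 60), 35, ny = ny, nx = nx)
  chrom <- matrix(0, ny, nx); chrom[nl_mask] <- 50
  chrom[58:60, 50:54] <- 100        # 3 x 5 = 15 px: rejected (not above 15)
  chrom[70:73, 60:63] <- 100        # 4 x 4 = 16 px: retained
  chrom[48:49, 52:71] <- 100        # 2 x 20 streak: circularity ~0.31
  sc <- image_scene(array(c(chrom, nl_mask * 100), c(ny, nx, 2)), 40,
                    c(chromatin = 1L, nucleolus = 2L))
  nl <- label_map(nl_mask, "nucleolus"); nl$parent_of <- c("1" = 1L)
  out <- segment_intranucleolar_foci(sc, nl, erode_px = 5L,
                                     smooth_sigma_px = 0)
  expect_identical(n_labels(out), 1L)
  kept <- shape_metrics(out)
  expect_equal(kept$area_px, 16)
  expect_identical(unname(out$parent_of[["1"]]), 1L)
})

test_that("FC regions are thresholded at 0.5 and densities counted per nucleus", {
  ny <- 100; nx <- 100
  nl_mask <- raster_shape(c(50, 50), 30, ny = ny, nx = nx)
  nl <- label_map(nl_mask, "nucleolus"); nl$parent_of <- c("1" = 1L)
  pm <- matrix(0.1, ny, nx)
  for (cc in list(c(42, 42), c(58, 44), c(50, 62), c(60, 60))) {
    pm[raster_shape(cc, 3, ny = ny, nx = nx)] <- 0.9
  }
  res <- segment_fc_regions(pm, nl)
  expect_identical(n_labels(res$fc), 4L)
  expect_equal(res$per_nucleus$n_fc, 4L)
  # hand-counted density: 4 FC / summed nucleolar area
  expect_equal(res$per_nucleus$fc_density, 4 / sum(nl_mask))

  uni <- segment_fc_regions(matrix(0.4, ny, nx), nl)
  expect_identical(n_labels(uni$fc), 0L)
  expect_equal(uni$per_nucleus$fc_density, 0)
  expect_equal(uni$per_nucleus$n_fc, 0L)

  expect_error(segment_fc_regions(matrix(1.2, ny, nx), nl), "\\[0, 1\\]")
})

test_that("noise-free foci of >= 20 px and 2x contrast are found with F1 = 1", {
  hits <- 0L; total <- 0L; fp <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    jit <- runif(2, -3, 3)
    p <- scene_params(
      nucleoli = list(
        nucleolus_spec(c(118, 104), 32,
                       irregularity = list(c(3, 0.08, 0.5)),
                       foci = list(list(center = c(116, 102) + jit,
                                        radius = 4))),
        nucleolus_spec(c(150, 170), 20)),
      noise = no_noise(), seed = seed)
    gs <- generate_scene(p)
    seg <- segment_standard(gs$scene)
    foci <- segment_intranucleolar_foci(gs$scene, seg$nucleoli)
    sm <- shape_metrics(foci)
    truth_c <- gs$truth$foci_centers_px
    total <- total + nrow(truth_c)
    for (i in seq_len(nrow(truth_c))) {
      d <- sqrt((sm$centroid_y - truth_c[i, "y"])^2 +
                  (sm$centroid_x - truth_c[i, "x"])^2)
      if (length(d) && min(d) < 3) hits <- hits + 1L
    }
    fp <- fp + max(0L, nrow(sm) - nrow(truth_c))
  }
  precision <- hits / (hits + fp); recall <- hits / total
  expect_equal(2 * precision * recall / (precision + recall), 1)
})
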