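#' Labelled region image
#'
#' Integer-labelled image (0 = background) for nuclei, nucleoli, chromatin
#' foci or fibrillar-centre regions, optionally carrying the child-parent
#' link map established by [assign_children()].
#'
#' @param labels Integer matrix; positive labels, 0 background.
#' @param kind One of `"nucleus"`, `"nucleolus"`, `"focus"`, `"fc"`.
#' @param parent_of Named integer vector, child label -> parent label.
#' @return A `"label_map"` object.
#' @export
label_map <- function(labels, kind = c("nucleus", "nucleolus", "focus", "fc"),
                      parent_of = NULL) {
  kind <- match.arg(kind)
  labels <- label_matrix(labels)
  structure(list(labels = labels, kind = kind, parent_of = parent_of),
            class = "label_map")
}

# Accept a label_map, a logical mask or an integer matrix; return the
# integer label matrix.
label_matrix <- function(x) {
  if (inherits(x, "label_map")) return(x$labels)
  if (is.logical(x)) return(matrix(as.integer(x), nrow(x), ncol(x)))
  stopifnot(is.matrix(x))
  if (any(x < 0) || any(x != round(x))) stop("labels must be non-negative integers")
  matrix(as.integer(x), nrow(x), ncol(x))
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map:%s> %d x %d px, %d label(s)\n", x$kind,
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

#' Number of labels in a label map
#' @param x A [label_map()].
#' @return Integer count.
#' @export
n_labels <- function(x) max(label_matrix(x))

# Adaptive Otsu threshold surface: Otsu thresholds are computed on a grid
# of window_px x window_px windows (stride window_px / 2) and bilinearly
# interpolated to every pixel. Local thresholds are bounded to
# [bounds[1], bounds[2]] x the global Otsu threshold so that windows
# containing only background noise cannot segment it as foreground.
adaptive_otsu_surface <- function(img, window_px, bounds = c(0.7, 1.5),
                                  otsu_classes = 2L) {
  otsu_fun <- if (otsu_classes == 3L) otsu_threshold3 else otsu_threshold
  global <- otsu_fun(img)
  if (is.na(global)) return(NULL)
  nr <- nrow(img); nc <- ncol(img)
  half <- window_px %/% 2L
  stride <- max(half, 1L)
  gy <- unique(pmin(pmax(seq(1L, nr, by = stride), half + 1L), nr - half))
  gx <- unique(pmin(pmax(seq(1L, nc, by = stride), half + 1L), nc - half))
  if (length(gy) == 0L) gy <- (nr + 1L) %/% 2L
  if (length(gx) == 0L) gx <- (nc + 1L) %/% 2L
  thr <- matrix(global, length(gy), length(gx))
  for (i in seq_along(gy)) {
    ys <- max(1L, gy[i] - half):min(nr, gy[i] + half)
    for (j in seq_along(gx)) {
      xs <- max(1L, gx[j] - half):min(nc, gx[j] + half)
      t_ij <- otsu_fun(img[ys, xs])
      if (!is.na(t_ij)) thr[i, j] <- t_ij
    }
  }
  thr <- pmin(pmax(thr, bounds[1] * global), bounds[2] * global)
  interp_grid(thr, gy, gx, nr, nc)
}

# Separable linear interpolation of a coarse grid (values at rows gy,
# cols gx) onto the full nr x nc raster, constant extrapolation outside.
interp_grid <- function(vals, gy, gx, nr, nc) {
  rows <- if (length(gy) == 1L) {
    matrix(vals, nr, ncol(vals), byrow = TRUE)
  } else {
    apply(vals, 2L, function(col) stats::approx(gy, col, xout = seq_len(nr),
                                                rule = 2)$y)
  }
  if (length(gx) == 1L) {
    matrix(rows, nr, nc)
  } else {
    t(apply(rows, 1L, function(row) stats::approx(gx, row, xout = seq_len(nc),
                                                  rule = 2)$y))
  }
}

#' Segment bright regions by adaptive Otsu thresholding
#'
#' Computes a locally adaptive Otsu threshold surface over sliding windows,
#' thresholds the channel, fills holes, removes components smaller than
#' `min_area_px`, and labels connected components with 8-connectivity.
#' A constant (blank) channel yields an empty label map with a warning.
#'
#' @param scene An [image_scene()].
#' @param role Channel role to segment.
#' @param min_area_px Components with fewer pixels are discarded.
#' @param window_px Odd window size (>= 3) of the local threshold.
#' @param kind Label-map kind (see [label_map()]).
#' @param bounds Lower/upper bounds on local thresholds relative to the
#'   global Otsu threshold (windows containing only background noise
#'   would otherwise segment it).
#' @param otsu_classes 2 (default) for classic Otsu; 3 for three-class
#'   Otsu with the middle and upper classes as foreground — the standard
#'   choice for channels whose foreground holds a much brighter
#'   substructure (e.g. a chromatin channel with a bright peri-nucleolar
#'   rim).
#' @return A [label_map()].
#' @export
segment_regions <- function(scene, role, min_area_px = 64L, window_px = 51L,
                            kind = "nucleus", bounds = c(0.7, 1.5),
                            otsu_classes = 2L) {
  stopifnot(window_px %% 2L == 1L, window_px >= 3L, otsu_classes %in% 2:3)
  img <- scene_channel(scene, role)
  thr <- adaptive_otsu_surface(img, window_px, bounds, otsu_classes)
  if (is.null(thr)) {
    warning("blank channel '", role, "': returning empty label map")
    return(label_map(matrix(0L, nrow(img), ncol(img)), kind = kind))
  }
  mask <- fill_holes(img > thr)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_area_px)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  label_map(lab, kind = kind)
}

#' Link child regions to parent regions
#'
#' Each child label is assigned to the parent owning the plurality of its
#' pixels; ties between parents go to the lower parent label. Children
#' whose pixels lie mostly on background (strictly more background pixels
#' than the best parent's overlap) are dropped from the map with a
#' message. Surviving labels are renumbered gaplessly.
#'
#' @param child,parent [label_map()] objects on the same pixel grid.
#' @return The child [label_map()] with `parent_of` filled in.
#' @export
assign_children <- function(child, parent) {
  cl <- label_matrix(child); pl <- label_matrix(parent)
  stopifnot(all(dim(cl) == dim(pl)))
  ids <- sort(unique(cl[cl > 0L]))
  parent_of <- integer(0)
  dropped <- integer(0)
  for (id in ids) {
    counts <- table(pl[cl == id])
    bg <- if ("0" %in% names(counts)) counts[["0"]] else 0L
    pc <- counts[names(counts) != "0"]
    if (length(pc) == 0L || max(pc) < bg) {
      dropped <- c(dropped, id)
    } else {
      best <- names(pc)[pc == max(pc)]
      parent_of[as.character(id)] <- min(as.integer(best))
    }
  }
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " child region(s) lying mostly on background")
    cl[cl %in% dropped] <- 0L
  }
  keep <- sort(unique(cl[cl > 0L]))
  cl[cl > 0L] <- match(cl[cl > 0L], keep)
  po <- stats::setNames(unname(parent_of[as.character(keep)]),
                        as.character(seq_along(keep)))
  label_map(cl, kind = if (inherits(child, "label_map")) child$kind else "nucleolus",
            parent_of = po)
}

#' Quality-control filter for segmented nuclei
#'
#' A nucleus is excluded when its area or circularity lies outside the
#' dataset interval `mean +/- 2 SD`, or when its mean intensity in the
#' nucleolar-marker channel falls below `marker_min` (insufficient marker
#' signal). With fewer than 3 nuclei the SD is undefined and the
#' shape/area exclusion is skipped with a warning; with SD = 0 the
#' interval degenerates to a point and equality passes.
#'
#' @param nuclei Nucleus [label_map()].
#' @param scene An [image_scene()].
#' @param marker_role Channel role of the nucleolar marker.
#' @param marker_min Minimum acceptable marker mean intensity.
#' @return A tibble (`nucleus`, `area_px`, `circularity`, `marker_mean`,
#'   `included`, `reasons`); `reasons` is `NA` for included nuclei.
#' @export
qc_filter_nuclei <- function(nuclei, scene, marker_role, marker_min = 0) {
  shp <- shape_metrics(nuclei)
  mk <- label_means(label_matrix(nuclei), scene_channel(scene, marker_role))
  out <- shp |>
    dplyr::transmute(nucleus = .data$label, area_px = .data$area_px,
                     circularity = .data$circularity,
                     marker_mean = unname(mk[as.character(.data$label)]))
  n <- nrow(out)
  reasons <- vector("list", n)
  if (n >= 3L) {
    for (col in c("area_px", "circularity")) {
      v <- out[[col]]
      lo <- mean(v) - 2 * stats::sd(v); hi <- mean(v) + 2 * stats::sd(v)
      bad <- v < lo | v > hi
      tag <- if (col == "area_px") "area" else "circularity"
      for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], tag)
    }
  } else if (n > 0L) {
    warning("fewer than 3 nuclei: skipping area/circularity exclusion")
  }
  for (i in which(out$marker_mean < marker_min)) {
    reasons[[i]] <- c(reasons[[i]], "marker")
  }
  out$included <- lengths(reasons) == 0L
  out$reasons <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = ";") else NA_character_, character(1))
  out
}

#' Partition nuclei into nucleolar interior, rim and nucleoplasm
#'
#' Implements the mask shrink/expand algebra: the interior is each
#' nucleolus eroded by `k_px`, the rim is the nucleolus dilated by `k_px`
#' minus the interior, and the nucleoplasm is the parent nucleus minus all
#' dilated nucleoli. Erosion and dilation use a Euclidean disc
#' (distance-threshold) structuring element, so at 40 nm/px the standard
#' `k_px = 5` makes the rim extend ~200 nm on either side of the nucleolar
#' boundary. All masks are clipped to the parent nucleus. Rim pixels
#' reachable from several nucleoli are attributed to the nearest one.
#'
#' @param nucleoli Nucleolus [label_map()] with `parent_of` links
#'   (see [assign_children()]).
#' @param nuclei Nucleus [label_map()].
#' @param k_px Shrink/expand radius in px (>= 1). The conventional default
#'   for a given pixel size is `round(200 / pixel_size_nm)`.
#' @return A `"region_partition"`: label matrices `interior_labels` and
#'   `rim_labels` (labelled by nucleolus), `nucleoplasm_labels` (labelled
#'   by nucleus), `k_px`, `rim_halfwidth_nm` provenance when the scene
#'   pixel size is supplied via `pixel_size_nm`, and a `flags` tibble
#'   marking nucleoli whose interior vanished under erosion.
#' @param pixel_size_nm Optional pixel size used only to record the
#'   physical rim half-width in the result.
#' @export
make_partition <- function(nucleoli, nuclei, k_px, pixel_size_nm = NULL) {
  if (k_px < 1L) stop("k_px must be >= 1")
  nl <- label_matrix(nucleoli); nuc <- label_matrix(nuclei)
  stopifnot(all(dim(nl) == dim(nuc)))
  parent_of <- nucleoli$parent_of
  if (is.null(parent_of)) stop("nucleoli must be assigned to nuclei first")
  ids <- sort(unique(nl[nl > 0L]))
  interior <- matrix(0L, nrow(nl), ncol(nl))
  dilated_by <- matrix(Inf, nrow(nl), ncol(nl))   # distance to owning nucleolus
  dilated_lab <- matrix(0L, nrow(nl), ncol(nl))
  flags <- tibble::tibble(nucleolus = integer(0), flag = character(0))
  for (id in ids) {
    mask <- nl == id
    p <- parent_of[[as.character(id)]]
    in_parent <- nuc == p
    er <- erode_disc(mask, k_px) & in_parent
    if (!any(er)) {
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        nucleolus = id, flag = "interior_empty"))
    }
    interior[er] <- id
    d <- distance_to_mask(mask)
    d[mask] <- 0
    grab <- (d <= k_px) & in_parent & d < dilated_by
    dilated_lab[grab] <- id
    dilated_by[grab] <- d[grab]
  }
  rim <- dilated_lab
  rim[interior > 0L] <- 0L
  dilated_any <- dilated_lab > 0L
  nucleoplasm <- nuc
  nucleoplasm[dilated_any] <- 0L
  structure(
    list(interior_labels = interior, rim_labels = rim,
         nucleoplasm_labels = nucleoplasm, k_px = as.integer(k_px),
         parent_of = parent_of,
         rim_halfwidth_nm = if (is.null(pixel_size_nm)) NA_real_ else
           k_px * pixel_size_nm,
         flags = flags),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> k = %d px; %d nucleolus interior(s)\n",
              x$k_px, length(setdiff(unique(as.vector(x$interior_labels)), 0L))))
  invisible(x)
}

#' Default shrink/expand radius for a pixel size
#'
#' The conventional rim half-width is ~200 nm (5 px at 40 nm/px).
#' @param pixel_size_nm Pixel size in nm.
#' @return Integer radius in px (at least 1).
#' @export
default_k_px <- function(pixel_size_nm) max(1L, as.integer(round(200 / pixel_size_nm)))

#' Segment intranucleolar chromatin foci
#'
#' Within each nucleolus, a sub-region is formed by eroding the nucleolar
#' mask by `erode_px` (excluding the peri-nucleolar rim zone); the upper
#' quantile of chromatin intensity in that sub-region is subtracted from
#' the chromatin channel (negatives clipped to 0), the result is
#' Gaussian-smoothed and Otsu-thresholded within the sub-region, and the
#' resulting components are kept only when their area and circularity are
#' strictly above `min_area_px` and `min_circularity`. Survivors are
#' linked to their parent nucleolus.
#'
#' @param scene An [image_scene()] with a `"chromatin"` role.
#' @param nucleoli Nucleolus [label_map()].
#' @param erode_px Erosion radius forming the nucleolar sub-region.
#' @param quantile Upper quantile subtracted as local background (the
#'   upper quartile, 0.75, by default).
#' @param smooth_sigma_px Gaussian smoothing sigma.
#' @param min_area_px Foci must have area strictly above this (px).
#' @param min_circularity Foci must have circularity strictly above this.
#' @return A focus [label_map()] with `parent_of` mapping focus -> parent
#'   nucleolus; nucleoli whose sub-region vanished are recorded in
#'   `attr(, "flags")`.
#' @export
segment_intranucleolar_foci <- function(scene, nucleoli, erode_px = 20L,
                                        quantile = 0.75, smooth_sigma_px = 1,
                                        min_area_px = 15L,
                                        min_circularity = 0.7) {
  chrom <- scene_channel(scene, "chromatin")
  nl <- label_matrix(nucleoli)
  ids <- sort(unique(nl[nl > 0L]))
  out <- matrix(0L, nrow(nl), ncol(nl))
  parent_of <- integer(0)
  flags <- tibble::tibble(nucleolus = integer(0), flag = character(0))
  next_id <- 0L
  for (id in ids) {
    sub <- erode_disc(nl == id, erode_px)
    if (!any(sub)) {
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        nucleolus = id, flag = "subregion_empty"))
      next
    }
    q <- stats::quantile(chrom[sub], quantile, names = FALSE)
    img <- matrix(0, nrow(nl), ncol(nl))
    img[sub] <- pmax(chrom[sub] - q, 0)
    img <- gaussian_blur(img, smooth_sigma_px)
    thr <- otsu_threshold(img[sub])
    if (is.na(thr)) next
    lab <- label_components(img > thr & sub)
    if (max(lab) == 0L) next
    shp <- shape_metrics(lab)
    keep <- shp$label[shp$area_px > min_area_px &
                        shp$circularity > min_circularity]
    for (k in keep) {
      next_id <- next_id + 1L
      out[lab == k] <- next_id
      parent_of[as.character(next_id)] <- id
    }
  }
  res <- label_map(out, kind = "focus", parent_of = parent_of)
  attr(res, "flags") <- flags
  res
}

#' Segment fibrillar-centre regions from a probability map
#'
#' Thresholds a pixel-classifier probability map at `threshold` (default
#' 0.5), labels components inside nucleoli, links them to their parent
#' nucleolus, and reports per nucleus the median FC area and the FC
#' density (FC count divided by the summed nucleolar area of the nucleus).
#'
#' @param prob_map Numeric matrix in `[0, 1]`.
#' @param nucleoli Nucleolus [label_map()] with `parent_of` links.
#' @param threshold Probability cut-off; pixels `>= threshold` are FC.
#' @return A list: `fc` (focus [label_map()] with `parent_of` = parent
#'   nucleolus) and `per_nucleus` tibble (`nucleus`, `n_fc`,
#'   `median_fc_area`, `fc_density`).
#' @export
segment_fc_regions <- function(prob_map, nucleoli, threshold = 0.5) {
  if (any(prob_map < 0) || any(prob_map > 1)) {
    stop("probability map values must lie in [0, 1]")
  }
  nl <- label_matrix(nucleoli)
  stopifnot(all(dim(prob_map) == dim(nl)))
  if (is.null(nucleoli$parent_of)) stop("nucleoli must carry parent links")
  lab <- label_components(prob_map >= threshold & nl > 0L)
  fc <- assign_children(label_map(lab, kind = "fc"),
                        label_map(nl, kind = "nucleolus"))
  fc$kind <- "fc"
  shp <- shape_metrics(fc)
  nucleolus_area <- tabulate(nl[nl > 0L])
  nucleus_of <- nucleoli$parent_of
  per_nucleolus_area <- tibble::tibble(
    nucleolus = seq_along(nucleolus_area), area = nucleolus_area) |>
    dplyr::filter(.data$area > 0) |>
    dplyr::mutate(nucleus = unname(nucleus_of[as.character(.data$nucleolus)]))
  area_by_nucleus <- per_nucleolus_area |>
    dplyr::group_by(.data$nucleus) |>
    dplyr::summarise(nucleolar_area = sum(.data$area), .groups = "drop")
  fc_tbl <- if (nrow(shp)) {
    shp |>
      dplyr::mutate(
        nucleolus = unname(fc$parent_of[as.character(.data$label)]),
        nucleus = unname(nucleus_of[as.character(.data$nucleolus)])) |>
      dplyr::group_by(.data$nucleus) |>
      dplyr::summarise(n_fc = dplyr::n(),
                       median_fc_area = stats::median(.data$area_px),
                       .groups = "drop")
  } else {
    tibble::tibble(nucleus = integer(0), n_fc = integer(0),
                   median_fc_area = numeric(0))
  }
  per_nucleus <- area_by_nucleus |>
    dplyr::left_join(fc_tbl, by = "nucleus") |>
    dplyr::mutate(n_fc = dplyr::coalesce(.data$n_fc, 0L),
                  fc_density = .data$n_fc / .data$nucleolar_area) |>
    dplyr::select("nucleus", "n_fc", "median_fc_area", "fc_density")
  list(fc = fc, per_nucleus = per_nucleus)
}
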