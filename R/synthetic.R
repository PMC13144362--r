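#' Specify one synthetic nucleolus
#'
#' Nucleolar boundaries are modelled as a low-order Fourier perturbation of
#' a circle, `r(theta) = r0 * (1 + sum_m a_m cos(m theta + phi_m))`: smooth,
#' tunable irregularity whose area and perimeter admit dense-quadrature
#' ground truth. Intranucleolar chromatin foci are discs inside the
#' boundary.
#'
#' @param center Numeric `(y, x)` centre in px.
#' @param base_radius_px Positive base radius `r0` in px.
#' @param irregularity List of `c(mode, amplitude, phase)` triples; the
#'   amplitudes must satisfy `sum(|a_m|) < 1` so the radius stays positive.
#' @param foci List of `list(center = c(y, x), radius = r)` discs that must
#'   lie inside the boundary.
#' @return A `"nucleolus_spec"` list.
#' @export
nucleolus_spec <- function(center, base_radius_px, irregularity = list(),
                           foci = list()) {
  stopifnot(length(center) == 2L, base_radius_px > 0)
  irregularity <- lapply(irregularity, function(m) {
    m <- as.numeric(m)
    stopifnot(length(m) == 3L, m[1] == round(m[1]), m[1] >= 1)
    m
  })
  amps <- vapply(irregularity, `[`, numeric(1), 2L)
  if (length(amps) && sum(abs(amps)) >= 1) {
    stop("sum of |irregularity amplitudes| must be < 1")
  }
  spec <- structure(
    list(center = as.numeric(center), base_radius_px = base_radius_px,
         irregularity = irregularity, foci = foci),
    class = "nucleolus_spec"
  )
  for (f in foci) {
    th <- atan2(f$center[1] - center[1], f$center[2] - center[2])
    d <- sqrt(sum((f$center - center)^2))
    if (d + f$radius >= boundary_radius(spec, th)) {
      stop("focus extends outside the nucleolar boundary")
    }
  }
  spec
}

# r(theta) for a nucleolus_spec (vectorised over theta).
boundary_radius <- function(spec, theta) {
  r <- rep(1, length(theta))
  for (m in spec$irregularity) {
    r <- r + m[2] * cos(m[1] * theta + m[3])
  }
  spec$base_radius_px * r
}

# d r / d theta, for perimeter quadrature.
boundary_radius_deriv <- function(spec, theta) {
  d <- rep(0, length(theta))
  for (m in spec$irregularity) {
    d <- d - m[2] * m[1] * sin(m[1] * theta + m[3])
  }
  spec$base_radius_px * d
}

#' Parameters of a synthetic microscopy scene
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: a 256 x 256 px field at 40 nm/px holding one elliptical nucleus
#' with two irregular nucleoli (one carrying a chromatin focus), a
#' chromatin channel with nucleoplasm baseline, a 2x peri-nucleolar
#' heterochromatin band straddling the nucleolar boundary (extending
#' `rim_width_nm` to each side — the reason interior masks are shrunk at
#' analysis time), a 0.5x darkened nucleolar interior and a bright
#' 2x-contrast focus, a uniform nucleolar fill channel, and a
#' boundary-marker channel forming a Gaussian shell (sigma 100 nm) at a
#' signed offset from the nucleolar boundary (positive offsets point
#' towards the nucleolar interior; the default +100 nm emulates an
#' interface protein sitting just inside the chromatin rim centre, and
#' the marker also coats the focus surface). Optics apply a per-channel
#' chromatic shift, then a Gaussian
#' PSF of sigma 40 nm (1 px); noise is Poisson shot noise on the blurred
#' field plus additive Gaussian read noise.
#'
#' @param image_size_px `(ny, nx)` image size.
#' @param pixel_size_nm Pixel size, nm.
#' @param nucleus List with `center` `(y, x)` and `semi_axes` `(ay, ax)` px.
#' @param nucleoli List of [nucleolus_spec()] objects.
#' @param chromatin_levels List: `nucleoplasm_mean`, `rim_factor`,
#'   `interior_factor`, `focus_factor` (all multiply `nucleoplasm_mean`).
#' @param rim_width_nm Half-width of the enriched peri-nucleolar band: the
#'   band spans this far on each side of the nucleolar boundary, nm.
#' @param nucleolus_fill Fill intensity of the nucleolus channel.
#' @param marker_shells Named list (one entry per marker channel) of lists
#'   with `offset_nm` (signed; positive = towards the nucleolar interior),
#'   `shell_sigma_nm`, `amplitude`, and `coat_foci` (also draw a shell on
#'   each chromatin focus surface).
#' @param optics List: `psf_sigma_nm` (scalar or per-channel vector) and
#'   `chromatic_shift_px` (list of per-channel `(dy, dx)` shifts).
#' @param noise List: `photon_scale` (photons per intensity unit;
#'   `Inf` disables shot noise) and `read_sigma` (additive Gaussian SD; 0
#'   disables). See [no_noise()].
#' @param seed Integer seed; scenes are bit-identical for identical
#'   parameters and seed.
#' @return A `"scene_params"` list.
#' @export
scene_params <- function(image_size_px = c(256L, 256L),
                         pixel_size_nm = 40,
                         nucleus = list(center = c(128, 128),
                                        semi_axes = c(78, 100)),
                         nucleoli = default_nucleoli(),
                         chromatin_levels = list(nucleoplasm_mean = 100,
                                                 rim_factor = 2,
                                                 interior_factor = 0.5,
                                                 focus_factor = 1),
                         rim_width_nm = 200,
                         nucleolus_fill = 150,
                         marker_shells = list(
                           marker_a = list(offset_nm = 100, shell_sigma_nm = 100,
                                           amplitude = 120, coat_foci = TRUE)),
                         optics = list(psf_sigma_nm = 40,
                                       chromatic_shift_px = NULL),
                         noise = list(photon_scale = 1, read_sigma = 2),
                         seed = 1L) {
  stopifnot(rim_width_nm > 0, noise$photon_scale > 0)
  for (ms in marker_shells) stopifnot(ms$shell_sigma_nm > 0)
  # nucleoli must lie inside the nucleus
  for (sp in nucleoli) {
    rmax <- sp$base_radius_px *
      (1 + sum(abs(vapply(sp$irregularity, `[`, numeric(1), 2L))))
    u <- (sp$center - nucleus$center) /
      (nucleus$semi_axes - rmax)
    if (any(nucleus$semi_axes - rmax <= 0) || sum(u^2) > 1) {
      stop("nucleolus does not fit inside the nucleus")
    }
  }
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_nm = pixel_size_nm, nucleus = nucleus,
         nucleoli = nucleoli, chromatin_levels = chromatin_levels,
         rim_width_nm = rim_width_nm, nucleolus_fill = nucleolus_fill,
         marker_shells = marker_shells, optics = optics, noise = noise,
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

#' @rdname scene_params
#' @export
default_nucleoli <- function() {
  list(
    nucleolus_spec(center = c(118, 104), base_radius_px = 32,
                   irregularity = list(c(3, 0.08, 0.5), c(4, 0.05, 2.0)),
                   foci = list(list(center = c(116, 102), radius = 4))),
    nucleolus_spec(center = c(150, 170), base_radius_px = 20,
                   irregularity = list(c(2, 0.10, 1.0)))
  )
}

#' Disable simulated noise
#' @return A noise list with shot and read noise off.
#' @export
no_noise <- function() list(photon_scale = Inf, read_sigma = 0)

#' Generate a synthetic multichannel scene with ground truth
#'
#' Composes the ideal (noise-free, unblurred) intensity fields implied by
#' the parameters, derives exact ground truth from the geometry, then
#' applies per-channel chromatic shift (Fourier sub-pixel translation),
#' Gaussian PSF blur, Poisson shot noise and Gaussian read noise.
#'
#' Channel layout: channel 1 `"chromatin"`, channel 2 `"nucleolus"`, then
#' one channel per entry of `marker_shells` in order.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `scene` (an [image_scene()]) and `truth`
#'   (masks, foci centres, true factors and super-sampled shape metrics).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  ny <- params$image_size_px[1]; nx <- params$image_size_px[2]
  Y <- row_grid(ny, nx); X <- col_grid(ny, nx)
  px <- params$pixel_size_nm

  nuc <- params$nucleus
  nucleus_mask <- ((Y - nuc$center[1]) / nuc$semi_axes[1])^2 +
    ((X - nuc$center[2]) / nuc$semi_axes[2])^2 <= 1

  nucleolus_masks <- lapply(params$nucleoli, function(sp) {
    dy <- Y - sp$center[1]; dx <- X - sp$center[2]
    sqrt(dy^2 + dx^2) <= boundary_radius(sp, atan2(dy, dx))
  })
  nucleolus_labels <- matrix(0L, ny, nx)
  for (i in seq_along(nucleolus_masks)) {
    nucleolus_labels[nucleolus_masks[[i]]] <- i
  }
  nucleolus_union <- nucleolus_labels > 0L

  foci <- list(); focus_mask <- matrix(FALSE, ny, nx)
  for (i in seq_along(params$nucleoli)) {
    for (f in params$nucleoli[[i]]$foci) {
      foci[[length(foci) + 1L]] <- c(nucleolus = i, y = f$center[1],
                                     x = f$center[2], radius = f$radius)
      focus_mask <- focus_mask |
        ((Y - f$center[1])^2 + (X - f$center[2])^2 <= f$radius^2)
    }
  }
  foci_centers <- if (length(foci)) do.call(rbind, foci) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("nucleolus", "y", "x", "radius")))

  # --- signed distance to the nucleolar boundary -----------------------
  # positive towards the nucleolar interior; the rasterised boundary lies
  # half a pixel outside the outermost inside pixel centres, hence the
  # 0.5 px correction.
  dist_out <- distance_to_mask(nucleolus_union)
  sd_px <- ifelse(nucleolus_union,
                  distance_in_mask(nucleolus_union) - 0.5,
                  -(dist_out - 0.5))

  # --- ideal chromatin field -------------------------------------------
  # The peri-nucleolar heterochromatin band straddles the nucleolar
  # boundary (which is why interior masks are shrunk at analysis time to
  # exclude it). Its extent uses the same Euclidean pixel-set distance as
  # the morphological shrink/expand operators, so eroding the true mask
  # by rim_width exactly excludes the band and dilating exactly covers
  # it.
  lv <- params$chromatin_levels
  rim_px <- params$rim_width_nm / px
  rim_mask_true <- nucleus_mask &
    ((nucleolus_union & distance_in_mask(nucleolus_union) <= rim_px) |
       (!nucleolus_union & dist_out <= rim_px))
  chromatin <- matrix(0, ny, nx)
  chromatin[nucleus_mask] <- lv$nucleoplasm_mean
  chromatin[nucleolus_union] <- lv$nucleoplasm_mean * lv$interior_factor
  chromatin[rim_mask_true] <- lv$nucleoplasm_mean * lv$rim_factor
  chromatin[focus_mask] <- lv$nucleoplasm_mean * lv$focus_factor

  # --- nucleolar fill channel ------------------------------------------
  fill <- matrix(0, ny, nx)
  fill[nucleus_mask] <- 0.1 * params$nucleolus_fill
  fill[nucleolus_union] <- params$nucleolus_fill

  # --- marker shells: Gaussian of signed boundary distance -------------
  marker_fields <- list()
  for (nm in names(params$marker_shells)) {
    ms <- params$marker_shells[[nm]]
    field <- ms$amplitude *
      exp(-(sd_px * px - ms$offset_nm)^2 / (2 * ms$shell_sigma_nm^2))
    if (isTRUE(ms$coat_foci) && length(foci)) {
      for (f in foci) {
        d_f <- (sqrt((Y - f["y"])^2 + (X - f["x"])^2) - f["radius"]) * px
        field <- pmax(field, ms$amplitude * exp(-d_f^2 / (2 * ms$shell_sigma_nm^2)))
      }
    }
    marker_fields[[nm]] <- field
  }

  ideal <- c(list(chromatin = chromatin, nucleolus = fill), marker_fields)
  roles <- stats::setNames(seq_along(ideal), names(ideal))

  # --- ground truth (computed on the ideal geometry, before optics) ----
  truth <- list(
    nucleus_mask = nucleus_mask,
    nucleolus_masks = nucleolus_masks,
    nucleolus_labels = nucleolus_labels,
    rim_mask = rim_mask_true,
    focus_mask = focus_mask,
    foci_centers_px = foci_centers,
    true_shell_offsets_nm = vapply(params$marker_shells, `[[`, numeric(1),
                                   "offset_nm"),
    true_ratio_interior = lv$interior_factor,
    true_ratio_rim = lv$rim_factor,
    shape = true_shape_metrics(params$nucleoli),
    seed = params$seed
  )

  # --- optics and noise -------------------------------------------------
  n_ch <- length(ideal)
  psf <- params$optics$psf_sigma_nm
  if (length(psf) == 1L) psf <- rep(psf, n_ch)
  shifts <- params$optics$chromatic_shift_px
  if (is.null(shifts)) shifts <- rep(list(c(0, 0)), n_ch)
  pixels <- array(0, c(ny, nx, n_ch))
  for (ch in seq_len(n_ch)) {
    img <- ideal[[ch]]
    img <- fourier_shift(img, shifts[[ch]][1], shifts[[ch]][2])
    img <- gaussian_blur(img, psf[ch] / px)
    img[img < 0] <- 0
    if (is.finite(params$noise$photon_scale)) {
      img <- matrix(stats::rpois(length(img), params$noise$photon_scale * img) /
                      params$noise$photon_scale, ny, nx)
    }
    if (params$noise$read_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, params$noise$read_sigma),
                          ny, nx)
    }
    img[img < 0] <- 0
    pixels[, , ch] <- img
  }

  scene <- image_scene(pixels, px, roles,
                       metadata = list(generator = "generate_scene",
                                       seed = params$seed))
  list(scene = scene, truth = truth)
}

# Exact shape metrics for each nucleolus boundary: area and perimeter by
# dense quadrature of the polar boundary, second moments (for the
# moments-equivalent-ellipse aspect ratio) by 8x super-sampled
# rasterisation.
true_shape_metrics <- function(nucleoli, n_theta = 8192L, supersample = 8L) {
  purrr::imap_dfr(nucleoli, function(sp, i) {
    th <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
    r <- boundary_radius(sp, th)
    dr <- boundary_radius_deriv(sp, th)
    area <- 0.5 * sum(r^2) * (2 * pi / n_theta)
    perim <- sum(sqrt(r^2 + dr^2)) * (2 * pi / n_theta)
    # super-sampled raster for the moment ellipse
    rmax <- sp$base_radius_px *
      (1 + sum(abs(vapply(sp$irregularity, `[`, numeric(1), 2L)))) + 1
    s <- 1 / supersample
    g <- seq(-rmax, rmax, by = s)
    gy <- rep(g, times = length(g)); gx <- rep(g, each = length(g))
    inside <- sqrt(gy^2 + gx^2) <= boundary_radius(sp, atan2(gy, gx))
    yy <- gy[inside]; xx <- gx[inside]
    mu_y <- mean(yy); mu_x <- mean(xx)
    cyy <- mean((yy - mu_y)^2); cxx <- mean((xx - mu_x)^2)
    cyx <- mean((yy - mu_y) * (xx - mu_x))
    tr <- cyy + cxx; det_ <- cyy * cxx - cyx^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
    l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det_, 0))
    tibble::tibble(
      nucleolus = i, area_px = area, perimeter_px = perim,
      aspect_ratio = sqrt(l1 / l2),
      circularity = 4 * pi * area / perim^2
    )
  })
}

#' Generate 1D two-channel boundary line profiles
#'
#' Direct fixture for the peak-displacement measurement: each profile is a
#' pair of Gaussian peaks (shell sigma in nm) on a flat baseline, sampled
#' at one pixel spacing along an outside-to-inside axis. The two channels'
#' peak positions differ by `offsets_nm[1] - offsets_nm[2]`; positive
#' offsets point towards the nucleolar interior (larger positions).
#'
#' @param offsets_nm Length-2 signed peak offsets (channel a, channel b).
#' @param shell_sigma_nm Gaussian sigma of both peaks, nm.
#' @param pixel_size_nm Sample spacing, nm.
#' @param n_lines Number of profiles.
#' @param noise `NULL` for none, else list with `sd` (additive Gaussian SD
#'   relative to unit peak amplitude) and `baseline` (flat offset).
#' @param seed Integer seed.
#' @param n_samples Samples per profile.
#' @param center_jitter_nm Half-range of the uniform jitter of the boundary
#'   position between lines.
#' @return List of `"line_profile"` objects with channels `"a"` and `"b"`.
#' @export
generate_line_profiles <- function(offsets_nm, shell_sigma_nm = 100,
                                   pixel_size_nm = 40, n_lines = 1L,
                                   noise = list(sd = 0.05, baseline = 0.05),
                                   seed = 1L, n_samples = 48L,
                                   center_jitter_nm = 80) {
  stopifnot(n_lines >= 1L, length(offsets_nm) == 2L)
  set.seed(seed)
  pos <- (seq_len(n_samples) - 1) * pixel_size_nm
  mid <- mean(range(pos))
  baseline <- if (is.null(noise)) 0 else noise$baseline
  lapply(seq_len(n_lines), function(i) {
    b <- mid + stats::runif(1, -center_jitter_nm, center_jitter_nm)
    mk <- function(offset) {
      v <- baseline + exp(-(pos - (b + offset))^2 / (2 * shell_sigma_nm^2))
      if (!is.null(noise) && noise$sd > 0) {
        v <- v + stats::rnorm(n_samples, 0, noise$sd)
      }
      v
    }
    line_profile(positions_nm = pos,
                 intensities = cbind(a = mk(offsets_nm[1]), b = mk(offsets_nm[2])),
                 pixel_size_nm = pixel_size_nm, width_px = 2L,
                 direction = c(0, 1), id = i,
                 true_peaks_nm = c(a = b + offsets_nm[1], b = b + offsets_nm[2]))
  })
}

#' Generate raw FRAP traces with known ground truth
#'
#' The bleach-region trace follows
#' `baseline * exp(-kappa t) * inner(t)` with
#' `inner = 1` before the bleach and
#' `inner = floor + (1 - floor) * mobile * (1 - exp(-rate tau))` after it
#' (`tau` = frames since the bleach), so the double-normalised plateau is
#' `floor + (1 - floor) * mobile`. The reference region decays by
#' acquisition bleaching only and the background is constant; all three
#' traces include the background offset and additive Gaussian noise.
#'
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param rate_per_frame Recovery rate per frame (>= 0).
#' @param n_frames Total frames.
#' @param n_prebleach Pre-bleach frames (>= 1).
#' @param acquisition_bleach_per_frame Acquisition photobleaching rate.
#' @param noise_sigma Relative additive noise SD.
#' @param n_curves Number of traces.
#' @param seed Integer seed.
#' @param bleach_floor Immediate post-bleach level relative to pre-bleach.
#' @param baseline,reference_level,background_level Raw intensity levels.
#' @return List of `"frap_trace"` tibbles (frame, bleach, reference,
#'   background) with attributes `n_prebleach` and `bleach_frame`.
#' @export
generate_frap_series <- function(mobile_fraction, rate_per_frame,
                                 n_frames = 400L, n_prebleach = 10L,
                                 acquisition_bleach_per_frame = 5e-4,
                                 noise_sigma = 0.01, n_curves = 1L,
                                 seed = 1L, bleach_floor = 0.3,
                                 baseline = 1000, reference_level = 1000,
                                 background_level = 50) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, rate_per_frame >= 0,
            n_prebleach >= 1L, n_frames > n_prebleach)
  set.seed(seed)
  t <- seq_len(n_frames) - 1
  bleach_frame <- n_prebleach + 1L
  tau <- pmax(0, seq_len(n_frames) - bleach_frame + 1L)
  inner <- ifelse(seq_len(n_frames) <= n_prebleach, 1,
                  bleach_floor + (1 - bleach_floor) * mobile_fraction *
                    (1 - exp(-rate_per_frame * tau)))
  acq <- exp(-acquisition_bleach_per_frame * t)
  lapply(seq_len(n_curves), function(i) {
    noisy <- function(x, level) {
      if (noise_sigma > 0) x + stats::rnorm(n_frames, 0, noise_sigma * level) else x
    }
    frap_trace(
      frame = seq_len(n_frames),
      bleach = noisy(background_level + baseline * acq * inner, baseline),
      reference = noisy(background_level + reference_level * acq, reference_level),
      background = noisy(rep(background_level, n_frames), background_level),
      n_prebleach = n_prebleach
    )
  })
}

#' Generate a per-cell screen table with known effects
#'
#' Emulates the tabular output of a high-content RNAi screen: wells of
#' cells with a class label and a right-skewed nucleolar aspect-ratio draw,
#' `AR = 1 + Lognormal(log(control_median - 1 + shift), sdlog)`, so the
#' per-gene shift moves the population median of `AR - 1`.
#'
#' @param n_genes,sirnas_per_gene,wells_per_sirna,cells_per_well Layout.
#' @param effect_map Named numeric vector of per-gene aspect-ratio shifts
#'   (unnamed genes shift 0), or a single unnamed vector recycled over
#'   genes in order.
#' @param apoptotic_fraction_map Named per-gene apoptotic fraction
#'   (default 0.05 everywhere).
#' @param seed Integer seed.
#' @param n_control_wells Wells of the non-targeting control.
#' @param control_median Control median aspect ratio (irregular nucleoli).
#' @param sdlog Lognormal shape parameter of the per-cell draw.
#' @param mitotic_fraction Fraction of mitotic cells per well.
#' @return Tibble with columns well, gene, sirna, cell, class,
#'   aspect_ratio.
#' @export
generate_screen_table <- function(n_genes = 50L, sirnas_per_gene = 2L,
                                  wells_per_sirna = 3L, cells_per_well = 200L,
                                  effect_map = NULL,
                                  apoptotic_fraction_map = NULL,
                                  seed = 1L, n_control_wells = 24L,
                                  control_median = 1.5, sdlog = 0.4,
                                  mitotic_fraction = 0.05) {
  stopifnot(n_genes >= 1L, sirnas_per_gene >= 1L, wells_per_sirna >= 1L,
            cells_per_well >= 1L)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  shift_of <- function(g) {
    if (is.null(effect_map)) 0
    else if (!is.null(names(effect_map))) {
      if (g %in% names(effect_map)) unname(effect_map[[g]]) else 0
    } else effect_map[[match(g, genes)]]
  }
  apo_of <- function(g) {
    if (is.null(apoptotic_fraction_map)) 0.05
    else if (g %in% names(apoptotic_fraction_map))
      unname(apoptotic_fraction_map[[g]])
    else 0.05
  }
  draw_well <- function(well, gene, sirna, shift, apo) {
    stopifnot(apo >= 0, apo <= 1)
    m <- max(control_median - 1 + shift, 0.05)
    cls <- sample(c("apoptotic", "mitotic", "interphase"), cells_per_well,
                  replace = TRUE,
                  prob = c(apo, mitotic_fraction * (1 - apo),
                           (1 - mitotic_fraction) * (1 - apo)))
    tibble::tibble(
      well = well, gene = gene, sirna = sirna,
      cell = seq_len(cells_per_well), class = cls,
      aspect_ratio = 1 + stats::rlnorm(cells_per_well, log(m), sdlog)
    )
  }
  out <- list()
  for (g in genes) {
    for (s in seq_len(sirnas_per_gene)) {
      for (w in seq_len(wells_per_sirna)) {
        out[[length(out) + 1L]] <-
          draw_well(sprintf("%s_s%d_w%d", g, s, w), g,
                    sprintf("%s_si%d", g, s), shift_of(g), apo_of(g))
      }
    }
  }
  for (w in seq_len(n_control_wells)) {
    out[[length(out) + 1L]] <-
      draw_well(sprintf("control_w%02d", w), "control", "siControl", 0,
                apo_of("control"))
  }
  dplyr::bind_rows(out)
}

#' Generate a two-channel bead calibration scene
#'
#' Renders Gaussian spots at common positions in two channels, with channel
#' `marker_a` displaced by a known sub-pixel chromatic shift relative to
#' `marker_b` — the fixture for bead-based chromatic-aberration
#' calibration.
#'
#' @param n_beads Number of beads.
#' @param shift_px `(dy, dx)` true shift of channel a relative to b, px.
#' @param image_size_px,pixel_size_nm Field geometry.
#' @param bead_sigma_px Spot Gaussian sigma, px.
#' @param amplitude,background Intensity levels.
#' @param noise Noise list as in [scene_params()].
#' @param seed Integer seed.
#' @param min_sep_px Minimum bead separation.
#' @return List with `scene` (roles `marker_a`, `marker_b`) and `truth`
#'   (bead positions, true shift).
#' @export
generate_bead_scene <- function(n_beads = 50L, shift_px = c(0, 0),
                                image_size_px = c(256L, 256L),
                                pixel_size_nm = 40, bead_sigma_px = 1.5,
                                amplitude = 400, background = 10,
                                noise = list(photon_scale = 1, read_sigma = 2),
                                seed = 1L, min_sep_px = 12) {
  set.seed(seed)
  ny <- image_size_px[1]; nx <- image_size_px[2]
  margin <- 10
  pos <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pos) < n_beads && tries < 20000) {
    p <- c(stats::runif(1, margin, ny - margin), stats::runif(1, margin, nx - margin))
    if (nrow(pos) == 0 ||
        min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >= min_sep_px) {
      pos <- rbind(pos, p)
    }
    tries <- tries + 1
  }
  if (nrow(pos) < n_beads) stop("could not place beads with the requested separation")
  render <- function(centers) {
    img <- matrix(background, ny, nx)
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      ys <- max(1, floor(cy - 6)):min(ny, ceiling(cy + 6))
      xs <- max(1, floor(cx - 6)):min(nx, ceiling(cx + 6))
      img[ys, xs] <- img[ys, xs] + amplitude *
        exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) / (2 * bead_sigma_px^2))
    }
    img
  }
  apply_noise <- function(img) {
    if (is.finite(noise$photon_scale)) {
      img <- matrix(stats::rpois(length(img), noise$photon_scale * img) /
                      noise$photon_scale, ny, nx)
    }
    if (noise$read_sigma > 0) {
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise$read_sigma),
                               ny, nx), 0)
    }
    img
  }
  a <- apply_noise(render(sweep(pos, 2, shift_px, "+")))
  b <- apply_noise(render(pos))
  scene <- image_scene(array(c(a, b), c(ny, nx, 2)), pixel_size_nm,
                       c(marker_a = 1L, marker_b = 2L),
                       metadata = list(generator = "generate_bead_scene"))
  list(scene = scene, truth = list(positions_px = pos, shift_px = shift_px))
}
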