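#' Multichannel image scene
#'
#' An `image_scene` is the basic in-memory container for a single-plane
#' multichannel fluorescence image: a 3D numeric array laid out
#' `[y, x, channel]`, a physical pixel size in nanometres, and a named map
#' from biological channel roles (e.g. `"chromatin"`, `"nucleolus"`,
#' `"marker_a"`) to channel indices.
#'
#' @param pixels 3D numeric array `[y, x, channel]` of finite, non-negative
#'   intensities. A 2D matrix is promoted to a single-channel array.
#' @param pixel_size_nm Positive scalar; physical size of a pixel in nm.
#'   Pixels are assumed square (analyses are 2D single-plane).
#' @param channel_roles Named integer vector mapping role names to channel
#'   indices (1-based). Roles must be unique and indices valid.
#' @param metadata Free-form named list of provenance information.
#'
#' @return An object of class `"image_scene"`.
#' @seealso [z_stack()], [read_scene()], [select_focus_slice()]
#' @export
image_scene <- function(pixels, pixel_size_nm, channel_roles, metadata = list()) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("scene intensities must be finite")
  }
  if (any(pixels < 0)) stop("scene intensities must be non-negative")
  check_roles(channel_roles, dim(pixels)[3L])
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a positive scalar")
  }
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         channel_roles = channel_roles, metadata = metadata),
    class = "image_scene"
  )
}

#' Multichannel z-stack
#'
#' @param pixels 4D numeric array `[y, x, channel, z]`.
#' @param z_step_nm Positive scalar; axial spacing between slices in nm.
#' @inheritParams image_scene
#' @return An object of class `"z_stack"`.
#' @export
z_stack <- function(pixels, pixel_size_nm, channel_roles, z_step_nm = NA_real_,
                    metadata = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L, dim(pixels)[4L] >= 1L)
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("stack intensities must be finite and non-negative")
  }
  check_roles(channel_roles, dim(pixels)[3L])
  stopifnot(is.numeric(pixel_size_nm), pixel_size_nm > 0)
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         z_step_nm = as.numeric(z_step_nm), channel_roles = channel_roles,
         metadata = metadata),
    class = "z_stack"
  )
}

check_roles <- function(channel_roles, n_channels) {
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles)))) {
    stop("channel_roles must be a named integer vector")
  }
  if (anyDuplicated(names(channel_roles))) stop("channel roles must be unique")
  idx <- as.integer(channel_roles)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_channels)) {
    stop("channel role indices must lie in 1..", n_channels)
  }
  invisible(TRUE)
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_scene> %d x %d px, %d channel(s), %.1f nm/px\n",
              d[1], d[2], d[3], x$pixel_size_nm))
  cat("roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                              x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<z_stack> %d x %d px, %d channel(s), %d slice(s), %.1f nm/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size_nm))
  invisible(x)
}

#' Extract one channel of a scene by role
#'
#' @param scene An [image_scene()].
#' @param role Role name present in `scene$channel_roles`.
#' @return Numeric matrix `[y, x]`.
#' @export
scene_channel <- function(scene, role) {
  stopifnot(inherits(scene, "image_scene"))
  if (!role %in% names(scene$channel_roles)) {
    stop("unknown channel role: ", role)
  }
  scene$pixels[, , scene$channel_roles[[role]], drop = TRUE]
}

#' Read a TIFF / OME-TIFF image into a scene or z-stack
#'
#' Reads a single- or multi-page TIFF. Pages are interpreted as channels
#' (channel-fastest) when the page count equals the declared channel count,
#' and as a z-stack of `pages / n_channels` slices when it is a multiple of
#' it. Pixel size and channel roles come from the caller (configuration),
#' not from embedded metadata, whose dialects vary between writers; pixel
#' values are preserved bit-exactly for integer TIFFs.
#'
#' @param path Path to a TIFF file.
#' @param channel_roles Named integer vector of roles (see [image_scene()]).
#' @param pixel_size_nm Pixel size in nm.
#' @param n_channels Number of channels interleaved in the file. Defaults to
#'   the largest declared role index (or the page count for a single-role
#'   file with multiple identical-size pages when only one role is given).
#' @return An [image_scene()] if one focal plane is present, otherwise a
#'   [z_stack()].
#' @export
read_scene <- function(path, channel_roles, pixel_size_nm,
                       n_channels = max(as.integer(channel_roles))) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      stop("multi-sample TIFF pages are not supported; write one page per channel")
    }
    if (!is.numeric(p)) stop("non-numeric pixel data in ", path)
    p
  })
  n_pages <- length(pages)
  if (n_channels > n_pages || n_pages %% n_channels != 0L) {
    stop(sprintf("file has %d page(s) which is not a multiple of %d channel(s)",
                 n_pages, n_channels))
  }
  check_roles(channel_roles, n_channels)
  n_z <- n_pages %/% n_channels
  d <- dim(pages[[1L]])
  arr <- array(0, c(d[1L], d[2L], n_channels, n_z))
  for (z in seq_len(n_z)) {
    for (ch in seq_len(n_channels)) {
      arr[, , ch, z] <- pages[[(z - 1L) * n_channels + ch]]
    }
  }
  meta <- list(source = path, n_pages = n_pages)
  if (n_z == 1L) {
    image_scene(arr[, , , 1L, drop = TRUE], pixel_size_nm, channel_roles,
                metadata = meta)
  } else {
    z_stack(arr, pixel_size_nm, channel_roles, metadata = meta)
  }
}

#' Write a scene to a multi-page 16-bit TIFF
#'
#' Channels (and slices, channel-fastest) are written as successive pages.
#' Integer intensities up to 65535 round-trip bit-exactly through
#' [read_scene()].
#'
#' @param scene An [image_scene()] or [z_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  px <- scene$pixels
  if (length(dim(px)) == 3L) dim(px) <- c(dim(px), 1L)
  if (max(px) > 65535 || any(px != round(px))) {
    stop("write_scene stores 16-bit integer TIFFs; intensities must be ",
         "integers in [0, 65535]")
  }
  pages <- list()
  for (z in seq_len(dim(px)[4L])) {
    for (ch in seq_len(dim(px)[3L])) {
      pages[[length(pages) + 1L]] <- px[, , ch, z] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Select the in-focus slice of a z-stack
#'
#' Picks the slice with the highest whole-frame mean intensity in the named
#' channel (conventionally the nucleolar marker). Ties are broken towards
#' the lowest z index so selection is deterministic.
#'
#' @param stack A [z_stack()].
#' @param role Channel role used to score slices.
#' @return An [image_scene()] carrying all channels of the chosen slice;
#'   the selected index is recorded in `metadata$focus_slice`.
#' @export
select_focus_slice <- function(stack, role) {
  stopifnot(inherits(stack, "z_stack"))
  if (!role %in% names(stack$channel_roles)) stop("unknown role: ", role)
  ch <- stack$channel_roles[[role]]
  means <- apply(stack$pixels[, , ch, , drop = FALSE], 4L, mean)
  z_sel <- which.max(means)            # which.max takes the first maximum
  meta <- stack$metadata
  meta$focus_slice <- as.integer(z_sel)
  meta$focus_role <- role
  slice <- stack$pixels[, , , z_sel, drop = FALSE]
  dim(slice) <- dim(slice)[1:3]
  image_scene(slice, stack$pixel_size_nm, stack$channel_roles, metadata = meta)
}

#' Write a measurement table to CSV
#'
#' Numeric columns are written at full double precision and round-trip
#' losslessly through [read_measurements()].
#'
#' @param table A data frame of measurements.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read an analysis configuration file
#'
#' YAML configuration holding pixel size, channel roles and the numeric
#' parameters of the segmentation/profile/displacement stages. Returned as
#' a plain named list; `channel_roles` entries, if present, are coerced to
#' a named integer vector.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$channel_roles)) {
    cfg$channel_roles <- unlist(cfg$channel_roles)
    storage.mode(cfg$channel_roles) <- "integer"
  }
  cfg
}
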