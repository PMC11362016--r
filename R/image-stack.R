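#' Multi-channel 3D image stack
#'
#' Container for a voxel grid with one or more intensity channels and a
#' physical voxel spacing. Arrays are indexed `[x, y, z]` and the physical
#' coordinate of voxel `(i, j, k)` is `(i-1, j-1, k-1) * spacing` micrometres
#' (grid registered at voxel centres).
#'
#' @param channels named list of 3D numeric arrays, all with the same
#'   dimensions. Intensities must be non-negative.
#' @param spacing numeric length-3, micrometres per voxel along x, y, z.
#' @return an object of class `image_stack`.
#' @examples
#' st <- image_stack(list(gfp = array(0, c(4, 4, 2))), spacing = c(1, 1, 2))
#' dim(st)
#' @export
image_stack <- function(channels, spacing) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("'channels' must be a named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stopf("all channels must be 3D arrays")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stopf("all channels must share one grid shape")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L) stopf("'spacing' must have length 3")
  check_positive(spacing, "spacing")
  structure(list(channels = channels, spacing = spacing),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

get_channel <- function(stack, channel) {
  if (!inherits(stack, "image_stack")) stopf("expected an 'image_stack'")
  if (!channel %in% names(stack$channels))
    stopf("channel '%s' not present (have: %s)", channel,
          paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]]
}

#' Write / read an image stack as multi-page TIFF plus a YAML sidecar
#'
#' Each channel is written as `<name>_<channel>.tif` (one page per z slice,
#' 32-bit float) and the voxel spacing and channel names are recorded in
#' `<name>.yaml`.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return `write_image_stack` returns the sidecar path invisibly;
#'   `read_image_stack` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, dir, name = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  scales <- offsets <- numeric(0)
  for (ch in names(stack$channels)) {
    vol <- stack$channels[[ch]]
    # TIFF samples are stored in [0, 1]; keep the affine map in the sidecar
    # (read noise can make intensities slightly negative)
    lo <- min(min(vol), 0)
    sc <- max(max(vol) - lo, .Machine$double.eps)
    vol <- pmin(pmax((vol - lo) / sc, 0), 1)
    dim(vol) <- dim(stack)
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
    f <- file.path(dir, sprintf("%s_%s.tif", name, ch))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L)
    files[ch] <- basename(f)
    scales[ch] <- sc
    offsets[ch] <- lo
  }
  side <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(list(spacing_um = as.list(stack$spacing),
                        channels = as.list(files),
                        intensity_scale = as.list(scales),
                        intensity_offset = as.list(offsets)), side)
  invisible(side)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir, name = "stack") {
  side <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(side)) stopf("sidecar '%s' not found", side)
  meta <- yaml::read_yaml(side)
  channels <- lapply(names(meta$channels), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, meta$channels[[ch]]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    off <- if (is.null(meta$intensity_offset)) 0 else
      meta$intensity_offset[[ch]]
    arr * meta$intensity_scale[[ch]] + off
  })
  names(channels) <- names(meta$channels)
  image_stack(channels, spacing = unlist(meta$spacing_um))
}
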