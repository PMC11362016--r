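#' Parameters for density-based region segmentation
#'
#' Controls the fixed filtering/binarization pipeline used by
#' [extract_lobe_mask()] and [segment_dense_region()]: per-slice 2D median
#' filtering, 3D Gaussian smoothing in physical units, min-max normalization
#' with a fractional threshold, morphological closing and a minimum component
#' volume. All spatial parameters are micrometres except the median radius,
#' which is in pixels per slice.
#'
#' The original interactive intensity thresholds are interpreted as a
#' fractional threshold applied after min-max normalization. `normalize`
#' selects the normalization window: `"slice"` rescales each z slice by its
#' own min and max (a slice whose min equals max contributes no foreground);
#' `"volume"` uses the global min and max, which is more stable when a
#' bright structure is present only in some slices. `threshold_method =
#' "otsu"` replaces the fixed fraction by the median per-slice Otsu
#' threshold of the normalized volume.
#'
#' @param median_radius per-slice 2D median filter radius in pixels (0
#'   disables).
#' @param gaussian_sigma isotropic physical sigma in micrometres, divided by
#'   the per-axis spacing to honour anisotropy (0 disables).
#' @param binarize_threshold fraction in (0, 1) applied after normalization.
#' @param min_component_volume components below this volume (um^3) are
#'   dropped after closing.
#' @param closing_radius morphological closing radius in micrometres.
#' @param normalize `"slice"` or `"volume"` min-max window.
#' @param threshold_method `"fixed"` or `"otsu"`.
#' @param norm_quantile upper anchor of the `"volume"` normalization: 1 uses
#'   the maximum voxel; a high quantile (e.g. 0.999) is a much more stable
#'   anchor on shot-noise-limited volumes, whose single brightest voxel
#'   fluctuates by several percent between acquisitions.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius = 2,
                                gaussian_sigma = 5,
                                binarize_threshold = 0.5,
                                min_component_volume = 1e4,
                                closing_radius = 3,
                                normalize = c("slice", "volume"),
                                threshold_method = c("fixed", "otsu"),
                                norm_quantile = 1) {
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stopf("binarize_threshold must be in the open interval (0, 1)")
  if (median_radius < 0 || gaussian_sigma < 0 || closing_radius < 0 ||
      min_component_volume < 0)
    stopf("radii, sigmas and volumes must be >= 0")
  if (norm_quantile <= 0 || norm_quantile > 1)
    stopf("norm_quantile must be in (0, 1]")
  structure(list(median_radius = median_radius,
                 gaussian_sigma = gaussian_sigma,
                 binarize_threshold = binarize_threshold,
                 min_component_volume = min_component_volume,
                 closing_radius = closing_radius,
                 normalize = match.arg(normalize),
                 threshold_method = match.arg(threshold_method),
                 norm_quantile = norm_quantile),
            class = "segmentation_params")
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# 2D median (per slice) then 3D Gaussian smoothing in physical units.
# Output is on the global [0, 1] intensity scale of the input volume, which
# makes downstream thresholds invariant to positive rescaling of the input.
filter_volume <- function(vol, spacing, params) {
  rng <- range(vol)
  if (rng[2] > rng[1]) vol <- (vol - rng[1]) / (rng[2] - rng[1])
  else vol <- array(0, dim(vol))
  if (params$median_radius > 0) {
    for (k in seq_len(dim(vol)[3]))
      vol[, , k] <- EBImage::medianFilter(vol[, , k],
                                          size = params$median_radius)
  }
  if (params$gaussian_sigma > 0) {
    dm <- dim(vol)
    for (ax in 1:3) {
      kern <- gaussian_kernel_1d(params$gaussian_sigma / spacing[ax])
      if (length(kern) > 1)
        vol <- array(cpp_conv_axis(vol, dm, kern, ax), dm)
    }
  }
  vol
}

otsu_threshold <- function(vol) {
  # median of per-slice Otsu thresholds on the normalized volume
  th <- vapply(seq_len(dim(vol)[3]), function(k) {
    sl <- vol[, , k]
    if (diff(range(sl)) <= 0) return(NA_real_)
    EBImage::otsu(EBImage::Image(pmin(pmax(sl, 0), 1)), range = c(0, 1))
  }, 0)
  th <- th[is.finite(th)]
  if (!length(th)) stopf("Otsu thresholding failed: volume is constant")
  median(th)
}

binarize_minmax <- function(vol, params) {
  thr <- params$binarize_threshold
  q <- params$norm_quantile %||% 1
  if (params$normalize == "volume") {
    # a high quantile is a far more stable intensity anchor than the single
    # maximum voxel of a shot-noise-limited volume
    hi <- if (q < 1) quantile(vol, q, names = FALSE) else max(vol)
    lo <- min(vol)
    if (hi <= lo) return(array(FALSE, dim(vol)))
    norm <- (vol - lo) / (hi - lo)
    if (params$threshold_method == "otsu") thr <- otsu_threshold(norm)
    return(norm >= thr)
  }
  out <- array(FALSE, dim(vol))
  norm <- array(0, dim(vol))
  for (k in seq_len(dim(vol)[3])) {
    sl <- vol[, , k]
    rng <- range(sl)
    if (rng[2] <= rng[1]) next                 # degenerate slice: no foreground
    norm[, , k] <- (sl - rng[1]) / (rng[2] - rng[1])
  }
  if (params$threshold_method == "otsu") thr <- otsu_threshold(norm)
  for (k in seq_len(dim(vol)[3])) {
    sl <- vol[, , k]
    if (diff(range(sl)) <= 0) next
    out[, , k] <- norm[, , k] >= thr
  }
  out
}

morph_close <- function(mask, radius, spacing) {
  if (radius <= 0 || !any(mask) || all(mask)) return(mask)
  dm <- dim(mask)
  dil <- array(cpp_edt_sq(mask, dm, spacing) <= radius^2, dm)
  if (all(dil)) return(mask)  # closing cannot be computed; keep input
  ero <- array(cpp_edt_sq(!dil, dm, spacing) > radius^2, dm)
  ero
}

morph_erode <- function(mask, radius, spacing) {
  if (radius <= 0 || !any(mask)) return(mask)
  dm <- dim(mask)
  if (all(mask)) return(mask)
  array(cpp_edt_sq(!mask, dm, spacing) > radius^2, dm)
}

morph_open <- function(mask, radius, spacing) {
  if (radius <= 0 || !any(mask) || all(mask)) return(mask)
  dm <- dim(mask)
  ero <- array(cpp_edt_sq(!mask, dm, spacing) > radius^2, dm)
  if (!any(ero)) return(ero)
  array(cpp_edt_sq(ero, dm, spacing) <= radius^2, dm)
}

drop_small_components <- function(mask, min_volume, spacing) {
  if (min_volume <= 0 || !any(mask)) return(mask)
  lab <- cpp_label3d(mask, dim(mask))
  sizes <- tabulate(lab)
  keep <- which(sizes * prod(spacing) >= min_volume)
  array(lab %in% keep, dim(mask))
}

fill_holes <- function(mask) {
  dm <- dim(mask)
  lab <- cpp_label3d(!mask, dm)
  lab <- array(lab, dm)
  border <- unique(c(lab[1, , ], lab[dm[1], , ], lab[, 1, ], lab[, dm[2], ],
                     lab[, , 1], lab[, , dm[3]]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

largest_component <- function(mask) {
  lab <- cpp_label3d(mask, dim(mask))
  sizes <- tabulate(lab)
  if (!length(sizes)) return(mask)
  array(lab == which.max(sizes), dim(mask))
}

#' Extract the whole-lobe mask
#'
#' Smooths the summed nuclear reporter channels (every cell carries one of
#' the two reporters, so their sum covers the whole tissue; in particular
#' tdTomato-negative HD regions still contribute GFP signal), binarizes,
#' applies a generous morphological closing to bridge the gaps between
#' sparse nuclei, fills interior holes and keeps the single largest
#' connected component.
#'
#' The defaults differ from [segmentation_params()] defaults because the
#' lobe is reconstructed from a sparse point process rather than a dense
#' plateau: a wider Gaussian (10 um), a lower threshold (0.2 with
#' volume-wide normalization) and a 15-um closing.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()].
#' @param channels channels to sum; defaults to all channels in the stack.
#' @return logical lobe mask (3D array).
#' @export
extract_lobe_mask <- function(stack,
                              params = segmentation_params(
                                gaussian_sigma = 10,
                                binarize_threshold = 0.2,
                                closing_radius = 15,
                                normalize = "volume"),
                              channels = NULL) {
  if (is.null(channels)) channels <- names(stack$channels)
  missing_ch <- setdiff(channels, names(stack$channels))
  if (length(missing_ch))
    stopf("channel(s) not present: %s", paste(missing_ch, collapse = ", "))
  vol <- Reduce(`+`, stack$channels[channels])
  if (all(vol == 0)) stopf("lobe channel(s) identically zero")
  sm <- filter_volume(vol, stack$spacing, params)
  mask <- binarize_minmax(sm, params)
  mask <- morph_close(mask, params$closing_radius, stack$spacing)
  mask <- drop_small_components(mask, params$min_component_volume,
                                stack$spacing)
  if (!any(mask)) stopf("lobe segmentation is empty")
  mask <- largest_component(mask)
  fill_holes(mask)
}

#' Segment a dense nuclear region from one or more channels
#'
#' Fixed pipeline: (1) sum the named channels; (2) per-slice 2D median
#' filter; (3) 3D Gaussian filter in physical units; (4) min-max
#' normalization and fractional threshold; (5) morphological closing;
#' (6) drop components below the minimum volume; (7) intersect with
#' `restrict_to`. Used for the medulla (GFP plus a keratin-like channel,
#' combined) and for HD-TEC regions (GFP only).
#'
#' @param stack an [image_stack()].
#' @param channels character vector of channel names to sum.
#' @param params a [segmentation_params()].
#' @param restrict_to optional logical mask (e.g. the lobe) intersected with
#'   the result.
#' @return logical region mask.
#' @export
segment_dense_region <- function(stack, channels,
                                 params = segmentation_params(),
                                 restrict_to = NULL) {
  missing_ch <- setdiff(channels, names(stack$channels))
  if (length(missing_ch))
    stopf("channel(s) not present: %s", paste(missing_ch, collapse = ", "))
  vol <- Reduce(`+`, stack$channels[channels])
  sm <- filter_volume(vol, stack$spacing, params)
  mask <- binarize_minmax(sm, params)
  mask <- morph_close(mask, params$closing_radius, stack$spacing)
  mask <- drop_small_components(mask, params$min_component_volume,
                                stack$spacing)
  if (!is.null(restrict_to)) mask <- mask & restrict_to
  mask
}

#' Compose lobe, medulla and HD masks into disjoint regions
#'
#' Voxels claimed by both the raw medulla and raw HD masks are assigned to
#' HD (the stricter, compaction-defined region), and the cortex is computed
#' by subtraction, so that cortex + medulla + HD = lobe exactly on voxel
#' counts.
#'
#' @param lobe,medulla_raw,hd_raw logical masks on one grid; `hd_raw` may be
#'   `NULL` (young-thymus case, no HD term).
#' @param spacing voxel spacing in micrometres.
#' @return a [region_mask_set()].
#' @export
compose_regions <- function(lobe, medulla_raw, hd_raw = NULL, spacing) {
  if (is.null(hd_raw)) hd_raw <- array(FALSE, dim(lobe))
  if (!identical(dim(lobe), dim(medulla_raw)) ||
      !identical(dim(lobe), dim(hd_raw)))
    stopf("all masks must be on one grid")
  if (any(medulla_raw & !lobe))
    stopf("medulla mask extends outside the lobe; restrict it to the lobe first")
  hd <- hd_raw & lobe
  medulla <- medulla_raw & !hd                 # overlap goes to HD
  cortex <- lobe & !medulla & !hd
  region_mask_set(list(lobe = lobe, medulla = medulla, hd = hd,
                       cortex = cortex), spacing)
}

#' Segment all thymic regions of a two-channel reporter stack
#'
#' Convenience pipeline for aged/young nuclear-reporter volumes in which
#' every cell carries exactly one reporter (GFP for epithelium, tdTomato for
#' everything else) and HD-TEC clusters are GFP-dense but tdTomato-free:
#' \enumerate{
#'   \item lobe from the summed channels ([extract_lobe_mask()]);
#'   \item a GFP-dense mask at `medulla_threshold` (medulla plus HD);
#'   \item a tdTomato-positive mask at `tdtom_threshold`;
#'   \item HD candidate: GFP at the higher `hd_threshold`, minus the
#'     tdTomato mask eroded by `hd_guard_erosion` (compensates reporter
#'     bleed at the medulla/HD interface), small components dropped;
#'   \item medulla: the dense mask restricted to tdTomato-positive voxels,
#'     opened by `medulla_opening` to cut the thin halo that smoothing
#'     creates around HD clusters;
#'   \item [compose_regions()] (overlap to HD, cortex by subtraction).
#' }
#' On young-type images (no compacted clusters) the tdTomato exclusion
#' leaves no HD candidate, so the HD mask is empty without special-casing.
#'
#' @param stack an [image_stack()] with `gfp` and `tdtom` channels.
#' @param medulla_threshold,hd_threshold,tdtom_threshold binarization
#'   fractions for the three passes (volume-normalized min-max).
#' @param gaussian_sigma smoothing sigma (um) for the region passes.
#' @param closing_radius closing radius (um) for the region passes.
#' @param hd_guard_erosion erosion (um) of the tdTomato mask before it vetoes
#'   HD voxels.
#' @param medulla_opening opening radius (um) applied to the medulla mask.
#' @param min_component_volume minimum component volume (um^3).
#' @param lobe_params optional [segmentation_params()] for the lobe pass.
#' @return a [region_mask_set()].
#' @export
segment_phantom_regions <- function(stack,
                                    medulla_threshold = 0.22,
                                    hd_threshold = 0.36,
                                    tdtom_threshold = 0.22,
                                    gaussian_sigma = 5,
                                    closing_radius = 6,
                                    hd_guard_erosion = 2,
                                    medulla_opening = 5,
                                    min_component_volume = 1e4,
                                    norm_quantile = 0.999,
                                    lobe_params = NULL) {
  lobe <- if (is.null(lobe_params)) extract_lobe_mask(stack)
          else extract_lobe_mask(stack, lobe_params)
  sp <- stack$spacing
  pars <- function(thr) segmentation_params(
    gaussian_sigma = gaussian_sigma, binarize_threshold = thr,
    min_component_volume = min_component_volume,
    closing_radius = closing_radius, normalize = "volume",
    norm_quantile = norm_quantile)
  dense <- segment_dense_region(stack, "gfp", pars(medulla_threshold),
                                restrict_to = lobe)
  td <- segment_dense_region(stack, "tdtom", pars(tdtom_threshold),
                             restrict_to = lobe)
  hd_hi <- segment_dense_region(stack, "gfp", pars(hd_threshold),
                                restrict_to = lobe)
  hd_raw <- drop_small_components(hd_hi & !morph_erode(td, hd_guard_erosion, sp),
                                  min_component_volume, sp)
  # opening cuts the thin halo around HD clusters; filling enclosed cavities
  # afterwards repairs speckle holes the tdTomato mask punched into the blobs
  med_raw <- drop_small_components(
    fill_holes(morph_open(dense & td & !hd_raw, medulla_opening, sp)),
    min_component_volume, sp)
  compose_regions(lobe, med_raw, hd_raw, sp)
}

#' Dice coefficient of two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
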