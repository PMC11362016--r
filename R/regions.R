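#' Physical volume of a binary mask
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in micrometres (length 3).
#' @return volume in cubic micrometres (voxel count times voxel volume).
#' @export
mask_volume <- function(mask, spacing) {
  check_positive(spacing, "spacing")
  sum(mask) * prod(spacing)
}

#' Region mask set for a thymic lobe
#'
#' Bundles the lobe, medulla, HD-TEC and cortex masks on one voxel grid with
#' their physical volumes. Constructed directly or, with overlap resolution
#' and cortex-by-subtraction, via [compose_regions()].
#'
#' @param masks named list of logical arrays `lobe`, `medulla`, `hd`,
#'   `cortex`, all on one grid. `medulla`, `hd` and `cortex` must be pairwise
#'   disjoint subsets of `lobe` and partition it.
#' @param spacing voxel spacing in micrometres.
#' @return object of class `region_mask_set` with elements `masks`,
#'   `spacing` and `volumes` (named, cubic micrometres).
#' @export
region_mask_set <- function(masks, spacing) {
  need <- c("lobe", "medulla", "hd", "cortex")
  if (!all(need %in% names(masks)))
    stopf("masks must include: %s", paste(need, collapse = ", "))
  masks <- masks[need]
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stopf("all masks must be on one grid")
  if (any(masks$medulla & !masks$lobe) || any(masks$hd & !masks$lobe) ||
      any(masks$cortex & !masks$lobe))
    stopf("medulla, hd and cortex must be subsets of lobe")
  if (any(masks$medulla & masks$hd) || any(masks$medulla & masks$cortex) ||
      any(masks$hd & masks$cortex))
    stopf("medulla, hd and cortex must be pairwise disjoint")
  if (!identical(sum(masks$medulla) + sum(masks$hd) + sum(masks$cortex),
                 sum(masks$lobe)))
    stopf("cortex + medulla + hd must partition the lobe")
  volumes <- vapply(masks, mask_volume, 0, spacing = spacing)
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 volumes = volumes),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat("region_mask_set (volumes in um^3):\n")
  print(round(x$volumes, 1))
  invisible(x)
}

#' @export
as.data.frame.region_mask_set <- function(x, ...) {
  data.frame(region = names(x$volumes),
             voxels = vapply(x$masks, sum, 0L),
             volume_um3 = unname(x$volumes),
             row.names = NULL)
}
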