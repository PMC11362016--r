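#' Distance rules for nucleus classification
#'
#' Encodes the compartment rules used for confocal sections: nuclei at
#' signed distance \eqn{\le 0} um to the medullary or HD surface are
#' medullary/HD, nuclei at signed distance \eqn{\ge -25} um to the section
#' edge are subcapsular, and the remainder are cortical (cTEC). Signed
#' distances are negative inside a surface.
#'
#' @param region_inside_threshold inclusion threshold (um) for the
#'   medullary/HD rule; default 0.
#' @param subcapsular_band_threshold edge-band threshold (um), must be
#'   \eqn{\le 0}; default -25 (within 25 um inside the edge).
#' @return object of class `classification_rules`.
#' @export
classification_rules <- function(region_inside_threshold = 0,
                                 subcapsular_band_threshold = -25) {
  if (subcapsular_band_threshold > 0)
    stopf("subcapsular_band_threshold must be <= 0")
  structure(list(region_inside_threshold = region_inside_threshold,
                 subcapsular_band_threshold = subcapsular_band_threshold),
            class = "classification_rules")
}

#' Detect nuclear spots by scale-space blob detection
#'
#' Laplacian-of-Gaussian detector: the channel is smoothed with an
#' anisotropy-corrected Gaussian at `sigma = diameter / (2 sqrt(3))` in
#' physical units, the scale-normalized negative Laplacian is computed with
#' per-axis physical spacing, and 26-neighborhood local maxima above
#' `score_threshold` are reported with sub-voxel centres (per-axis quadratic
#' interpolation). The response is linear in image intensity, so doubling
#' both the intensities and the threshold leaves detections unchanged.
#'
#' @param stack an [image_stack()].
#' @param channel channel to detect in.
#' @param diameter_um expected nuclear diameter in micrometres; must be at
#'   least one voxel on every axis.
#' @param score_threshold minimum blob score (scale-normalized LoG response).
#' @return data.frame with `x_um`, `y_um`, `z_um`, `channel`, `score`.
#' @export
detect_nuclei <- function(stack, channel = "gfp", diameter_um = 5,
                          score_threshold = 0.1) {
  if (diameter_um <= 0) stopf("diameter_um must be > 0")
  spacing <- stack$spacing
  if (any(diameter_um < spacing))
    stopf("diameter (%g um) is smaller than one voxel on axis %s",
          diameter_um, paste(which(diameter_um < spacing), collapse = ","))
  vol <- get_channel(stack, channel)
  dm <- dim(vol)
  sigma <- diameter_um / (2 * sqrt(3))
  sm <- vol
  for (ax in 1:3) {
    kern <- gaussian_kernel_1d(sigma / spacing[ax])
    if (length(kern) > 1) sm <- array(cpp_conv_axis(sm, dm, kern, ax), dm)
  }
  resp <- array(0, dm)
  for (ax in 1:3) {
    lap <- cpp_conv_axis(sm, dm, c(1, -2, 1) / spacing[ax]^2, ax)
    resp <- resp + array(lap, dm)
  }
  resp <- -sigma^2 * resp                       # scale-normalized, bright blobs
  idx <- cpp_local_maxima(resp, dm, score_threshold)
  if (!length(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      channel = character(0), score = numeric(0)))
  idx0 <- idx - 1L
  vx <- idx0 %% dm[1]
  vy <- (idx0 %/% dm[1]) %% dm[2]
  vz <- idx0 %/% (dm[1] * dm[2])
  # sub-voxel refinement: 1D quadratic fit through the response per axis
  offset_axis <- function(v, ax, pos) {
    n <- dm[ax]
    p0 <- pmax(pos - 1L, 0L)
    p1 <- pmin(pos + 1L, n - 1L)
    at <- function(p) {
      i <- switch(ax, cbind(p, vy, vz), cbind(vx, p, vz), cbind(vx, vy, p))
      resp[i + 1L]
    }
    a <- at(p0); b <- at(pos); c_ <- at(p1)
    den <- a - 2 * b + c_
    off <- ifelse(abs(den) > 0, 0.5 * (a - c_) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  ox <- offset_axis(resp, 1L, vx)
  oy <- offset_axis(resp, 2L, vy)
  oz <- offset_axis(resp, 3L, vz)
  data.frame(x_um = (vx + ox) * spacing[1],
             y_um = (vy + oy) * spacing[2],
             z_um = (vz + oz) * spacing[3],
             channel = channel,
             score = resp[idx])
}

#' Signed distance from points to a region surface
#'
#' Anisotropic Euclidean distance to the region surface, negative inside the
#' mask, positive outside, computed from distance transforms of the mask and
#' its complement and sampled at the nearest voxel.
#'
#' @param points numeric matrix or data.frame with micrometre columns
#'   x, y, z (first three columns are used).
#' @param mask logical 3D array.
#' @param spacing voxel spacing in micrometres.
#' @return numeric vector of signed distances (um). For an empty mask every
#'   distance is `Inf` and a warning is raised.
#' @export
signed_distance <- function(points, mask, spacing) {
  pts <- as.matrix(points)[, 1:3, drop = FALSE]
  if (nrow(pts) == 0) return(numeric(0))
  if (!any(mask)) {
    warnf("empty mask: signed distances are +Inf")
    return(rep(Inf, nrow(pts)))
  }
  dm <- dim(mask)
  vox <- cbind(pmin(pmax(round(pts[, 1] / spacing[1]), 0), dm[1] - 1),
               pmin(pmax(round(pts[, 2] / spacing[2]), 0), dm[2] - 1),
               pmin(pmax(round(pts[, 3] / spacing[3]), 0), dm[3] - 1))
  lin <- vox[, 1] + dm[1] * (vox[, 2] + dm[2] * vox[, 3]) + 1
  inside <- mask[lin]
  out <- numeric(nrow(pts))
  if (any(!inside)) {
    d_out <- sqrt(cpp_edt_sq(mask, dm, spacing))
    out[!inside] <- d_out[lin[!inside]]
  }
  if (any(inside)) {
    if (all(mask)) out[inside] <- -Inf
    else {
      d_in <- sqrt(cpp_edt_sq(!mask, dm, spacing))
      out[inside] <- -d_in[lin[inside]]
    }
  }
  out
}

# Per-slice signed distance to the lateral (in-plane) boundary of `mask`.
# The two cut faces of a section (top/bottom z) do not count as edge.
lateral_edge_distance <- function(points, mask, spacing) {
  pts <- as.matrix(points)[, 1:3, drop = FALSE]
  if (nrow(pts) == 0) return(numeric(0))
  dm <- dim(mask)
  zi <- pmin(pmax(round(pts[, 3] / spacing[3]), 0), dm[3] - 1)
  out <- rep(Inf, nrow(pts))
  for (z in unique(zi)) {
    sl <- mask[, , z + 1]
    dim(sl) <- c(dm[1], dm[2], 1L)
    sel <- which(zi == z)
    if (!any(sl)) next
    out[sel] <- signed_distance(cbind(pts[sel, 1], pts[sel, 2], 0),
                                sl, c(spacing[1], spacing[2], 1))
  }
  out
}

#' Classify detected nuclei by signed distance rules
#'
#' Applies the compartment rules in fixed precedence: nuclei within the
#' medullary or HD surface (signed distance \eqn{\le} threshold, default 0)
#' are `medullary_or_hd`; of the remainder, nuclei within the subcapsular
#' band of the section edge (signed edge distance \eqn{\ge} -25 um) are
#' `subcapsular`; the rest are `cortical`. Every nucleus receives exactly
#' one label. The section edge is the lateral lobe boundary computed per
#' slice; the top/bottom cut faces of a section are excluded. A `region`
#' column attributes each nucleus to `medulla`, `hd` or `cortex` (for
#' `medullary_or_hd`, the surface with the most negative distance wins,
#' ties going to HD).
#'
#' @param table data.frame with `x_um`, `y_um`, `z_um` (e.g. from
#'   [detect_nuclei()]).
#' @param regions a [region_mask_set()].
#' @param rules a [classification_rules()].
#' @return the input table with columns `d_medulla_um`, `d_hd_um`,
#'   `d_edge_um`, `label`, `region` appended.
#' @export
classify_nuclei <- function(table, regions, rules = classification_rules()) {
  stopifnot(inherits(regions, "region_mask_set"))
  sp <- regions$spacing
  pts <- table[, c("x_um", "y_um", "z_um")]
  d_med <- if (any(regions$masks$medulla))
    signed_distance(pts, regions$masks$medulla, sp) else rep(Inf, nrow(table))
  d_hd <- if (any(regions$masks$hd))
    signed_distance(pts, regions$masks$hd, sp) else rep(Inf, nrow(table))
  d_edge <- lateral_edge_distance(pts, regions$masks$lobe, sp)

  thr <- rules$region_inside_threshold
  in_region <- pmin(d_med, d_hd) <= thr
  subcap <- !in_region & d_edge >= rules$subcapsular_band_threshold
  label <- ifelse(in_region, "medullary_or_hd",
                  ifelse(subcap, "subcapsular", "cortical"))
  region <- ifelse(in_region, ifelse(d_med < d_hd, "medulla", "hd"), "cortex")
  table$d_medulla_um <- d_med
  table$d_hd_um <- d_hd
  table$d_edge_um <- d_edge
  table$label <- label
  table$region <- region
  table
}

#' Nucleus densities per region and channel
#'
#' Divides the number of classified nuclei by the physical region volume.
#' Exact identity: `density * volume == count`.
#'
#' @param table classified nucleus table (needs `region`, `channel`).
#' @param regions a [region_mask_set()].
#' @return data.frame with `region`, `channel`, `count`, `volume_um3`,
#'   `density` (nuclei per um^3; 0 for empty regions).
#' @export
compute_densities <- function(table, regions) {
  stopifnot(inherits(regions, "region_mask_set"))
  regs <- c("cortex", "medulla", "hd")
  chans <- unique(as.character(table$channel))
  if (!length(chans)) chans <- "gfp"
  grid <- expand.grid(region = regs, channel = chans,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(r, ch)
    sum(table$region == r & table$channel == ch),
    grid$region, grid$channel)
  grid$volume_um3 <- regions$volumes[grid$region]
  bad <- grid$count > 0 & grid$volume_um3 <= 0
  if (any(bad))
    stopf("nonzero count in zero-volume region(s): %s",
          paste(unique(grid$region[bad]), collapse = ", "))
  grid$density <- ifelse(grid$count == 0, 0, grid$count / grid$volume_um3)
  grid
}

#' Paired-lobe cell-count estimation
#'
#' Estimates whole-lobe cell counts by multiplying the mean densities
#' measured in one sample (e.g. confocal sections of the left lobe) by the
#' region volumes of another (e.g. light-sheet imaging of the right lobe):
#' `count[region] = density_A[region] * volume_B[region]`.
#'
#' @param densities data.frame from [compute_densities()] (sample A).
#' @param volumes a [region_mask_set()] or named numeric vector of region
#'   volumes in um^3 (sample B).
#' @param density_rel_err,volume_rel_err optional relative errors; when both
#'   are given, the propagated relative error (their sum) is reported.
#' @return data.frame with `region`, `channel`, `density`, `volume_um3`,
#'   `estimated_count` (and `rel_error` when inputs are provided).
#' @export
estimate_counts <- function(densities, volumes,
                            density_rel_err = NULL, volume_rel_err = NULL) {
  vol <- if (inherits(volumes, "region_mask_set")) volumes$volumes else volumes
  if (is.null(names(vol))) stopf("'volumes' must be named by region")
  unmatched <- setdiff(unique(densities$region), names(vol))
  if (length(unmatched))
    stopf("regions missing from 'volumes': %s",
          paste(unmatched, collapse = ", "))
  out <- densities[, c("region", "channel", "density")]
  out$volume_um3 <- unname(vol[out$region])
  out$estimated_count <- out$density * out$volume_um3
  if (!is.null(density_rel_err) && !is.null(volume_rel_err))
    out$rel_error <- density_rel_err + volume_rel_err
  out
}
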