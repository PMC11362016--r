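#' Specification of a synthetic thymic-lobe phantom
#'
#' Describes a two-channel (GFP / tdTomato nuclear reporter) volumetric
#' phantom of a thymic lobe: an ellipsoidal lobe containing dense medullary
#' blobs, optional peri-medullary high-density (HD-TEC) shells that exclude
#' the tdTomato channel, and a sparse reporter-positive cortex. Nuclei are
#' placed by a hard-sphere Poisson process, rendered as Gaussian point-spread
#' functions on an anisotropic voxel grid, and corrupted with Poisson and
#' additive Gaussian noise.
#'
#' Density defaults encode the qualitative ordering seen in aged reporter
#' mice: compacted HD clusters are several-fold denser than the medulla,
#' which in turn is an order of magnitude denser than the sparse cortex.
#' The tdTomato background covers cortex and medulla but is absent from HD
#' regions.
#'
#' @param preset voxel-spacing preset: `"lightsheet"` (0.915, 0.915, 4.9 um)
#'   or `"confocal"` (0.22, 0.22, 2 um); ignored when `voxel_spacing` is
#'   given.
#' @param shape integer length-3 grid shape (nx, ny, nz); default is derived
#'   from the lobe semi-axes with a 15% margin.
#' @param lobe_semi_axes ellipsoid semi-axes in micrometres.
#' @param voxel_spacing micrometres per voxel along x, y, z.
#' @param n_medulla_blobs number of medullary blobs.
#' @param medulla_blob_radius nominal blob radius in micrometres (each blob
#'   is jittered by +/-20%).
#' @param hd_fraction fraction of the medullary boundary coated by HD shells,
#'   in `[0, 1]`. Zero reproduces the young-thymus limit (no HD regions).
#' @param hd_thickness HD shell thickness in micrometres.
#' @param densities named nuclei-per-um^3 densities: `cortex_gfp`,
#'   `medulla_gfp`, `hd_gfp`, `tdtom_background`. Must satisfy
#'   `hd_gfp > medulla_gfp > cortex_gfp`.
#' @param nuclear_radius hard-sphere nuclear radius in micrometres; centres
#'   are kept at least two radii apart.
#' @param psf_sigma Gaussian point-spread sigma in micrometres per axis.
#' @param noise list with `poisson_scale` (photon scaling of the Poisson
#'   component; 0 disables) and `gaussian_sd` (additive read noise).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(preset = c("lightsheet", "confocal"),
                         shape = NULL,
                         lobe_semi_axes = c(95, 95, 125),
                         voxel_spacing = NULL,
                         n_medulla_blobs = 3,
                         medulla_blob_radius = 45,
                         hd_fraction = 0.5,
                         hd_thickness = 30,
                         densities = c(cortex_gfp = 1.5e-4,
                                       medulla_gfp = 1.2e-3,
                                       hd_gfp = 3.2e-3,
                                       tdtom_background = 1.0e-3),
                         nuclear_radius = 2.5,
                         psf_sigma = c(1.8, 1.8, 4.0),
                         noise = list(poisson_scale = 20, gaussian_sd = 0.05),
                         seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(voxel_spacing))
    voxel_spacing <- switch(preset,
                            lightsheet = c(0.915, 0.915, 4.9),
                            confocal = c(0.22, 0.22, 2.0))
  check_positive(voxel_spacing, "voxel_spacing")
  check_positive(lobe_semi_axes, "lobe_semi_axes")
  need <- c("cortex_gfp", "medulla_gfp", "hd_gfp", "tdtom_background")
  if (!all(need %in% names(densities)))
    stopf("densities must be named: %s", paste(need, collapse = ", "))
  densities <- densities[need]
  if (any(densities < 0)) stopf("densities must be >= 0")
  if (!(densities["hd_gfp"] > densities["medulla_gfp"] &&
        densities["medulla_gfp"] > densities["cortex_gfp"]))
    stopf("densities must satisfy hd_gfp > medulla_gfp > cortex_gfp")
  if (hd_fraction < 0 || hd_fraction > 1)
    stopf("hd_fraction must be in [0, 1]")
  if (is.null(shape))
    shape <- pmax(8L, as.integer(ceiling(2.3 * lobe_semi_axes / voxel_spacing)))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) stopf("invalid grid shape")
  structure(list(preset = preset, shape = shape,
                 lobe_semi_axes = as.numeric(lobe_semi_axes),
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_medulla_blobs = as.integer(n_medulla_blobs),
                 medulla_blob_radius = medulla_blob_radius,
                 hd_fraction = hd_fraction, hd_thickness = hd_thickness,
                 densities = densities, nuclear_radius = nuclear_radius,
                 psf_sigma = as.numeric(psf_sigma), noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized ellipsoid coordinate for every voxel centre.
ellipsoid_field <- function(shape, spacing, centre, semi) {
  ax <- (((seq_len(shape[1]) - 1) * spacing[1] - centre[1]) / semi[1])^2
  ay <- (((seq_len(shape[2]) - 1) * spacing[2] - centre[2]) / semi[2])^2
  az <- (((seq_len(shape[3]) - 1) * spacing[3] - centre[3]) / semi[3])^2
  outer(outer(ax, ay, `+`), az, `+`)
}

# Physical coordinates (um) of voxel linear indices.
voxel_coords <- function(idx, shape, spacing) {
  idx0 <- idx - 1L
  x <- idx0 %% shape[1]
  y <- (idx0 %/% shape[1]) %% shape[2]
  z <- idx0 %/% (shape[1] * shape[2])
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

# HD shells: voxels within `thickness` outside the medulla, restricted to the
# lobe, coated patchily so that roughly `fraction` of the shell is covered.
grow_hd_shell <- function(medulla, lobe, shape, spacing, thickness, fraction,
                          patch_radius = 40) {
  if (fraction <= 0 || !any(medulla))
    return(array(FALSE, shape))
  d2 <- cpp_edt_sq(medulla, shape, spacing)
  shell <- !medulla & lobe & d2 <= thickness^2
  if (fraction >= 1 || !any(shell)) return(shell)
  shell_idx <- which(shell)
  pos <- voxel_coords(shell_idx, shape, spacing)
  covered <- logical(length(shell_idx))
  target <- fraction * length(shell_idx)
  seeds <- sample(length(shell_idx))
  for (s in seeds) {
    if (sum(covered) >= target) break
    if (covered[s]) next
    d <- (pos[, 1] - pos[s, 1])^2 + (pos[, 2] - pos[s, 2])^2 +
      (pos[, 3] - pos[s, 3])^2
    covered <- covered | d <= patch_radius^2
  }
  out <- array(FALSE, shape)
  out[shell_idx[covered]] <- TRUE
  out
}

# Hard-sphere placement of `n` nuclei uniformly inside `region`.
place_nuclei <- function(region, n, existing, shape, spacing, min_dist,
                         region_name, max_tries = 40L) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  vox <- which(region)
  if (length(vox) == 0) stopf("region '%s' is empty", region_name)
  cand_idx <- sample(vox, n * max_tries, replace = TRUE)
  jitter <- matrix(runif(3 * length(cand_idx), -0.5, 0.5), ncol = 3)
  cand <- voxel_coords(cand_idx, shape, spacing) +
    jitter * matrix(spacing, nrow = length(cand_idx), ncol = 3, byrow = TRUE)
  keep <- cpp_hardsphere_accept(cand, existing, min_dist, n)
  if (length(keep) < n)
    stopf(paste0("hard-sphere placement failed in region '%s': placed %d of ",
                 "%d nuclei; reduce the density or the nuclear radius"),
          region_name, length(keep), n)
  cand[keep, , drop = FALSE]
}

# Render unit-amplitude Gaussian PSFs at nucleus centres onto the grid.
render_gaussians <- function(centers, shape, spacing, sigma) {
  vol <- array(0, shape)
  if (nrow(centers) == 0) return(vol)
  half <- ceiling(3 * sigma / spacing)
  for (i in seq_len(nrow(centers))) {
    c_vox <- centers[i, ] / spacing          # 0-based fractional index
    lo <- pmax(0L, as.integer(floor(c_vox - half)))
    hi <- pmin(shape - 1L, as.integer(ceiling(c_vox + half)))
    if (any(lo > hi)) next
    gx <- exp(-0.5 * (((lo[1]:hi[1]) * spacing[1] - centers[i, 1]) / sigma[1])^2)
    gy <- exp(-0.5 * (((lo[2]:hi[2]) * spacing[2] - centers[i, 2]) / sigma[2])^2)
    gz <- exp(-0.5 * (((lo[3]:hi[3]) * spacing[3] - centers[i, 3]) / sigma[3])^2)
    vol[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
        (lo[3] + 1):(hi[3] + 1)] <-
      vol[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
          (lo[3] + 1):(hi[3] + 1)] + outer(outer(gx, gy), gz)
  }
  vol
}

apply_noise <- function(vol, noise) {
  if (!is.null(noise$poisson_scale) && noise$poisson_scale > 0)
    vol <- array(rpois(length(vol), noise$poisson_scale * vol) /
                   noise$poisson_scale, dim(vol))
  if (!is.null(noise$gaussian_sd) && noise$gaussian_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, noise$gaussian_sd), dim(vol))
  vol
}

#' Generate a two-channel lobe phantom with ground truth
#'
#' Builds the region masks (lobe, medulla, HD, cortex), places nuclei per
#' region and channel by a hard-sphere Poisson process, renders each channel
#' by sampling a Gaussian PSF per nucleus onto the voxel grid, and applies
#' Poisson and additive Gaussian noise. The returned truth object records the
#' masks, every nucleus centre with channel and true region label, and the
#' per-region counts and volumes; HD regions contain no tdTomato nuclei.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `thymo_phantom` with elements
#'   \describe{
#'     \item{stack}{[image_stack()] with channels `gfp` and `tdtom`.}
#'     \item{truth}{list: `regions` ([region_mask_set()]), `nuclei`
#'       (data.frame `x_um`, `y_um`, `z_um`, `channel`, `region`),
#'       `counts` (data.frame region x channel) and `volumes`.}
#'     \item{spec}{the input specification.}
#'   }
#' @examples
#' sp <- phantom_spec(shape = c(48, 48, 16), lobe_semi_axes = c(18, 18, 30),
#'                    n_medulla_blobs = 1, medulla_blob_radius = 9,
#'                    hd_thickness = 5, seed = 7)
#' ph <- make_phantom(sp)
#' ph$truth$counts
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    spacing <- spec$voxel_spacing
    centre <- (shape - 1) * spacing / 2

    lobe <- ellipsoid_field(shape, spacing, centre, spec$lobe_semi_axes) <= 1
    if (!any(lobe)) stopf("lobe ellipsoid does not intersect the grid")

    medulla <- array(FALSE, shape)
    blob_r <- spec$medulla_blob_radius *
      runif(spec$n_medulla_blobs, 0.8, 1.2)
    for (b in seq_len(spec$n_medulla_blobs)) {
      # blob centres inside a shrunken lobe so blobs stay interior
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      bc <- centre + u * pmax(spec$lobe_semi_axes - blob_r[b] - 5, 0) * 0.9
      medulla <- medulla |
        ellipsoid_field(shape, spacing, bc, rep(blob_r[b], 3)) <= 1
    }
    medulla <- medulla & lobe

    hd <- grow_hd_shell(medulla, lobe, shape, spacing, spec$hd_thickness,
                        spec$hd_fraction)
    cortex <- lobe & !medulla & !hd
    regions <- region_mask_set(list(lobe = lobe, medulla = medulla, hd = hd,
                                    cortex = cortex), spacing)

    # nucleus placement: GFP per region density, tdTomato background in
    # cortex and medulla only (HD clusters exclude the tdTomato reporter)
    plan <- list(
      list(region = "cortex", channel = "gfp",
           density = spec$densities[["cortex_gfp"]]),
      list(region = "medulla", channel = "gfp",
           density = spec$densities[["medulla_gfp"]]),
      list(region = "hd", channel = "gfp",
           density = spec$densities[["hd_gfp"]]),
      list(region = "cortex", channel = "tdtom",
           density = spec$densities[["tdtom_background"]]),
      list(region = "medulla", channel = "tdtom",
           density = spec$densities[["tdtom_background"]]))

    existing <- matrix(numeric(0), ncol = 3)
    nuc <- list()
    for (p in plan) {
      vol_um3 <- regions$volumes[[p$region]]
      if (vol_um3 == 0 || p$density == 0) next
      n <- rpois(1, p$density * vol_um3)
      pts <- place_nuclei(regions$masks[[p$region]], n, existing, shape,
                          spacing, 2 * spec$nuclear_radius, p$region)
      existing <- rbind(existing, pts)
      if (n > 0)
        nuc[[length(nuc) + 1]] <- data.frame(
          x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
          channel = p$channel, region = p$region)
    }
    nuclei <- if (length(nuc)) do.call(rbind, nuc) else
      data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 channel = character(0), region = character(0))

    counts <- as.data.frame(table(region = factor(nuclei$region,
                                                  c("cortex", "medulla", "hd")),
                                  channel = factor(nuclei$channel,
                                                   c("gfp", "tdtom"))),
                            responseName = "count")

    channels <- list()
    for (ch in c("gfp", "tdtom")) {
      sel <- nuclei$channel == ch
      img <- render_gaussians(as.matrix(nuclei[sel, c("x_um", "y_um", "z_um")]),
                              shape, spacing, spec$psf_sigma)
      channels[[ch]] <- apply_noise(img, spec$noise)
    }

    structure(list(stack = image_stack(channels, spacing),
                   truth = list(regions = regions, nuclei = nuclei,
                                counts = counts,
                                volumes = regions$volumes),
                   spec = spec),
              class = "thymo_phantom")
  })
}

#' Standard validation phantom configurations
#'
#' Fixed phantom configurations used throughout the package's validation
#' suite: an aged-type and a young-type whole-lobe light-sheet phantom
#' (256 x 256 x 64 voxels at 0.915 x 0.915 x 4.9 um), and a thick-section
#' confocal-style phantom (1 x 1 x 2 um; the axial spacing matches confocal
#' acquisition, the lateral spacing is downsampled to keep the volume at
#' desk scale) sized so that each region holds enough nuclei for
#' percent-level density estimates (about 1,000 in the sparse cortex).
#'
#' @param type one of `"lightsheet_aged"`, `"lightsheet_young"`,
#'   `"confocal_section"`.
#' @param seed integer seed.
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
validation_phantom_spec <- function(type = c("lightsheet_aged",
                                             "lightsheet_young",
                                             "confocal_section"),
                                    seed = 1L, ...) {
  type <- match.arg(type)
  switch(type,
    lightsheet_aged = phantom_spec(shape = c(256, 256, 64), seed = seed, ...),
    lightsheet_young = phantom_spec(shape = c(256, 256, 64), hd_fraction = 0,
                                    seed = seed, ...),
    confocal_section = phantom_spec(voxel_spacing = c(1, 1, 2),
                                    shape = c(380, 380, 120),
                                    lobe_semi_axes = c(180, 180, 115),
                                    n_medulla_blobs = 3,
                                    medulla_blob_radius = 60,
                                    psf_sigma = c(1.3, 1.3, 2.0),
                                    seed = seed, ...))
}

#' @export
print.thymo_phantom <- function(x, ...) {
  cat("thymo_phantom:", nrow(x$truth$nuclei), "nuclei\n")
  print(x$truth$regions)
  invisible(x)
}
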