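test_that("signed distance matches analytic values for ball and plane", {
  dm <- c(41, 41, 21)
  sp <- c(1, 1, 2)
  centre <- c(20, 20, 20)                     # um
  ball <- array(FALSE, dm)
  for (z in seq_len(dm[3])) {
    dz2 <- ((z - 1) * sp[3] - centre[3])^2
    for (y in seq_len(dm[2])) {
      dy2 <- ((y - 1) - centre[2])^2
      xs <- which(((seq_len(dm[1]) - 1) - centre[1])^2 + dy2 + dz2 <= 10^2)
      ball[xs, y, z] <- TRUE
    }
  }
  diag_vox <- sqrt(sum(sp^2))
  # centroid of a solid ball of radius 10 -> distance ~ -10
  d_centre <- signed_distance(matrix(centre, 1), ball, sp)
  expect_lt(abs(d_centre + 10), diag_vox)
  # boundary voxel -> |distance| <= voxel diagonal
  d_bnd <- signed_distance(matrix(c(30, 20, 20), 1), ball, sp)
  expect_lte(abs(d_bnd), diag_vox)
  # outside at gap g from a flat face (use a half-space slab)
  slab <- array(FALSE, dm)
  slab[1:11, , ] <- TRUE                      # face at x = 10 um
  d_out <- signed_distance(matrix(c(25, 20, 20), 1), slab, sp)
  expect_equal(unname(d_out), 15, tolerance = 1e-9)
  # inside the slab: negative
  expect_lt(signed_distance(matrix(c(2, 20, 20), 1), slab, sp), 0)
})

test_that("empty masks yield +Inf sentinel with a warning", {
  empty <- array(FALSE, c(4, 4, 2))
  expect_warning(d <- signed_distance(matrix(c(1, 1, 1), 1), empty, c(1, 1, 1)),
                 "empty mask")
  expect_identical(unname(d), Inf)
})

test_that("classification follows the distance rules with fixed precedence", {
  regions <- toy_regions()
  # medulla ball centre (30,40,12) r=10; lobe x in [5,154], y in [5,74] um
  pts <- data.frame(
    x_um = c(30,   # deep inside medulla
             30,   # medulla boundary voxel
             12,   # cortex, 7 um from lateral edge -> subcapsular
             80),  # deep cortex, > 25 um from every edge
    y_um = c(40, 40, 40, 40),
    z_um = c(12, 12, 12, 12))
  pts$x_um[2] <- 39                            # on the ball surface
  cl <- classify_nuclei(pts, regions)
  expect_equal(cl$label,
               c("medullary_or_hd", "medullary_or_hd", "subcapsular",
                 "cortical"))
  expect_true(cl$d_medulla_um[1] < -5)
  expect_lte(cl$d_medulla_um[2], 0)           # boundary included by <=
  expect_gte(cl$d_edge_um[3], -25)
  expect_lt(cl$d_edge_um[4], -25)
  expect_gt(cl$d_medulla_um[3], 0)
  # every nucleus gets exactly one label
  expect_true(all(cl$label %in% c("medullary_or_hd", "subcapsular",
                                  "cortical")))
})

test_that("boundary-equality inclusion and band monotonicity hold", {
  regions <- toy_regions()
  pts <- data.frame(x_um = c(41, 12, 30), y_um = c(40, 40, 40),
                    z_um = c(12, 12, 12))
  d <- signed_distance(pts, regions$masks$medulla, regions$spacing)
  # threshold equal to the computed distance -> included (<= rule)
  cl_eq <- classify_nuclei(pts[1, , drop = FALSE], regions,
                           classification_rules(region_inside_threshold = d[1]))
  expect_equal(cl_eq$label, "medullary_or_hd")
  cl_lt <- classify_nuclei(pts[1, , drop = FALSE], regions,
                           classification_rules(
                             region_inside_threshold = d[1] - 1e-9))
  expect_false(cl_lt$label == "medullary_or_hd")

  # shrinking the subcapsular band toward 0 never increases subcapsular count
  ph <- make_phantom(small_phantom_spec(seed = 8))
  det <- ph$truth$nuclei[ph$truth$nuclei$channel == "gfp", ]
  counts <- vapply(c(-25, -15, -5, -1), function(b) {
    cl <- classify_nuclei(det, ph$truth$regions,
                          classification_rules(subcapsular_band_threshold = b))
    sum(cl$label == "subcapsular")
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(classification_rules(subcapsular_band_threshold = 5), "<= 0")
})

test_that("classification partitions all detections", {
  ph <- make_phantom(small_phantom_spec(seed = 9))
  det <- detect_nuclei(ph$stack, "gfp", diameter_um = 5, score_threshold = 0.1)
  cl <- classify_nuclei(det, ph$truth$regions)
  expect_equal(nrow(cl), nrow(det))
  expect_false(any(is.na(cl$label)))
  expect_equal(sum(table(cl$label)), nrow(det))
})

test_that("density and count estimation are exact arithmetic", {
  regions <- toy_regions()
  tab <- data.frame(region = c(rep("cortex", 4), rep("medulla", 2)),
                    channel = "gfp")
  den <- compute_densities(tab, regions)
  vc <- regions$volumes[["cortex"]]
  expect_equal(den$density[den$region == "cortex"], 4 / vc)
  expect_equal(den$density[den$region == "hd"], 0)   # empty region -> 0
  expect_equal(den$density * den$volume_um3, den$count)

  est <- estimate_counts(data.frame(region = "medulla", channel = "gfp",
                                    density = 0.001),
                         c(medulla = 5e7))
  expect_equal(est$estimated_count, 5e4)
  est0 <- estimate_counts(data.frame(region = "medulla", channel = "gfp",
                                     density = 0.001), c(medulla = 0))
  expect_equal(est0$estimated_count, 0)
  expect_error(estimate_counts(data.frame(region = "medulla", channel = "gfp",
                                          density = 1e-3),
                               c(cortex = 1)), "medulla")
  est2 <- estimate_counts(den, regions, density_rel_err = 0.02,
                          volume_rel_err = 0.03)
  expect_equal(unique(est2$rel_error), 0.05)
})

test_that("nonzero count in a zero-volume region fails", {
  regions <- toy_regions()
  regions$volumes[["hd"]] <- 0
  tab <- data.frame(region = "hd", channel = "gfp")
  expect_error(compute_densities(tab, regions), "zero-volume")
})

test_that("LoG detection on an empty image returns an empty table", {
  st <- image_stack(list(gfp = array(0, c(16, 16, 8))), c(1, 1, 2))
  det <- detect_nuclei(st, "gfp", diameter_um = 5, score_threshold = 0.05)
  expect_equal(nrow(det), 0)
})

test_that("LoG detection is linear: doubling image and threshold is a no-op", {
  ph <- make_phantom(small_phantom_spec(
    seed = 10, voxel_spacing = c(1, 1, 2), lobe_semi_axes = c(25, 25, 22),
    psf_sigma = c(1.3, 1.3, 2),
    noise = list(poisson_scale = 0, gaussian_sd = 0)))
  d1 <- detect_nuclei(ph$stack, "gfp", diameter_um = 5, score_threshold = 0.1)
  st2 <- image_stack(lapply(ph$stack$channels, function(v) 2 * v),
                     ph$stack$spacing)
  d2 <- detect_nuclei(st2, "gfp", diameter_um = 5, score_threshold = 0.2)
  expect_equal(d1[, c("x_um", "y_um", "z_um")], d2[, c("x_um", "y_um", "z_um")])
  expect_equal(2 * d1$score, d2$score, tolerance = 1e-9)
})

test_that("diameter below one voxel fails", {
  st <- image_stack(list(gfp = array(0, c(8, 8, 4))), c(1, 1, 4))
  expect_error(detect_nuclei(st, "gfp", diameter_um = 2), "smaller than one voxel")
})

test_that("detection recovers well-separated noiseless nuclei", {
  sp <- phantom_spec(voxel_spacing = c(1, 1, 2), lobe_semi_axes = c(45, 45, 35),
                     n_medulla_blobs = 1, medulla_blob_radius = 18,
                     hd_thickness = 10, psf_sigma = c(1.3, 1.3, 2),
                     noise = list(poisson_scale = 0, gaussian_sd = 0),
                     seed = 13)
  ph <- make_phantom(sp)
  det <- detect_nuclei(ph$stack, "gfp", diameter_um = 5, score_threshold = 0.1)
  truth <- ph$truth$nuclei[ph$truth$nuclei$channel == "gfp", ]
  m <- match_detections(det, truth, radius = 2.5)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})
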