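test_that("anisotropic EDT matches brute force on random masks", {
  set.seed(42)
  for (i in 1:4) {
    dm <- c(9, 7, 5)
    mask <- array(runif(prod(dm)) < 0.15, dm)
    sp <- c(0.9, 1.1, 2.5)
    got <- array(thymoquant:::cpp_edt_sq(mask, dm, sp), dm)
    expect_equal(got, brute_edt_sq(mask, sp), tolerance = 1e-9)
  }
})

test_that("3D labeling separates disconnected components", {
  dm <- c(10, 10, 4)
  mask <- array(FALSE, dm)
  mask[1:3, 1:3, 1] <- TRUE
  mask[7:9, 7:9, 3:4] <- TRUE
  lab <- array(thymoquant:::cpp_label3d(mask, dm), dm)
  expect_equal(max(lab), 2)
  expect_true(all(lab[1:3, 1:3, 1] == lab[1, 1, 1]))
  expect_true(all(lab[7:9, 7:9, 3:4] == lab[7, 7, 3]))
  expect_true(lab[1, 1, 1] != lab[7, 7, 3])
})

test_that("noiseless binary ellipsoid volume is recovered within a voxel shell", {
  shape <- c(60, 60, 30)
  spacing <- c(1, 1, 2)
  semi <- c(20, 22, 18)
  centre <- (shape - 1) * spacing / 2
  vol <- array(0, shape)
  vol[thymoquant:::ellipsoid_field(shape, spacing, centre, semi) <= 1] <- 1
  st <- image_stack(list(tdtom = vol), spacing)
  mask <- extract_lobe_mask(st, segmentation_params(
    median_radius = 0, gaussian_sigma = 2, binarize_threshold = 0.5,
    closing_radius = 0, min_component_volume = 0, normalize = "volume"))
  analytic <- 4 / 3 * pi * prod(semi)
  # one-voxel surface shell bound
  area <- 4 * pi * (prod(semi^2)^(1 / 3))      # sphere-equivalent area
  shell <- area * max(spacing)
  expect_lt(abs(mask_volume(mask, spacing) - analytic), shell)
})

test_that("empty or all-zero input raises explicit errors", {
  st <- image_stack(list(tdtom = array(0, c(8, 8, 4))), c(1, 1, 2))
  expect_error(extract_lobe_mask(st), "zero")
  st2 <- image_stack(list(gfp = array(1, c(8, 8, 4))), c(1, 1, 2))
  expect_error(segment_dense_region(st2, c("gfp", "krt14")), "krt14")
})

test_that("raising the binarization threshold never increases volume", {
  set.seed(7)
  vol <- array(runif(40 * 40 * 8), c(40, 40, 8))
  st <- image_stack(list(gfp = vol), c(1, 1, 2))
  vols <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    p <- segmentation_params(median_radius = 1, gaussian_sigma = 2,
                             binarize_threshold = th, closing_radius = 0,
                             min_component_volume = 0)
    mask_volume(segment_dense_region(st, "gfp", p), st$spacing)
  }, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("a constant-intensity slice contributes no foreground", {
  vol <- array(runif(16 * 16 * 4), c(16, 16, 4))
  vol[, , 2] <- 0.7
  st <- image_stack(list(gfp = vol), c(1, 1, 1))
  p <- segmentation_params(median_radius = 0, gaussian_sigma = 0,
                           binarize_threshold = 0.3, closing_radius = 0,
                           min_component_volume = 0, normalize = "slice")
  mask <- segment_dense_region(st, "gfp", p)
  expect_false(any(mask[, , 2]))
  expect_true(any(mask[, , 1]))
})

test_that("segmentation is invariant to positive intensity rescaling", {
  ph <- make_phantom(small_phantom_spec(seed = 5))
  p <- segmentation_params(gaussian_sigma = 5, binarize_threshold = 0.3,
                           normalize = "volume")
  m1 <- segment_dense_region(ph$stack, "gfp", p)
  scaled <- image_stack(lapply(ph$stack$channels, function(v) 7.3 * v),
                        ph$stack$spacing)
  m2 <- segment_dense_region(scaled, "gfp", p)
  expect_identical(m1, m2)
})

test_that("compose_regions enforces the exact subtraction identity", {
  dm <- c(20, 20, 5)
  lobe <- array(FALSE, dm); lobe[3:18, 3:18, ] <- TRUE
  med <- array(FALSE, dm); med[5:10, 5:10, ] <- TRUE
  hd <- array(FALSE, dm); hd[12:14, 12:14, ] <- TRUE
  r <- compose_regions(lobe, med, hd, c(1, 1, 1))
  expect_equal(r$volumes[["cortex"]],
               r$volumes[["lobe"]] - r$volumes[["medulla"]] - r$volumes[["hd"]])
  expect_equal(sum(r$masks$cortex) + sum(r$masks$medulla) + sum(r$masks$hd),
               sum(r$masks$lobe))

  # young case: no HD term
  r2 <- compose_regions(lobe, med, NULL, c(1, 1, 1))
  expect_equal(r2$volumes[["hd"]], 0)
  expect_equal(r2$volumes[["cortex"]],
               r2$volumes[["lobe"]] - r2$volumes[["medulla"]])

  # precedence: identical raw masks resolve entirely to HD
  r3 <- compose_regions(lobe, med, med, c(1, 1, 1))
  expect_equal(r3$volumes[["medulla"]], 0)
  expect_equal(r3$volumes[["hd"]], sum(med) * 1)

  out <- array(FALSE, dm); out[1, 1, 1] <- TRUE
  expect_error(compose_regions(lobe, med | out, NULL, c(1, 1, 1)),
               "outside the lobe")
})

test_that("noiseless medulla segmentation is accurate at matched blur", {
  # Half-maximum thresholding of the smoothed nuclear density recovers the
  # medulla once the total blur (PSF plus filter) averages enough nuclei to
  # suppress shot-noise speckle, while staying below the blob scale. The
  # young image's medullary plateau is the brightest structure, so the
  # half-maximum threshold is ~0.45 of the volume-normalized range.
  dens <- c(cortex_gfp = 3e-4, medulla_gfp = 3e-3, hd_gfp = 6.5e-3,
            tdtom_background = 2e-3)
  dice_at <- function(psf) {
    sp <- small_phantom_spec(seed = 6, psf_sigma = psf, densities = dens,
                             nuclear_radius = 2, hd_fraction = 0,
                             noise = list(poisson_scale = 0, gaussian_sd = 0))
    ph <- make_phantom(sp)
    p <- segmentation_params(gaussian_sigma = 4, binarize_threshold = 0.45,
                             closing_radius = 3, min_component_volume = 1e3,
                             normalize = "volume")
    dense <- segment_dense_region(ph$stack, "gfp", p)
    dice_coefficient(dense, ph$truth$regions$masks$medulla)
  }
  expect_gt(dice_at(c(2, 2, 3)), 0.7)
  expect_gt(dice_at(c(4, 4, 8)), 0.78)
})
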