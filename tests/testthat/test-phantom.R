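test_that("identical seeds give bit-identical phantoms", {
  a <- make_phantom(small_phantom_spec(seed = 11))
  b <- make_phantom(small_phantom_spec(seed = 11))
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  c <- make_phantom(small_phantom_spec(seed = 12))
  expect_false(identical(a$truth$nuclei, c$truth$nuclei))
})

test_that("young-thymus limit: hd_fraction = 0 yields empty HD mask", {
  ph <- make_phantom(small_phantom_spec(seed = 2, hd_fraction = 0))
  m <- ph$truth$regions$masks
  expect_false(any(m$hd))
  expect_identical(m$cortex | m$medulla, m$lobe)
  expect_equal(sum(ph$truth$nuclei$region == "hd"), 0)
})

test_that("truth is self-consistent: partition, tallies, HD tdTomato-free", {
  ph <- make_phantom(small_phantom_spec(seed = 3))
  m <- ph$truth$regions$masks
  expect_false(any(m$medulla & m$hd))
  expect_false(any(m$medulla & m$cortex))
  expect_false(any(m$hd & m$cortex))
  expect_identical(m$cortex | m$medulla | m$hd, m$lobe)
  expect_equal(sum(ph$truth$counts$count), nrow(ph$truth$nuclei))
  tab <- table(ph$truth$nuclei$region, ph$truth$nuclei$channel)
  for (r in rownames(tab)) for (ch in colnames(tab))
    expect_equal(
      ph$truth$counts$count[ph$truth$counts$region == r &
                              ph$truth$counts$channel == ch],
      unname(tab[r, ch]))
  expect_equal(sum(ph$truth$nuclei$channel == "tdtom" &
                     ph$truth$nuclei$region == "hd"), 0)
})

test_that("realized counts follow the Poisson sampling law over 20 seeds", {
  tot <- c(cortex = 0, medulla = 0, hd = 0)
  exp_tot <- c(cortex = 0, medulla = 0, hd = 0)
  lambda <- c(cortex = 1.5e-4, medulla = 1.2e-3, hd = 3.2e-3)
  for (s in 1:20) {
    ph <- make_phantom(small_phantom_spec(
      seed = s, noise = list(poisson_scale = 0, gaussian_sd = 0)))
    tc <- ph$truth$counts
    for (r in names(tot)) {
      tot[r] <- tot[r] + tc$count[tc$region == r & tc$channel == "gfp"]
      exp_tot[r] <- exp_tot[r] + lambda[r] * ph$truth$volumes[r]
    }
  }
  z <- (tot - exp_tot) / sqrt(exp_tot)
  expect_true(all(abs(z) < 4))
})

test_that("expected HD count increases with HD density", {
  n_lo <- n_hi <- 0
  for (s in 1:3) {
    d_lo <- c(cortex_gfp = 1.5e-4, medulla_gfp = 1.2e-3, hd_gfp = 1.8e-3,
              tdtom_background = 1.0e-3)
    d_hi <- c(cortex_gfp = 1.5e-4, medulla_gfp = 1.2e-3, hd_gfp = 3.2e-3,
              tdtom_background = 1.0e-3)
    ph_lo <- make_phantom(small_phantom_spec(seed = s, densities = d_lo))
    ph_hi <- make_phantom(small_phantom_spec(seed = s, densities = d_hi))
    tc <- function(p) p$truth$counts$count[p$truth$counts$region == "hd" &
                                             p$truth$counts$channel == "gfp"]
    n_lo <- n_lo + tc(ph_lo)
    n_hi <- n_hi + tc(ph_hi)
  }
  expect_gt(n_hi, n_lo)
})

test_that("hard-sphere placement fails loudly at unplaceable densities", {
  sp <- small_phantom_spec(
    seed = 1,
    densities = c(cortex_gfp = 1.5e-4, medulla_gfp = 1.2e-3, hd_gfp = 3e-2,
                  tdtom_background = 1.0e-3))
  expect_error(make_phantom(sp), "hard-sphere placement failed.*'hd'")
})

test_that("phantom spec validates density ordering and hd_fraction", {
  expect_error(phantom_spec(densities = c(cortex_gfp = 2e-3,
                                          medulla_gfp = 1.2e-3,
                                          hd_gfp = 3.2e-3,
                                          tdtom_background = 1e-3)),
               "hd_gfp > medulla_gfp > cortex_gfp")
  expect_error(phantom_spec(hd_fraction = 1.5), "hd_fraction")
  expect_error(phantom_spec(voxel_spacing = c(1, 0, 1)), "positive")
})

test_that("image stacks round-trip through TIFF plus YAML sidecar", {
  ph <- make_phantom(small_phantom_spec(seed = 4))
  dir <- withr::local_tempdir()
  write_image_stack(ph$stack, dir, "ph")
  back <- read_image_stack(dir, "ph")
  expect_equal(back$spacing, ph$stack$spacing)
  # stored as 32-bit float scaled to [0, 1]: absolute error ~1e-7 x scale
  for (ch in c("gfp", "tdtom")) {
    scale <- max(ph$stack$channels[[ch]])
    expect_lt(max(abs(back$channels[[ch]] - ph$stack$channels[[ch]])),
              1e-5 * scale)
  }
})
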