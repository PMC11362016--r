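test_that("identically expressed genes score exactly zero", {
  x <- matrix(0.7, nrow = 10, ncol = 40)
  colnames(x) <- paste0("g", 1:40)
  rownames(x) <- paste0("c", 1:10)
  sc <- score_signature(x, c("g1", "g2", "g3"), seed = 1)
  expect_equal(as.numeric(sc), rep(0, 10))
})

test_that("score equals the brute-force mean difference for its reference", {
  set.seed(51)
  x <- matrix(rlnorm(60 * 120), nrow = 60)
  colnames(x) <- paste0("g", 1:120)
  rownames(x) <- paste0("c", 1:60)
  sig <- c("g5", "g17", "g60")
  sc <- score_signature(x, sig, seed = 7)
  ctrl <- attr(sc, "control_genes")
  brute <- rowMeans(x[, sig]) - rowMeans(x[, ctrl])
  expect_equal(as.numeric(sc), unname(brute), tolerance = 1e-12)

  # fixed seed -> identical scores; gene order does not matter
  sc2 <- score_signature(x, sig, seed = 7)
  expect_identical(sc, sc2)
  sc3 <- score_signature(x, rev(sig), seed = 7)
  expect_equal(as.numeric(sc), as.numeric(sc3), tolerance = 1e-12)
})

test_that("a shift planted in target cells is recovered by the score", {
  set.seed(52)
  n <- 80
  x <- matrix(rnorm(n * 200, 1, 0.1), nrow = n)
  colnames(x) <- paste0("g", 1:200)
  sig <- paste0("g", 1:10)
  delta <- 0.8
  target <- 1:20
  x[target, sig] <- x[target, sig] + delta
  sc <- score_signature(x, sig, seed = 3)
  expect_equal(mean(sc[target]), delta, tolerance = 0.1)
  expect_lt(abs(mean(sc[-target])), 0.1)
})

test_that("missing signature genes are dropped; empty signature fails", {
  x <- matrix(rnorm(50), nrow = 5)
  colnames(x) <- paste0("g", 1:10)
  expect_warning(sc <- score_signature(x, c("g1", "nope"), seed = 1),
                 "dropping 1")
  expect_length(sc, 5)
  expect_error(suppressWarnings(score_signature(x, "nope", seed = 1)),
               "empty")
})

test_that("argmax mapping assigns, reports margins and leaves ties NA", {
  scores <- cbind(a = c(0.9, 0.2, 0.5), b = c(0.1, 0.8, 0.5))
  rownames(scores) <- paste0("s", 1:3)
  mp <- map_subsets(scores)
  expect_equal(mp$assigned, c("a", "b", NA))
  expect_equal(mp$margin, c(0.8, 0.6, 0))
  expect_equal(mp$best_score, c(0.9, 0.8, 0.5))
})

test_that("scaled frequency change is the max-normalized difference", {
  freq <- data.frame(
    subset = rep(c("x", "y", "z"), 2),
    condition = rep(c("young", "aged"), each = 3),
    frequency = c(0.5, 0.3, 0.2, 0.3, 0.3, 0.4))
  out <- scaled_frequency_change(freq)
  expect_equal(out$change, c(-0.2, 0, 0.2))
  expect_equal(out$scaled_change, c(-1, 0, 1))

  eq <- scaled_frequency_change(data.frame(
    subset = rep(c("x", "y"), 2),
    condition = rep(c("young", "aged"), each = 2),
    frequency = rep(0.5, 4)))
  expect_equal(eq$scaled_change, c(0, 0))

  hand <- scaled_frequency_change(data.frame(
    subset = rep(c("x", "y", "z"), 2),
    condition = rep(c("young", "aged"), each = 3),
    frequency = c(0.6, 0.3, 0.1, 0.45, 0.35, 0.2)))
  expect_equal(hand$scaled_change, c(-1, 1 / 3, 2 / 3))
  expect_error(scaled_frequency_change(data.frame(
    subset = c("x", "x"), condition = c("young", "aged"),
    frequency = c(0.7, 1))), "sum to 1")
})

test_that("EMT axis orders by anchor and classes quadrants", {
  x <- rbind(
    epithelial = c(Cdh1 = 2.0, Vim = 0.0, Krt8 = 1.5, Col1a1 = 0.0),
    hybrid     = c(Cdh1 = 1.0, Vim = 1.0, Krt8 = 1.0, Col1a1 = 0.5),
    pemt       = c(Cdh1 = 0.0, Vim = 2.0, Krt8 = 0.2, Col1a1 = 1.5),
    dn         = c(Cdh1 = 0.0, Vim = 0.0, Krt8 = 0.0, Col1a1 = 0.0))
  res <- emt_axis(x, epithelial_set = "Krt8", mesenchymal_set = "Col1a1")
  expect_equal(res$table$quadrant,
               c("epithelial", "hybrid", "pEMT", "double_negative"))
  expect_equal(rownames(x)[res$ordering][1], "epithelial")
  expect_true(res$table$e_score[1] > 0 && res$table$m_score[1] == 0)
  expect_error(emt_axis(x, anchor = "Missing"), "Missing")
})

test_that("synthetic partial-EMT cells land in the low-E/high-M quadrant", {
  set.seed(53)
  n <- 60
  x <- matrix(rlnorm(n * 6, 0, 0.2), nrow = n)
  colnames(x) <- c("Cdh1", "Vim", "Krt8", "Krt5", "Col1a1", "Fn1")
  pemt <- 41:60
  x[pemt, c("Cdh1", "Krt8", "Krt5")] <- 0           # anchor lost, E attenuated
  x[1:40, "Vim"] <- 0                               # epithelial bulk Vim-
  res <- emt_axis(x, epithelial_set = c("Krt8", "Krt5"),
                  mesenchymal_set = c("Col1a1", "Fn1"))
  expect_true(all(res$table$quadrant[pemt] == "pEMT"))
  expect_gt(mean(res$table$m_score[pemt]), mean(res$table$e_score[pemt]))
})

test_that("mapping accuracy improves with marker fold change", {
  accs <- vapply(c(0.3, 2), function(lfc) {
    ex <- make_expression(tiny_expr_spec(seed = 54,
                                         marker_log_fold_change = lfc,
                                         doublet_fraction = 0,
                                         lowq_cell_fraction = 0))
    nm <- normalize_log1p(ex)
    mk <- rank_markers(nm, ex$cell_meta$subset)
    sigs <- suppressWarnings(build_signatures(mk, n = 20))
    sc <- score_signature_set(nm, sigs, seed = 5)
    mp <- map_subsets(sc)
    mean(mp$assigned == ex$cell_meta$subset, na.rm = TRUE)
  }, 0)
  expect_gte(accs[2], accs[1])
})
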