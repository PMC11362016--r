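# Shared fixtures: small phantoms, toy region worlds, matching and
# enumeration oracles. Everything is generated in code at test time.

small_phantom_spec <- function(seed = 1L, ...) {
  args <- list(shape = c(72, 72, 28), lobe_semi_axes = c(30, 30, 60),
               n_medulla_blobs = 1, medulla_blob_radius = 15,
               hd_fraction = 0.5, hd_thickness = 8, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

tiny_expr_spec <- function(seed = 1L, ...) {
  expr_sim_spec(n_cells = 400, n_genes = 200, markers_per_subset = 8,
                subsets = c("A", "B", "C"),
                frequencies = list(young = c(A = 0.5, B = 0.5, C = 0),
                                   aged = c(A = 0.3, B = 0.3, C = 0.4)),
                seed = seed, ...)
}

# Toy region world on a 1 x 1 x 2 um grid: a box lobe, a spherical medulla,
# no HD. The lateral lobe boundary provides the section edge; the lobe is
# wide enough that its centre is more than 25 um from every lateral edge.
toy_regions <- function() {
  shape <- c(160, 80, 12)
  spacing <- c(1, 1, 2)
  lobe <- array(FALSE, shape)
  lobe[6:155, 6:75, ] <- TRUE
  centre <- c(30, 40, 12)                     # um
  medulla <- array(FALSE, shape)
  for (z in seq_len(shape[3])) {
    dz2 <- ((z - 1) * spacing[3] - centre[3])^2
    for (y in seq_len(shape[2])) {
      dy2 <- ((y - 1) - centre[2])^2
      xs <- which(((seq_len(shape[1]) - 1) - centre[1])^2 + dy2 + dz2 <= 10^2)
      medulla[xs, y, z] <- TRUE
    }
  }
  medulla <- medulla & lobe
  hd <- array(FALSE, shape)
  cortex <- lobe & !medulla
  region_mask_set(list(lobe = lobe, medulla = medulla, hd = hd,
                       cortex = cortex), spacing)
}

# Greedy matching of detections to truth centres within `radius` um.
match_detections <- function(det, truth, radius = 2.5) {
  if (nrow(det) == 0)
    return(list(recall = 0, precision = NA_real_, matched = logical(0)))
  used <- rep(FALSE, nrow(det))
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2 +
      (det$z_um - truth$z_um[i])^2
    j <- which(!used & d2 <= radius^2)
    if (length(j)) {
      used[j[which.min(d2[j])]] <- TRUE
      hits <- hits + 1
    }
  }
  list(recall = hits / nrow(truth), precision = hits / nrow(det),
       matched = used)
}

# Exhaustive permutation null of the rank-sum statistic for one gene:
# returns the exact mean and sd of the group-1 rank sum over all
# choose(N, n1) assignments, handling ties through midranks.
enum_ranksum_moments <- function(x, n1) {
  r <- rank(x)
  combs <- utils::combn(length(x), n1)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  list(mean = mean(sums), sd = sqrt(mean((sums - mean(sums))^2)))
}

# Brute-force squared EDT for the oracle tests.
brute_edt_sq <- function(mask, spacing) {
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dm)
  if (nrow(idx) == 0) return(out)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    d2 <- ((x - idx[, 1]) * spacing[1])^2 + ((y - idx[, 2]) * spacing[2])^2 +
      ((z - idx[, 3]) * spacing[3])^2
    out[x, y, z] <- min(d2)
  }
  out
}
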