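#' Specification of synthetic injury-recovery time courses
#'
#' Models per-subset abundance after acute injury (total body irradiation)
#' as a double-exponential depletion/recovery curve
#' \deqn{m(t) = B (1 - d \, f(t) / f(t^*)), \quad
#'       f(t) = e^{-\rho t} - e^{-\delta t},}
#' where `B` is the age-matched day-0 baseline, `d` the maximal fractional
#' depletion, `\delta` the (fast) depletion rate and `\rho` the recovery
#' rate; `f` is normalized by its maximum so `d` is the depth of the nadir.
#' The curve equals the baseline exactly at day 0 and returns to it as
#' recovery completes; aged animals are given a slower recovery rate.
#' Replicates are multiplicative lognormal perturbations with coefficient of
#' variation `noise_cv` (mean preserved).
#'
#' @param days sampling days after injury.
#' @param subsets subset names.
#' @param age_groups age-group names.
#' @param baseline named per-subset baseline abundance (cells).
#' @param depletion_depth named per-subset maximal fractional depletion in
#'   `[0, 1]`.
#' @param recovery_rate named per-age-group recovery rate `rho` (per day).
#' @param depletion_rate depletion rate `delta` (per day), shared.
#' @param replicates replicates per (subset, age, day).
#' @param noise_cv replicate coefficient of variation; 0 gives the exact
#'   mean curve.
#' @param seed integer seed.
#' @return object of class `timecourse_spec`.
#' @export
timecourse_spec <- function(days = c(0, 1, 4, 7),
                            subsets = c("cTEC", "mTEC", "aaTEC1", "aaTEC2"),
                            age_groups = c("young", "aged"),
                            baseline = c(cTEC = 2e4, mTEC = 8e4,
                                         aaTEC1 = 5e3, aaTEC2 = 4e3),
                            depletion_depth = c(cTEC = 0.8, mTEC = 0.7,
                                                aaTEC1 = 0.9, aaTEC2 = 0.9),
                            recovery_rate = c(young = 0.5, aged = 0.15),
                            depletion_rate = 3,
                            replicates = 10,
                            noise_cv = 0.1,
                            seed = 1L) {
  if (any(diff(sort(days)) == 0)) stopf("days must be distinct")
  if (!all(subsets %in% names(baseline)) ||
      !all(subsets %in% names(depletion_depth)))
    stopf("baseline and depletion_depth must be named by subset")
  if (!all(age_groups %in% names(recovery_rate)))
    stopf("recovery_rate must be named by age group")
  if (any(baseline < 0) || any(depletion_depth < 0 | depletion_depth > 1))
    stopf("baseline must be >= 0 and depletion_depth in [0, 1]")
  if (any(recovery_rate >= depletion_rate))
    stopf("recovery_rate must be smaller than depletion_rate")
  structure(list(days = sort(days), subsets = subsets,
                 age_groups = age_groups, baseline = baseline,
                 depletion_depth = depletion_depth,
                 recovery_rate = recovery_rate,
                 depletion_rate = depletion_rate,
                 replicates = as.integer(replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "timecourse_spec")
}

#' Closed-form mean curve of a time-course specification
#'
#' @param spec a [timecourse_spec()].
#' @return function `(subset, age_group, t)` returning the noiseless mean
#'   abundance.
#' @export
timecourse_mean <- function(spec) {
  function(subset, age_group, t) {
    B <- spec$baseline[[subset]]
    d <- spec$depletion_depth[[subset]]
    rho <- spec$recovery_rate[[age_group]]
    delta <- spec$depletion_rate
    f <- function(x) exp(-rho * x) - exp(-delta * x)
    tstar <- log(delta / rho) / (delta - rho)
    B * (1 - d * f(t) / f(tstar))
  }
}

#' Generate a replicate-level injury-recovery time-course table
#'
#' @param spec a [timecourse_spec()].
#' @return data.frame with `subset`, `age_group`, `day`, `replicate`,
#'   `abundance` (>= 0); deterministic under the spec seed.
#' @export
make_timecourse <- function(spec) {
  stopifnot(inherits(spec, "timecourse_spec"))
  m <- timecourse_mean(spec)
  cv <- spec$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2                       # unit-mean lognormal noise
  with_seed(spec$seed, {
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        day = spec$days,
                        age_group = spec$age_groups,
                        subset = spec$subsets,
                        stringsAsFactors = FALSE)
    mu <- mapply(m, grid$subset, grid$age_group, grid$day)
    noise <- if (cv > 0) rlnorm(nrow(grid), meanlog, sdlog) else 1
    out <- data.frame(subset = grid$subset, age_group = grid$age_group,
                      day = grid$day, replicate = grid$replicate,
                      abundance = mu * noise)
    out[order(out$subset, out$age_group, out$day, out$replicate), ,
        drop = FALSE]
  })
}
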