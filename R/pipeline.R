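#' Run an end-to-end quantification pipeline from a single config
#'
#' Orchestrates the package's stages from a YAML config (or an equivalent
#' list): phantom generation, region segmentation, nucleus detection /
#' classification / density estimation, paired-lobe count estimation,
#' synthetic expression with QC, marker ranking, signature construction,
#' scoring and subset mapping, and time-course statistics. The config is
#' validated against the known stage names before anything executes; the
#' global seed propagates to every stochastic stage (each stage derives its
#' own sub-seed), so re-running an identical config reproduces identical
#' outputs. A run manifest (package version, seed, per-stage outputs with
#' MD5 hashes and timings) is written as `manifest.json`.
#'
#' Supported stages and their main outputs:
#' \describe{
#'   \item{phantom}{[make_phantom()]; `truth_nuclei.csv`, `truth_regions.csv`.}
#'   \item{segment}{[segment_phantom_regions()]; `regions.csv`.}
#'   \item{nuclei}{[detect_nuclei()] + [classify_nuclei()] +
#'     [compute_densities()]; `nuclei.csv`, `densities.csv`.}
#'   \item{estimate}{[estimate_counts()] against segmented volumes;
#'     `count_estimates.csv`.}
#'   \item{expression}{[make_expression()]; MTX triplet + metadata.}
#'   \item{qc}{[qc_flag_cells()] + [exclude_low_quality_clusters()];
#'     `qc_flags.csv`, `qc_clusters.csv`.}
#'   \item{markers}{[normalize_log1p()] + [rank_markers()] on retained
#'     cells; `markers.csv`.}
#'   \item{signatures}{[build_signatures()]; `signatures.json`.}
#'   \item{map}{[score_signature_set()] + [map_subsets()]; `scores.csv`,
#'     `assignments.csv`.}
#'   \item{timecourse}{[make_timecourse()]; `timecourse.csv`.}
#'   \item{dynamics}{[recovery_fraction()], [auc_timecourse()],
#'     [aging_index()]; `recovery.csv`, `auc.csv`, `aging_index.csv`.}
#' }
#'
#' @param config path to a YAML file or a list with elements `stages` (list
#'   of `list(name = <stage>, ...params)`), optional `seed`, optional
#'   `outdir`.
#' @param seed overrides `config$seed`.
#' @param outdir overrides `config$outdir`.
#' @return the manifest (invisibly), a list with per-stage output files and
#'   hashes.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stages))
    stopf("config must contain a 'stages' list")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% stopf("no output directory given")

  known <- c("phantom", "segment", "nuclei", "estimate", "expression", "qc",
             "markers", "signatures", "map", "timecourse", "dynamics")
  stage_names <- vapply(config$stages, function(s) s$name %||% "", "")
  bad <- setdiff(stage_names, known)
  if (length(bad) || any(!nzchar(stage_names)))
    stopf("unknown or unnamed stage(s): %s",
          paste(bad[nzchar(bad)], collapse = ", "))

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list(package = "thymoquant",
                   version = as.character(utils::packageVersion("thymoquant")),
                   seed = seed, stages = list())

  for (st in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- run_stage(st$name, st, state, seed, outdir)
    manifest$stages[[st$name]] <- list(
      params = st[setdiff(names(st), "name")],
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(files)))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

take <- function(st, formals_of) {
  p <- st[setdiff(names(st), "name")]
  p[names(p) %in% names(formals(formals_of))]
}

run_stage <- function(name, st, state, seed, outdir) {
  out <- function(...) file.path(outdir, ...)
  switch(name,
    phantom = {
      sp <- do.call(phantom_spec,
                    c(take(st, phantom_spec),
                      if (is.null(st$seed)) list(seed = derive_seed(seed, "phantom"))))
      state$phantom <- make_phantom(sp)
      write.csv(state$phantom$truth$nuclei, out("truth_nuclei.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(state$phantom$truth$regions),
                out("truth_regions.csv"), row.names = FALSE)
      c(out("truth_nuclei.csv"), out("truth_regions.csv"))
    },
    segment = {
      if (is.null(state$phantom)) stopf("'segment' requires a 'phantom' stage")
      state$regions <- do.call(segment_phantom_regions,
                               c(list(state$phantom$stack),
                                 take(st, segment_phantom_regions)))
      write.csv(as.data.frame(state$regions), out("regions.csv"),
                row.names = FALSE)
      out("regions.csv")
    },
    nuclei = {
      if (is.null(state$phantom)) stopf("'nuclei' requires a 'phantom' stage")
      regions <- state$regions %||% state$phantom$truth$regions
      det <- do.call(detect_nuclei, c(list(state$phantom$stack),
                                      take(st, detect_nuclei)))
      state$nuclei <- classify_nuclei(det, regions)
      state$densities <- compute_densities(state$nuclei, regions)
      write.csv(state$nuclei, out("nuclei.csv"), row.names = FALSE)
      write.csv(state$densities, out("densities.csv"), row.names = FALSE)
      c(out("nuclei.csv"), out("densities.csv"))
    },
    estimate = {
      if (is.null(state$densities) || is.null(state$regions))
        stopf("'estimate' requires 'nuclei' and 'segment' stages")
      est <- estimate_counts(state$densities, state$regions)
      write.csv(est, out("count_estimates.csv"), row.names = FALSE)
      out("count_estimates.csv")
    },
    expression = {
      sp <- do.call(expr_sim_spec,
                    c(take(st, expr_sim_spec),
                      if (is.null(st$seed)) list(seed = derive_seed(seed, "expression"))))
      state$expr <- make_expression(sp)
      write_expression_mtx(state$expr, out("expression"))
      file.path(out("expression"),
                c("matrix.mtx", "features.tsv", "barcodes.tsv",
                  "cell_metadata.csv"))
    },
    qc = {
      if (is.null(state$expr)) stopf("'qc' requires an 'expression' stage")
      state$flags <- qc_flag_cells(state$expr,
                                   do.call(qc_thresholds, take(st, qc_thresholds)))
      state$clusters <- exclude_low_quality_clusters(state$expr, state$flags)
      write.csv(state$flags, out("qc_flags.csv"), row.names = FALSE)
      cl <- state$clusters
      cl$retained_pct <- attr(cl, "retained_pct")
      write.csv(cl, out("qc_clusters.csv"), row.names = FALSE)
      c(out("qc_flags.csv"), out("qc_clusters.csv"))
    },
    markers = {
      if (is.null(state$expr)) stopf("'markers' requires an 'expression' stage")
      keep <- qc_retained_cells(state)
      state$normalized <- normalize_log1p(state$expr$counts[keep, ])
      state$labels <- state$expr$cell_meta$subset[keep]
      state$markers <- rank_markers(state$normalized, state$labels)
      write.csv(state$markers, out("markers.csv"), row.names = FALSE)
      out("markers.csv")
    },
    signatures = {
      if (is.null(state$markers)) stopf("'signatures' requires a 'markers' stage")
      state$signatures <- do.call(build_signatures,
                                  c(list(state$markers),
                                    take(st, build_signatures)))
      write_signatures(state$signatures, out("signatures.json"))
      out("signatures.json")
    },
    map = {
      if (is.null(state$signatures)) stopf("'map' requires a 'signatures' stage")
      scores <- score_signature_set(state$normalized, state$signatures,
                                    seed = derive_seed(seed, "map"))
      assign <- map_subsets(scores)
      write.csv(cbind(cell = rownames(scores), as.data.frame(scores)),
                out("scores.csv"), row.names = FALSE)
      write.csv(assign, out("assignments.csv"), row.names = FALSE)
      c(out("scores.csv"), out("assignments.csv"))
    },
    timecourse = {
      sp <- do.call(timecourse_spec,
                    c(take(st, timecourse_spec),
                      if (is.null(st$seed)) list(seed = derive_seed(seed, "timecourse"))))
      state$timecourse <- make_timecourse(sp)
      write.csv(state$timecourse, out("timecourse.csv"), row.names = FALSE)
      out("timecourse.csv")
    },
    dynamics = {
      if (is.null(state$timecourse))
        stopf("'dynamics' requires a 'timecourse' stage")
      rec <- recovery_fraction(state$timecourse)
      auc <- auc_timecourse(state$timecourse)
      idx <- aging_index(state$timecourse,
                         seed = derive_seed(seed, "dynamics"),
                         n_boot = st$n_boot %||% 2000)
      write.csv(rec, out("recovery.csv"), row.names = FALSE)
      write.csv(auc, out("auc.csv"), row.names = FALSE)
      write.csv(idx, out("aging_index.csv"), row.names = FALSE)
      c(out("recovery.csv"), out("auc.csv"), out("aging_index.csv"))
    })
}

# Cells retained after cluster-level QC (all cells if QC was not run),
# excluding doublets when that flag exists.
qc_retained_cells <- function(state) {
  meta <- state$expr$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(state$clusters))
    keep <- !(meta$cluster %in% state$clusters$cluster[state$clusters$drop])
  if (!is.null(state$flags)) keep <- keep & !state$flags$low_quality
  if ("doublet" %in% names(meta)) keep <- keep & !meta$doublet
  keep
}
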