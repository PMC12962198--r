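# End-to-end orchestration: phantom or on-disk subjects in, motion-corrected
# maps, ROI tables, per-ROI Lorentzian fits and CI-vs-CN comparison reports
# out.

#' Pipeline configuration
#'
#' Subjects come either from an in-memory list (e.g. [generate_cohort()]
#' output) or from a manifest data.frame with columns `subject_id`, `group`,
#' `series`, `sidecar`, `reference`, `labels`, `lut` (file paths).
#'
#' @param subjects list of in-memory subjects, or NULL.
#' @param manifest manifest data.frame, or NULL.
#' @param offsets_of_interest positive ppm values for the asymmetry maps
#'   (default `c(1, 2, 3.5)`).
#' @param pool_prior a `pool_prior` for the ROI fits.
#' @param b0_window B0 search half-window in ppm (default 1.5).
#' @param grid_step dense interpolation step in ppm (default 0.01).
#' @param motion_correct logical; rigidly realign every offset volume to the
#'   reference before analysis (default FALSE — enable when subject motion is
#'   suspected; registration dominates run time).
#' @param motion_backend `"internal"` or `"external"`.
#' @param exclusions ROI names to drop (default the ventricular system).
#' @param composites composite definitions (default [default_composites()],
#'   built partially from whichever constituents exist), or NULL for none.
#' @param min_voxels minimum per-subject ROI size (default 1).
#' @param s0_floor reference floor fraction for [normalize_series()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param seed integer seed (stamped into provenance; the analysis itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects = NULL, manifest = NULL,
                            offsets_of_interest = c(1, 2, 3.5),
                            pool_prior = default_pool_prior(),
                            b0_window = 1.5, grid_step = 0.01,
                            motion_correct = FALSE,
                            motion_backend = c("internal", "external"),
                            exclusions = default_exclusions(),
                            composites = default_composites(),
                            min_voxels = 1, s0_floor = 0.1,
                            out_dir = NULL, seed = 1L) {
  if (is.null(subjects) && is.null(manifest)) {
    stop("config needs either in-memory subjects or a manifest")
  }
  if (!is.null(manifest)) {
    needed <- c("subject_id", "group", "series", "sidecar", "reference",
                "labels", "lut")
    missing <- setdiff(needed, names(manifest))
    if (length(missing)) stop("manifest missing columns: ", paste(missing, collapse = ", "))
    paths <- unlist(manifest[, c("series", "sidecar", "reference", "labels", "lut")])
    absent <- paths[!file.exists(paths)]
    if (length(absent)) stop("manifest paths do not exist: ", paste(absent, collapse = ", "))
  }
  if (any(offsets_of_interest <= 0)) stop("offsets_of_interest must be positive")
  structure(list(subjects = subjects, manifest = manifest,
                 offsets_of_interest = offsets_of_interest,
                 pool_prior = pool_prior, b0_window = b0_window,
                 grid_step = grid_step, motion_correct = motion_correct,
                 motion_backend = match.arg(motion_backend),
                 exclusions = exclusions, composites = composites,
                 min_voxels = min_voxels, s0_floor = s0_floor,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

subject_roiset <- function(labels, config) {
  rs <- roiset_from_lut(labels$lut)
  rs <- merge_bilateral(rs, labels$lut)
  if (!is.null(config$composites) && length(config$composites)) {
    rs <- build_composites(rs, config$composites, partial = TRUE)
  }
  rs <- exclude_rois(rs, config$exclusions)
  roi_voxel_counts(rs, labels)
}

process_subject <- function(subject, config) {
  series <- subject$series
  transforms <- NULL
  if (isTRUE(config$motion_correct)) {
    mc <- motion_correct_series(series, backend = config$motion_backend)
    series <- mc$series
    transforms <- mc$transforms
  }
  span <- max(abs(range(series$axis$offsets)))
  if (any(config$offsets_of_interest > span)) {
    stop(sprintf("offsets of interest exceed the sampled span (+/- %g ppm)", span))
  }
  zvol <- normalize_series(series, s0_floor = config$s0_floor)
  b0 <- compute_b0_map(zvol, window = config$b0_window,
                       grid_step = config$grid_step)
  maps <- mtr_asym_map(zvol, b0, offsets = config$offsets_of_interest)
  roiset <- subject_roiset(subject$labels, config)
  id <- subject$truth$subject_id %||% "subject"
  group <- subject$truth$group %||% NA_character_
  rows <- list()
  for (m in maps) {
    rows[[length(rows) + 1L]] <- roi_mean_map(
      m, roiset, subject$labels, subject_id = id, group = group,
      metric_name = sprintf("mtrasym_%g", m$offset))
  }
  spectra <- roi_mean_zspectrum(zvol, roiset, subject$labels, b0)
  fits <- list()
  for (nm in names(spectra)) {
    fit <- fit_multipool(spectra[[nm]], prior = config$pool_prior)
    fits[[nm]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, group = group, roi_name = nm,
      metric_name = paste0("lorentzian_", fit$pools$name),
      value = fit$pools$amplitude,
      n_voxels = attr(spectra[[nm]], "n_voxels"), stringsAsFactors = FALSE)
  }
  list(id = id, group = group, table = do.call(rbind, rows), roiset = roiset,
       maps = maps, b0 = b0, fits = fits, transforms = transforms)
}

load_manifest_subject <- function(row) {
  series <- load_cest_series(row$series, row$sidecar, row$reference)
  labels <- read_label_volume(row$labels, row$lut)
  list(series = series, labels = labels,
       truth = list(subject_id = row$subject_id, group = row$group))
}

#' Run the full subject-to-report pipeline
#'
#' Per subject: optional rigid motion correction, Z-normalization, voxel-wise
#' B0 map, MTR_asym maps at the configured offsets, ROI construction
#' (bilateral merging, composites, exclusions), ROI-mean map values, and
#' ROI-averaged Z-spectrum Lorentzian fits. Cohort level: common-ROI
#' intersection, Mann-Whitney CI-vs-CN comparisons for every MTR_asym metric
#' and Lorentzian pool amplitude, and TSV/JSON reports. A subject whose
#' processing fails is flagged and the cohort statistics are computed over
#' the completers.
#'
#' @param config a [pipeline_config()].
#' @return list with `roi_table` (all subjects, common ROIs only), `reports`
#'   (`mtrasym` and `lorentzian` `comparison_report`s), `common_roiset`,
#'   `per_subject` (per-subject results), `failed` (ids), `provenance`.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  subjects <- config$subjects
  if (is.null(subjects)) {
    subjects <- lapply(seq_len(nrow(config$manifest)), function(i) {
      load_manifest_subject(config$manifest[i, ])
    })
  }
  results <- list(); failed <- character(0)
  for (s in subjects) {
    res <- tryCatch(process_subject(s, config), error = function(e) e)
    if (inherits(res, "error")) {
      id <- s$truth$subject_id %||% "subject"
      warning(sprintf("subject '%s' failed: %s", id, conditionMessage(res)))
      failed <- c(failed, id)
    } else {
      results[[res$id]] <- res
    }
  }
  if (!length(results)) stop("no subject completed the pipeline")
  common <- common_rois(lapply(results, `[[`, "roiset"),
                        min_voxels = config$min_voxels)
  keep <- names(common$definitions)
  roi_table <- do.call(rbind, lapply(results, `[[`, "table"))
  roi_table <- roi_table[roi_table$roi_name %in% keep, , drop = FALSE]
  rownames(roi_table) <- NULL

  mtr_metrics <- sprintf("mtrasym_%g", config$offsets_of_interest)
  lor_metrics <- paste0("lorentzian_", config$pool_prior$name)
  cmp <- function(metrics) {
    do.call(rbind, Filter(Negate(is.null),
                          lapply(metrics, compare_groups, table = roi_table)))
  }
  reports <- list(
    mtrasym = comparison_report(cmp(mtr_metrics)),
    lorentzian = comparison_report(cmp(lor_metrics))
  )
  provenance <- list(
    package_version = as.character(utils::packageVersion("cestquant")),
    seed = config$seed, n_subjects = length(results), failed = failed,
    offsets_of_interest = config$offsets_of_interest,
    b0_window = config$b0_window, grid_step = config$grid_step,
    motion_correct = config$motion_correct,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  out <- list(roi_table = roi_table, reports = reports, common_roiset = common,
              per_subject = results, failed = failed, provenance = provenance)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_roi_table(out$roi_table, file.path(config$out_dir, "roi_table.tsv"))
  write_report(out$reports$mtrasym, file.path(config$out_dir, "mtrasym"))
  write_report(out$reports$lorentzian, file.path(config$out_dir, "lorentzian"))
  for (res in out$per_subject) {
    write_asym_maps(res$maps, file.path(config$out_dir, res$id))
  }
  jsonlite::write_json(out$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
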