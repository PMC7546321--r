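#' Declarative pipeline configuration
#'
#' All numeric conventions of the analysis live here as defaults — initial
#' volumes dropped (10), smoothing kernel (4 mm), pass band (0.01-0.08 Hz),
#' gray-matter probability threshold (0.2, strict), FD scrub threshold
#' (0.2 mm), voxel-level FWE alpha (0.05) — never hard-coded in stage logic.
#' Unknown keys are rejected by name so a typo cannot silently fall back to
#' a default.
#'
#' @param ... Overrides as nested lists, e.g.
#'   `pipeline_config(inference = list(n_perm = 500), seed = 7)`.
#' @return Object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    preprocess = list(k_drop = 10L, fwhm_mm = 4, band = c(0.01, 0.08),
                      fd_threshold = 0.2, scrub_floor = 30L,
                      max_trans_mm = 2, max_rot_deg = 2, erode_wm = TRUE,
                      rotation_unit = "radians"),
    mask = list(gm_threshold = 0.2),
    gfc = list(mode = "mean_z", include_self = FALSE, block_size = 512L),
    inference = list(alpha = 0.05, n_perm = 1000L, connectivity = 26L),
    classification = list(grid = NULL, nested = FALSE),
    output = list(write_subject_maps = FALSE, write_stat_maps = TRUE),
    simulate = list())
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, override, path) {
  if (length(override) == 0L) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("configuration overrides must be named (at '", path, "')")
  for (k in nm) {
    full <- paste0(path, if (nzchar(path)) "$" else "", k)
    # simulate holds a free-form cohort_spec override block
    if (!k %in% names(base) && path != "simulate")
      stop("unknown configuration key: ", full)
    if (is.list(base[[k]]) && !is.null(base[[k]]) && is.list(override[[k]]) &&
        k != "simulate" && k != "grid") {
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a cohort from the on-disk layout written by [write_cohort]
#'
#' Expects `participants.tsv`, `gm_prob.nii.gz`, `wm_mask.nii.gz`,
#' `csf_mask.nii.gz` and per-subject `<id>_bold.nii.gz` /
#' `<id>_motion.txt`. Images are loaded lazily by id, like synthetic
#' cohorts.
#'
#' @param dir Input directory.
#' @param rotation_unit Unit of the motion files' rotation columns.
#' @param tr Fallback TR (seconds) if headers carry none.
#' @return Object of class `disk_cohort` usable by [run_pipeline].
#' @export
load_cohort <- function(dir, rotation_unit = "radians", tr = NULL) {
  need <- file.path(dir, c("participants.tsv", "gm_prob.nii.gz"))
  for (f in need) if (!file.exists(f)) stop("missing input file: ", f)
  subjects <- utils::read.delim(file.path(dir, "participants.tsv"),
                                stringsAsFactors = FALSE)
  motion <- lapply(subjects$id, function(id) {
    f <- file.path(dir, paste0(id, "_motion.txt"))
    if (!file.exists(f)) stop("missing input file: ", f)
    read_motion(f, rotation_unit)
  })
  names(motion) <- subjects$id
  read_opt <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f)) read_volume3d(f) else NULL
  }
  structure(list(dir = dir, subjects = subjects, motion = motion,
                 gm_prob = read_volume3d(file.path(dir, "gm_prob.nii.gz"),
                                         probability = TRUE),
                 wm_mask = read_opt("wm_mask.nii.gz"),
                 csf_mask = read_opt("csf_mask.nii.gz"),
                 tr = tr),
            class = "disk_cohort")
}

subject_image <- function(cohort, i) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort_image(cohort, i))
  id <- cohort$subjects$id[i]
  f <- file.path(cohort$dir, paste0(id, "_bold.nii.gz"))
  if (!file.exists(f)) stop("missing input file: ", f)
  read_volume4d(f, tr = cohort$tr)
}

#' Run the full GFC analysis end-to-end
#'
#' Stages: (simulate) -> preprocess every subject -> per-subject GFC maps ->
#' covaried voxel-wise group inference with permutation FWE -> cluster
#' extraction -> cluster-mean features -> duration correlation (patients) ->
#' per-cluster SVM + ROC evaluation -> reports. Subjects failing the
#' gross-motion QC are excluded with a logged reason, and all reported
#' subject counts reflect exclusions. Every artefact lands in `out_dir`
#' together with a provenance record (config hash, seed, package version);
#' report files are byte-stable under a fixed seed.
#'
#' @param config A [pipeline_config] (or nested list of overrides).
#' @param cohort Optional in-memory `synthetic_cohort` or `disk_cohort`; if
#'   `NULL`, a synthetic cohort is generated from `config$simulate` and
#'   `config$seed`.
#' @param out_dir Output directory (created; default a fresh temp dir).
#' @param verbose Log one structured line per stage.
#' @return Object of class `gfc_run` collecting every stage's result:
#'   `subjects`, `mask`, `stat` (`group_stat_map`), `clusters`, `features`,
#'   `correlations`, `classification`, `roc`, `demographics`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = tempfile("gfc_run_"), verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[gfcpipe] %-10s %s", stage,
                    sprintf(...)))
  t0 <- proc.time()[3]

  if (is.null(cohort)) {
    spec <- do.call(cohort_spec, c(config$simulate,
                                   if (!"seed" %in% names(config$simulate))
                                     list(seed = config$seed)))
    cohort <- generate_cohort(spec)
    say("simulate", "%d subjects on a %s grid (seed %s)",
        nrow(cohort$subjects), paste(spec$grid_shape, collapse = "x"),
        format(spec$seed))
  }

  mask <- build_gm_mask(cohort$gm_prob, config$mask$gm_threshold)
  say("mask", "%d gray-matter voxels at p > %g", mask$n_voxels,
      config$mask$gm_threshold)

  pp <- config$preprocess
  n_all <- nrow(cohort$subjects)
  stack <- matrix(NA_real_, n_all, mask$n_voxels)
  mean_fd <- rep(NA_real_, n_all)
  excluded <- character(0)
  reports <- list()
  for (i in seq_len(n_all)) {
    id <- cohort$subjects$id[i]
    res <- preprocess_subject(subject_image(cohort, i), cohort$motion[[id]],
                              mask, cohort$wm_mask, cohort$csf_mask,
                              k_drop = pp$k_drop, fwhm_mm = pp$fwhm_mm,
                              band = pp$band, fd_threshold = pp$fd_threshold,
                              scrub_floor = pp$scrub_floor,
                              max_trans_mm = pp$max_trans_mm,
                              max_rot_deg = pp$max_rot_deg,
                              erode_wm = pp$erode_wm)
    reports[[id]] <- res$report
    mean_fd[i] <- res$fd$mean_fd
    if (is.null(res$ts)) {
      excluded <- c(excluded, id)
      say("preprocess", "%s EXCLUDED by motion QC (frame %s, %s)", id,
          format(res$qc$frame), format(res$qc$axis))
      next
    }
    g <- subject_gfc_map(res$ts, mask, mode = config$gfc$mode,
                         include_self = config$gfc$include_self,
                         block_size = config$gfc$block_size,
                         out_path = if (isTRUE(config$output$write_subject_maps))
                           file.path(out_dir, paste0(id, "_gfc.nii.gz")))
    stack[i, ] <- g$gfc$gfc
  }
  keep <- !cohort$subjects$id %in% excluded
  subjects <- cohort$subjects[keep, , drop = FALSE]
  subjects$mean_fd <- mean_fd[keep]
  stack <- stack[keep, , drop = FALSE]
  say("preprocess", "%d/%d subjects retained (%d excluded)", sum(keep),
      n_all, length(excluded))
  say("gfc", "mode %s over %d voxels", config$gfc$mode, mask$n_voxels)

  inf <- config$inference
  stat <- permutation_fwe(stack, subjects$group,
                          covariates = data.frame(mean_fd = subjects$mean_fd,
                                                  age = subjects$age),
                          n_perm = inf$n_perm, alpha = inf$alpha,
                          seed = derive_seed(config$seed, 11L))
  clusters <- extract_clusters(stat$significant, stat$t, mask,
                               connectivity = inf$connectivity)
  ctab <- cluster_table(clusters)
  say("group", "%d significant voxel(s), %d cluster(s) at FWE alpha = %g",
      sum(stat$significant), length(clusters), inf$alpha)

  features <- cluster_means(stack, clusters)
  correlations <- if ("duration_months" %in% names(subjects) &&
                      length(clusters) > 0)
    correlate_duration(features, subjects) else
    correlate_duration(matrix(numeric(0), nrow(subjects), 0), subjects)

  cls <- list(); roc <- list()
  grid <- if (is.null(config$classification$grid)) svm_grid() else
    config$classification$grid
  for (j in seq_len(ncol(features))) {
    region <- colnames(features)[j]
    cls[[region]] <- loocv_svm(features[, j], subjects$group, grid = grid,
                               nested = config$classification$nested)
    dir_j <- if (clusters[[j]]$peak_t < 0) "lower" else "higher"
    roc[[region]] <- roc_curve(features[, j], subjects$group,
                               direction = dir_j)
  }
  if (length(clusters)) say("classify", "%d region(s) evaluated", length(cls))

  demographics <- demographics_table(subjects)

  run <- structure(list(config = config, subjects = subjects, mask = mask,
                        stack = stack, stat = stat, clusters = clusters,
                        cluster_table = ctab, features = features,
                        correlations = correlations, classification = cls,
                        roc = roc, demographics = demographics,
                        excluded = excluded, preprocess_reports = reports,
                        out_dir = out_dir),
                   class = "gfc_run")
  write_run_artifacts(run, mask)
  say("report", "artifacts written to %s (%.1f s elapsed)", out_dir,
      proc.time()[3] - t0)
  run
}

write_run_artifacts <- function(run, mask) {
  out_dir <- run$out_dir
  cfg <- run$config
  if (isTRUE(cfg$output$write_stat_maps)) {
    write_volume(map_to_volume(run$stat$t, mask),
                 file.path(out_dir, "group_t_map.nii.gz"))
    write_volume(map_to_volume(run$stat$p_fwe, mask, background = 1),
                 file.path(out_dir, "group_p_fwe_map.nii.gz"))
  }
  utils::write.table(run$cluster_table,
                     file.path(out_dir, "cluster_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$correlations,
                     file.path(out_dir, "roi_correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$demographics,
                       file.path(out_dir, "demographics_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(run$classification, function(cr)
      list(best = cr$best,
           accuracy = cr$confusion$accuracy_str,
           sensitivity = cr$confusion$sensitivity_str,
           specificity = cr$confusion$specificity_str,
           grid = cr$grid)),
    file.path(out_dir, "classification_report.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(run$roc, function(rr)
      list(auc = rr$auc, cutoff = rr$cutoff,
           sensitivity = rr$sensitivity, specificity = rr$specificity,
           direction = rr$direction)),
    file.path(out_dir, "roc_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(run$preprocess_reports, function(r)
      r[c("frames_dropped", "qc_pass", "mean_fd", "scrubbed_frames",
          "frames_retained")]),
    file.path(out_dir, "preprocess_report.json"), auto_unbox = TRUE,
    digits = NA)
  cfg_json <- jsonlite::serializeJSON(unclass(cfg))
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_file)),
         seed = cfg$seed,
         n_subjects = nrow(run$subjects),
         excluded = run$excluded,
         package_version = as.character(utils::packageVersion("gfcpipe")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.gfc_run <- function(x, ...) {
  cat(sprintf("<gfc_run> %d subjects (%d excluded), %d cluster(s)\n",
              nrow(x$subjects), length(x$excluded), length(x$clusters)))
  if (nrow(x$cluster_table)) print(x$cluster_table)
  invisible(x)
}

#' Assemble publication-style summary tables from a finished run
#'
#' Emits the four standard tables of a case-control connectivity study:
#' demographics with between-group tests, the significant-cluster table,
#' per-region SVM classification, and per-region ROC results — as
#' data.frames, and as TSV files in the run directory when `write = TRUE`.
#' Percentages are formatted to two decimals with count fractions, e.g.
#' `"85.00% (17/20)"`.
#'
#' @param run A `gfc_run` from [run_pipeline].
#' @param write Write `report_*.tsv` files into `run$out_dir`.
#' @return List of data.frames: `demographics`, `clusters`,
#'   `classification`, `roc`.
#' @export
make_report <- function(run, write = TRUE) {
  dm <- run$demographics
  fmt_ms <- function(s) sprintf("%.2f +/- %.2f", s[[1]], s[[2]])
  demo <- data.frame(
    variable = c("sex_male_female", "age_years", "education_years", "fd_mm"),
    patients = c(sprintf("%d/%d", dm$sex$table["patient", "male"],
                         dm$sex$table["patient", "female"]),
                 fmt_ms(dm$age[c("patients_mean", "patients_sd")]),
                 fmt_ms(dm$education_years[c("patients_mean", "patients_sd")]),
                 if (!is.null(dm$mean_fd))
                   fmt_ms(dm$mean_fd[c("patients_mean", "patients_sd")])
                 else NA),
    controls = c(sprintf("%d/%d", dm$sex$table["control", "male"],
                         dm$sex$table["control", "female"]),
                 fmt_ms(dm$age[c("controls_mean", "controls_sd")]),
                 fmt_ms(dm$education_years[c("controls_mean", "controls_sd")]),
                 if (!is.null(dm$mean_fd))
                   fmt_ms(dm$mean_fd[c("controls_mean", "controls_sd")])
                 else NA),
    p_value = c(dm$sex$p, dm$age$p, dm$education_years$p,
                if (!is.null(dm$mean_fd)) dm$mean_fd$p else NA),
    stringsAsFactors = FALSE)

  cls <- if (length(run$classification))
    data.frame(region = names(run$classification),
               accuracy = vapply(run$classification,
                                 function(cr) cr$confusion$accuracy_str,
                                 character(1)),
               sensitivity = vapply(run$classification,
                                    function(cr) cr$confusion$sensitivity_str,
                                    character(1)),
               specificity = vapply(run$classification,
                                    function(cr) cr$confusion$specificity_str,
                                    character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(region = character(0), accuracy = character(0),
                  sensitivity = character(0), specificity = character(0))

  roc <- if (length(run$roc))
    data.frame(region = names(run$roc),
               auc = vapply(run$roc, `[[`, numeric(1), "auc"),
               cutoff = vapply(run$roc, `[[`, numeric(1), "cutoff"),
               sensitivity = sprintf("%.2f%%", vapply(run$roc, `[[`,
                                                      numeric(1),
                                                      "sensitivity")),
               specificity = sprintf("%.2f%%", vapply(run$roc, `[[`,
                                                      numeric(1),
                                                      "specificity")),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(region = character(0), auc = numeric(0),
                  cutoff = numeric(0), sensitivity = character(0),
                  specificity = character(0))

  tables <- list(demographics = demo, clusters = run$cluster_table,
                 classification = cls, roc = roc)
  if (write) {
    for (nm in names(tables))
      utils::write.table(tables[[nm]],
                         file.path(run$out_dir, paste0("report_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tables
}
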