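# Dataset-level pipeline: simulate cohorts to disk, measure a dataset
# directory, and write summary/comparison tables. Every run directory gets
# a manifest recording the seed, package version and a configuration hash,
# so a run can be reproduced bit-identically on the mesh path.

#' Simulate a cohort dataset to disk
#'
#' Samples the cohorts, writes one directory per subject x condition with
#' the structure meshes as ASCII PLY (optionally a NIfTI label volume),
#' and a top-level `manifest.csv` holding every file's condition metadata
#' and ground truth, plus a `manifest.txt` with the seed, version and
#' configuration hash.
#'
#' @param outdir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param specs list of [cohort_spec()] objects (one per group).
#' @param flexion,muscle optional condition filters (default: all six).
#' @param write_volumes also write voxelized label volumes (slower).
#' @param overwrite allow writing into an existing dataset directory.
#' @return the manifest data.frame, invisibly.
#' @export
simulate_dataset <- function(outdir, specs = list(cohort_spec("healthy"),
                                                  cohort_spec("pcl")),
                             flexion = NULL, muscle = NULL,
                             write_volumes = FALSE, overwrite = FALSE) {
  if (file.exists(file.path(outdir, "manifest.csv")) && !overwrite)
    stop("dataset already exists at ", outdir, call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  rows <- list()
  for (spec in specs) {
    cohort <- sample_cohort(spec)
    keep <- rep(TRUE, nrow(cohort$params))
    if (!is.null(flexion)) keep <- keep & cohort$params$flexion %in% flexion
    if (!is.null(muscle)) keep <- keep & cohort$params$muscle %in% muscle
    for (i in which(keep)) {
      scene <- cohort_scene(cohort, i)
      p <- cohort$params[i, ]
      rel <- file.path(p$subject, sprintf("f%02d_%s", p$flexion, p$muscle))
      dir.create(file.path(outdir, rel), recursive = TRUE, showWarnings = FALSE)
      for (nm in names(scene$meshes))
        write_ply(scene$meshes[[nm]],
                  file.path(outdir, rel, paste0(nm, ".ply")))
      if (write_volumes)
        write_label_volume(voxelize_knee(scene),
                           file.path(outdir, rel, "labels.nii.gz"))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(path = rel, seed = spec$seed), p)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- utils::capture.output(utils::str(lapply(specs, unclass)))
  writeLines(c(paste("package_version:", as.character(utils::packageVersion("kneekin"))),
               paste("seeds:", paste(vapply(specs, `[[`, 0L, "seed"),
                                     collapse = " ")),
               paste("config_hash:", config_hash(cfg)),
               paste("n_scenes:", nrow(manifest))),
             file.path(outdir, "manifest.txt"))
  invisible(manifest)
}

#' Measure every scene of a dataset directory
#'
#' Reads the manifest written by [simulate_dataset()] (or an equivalent
#' mesh-directory layout), loads each condition's meshes and measures them.
#' Scenes that fail to load or measure are skipped with a warning and
#' reported in the `failures` attribute; the run continues.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param write write `records.csv` into `dir`.
#' @return data.frame of kinematics records (one row per measured scene),
#'   with ground-truth columns from the manifest joined as `gt_*`.
#' @export
measure_dataset <- function(dir, write = TRUE) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf_path)
  need <- c("tibia_plateau", "condyle_medial", "condyle_lateral",
            "femur_shaft", "trochlea", "patella")
  out <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch({
      meshes <- lapply(stats::setNames(nm = need), function(nm)
        read_ply(file.path(dir, row$path, paste0(nm, ".ply")), tag = nm))
      f <- deg2rad(row$flexion)
      scene <- list(meshes = meshes,
                    hints = orientation_hints(femur_proximal = c(0, sin(f), cos(f))),
                    subject = row$subject, group = row$group,
                    flexion = row$flexion, muscle = row$muscle)
      measure_scene(scene)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning(sprintf("skipping %s: %s", row$path, conditionMessage(rec)),
              call. = FALSE)
      fails[[length(fails) + 1L]] <- data.frame(path = row$path,
                                                error = conditionMessage(rec))
    } else {
      gt <- row[intersect(KIN_PARAMETERS, names(row))]
      names(gt) <- paste0("gt_", names(gt))
      out[[length(out) + 1L]] <- cbind(rec, gt)
    }
  }
  if (!length(out)) stop("no scene could be measured", call. = FALSE)
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  attr(records, "failures") <- if (length(fails)) do.call(rbind, fails)
  if (write)
    utils::write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  records
}

#' Write summary and comparison tables for a measured dataset
#'
#' @param records kinematics records (from [measure_dataset()] or
#'   [measure_cohort()]).
#' @param outdir directory for the output files.
#' @param var_equal pooled-variance (TRUE) or Welch unpaired tests.
#' @return list with the `summary` and `comparisons` data.frames, invisibly.
#' @export
stats_tables <- function(records, outdir, var_equal = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summ <- summarize_kinematics(records)
  utils::write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE)
  for (g in unique(summ$group)) {
    tab <- kinematics_table(summ, g)
    utils::write.csv(as.data.frame(tab), file.path(outdir,
                                                   paste0("table_", g, ".csv")))
    writeLines(utils::capture.output(print(tab, quote = FALSE)),
               file.path(outdir, paste0("table_", g, ".txt")))
  }
  cmp <- compare_all(records, var_equal = var_equal)
  utils::write.csv(cmp, file.path(outdir, "comparisons.csv"), row.names = FALSE)
  invisible(list(summary = summ, comparisons = cmp))
}
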