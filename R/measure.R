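# Measurement pipeline: frames -> epicondylar axis -> tibiofemoral and
# patellofemoral parameters, for one scene or a whole dataset.

#' Measure one knee scene
#'
#' Runs the full measurement chain on a structure set: tibial frame from
#' the plateau, cylinder fit to both condylar bands jointly, reference
#' points projected onto the axis and expressed in the tibial frame,
#' femoral shaft axis, patellar frame, trochlear landmarks and the four
#' patellofemoral parameters.
#'
#' @param scene a `knee_scene`, or any list with named `meshes`
#'   (`tibia_plateau`, `condyle_medial`, `condyle_lateral`, `femur_shaft`,
#'   `trochlea`, `patella`), `hints`, and metadata fields `subject`,
#'   `group`, `flexion`, `muscle`.
#' @return one-row data.frame (class `kinematics_record`): condition
#'   metadata, condylar AP positions `ap_medial`, `ap_lateral`,
#'   `ap_central` (mm, anterior +), epicondylar `rotation` (degrees,
#'   internal +), `height`, `pf_angle`, `tilt`, `shift`, and the
#'   per-stage diagnostics `cyl_radius`, `cyl_rms` (mm).
#' @export
measure_scene <- function(scene) {
  ms <- scene$meshes
  need <- c("tibia_plateau", "condyle_medial", "condyle_lateral",
            "femur_shaft", "trochlea", "patella")
  miss <- setdiff(need, names(ms))
  if (length(miss))
    stop("scene lacks structures: ", paste(miss, collapse = ", "), call. = FALSE)
  hints <- scene$hints %||% orientation_hints()
  tib <- build_tibial_frame(ms$tibia_plateau, hints)
  pts <- rbind(ms$condyle_medial$vertices, ms$condyle_lateral$vertices)
  lateral_world <- tib$axes["x", ]
  cyl <- fit_cylinder(pts, lateral_hint = lateral_world)
  ref <- condylar_reference_points(cyl, ms$condyle_medial, ms$condyle_lateral)
  ref_local <- lapply(ref[c("medial", "lateral", "central")],
                      express_in_frame, frame = tib)
  pose <- pose_sample(scene$subject %||% "S", scene$group %||% "healthy",
                      scene$flexion %||% 0, scene$muscle %||% "relaxed",
                      ref_local)
  flong <- femoral_long_axis(ms$femur_shaft, hints)
  pfr <- build_patellar_frame(ms$patella, hints)
  lm <- trochlear_landmarks(ms$trochlea, pfr)
  out <- data.frame(
    subject = pose$subject, group = pose$group,
    flexion = pose$flexion, muscle = pose$muscle,
    ap_medial = ref_local$medial[2], ap_lateral = ref_local$lateral[2],
    ap_central = ref_local$central[2],
    rotation = epicondylar_rotation(pose),
    height = patellar_height(pfr, tib),
    pf_angle = patellofemoral_angle(pfr, flong),
    tilt = patellar_tilt(lm, pfr),
    shift = patellar_shift(pfr, lm, tib),
    cyl_radius = cyl$radius, cyl_rms = cyl$rms)
  class(out) <- c("kinematics_record", class(out))
  out
}

#' Measure a scene set reconstructed from a label volume
#'
#' Extracts the required structure surfaces from the labelled volume
#' (optionally after tri-linear upsampling) and measures them with
#' [measure_scene()]. Bone labels are contoured with indicator smoothing;
#' the thin articular-shell labels without.
#'
#' @param volume a `label_volume` using the [knee_labels()] coding.
#' @param hints an [orientation_hints()] record.
#' @param upsample integer indicator-interpolation factor passed to
#'   [extract_surface()] (1 = contour at native resolution).
#' @param subject,group,flexion,muscle condition metadata for the record.
#' @return one-row `kinematics_record` data.frame.
#' @export
measure_volume <- function(volume, hints = orientation_hints(), upsample = 1L,
                           subject = "S", group = "healthy",
                           flexion = 0, muscle = "relaxed") {
  lb <- knee_labels()
  need <- c("tibia_plateau", "trochlea", "condyle_medial", "condyle_lateral",
            "femur_shaft", "patella")
  meshes <- lapply(stats::setNames(nm = need), function(s)
    extract_surface(volume, lb[[s]], smooth = TRUE, upsample = upsample,
                    tag = s))
  measure_scene(list(meshes = meshes, hints = hints, subject = subject,
                     group = group, flexion = flexion, muscle = muscle))
}

#' Measure every condition of a sampled cohort
#'
#' Builds each subject-condition scene from the cohort's ground-truth
#' parameters and measures it through the full pipeline.
#'
#' @param cohort a `knee_cohort` from [sample_cohort()].
#' @param flexion,muscle optional filters restricting the measured
#'   conditions (e.g. `flexion = 90, muscle = "relaxed"`).
#' @return data.frame of `kinematics_record` rows.
#' @export
measure_cohort <- function(cohort, flexion = NULL, muscle = NULL) {
  keep <- rep(TRUE, nrow(cohort$params))
  if (!is.null(flexion)) keep <- keep & cohort$params$flexion %in% flexion
  if (!is.null(muscle)) keep <- keep & cohort$params$muscle %in% muscle
  rows <- lapply(which(keep), function(i) measure_scene(cohort_scene(cohort, i)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
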