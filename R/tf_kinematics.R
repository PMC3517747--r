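# Tibiofemoral kinematics: femoral reference points expressed in the
# tibial frame, axial rotation of the epicondylar axis, and differences
# between acquisitions.
#
# Sign conventions (fixed throughout the package): x lateral +, y anterior +,
# z proximal +; femoral internal rotation +. Each acquisition uses its own
# tibial frame, so cross-condition comparability rests on the deterministic
# frame construction in build_tibial_frame().

#' Express a world point in an anatomical frame
#'
#' `local = A (p - origin)` with `A` the frame's axis matrix (rows x, y, z);
#' the inverse mapping restores the input exactly.
#'
#' @param point length-3 world point, or an n x 3 matrix of points (mm).
#' @param frame an `anat_frame`.
#' @return local coordinates with the same shape as `point`.
#' @export
express_in_frame <- function(point, frame) {
  if (!inherits(frame, "anat_frame")) stop("frame must be an anat_frame")
  if (is.matrix(point))
    t(frame$axes %*% (t(point) - frame$origin))
  else
    as.numeric(frame$axes %*% (point - frame$origin))
}

#' Map local frame coordinates back to world coordinates
#' @inheritParams express_in_frame
#' @export
frame_to_world <- function(point, frame) {
  if (is.matrix(point))
    t(t(frame$axes) %*% t(point) + frame$origin)
  else
    as.numeric(t(frame$axes) %*% point + frame$origin)
}

#' Assemble a pose sample
#'
#' One acquisition of one subject: the femoral reference points already
#' expressed in that acquisition's tibial frame, plus condition metadata.
#'
#' @param subject subject identifier.
#' @param group `"healthy"` or `"pcl"`.
#' @param flexion flexion label in degrees: 0, 30 or 90.
#' @param muscle `"relaxed"` or `"active"` (isometric flexor activity).
#' @param refpoints_local list with `medial`, `lateral`, `central` length-3
#'   points in tibial-frame coordinates (mm).
#' @return object of class `pose_sample`.
#' @export
pose_sample <- function(subject, group = c("healthy", "pcl"),
                        flexion, muscle = c("relaxed", "active"),
                        refpoints_local) {
  group <- match.arg(group)
  muscle <- match.arg(muscle)
  if (!flexion %in% c(0, 30, 90))
    stop("flexion label must be one of 0, 30, 90", call. = FALSE)
  for (nm in c("medial", "lateral", "central"))
    stopifnot_finite(refpoints_local[[nm]], paste(nm, "reference point"))
  structure(list(subject = subject, group = group, flexion = flexion,
                 muscle = muscle, ref = refpoints_local),
            class = "pose_sample")
}

#' Axial rotation of the epicondylar axis in the tibial transverse plane
#'
#' Signed angle between the medial-to-lateral reference vector, projected
#' into the tibial x-y (transverse) plane, and the tibial x axis. Femoral
#' internal rotation (lateral condyle moving anteriorly) is positive; range
#' (-180, 180] degrees.
#'
#' @param pose a `pose_sample` (reference points in tibial coordinates).
#' @return rotation in degrees.
#' @export
epicondylar_rotation <- function(pose) {
  v <- pose$ref$lateral - pose$ref$medial
  if (vec_norm(v) < 1e-9)
    stop("medial and lateral reference points coincide", call. = FALSE)
  if (sqrt(v[1]^2 + v[2]^2) < 1e-6 * vec_norm(v))
    stop("degenerate projection: epicondylar axis is near-vertical", call. = FALSE)
  wrap_deg(rad2deg(atan2(v[2], v[1])))
}

#' Tibiofemoral change between two poses of one subject
#'
#' Anterior-posterior translation (anterior +) of the medial, lateral and
#' central reference points, and the change in epicondylar rotation
#' (internal +), from `pose_a` to `pose_b`. Each pose must be expressed in
#' its own acquisition's tibial frame.
#'
#' @param pose_a,pose_b `pose_sample` objects for the same subject.
#' @return object of class `tf_delta`: `ap_medial`, `ap_lateral`,
#'   `ap_central` (mm), `rotation` (degrees, wrapped to (-180, 180]).
#' @export
tf_delta <- function(pose_a, pose_b) {
  if (!identical(pose_a$subject, pose_b$subject) ||
      !identical(pose_a$group, pose_b$group))
    stop("poses belong to different subjects", call. = FALSE)
  structure(list(
    subject = pose_a$subject,
    from = c(flexion = pose_a$flexion, muscle = pose_a$muscle),
    to = c(flexion = pose_b$flexion, muscle = pose_b$muscle),
    ap_medial = pose_b$ref$medial[2] - pose_a$ref$medial[2],
    ap_lateral = pose_b$ref$lateral[2] - pose_a$ref$lateral[2],
    ap_central = pose_b$ref$central[2] - pose_a$ref$central[2],
    rotation = wrap_deg(epicondylar_rotation(pose_b) - epicondylar_rotation(pose_a))),
    class = "tf_delta")
}

#' @export
print.tf_delta <- function(x, ...) {
  cat(sprintf("tf_delta %s: %s/%s -> %s/%s\n", x$subject,
              x$from["flexion"], x$from["muscle"], x$to["flexion"], x$to["muscle"]))
  cat(sprintf("  AP medial %+.2f, lateral %+.2f, central %+.2f mm; rotation %+.2f deg\n",
              x$ap_medial, x$ap_lateral, x$ap_central, x$rotation))
  invisible(x)
}
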