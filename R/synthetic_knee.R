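# Parametric synthetic knee scenes with known ground-truth kinematics.
#
# The generator builds tibia, femur and patella structures in the tibial
# reference frame (x lateral, y anterior, z proximal, origin at the plateau
# centroid) and poses them according to a motion model, so that every
# quantity the measurement pipeline reports has an exact imposed twin:
#
#   * the condylar cylinder axis passes through the imposed medial/lateral
#     reference positions, making AP translation and axial rotation exact;
#   * the patellar ellipsoid is placed so that its inferior pole sits at the
#     imposed height, its long axis at the imposed patellofemoral angle,
#     its body rotated about the long axis by the imposed tilt, and the
#     trochlear groove floor offset medially by the imposed shift.
#
# Because translation and rotation of a rigid epicondylar axis are coupled,
# the motion model imposes the medial and lateral AP positions and the
# axial rotation follows as asin((lateral - medial) / (2 * condyle_offset)).

#' Shape parameters of the synthetic knee
#'
#' Defaults approximate adult knee dimensions; `condyle_offset` (half the
#' distance between the condylar reference points) is 28.65 mm so that one
#' degree of axial rotation corresponds to one millimetre of differential
#' medio-lateral AP translation.
#'
#' @param condyle_radius posterior condylar cylinder radius (mm).
#' @param condyle_halfwidth half-width of each condylar band along the
#'   epicondylar axis (mm).
#' @param condyle_offset axial distance of each condylar reference point
#'   from the femoral centre (mm).
#' @param condyle_height height of the epicondylar axis above the plateau (mm).
#' @param plateau_a,plateau_b tibial plateau semi-axes, medio-lateral and
#'   antero-posterior (mm).
#' @param trochlea_halfwidth medio-lateral half-width of each trochlear
#'   facet (mm).
#' @param trochlea_opening facet inclination from the medio-lateral axis
#'   (degrees); groove depth is `trochlea_halfwidth * tan(opening)`.
#' @param trochlea_length groove length along the patellar long axis (mm).
#' @param patella_semiaxes patellar ellipsoid semi-axes (medio-lateral,
#'   longitudinal, antero-posterior) in mm.
#' @param patella_gap distance between the posterior patellar pole and the
#'   groove floor (mm). The default keeps the trochlear facet wings clear
#'   of the patellar body over the default motion range, so that voxelized
#'   scenes have non-overlapping bone labels.
#' @param shaft_radius,shaft_length femoral shaft tube dimensions (mm).
#' @param tibia_length tibial shaft extent below the plateau (mm).
#' @param ipp_elevation elevation angle of the inferior patellar pole above
#'   the tibial transverse plane, in the sagittal plane (degrees).
#' @param voxel_spacing spacing for voxelized output (mm).
#' @return list of class `knee_shape_params`.
#' @export
knee_shape_params <- function(condyle_radius = 20, condyle_halfwidth = 10,
                              condyle_offset = 28.65, condyle_height = 21,
                              plateau_a = 35, plateau_b = 25,
                              trochlea_halfwidth = 12, trochlea_opening = 30,
                              trochlea_length = 30,
                              patella_semiaxes = c(20, 25, 10),
                              patella_gap = 11,
                              shaft_radius = 14, shaft_length = 110,
                              tibia_length = 70,
                              ipp_elevation = 35,
                              voxel_spacing = 1) {
  p <- as.list(environment())
  lens <- unlist(p[c("condyle_radius", "condyle_halfwidth", "condyle_offset",
                     "plateau_a", "plateau_b", "trochlea_halfwidth",
                     "trochlea_length", "patella_semiaxes", "patella_gap",
                     "shaft_radius", "shaft_length", "tibia_length",
                     "voxel_spacing")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all shape lengths must be positive", call. = FALSE)
  depth <- trochlea_halfwidth * tan(deg2rad(trochlea_opening))
  if (depth >= condyle_radius)
    stop("trochlear groove depth must be smaller than the condylar radius",
         call. = FALSE)
  structure(p, class = "knee_shape_params")
}

#' Table 1 patellofemoral calibration
#'
#' Per-condition means and standard deviations of the four patellofemoral
#' parameters for the healthy (n = 20) and PCL-deficient (n = 12) study
#' groups, used to calibrate the cohort generator.
#'
#' @param group `"healthy"` or `"pcl"`.
#' @return data.frame with columns `flexion`, `muscle` and
#'   `<parameter>_mean` / `<parameter>_sd` for height, pf_angle, tilt, shift.
#' @export
pf_calibration <- function(group = c("healthy", "pcl")) {
  group <- match.arg(group)
  base <- data.frame(flexion = rep(c(0, 30, 90), each = 2),
                     muscle = rep(c("relaxed", "active"), 3))
  vals <- if (group == "healthy") list(
    height_mean = c(16.2, 19.7, 17.0, 17.2, 23.5, 23.7),
    height_sd   = c(3.8, 4.9, 6.3, 3.6, 3.2, 7.6),
    pf_angle_mean = c(5.9, 7.8, 21.2, 16.3, 49.9, 52.2),
    pf_angle_sd   = c(5.2, 4.6, 8.2, 10.8, 6.3, 7.8),
    tilt_mean = c(8.7, 9.7, 9.2, 8.2, 7.5, 6.4),
    tilt_sd   = c(3.4, 4.1, 3.9, 2.9, 3.5, 6.1),
    shift_mean = c(1.9, 2.4, 1.9, 2.4, 4.7, 5.2),
    shift_sd   = c(2.9, 4.6, 1.7, 3.3, 5.0, 5.0)
  ) else list(
    height_mean = c(15.5, 15.3, 17.3, 16.7, 21.6, 21.0),
    height_sd   = c(8.0, 7.7, 8.4, 6.9, 7.9, 8.2),
    pf_angle_mean = c(4.3, 7.4, 18.9, 17.4, 52.3, 51.4),
    pf_angle_sd   = c(4.1, 6.1, 6.4, 8.7, 4.9, 5.3),
    tilt_mean = c(9.1, 9.5, 9.7, 9.5, 13.1, 14.0),
    tilt_sd   = c(5.3, 5.7, 4.6, 5.2, 9.1, 9.4),
    shift_mean = c(2.1, 3.0, 2.4, 3.2, 6.7, 6.8),
    shift_sd   = c(1.6, 2.1, 2.2, 3.1, 5.4, 5.3)
  )
  cbind(base, as.data.frame(vals))
}

#' Default motion models for the two study groups
#'
#' Per condition (flexion x muscle state) the imposed medial and lateral
#' condylar AP positions (mm, anterior +, relative to the tibial frame) and
#' the four patellofemoral parameters. The patellofemoral means are the
#' study calibration of [pf_calibration()]. The tibiofemoral pattern is a
#' configurable artifact choice reproducing the qualitative study findings:
#' healthy knees start internally rotated and roll back during flexion with
#' the lateral condyle translating further than the medial one (14 vs 4 mm
#' by 90 degrees, 10 degrees of external rotation); PCL-deficient knees
#' match the healthy pattern up to 30 degrees and then show a paradoxical
#' anterior translation of the medial condyle (+6 mm from 30 to 90 degrees,
#' +2 mm more under flexor activity) with a nearly constant lateral condyle
#' and reduced external rotation. Healthy knees are unaffected by flexor
#' activity.
#'
#' @param group `"healthy"` or `"pcl"`.
#' @return data.frame of class `motion_model`, one row per condition, with
#'   columns `flexion`, `muscle`, `ap_medial`, `ap_lateral`, `rotation`
#'   (derived), `height`, `pf_angle`, `tilt`, `shift` and a `group`
#'   attribute.
#' @export
default_motion_model <- function(group = c("healthy", "pcl")) {
  group <- match.arg(group)
  m <- pf_calibration(group)
  tf <- if (group == "healthy") data.frame(
    ap_medial  = c(0, 0, -2, -2, -4, -4),
    ap_lateral = c(5, 5, 1, 1, -9, -9)
  ) else data.frame(
    ap_medial  = c(0, 0, -2, -2, 4, 6),
    ap_lateral = c(5, 5, 1, 1, 0, 0)
  )
  out <- data.frame(flexion = m$flexion, muscle = m$muscle,
                    ap_medial = tf$ap_medial, ap_lateral = tf$ap_lateral,
                    height = m$height_mean, pf_angle = m$pf_angle_mean,
                    tilt = m$tilt_mean, shift = m$shift_mean)
  out$rotation <- derived_rotation(out$ap_medial, out$ap_lateral)
  attr(out, "group") <- group
  class(out) <- c("motion_model", class(out))
  out
}

# Axial rotation implied by the medial/lateral AP positions for the default
# condylar reference-point separation.
derived_rotation <- function(ap_medial, ap_lateral,
                             condyle_offset = knee_shape_params()$condyle_offset) {
  rad2deg(asin((ap_lateral - ap_medial) / (2 * condyle_offset)))
}

# --- parametric mesh primitives -------------------------------------------

# Split a quad (a,b,c,d) into two triangles preserving winding; `flip`
# selects the other diagonal. Alternating the diagonal in a checkerboard
# removes the orientation asymmetry a fixed split introduces, keeping the
# solid and surface moments of symmetric shapes exactly symmetric.
quad_tris <- function(a, b, c, d, flip = FALSE) {
  if (flip) list(c(a, b, d), c(b, c, d)) else list(c(a, b, c), c(a, c, d))
}

# Elliptical disk in the plane z = 0, fan + ring triangulation.
mesh_ellipse_disk <- function(a, b, center = c(0, 0, 0), nr = 8L, na = 48L,
                              tag = NULL) {
  th <- seq(0, 2 * pi, length.out = na + 1L)[-(na + 1L)]
  rr <- seq_len(nr) / nr
  v <- rbind(c(0, 0, 0),
             cbind(as.vector(outer(cos(th), rr * a)),
                   as.vector(outer(sin(th), rr * b)), 0))
  idx <- function(ring, k) 1L + (ring - 1L) * na + (k - 1L) %% na + 1L
  faces <- list()
  for (k in seq_len(na))
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, k), idx(1L, k + 1L))
  for (ring in seq_len(nr - 1L)) for (k in seq_len(na))
    faces <- c(faces, quad_tris(idx(ring, k), idx(ring + 1L, k),
                                idx(ring + 1L, k + 1L), idx(ring, k + 1L),
                                flip = (ring + k) %% 2L == 0L))
  m <- surface_mesh(v, do.call(rbind, faces), tag = tag)
  transform_mesh(m, translation = center)
}

# Symmetric quad tessellation: fan every quad through its centroid, so the
# triangulated solid inherits all symmetries of the quad grid (a fixed
# diagonal split would not).
quad_fan_mesh <- function(v, quads, extra_faces = list(), tag = NULL) {
  qc <- (v[quads[, 1], , drop = FALSE] + v[quads[, 2], , drop = FALSE] +
           v[quads[, 3], , drop = FALSE] + v[quads[, 4], , drop = FALSE]) / 4
  mi <- nrow(v) + seq_len(nrow(quads))
  faces <- vector("list", 4L * nrow(quads))
  for (q in seq_len(nrow(quads))) {
    qq <- quads[q, ]
    faces[[4L * q - 3L]] <- c(qq[1], qq[2], mi[q])
    faces[[4L * q - 2L]] <- c(qq[2], qq[3], mi[q])
    faces[[4L * q - 1L]] <- c(qq[3], qq[4], mi[q])
    faces[[4L * q]] <- c(qq[4], qq[1], mi[q])
  }
  surface_mesh(rbind(v, qc), do.call(rbind, c(faces, extra_faces)), tag = tag)
}

# Closed tube (cylinder with cap fans) from p0 to p1.
mesh_tube <- function(p0, p1, r, nseg = 24L, nlen = 8L, tag = NULL) {
  u <- unitize(p1 - p0)
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(seed - sum(seed * u) * u)
  e2 <- cross3(u, e1)
  len <- vec_norm(p1 - p0)
  th <- seq(0, 2 * pi, length.out = nseg + 1L)[-(nseg + 1L)]
  ll <- seq(0, len, length.out = nlen + 1L)
  ring <- outer(cos(th), e1) + outer(sin(th), e2)
  v <- do.call(rbind, lapply(ll, function(l)
    sweep(r * ring, 2, -(p0 + l * u))))
  nv <- nrow(v)
  v <- rbind(v, p0, p1)
  i_p0 <- nv + 1L; i_p1 <- nv + 2L
  idx <- function(row, k) (row - 1L) * nseg + (k - 1L) %% nseg + 1L
  quads <- do.call(rbind, lapply(seq_len(nlen), function(row)
    t(vapply(seq_len(nseg), function(k)
      c(idx(row, k), idx(row, k + 1L), idx(row + 1L, k + 1L), idx(row + 1L, k)),
      integer(4)))))
  caps <- list()
  for (k in seq_len(nseg)) {
    caps[[length(caps) + 1L]] <- c(i_p0, idx(1L, k + 1L), idx(1L, k))
    caps[[length(caps) + 1L]] <- c(i_p1, idx(nlen + 1L, k), idx(nlen + 1L, k + 1L))
  }
  quad_fan_mesh(v, quads, extra_faces = caps, tag = tag)
}

# Open cylindrical band: axis through `anchor` along unit `u`, radius r,
# axial range s_range, angular range phi_range (degrees) measured from
# `dir0` towards `dir90`.
mesh_cyl_band <- function(anchor, u, r, s_range, phi_range, dir0, dir90,
                          ns = 15L, nphi = 15L, tag = NULL) {
  s <- seq(s_range[1], s_range[2], length.out = ns)
  phi <- deg2rad(seq(phi_range[1], phi_range[2], length.out = nphi))
  grid_mesh(function(si, pj)
    anchor + si * u + r * (cos(pj) * dir0 + sin(pj) * dir90),
    s, phi, tag = tag)
}

# Structured grid -> triangle mesh helper. f(a, b) returns a 3-vector.
grid_mesh <- function(f, as, bs, tag = NULL) {
  na <- length(as); nb <- length(bs)
  v <- matrix(NA_real_, na * nb, 3)
  for (j in seq_len(nb)) for (i in seq_len(na))
    v[(j - 1L) * na + i, ] <- f(as[i], bs[j])
  faces <- list()
  idx <- function(i, j) (j - 1L) * na + i
  for (j in seq_len(nb - 1L)) for (i in seq_len(na - 1L))
    faces <- c(faces, quad_tris(idx(i, j), idx(i + 1L, j),
                                idx(i + 1L, j + 1L), idx(i, j + 1L),
                                flip = (i + j) %% 2L == 0L))
  surface_mesh(v, do.call(rbind, faces), tag = tag)
}

# Lat-long ellipsoid with pole vertices along the local Y axis.
# axes: 3x3 matrix whose COLUMNS are the local x, y, z directions.
mesh_ellipsoid <- function(center, semi, axes = diag(3), nu = 28L, nv = 21L,
                           tag = NULL) {
  lat <- seq(-pi / 2, pi / 2, length.out = nv)[-c(1L, nv)]
  lon <- seq(0, 2 * pi, length.out = nu + 1L)[-(nu + 1L)]
  v <- list(c(0, -semi[2], 0))
  for (la in lat) for (lo in lon)
    v[[length(v) + 1L]] <- c(semi[1] * cos(la) * cos(lo),
                             semi[2] * sin(la),
                             semi[3] * cos(la) * sin(lo))
  v[[length(v) + 1L]] <- c(0, semi[2], 0)
  v <- do.call(rbind, v)
  nlat <- length(lat)
  south <- 1L; north <- nrow(v)
  idx <- function(band, k) 1L + (band - 1L) * nu + (k - 1L) %% nu + 1L
  caps <- list()
  for (k in seq_len(nu)) {
    caps[[length(caps) + 1L]] <- c(south, idx(1L, k), idx(1L, k + 1L))
    caps[[length(caps) + 1L]] <- c(north, idx(nlat, k + 1L), idx(nlat, k))
  }
  quads <- do.call(rbind, lapply(seq_len(nlat - 1L), function(band)
    t(vapply(seq_len(nu), function(k)
      c(idx(band, k), idx(band + 1L, k), idx(band + 1L, k + 1L), idx(band, k + 1L)),
      integer(4)))))
  m <- quad_fan_mesh(v, quads, extra_faces = caps, tag = tag)
  m$vertices <- m$vertices %*% t(axes)
  transform_mesh(m, translation = center)
}

# V-profile trochlear groove: floor line through f0 along g, facets rising
# towards e3 (anterior) at `opening` degrees, half-width hw, length L.
mesh_groove <- function(f0, g, e1, e3, hw, opening, L, nt = 14L, nl = 25L,
                        tag = NULL) {
  tanw <- tan(deg2rad(opening))
  ts <- seq(-hw, hw, length.out = 2L * nt + 1L)
  ls <- seq(-L / 2, L / 2, length.out = nl)
  grid_mesh(function(t, l) f0 + l * g + t * e1 + abs(t) * tanw * e3,
            ts, ls, tag = tag)
}

# --- scene construction ----------------------------------------------------

# Internal: placement geometry shared by the mesh builder and the voxelizer.
knee_placement <- function(shape, params, flexion) {
  d <- shape$condyle_offset
  m <- params$ap_medial; l <- params$ap_lateral
  sinr <- (l - m) / (2 * d)
  if (abs(sinr) >= 1)
    stop("inconsistent condition: |ap_lateral - ap_medial| exceeds the ",
         "condylar separation", call. = FALSE)
  rho <- asin(sinr)
  u <- c(cos(rho), sin(rho), 0)
  A <- c(0, (m + l) / 2, shape$condyle_height)
  n_post <- unitize(cross3(u, c(0, 0, 1)))       # posterior-ish
  if (n_post[2] > 0) n_post <- -n_post
  n_inf <- cross3(u, n_post)
  if (n_inf[3] > 0) n_inf <- -n_inf
  f <- deg2rad(flexion)
  F_dir <- c(0, sin(f), cos(f))
  beta <- params$pf_angle
  Py0 <- as.numeric(rotation_about(c(1, 0, 0), beta) %*% F_dir)
  Px0 <- c(1, 0, 0)
  Pz0 <- cross3(Px0, Py0)
  Rt <- rotation_about(Py0, params$tilt)
  Px <- as.numeric(Rt %*% Px0)
  Pz <- as.numeric(Rt %*% Pz0)
  gam <- deg2rad(shape$ipp_elevation)
  ipp <- c(0, params$height * cos(gam), params$height * sin(gam))
  C <- ipp + shape$patella_semiaxes[2] * Py0
  f0 <- C - (shape$patella_semiaxes[3] + shape$patella_gap) * Pz0
  f0[1] <- C[1] - params$shift
  e1 <- c(1, 0, 0)                                # groove transverse dir
  list(rho = rho, u = u, A = A,
       P_m = A - d * u, P_l = A + d * u,
       n_post = n_post, n_inf = n_inf,
       F_dir = F_dir, Py = Py0, Px = Px, Pz = Pz, Pz0 = Pz0,
       C = C, ipp = ipp, groove_f0 = f0, groove_e1 = e1, groove_e3 = Pz0,
       shaft_p0 = A + 25 * F_dir,
       shaft_p1 = A + (25 + shape$shaft_length) * F_dir)
}

#' Generate one synthetic knee scene
#'
#' Builds the full structure set for one acquisition condition: tibial
#' plateau and shaft, femoral condylar bands, shaft tube and trochlear
#' groove, and the patellar ellipsoid, posed according to `params`
#' (defaults: the group motion model's row for the condition).
#'
#' @param shape a [knee_shape_params()] record.
#' @param motion a [default_motion_model()] data.frame (or compatible).
#' @param flexion flexion label: 0, 30 or 90 (degrees).
#' @param muscle `"relaxed"` or `"active"`.
#' @param params optional named list overriding the motion-model row
#'   (`ap_medial`, `ap_lateral`, `height`, `pf_angle`, `tilt`, `shift`).
#' @param subject,group identifiers stored with the scene.
#' @return object of class `knee_scene`: named `meshes`, `hints`,
#'   condition metadata and the `ground_truth` record.
#' @export
generate_knee <- function(shape = knee_shape_params(),
                          motion = default_motion_model("healthy"),
                          flexion = 0, muscle = c("relaxed", "active"),
                          params = NULL, subject = "S01",
                          group = attr(motion, "group") %||% "healthy") {
  muscle <- match.arg(muscle)
  if (!flexion %in% c(0, 30, 90))
    stop("inconsistent condition keys: flexion must be 0, 30 or 90",
         call. = FALSE)
  if (is.null(params)) {
    row <- motion[motion$flexion == flexion & motion$muscle == muscle, ]
    if (nrow(row) != 1L)
      stop("inconsistent condition keys: no unique motion-model row",
           call. = FALSE)
    params <- as.list(row[c("ap_medial", "ap_lateral", "height",
                            "pf_angle", "tilt", "shift")])
  }
  pl <- knee_placement(shape, params, flexion)
  hw <- shape$condyle_halfwidth
  meshes <- list(
    tibia_plateau = mesh_ellipse_disk(shape$plateau_a, shape$plateau_b,
                                      tag = "tibia_plateau"),
    tibia = mesh_tube(c(0, 0, -shape$tibia_length), c(0, 0, -1),
                      0.8 * shape$plateau_b, tag = "tibia"),
    condyle_medial = mesh_cyl_band(pl$P_m, pl$u, shape$condyle_radius,
                                   c(-hw, hw), c(-40, 80),
                                   pl$n_post, pl$n_inf, tag = "condyle_medial"),
    condyle_lateral = mesh_cyl_band(pl$P_l, pl$u, shape$condyle_radius,
                                    c(-hw, hw), c(-40, 80),
                                    pl$n_post, pl$n_inf, tag = "condyle_lateral"),
    femur_shaft = mesh_tube(pl$shaft_p0, pl$shaft_p1, shape$shaft_radius,
                            tag = "femur_shaft"),
    trochlea = mesh_groove(pl$groove_f0, pl$Py, pl$groove_e1, pl$groove_e3,
                           shape$trochlea_halfwidth, shape$trochlea_opening,
                           shape$trochlea_length, tag = "trochlea"),
    patella = mesh_ellipsoid(pl$C, shape$patella_semiaxes,
                             axes = cbind(pl$Px, pl$Py, pl$Pz),
                             tag = "patella"))
  gt <- list(ap_medial = params$ap_medial, ap_lateral = params$ap_lateral,
             ap_central = (params$ap_medial + params$ap_lateral) / 2,
             rotation = rad2deg(pl$rho),
             height = params$height, pf_angle = params$pf_angle,
             tilt = params$tilt, shift = params$shift)
  structure(list(meshes = meshes,
                 hints = orientation_hints(proximal = c(0, 0, 1),
                                           lateral = c(1, 0, 0),
                                           femur_proximal = pl$F_dir,
                                           superior = c(0, 0, 1)),
                 subject = subject, group = group,
                 flexion = flexion, muscle = muscle,
                 ground_truth = gt, shape = shape, params = params),
            class = "knee_scene")
}

#' Apply a rigid transform to a whole scene
#'
#' Transforms every mesh and every orientation hint; ground truth is
#' unchanged because the measured parameters are invariant under a common
#' rigid motion of all structures.
#'
#' @param scene a `knee_scene`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return the transformed `knee_scene`.
#' @export
transform_scene <- function(scene, rotation = diag(3), translation = c(0, 0, 0)) {
  scene$meshes <- lapply(scene$meshes, transform_mesh, rotation = rotation,
                         translation = translation)
  for (h in names(scene$hints))
    scene$hints[[h]] <- as.numeric(rotation %*% scene$hints[[h]])
  scene
}

#' Voxelize a synthetic knee into a label volume
#'
#' Analytic voxelization from the implicit solids of the generator (not
#' from the meshes): bone labels are solid regions, articular-surface
#' labels are thin shells of `shell_mm` total thickness around the exact
#' parametric surfaces.
#'
#' @param scene a `knee_scene` (from [generate_knee()]).
#' @param spacing voxel spacing in mm (default: the shape's `voxel_spacing`).
#' @param shell_mm articular-shell thickness (mm).
#' @param margin_mm padding around the scene bounding box (mm).
#' @return a `label_volume`.
#' @export
voxelize_knee <- function(scene, spacing = NULL, shell_mm = 2, margin_mm = 3) {
  shape <- scene$shape
  spacing <- spacing %||% shape$voxel_spacing
  pl <- knee_placement(shape, scene$params, scene$flexion)
  bb <- apply(do.call(rbind, lapply(scene$meshes, `[[`, "vertices")), 2, range)
  lo <- floor(bb[1, ] - margin_mm); hi <- ceiling(bb[2, ] + margin_mm)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + spacing * (seq_len(dims[1]) - 1L)
  gy <- lo[2] + spacing * (seq_len(dims[2]) - 1L)
  gz <- lo[3] + spacing * (seq_len(dims[3]) - 1L)
  X <- array(rep(gx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(gy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(gz, each = dims[1] * dims[2]), dims)
  dotv <- function(v) X * v[1] + Y * v[2] + Z * v[3]
  half <- shell_mm / 2
  lab <- array(0L, dims)
  # femur: condylar cylinder solid + shaft solid
  qs <- dotv(pl$u) - sum(pl$A * pl$u)
  rad2 <- (X - pl$A[1])^2 + (Y - pl$A[2])^2 + (Z - pl$A[3])^2 - qs^2
  hw_c <- shape$condyle_offset + shape$condyle_halfwidth
  lab[rad2 <= shape$condyle_radius^2 & abs(qs) <= hw_c] <- 1L
  su <- unitize(pl$shaft_p1 - pl$shaft_p0)
  ss <- dotv(su) - sum(pl$shaft_p0 * su)
  sr2 <- (X - pl$shaft_p0[1])^2 + (Y - pl$shaft_p0[2])^2 + (Z - pl$shaft_p0[3])^2 - ss^2
  in_shaft <- sr2 <= shape$shaft_radius^2 & ss >= 0 & ss <= shape$shaft_length
  lab[in_shaft] <- 1L
  # tibia solid below the plateau
  lab[(X / shape$plateau_a)^2 + (Y / shape$plateau_b)^2 <= 1 &
        Z >= -shape$tibia_length & Z <= -half] <- 2L
  # femoral shaft marker label: a proximal segment of the shaft, kept well
  # clear of the patella and trochlea so overlapping labels cannot bite it
  lab[in_shaft & ss >= 40] <- 6L
  # articular shells override bone labels
  lab[(X / shape$plateau_a)^2 + (Y / shape$plateau_b)^2 <= 1 & abs(Z) <= half] <- 4L
  tl <- dotv(pl$Py) - sum(pl$groove_f0 * pl$Py)
  tt <- dotv(pl$groove_e1) - sum(pl$groove_f0 * pl$groove_e1)
  td <- dotv(pl$groove_e3) - sum(pl$groove_f0 * pl$groove_e3)
  tanw <- tan(deg2rad(shape$trochlea_opening))
  lab[abs(td - abs(tt) * tanw) * cos(deg2rad(shape$trochlea_opening)) <= half &
        abs(tt) <= shape$trochlea_halfwidth &
        abs(tl) <= shape$trochlea_length / 2] <- 5L
  # condylar posterior bands (medial 7, lateral 8)
  rads <- sqrt(pmax(rad2, 0))
  phi <- atan2(dotv(pl$n_inf) - sum(pl$A * pl$n_inf),
               dotv(pl$n_post) - sum(pl$A * pl$n_post))
  in_band <- abs(rads - shape$condyle_radius) <= half &
    phi >= deg2rad(-40) & phi <= deg2rad(80)
  lab[in_band & abs(qs + shape$condyle_offset) <= shape$condyle_halfwidth] <- 7L
  lab[in_band & abs(qs - shape$condyle_offset) <= shape$condyle_halfwidth] <- 8L
  # patella last: the patellar body must never be carved by an overlapping
  # articular shell (the trochlear facets may pass through its margins)
  px <- dotv(pl$Px) - sum(pl$C * pl$Px)
  py <- dotv(pl$Py) - sum(pl$C * pl$Py)
  pz <- dotv(pl$Pz) - sum(pl$C * pl$Pz)
  sa <- shape$patella_semiaxes
  lab[(px / sa[1])^2 + (py / sa[2])^2 + (pz / sa[3])^2 <= 1] <- 3L
  label_volume(lab, spacing = rep(spacing, 3), origin = lo)
}

#' Cohort specification calibrated to the study groups
#'
#' @param group `"healthy"` (default n = 20) or `"pcl"` (default n = 12).
#' @param n number of subjects (>= 2).
#' @param motion mean structure, a [default_motion_model()] data.frame.
#' @param calibration per-condition SDs of the patellofemoral parameters
#'   (defaults: [pf_calibration()] for the group).
#' @param tf_sd between-subject SD of the condylar AP positions (mm).
#' @param subject_sd SD of a subject-level intercept shared across a
#'   subject's conditions (applied to every parameter, default 0).
#' @param seed RNG seed for [sample_cohort()].
#' @param shape a [knee_shape_params()] record.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("healthy", "pcl"),
                        n = NULL, motion = NULL, calibration = NULL,
                        tf_sd = 1.5, subject_sd = 0, seed = 1L,
                        shape = knee_shape_params()) {
  group <- match.arg(group)
  n <- n %||% if (group == "healthy") 20L else 12L
  if (n < 2L) stop("cohort needs n >= 2 subjects", call. = FALSE)
  calibration <- calibration %||% pf_calibration(group)
  if (any(unlist(calibration[grep("_sd$", names(calibration))]) < 0) ||
      tf_sd < 0 || subject_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(group = group, n = as.integer(n),
                 motion = motion %||% default_motion_model(group),
                 calibration = calibration, tf_sd = tf_sd,
                 subject_sd = subject_sd, seed = as.integer(seed),
                 shape = shape),
            class = "cohort_spec")
}

#' Sample a synthetic cohort
#'
#' Draws per-subject, per-condition kinematic parameters from normal
#' distributions centred on the motion model with the calibration SDs
#' (patellofemoral parameters) and `tf_sd` (condylar AP positions), in a
#' fixed order under the spec's seed so results are bit-reproducible.
#' Scenes are not built here; use [cohort_scene()] or [measure_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return object of class `knee_cohort`: the spec and a `params`
#'   data.frame (one row per subject x condition) holding the ground truth.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  mm <- spec$motion
  cal <- spec$calibration
  rows <- list()
  pf <- c("height", "pf_angle", "tilt", "shift")
  for (i in seq_len(spec$n)) {
    icpt <- stats::rnorm(6, 0, spec$subject_sd)
    names(icpt) <- c("ap_medial", "ap_lateral", pf)
    for (r in seq_len(nrow(mm))) {
      cr <- cal[cal$flexion == mm$flexion[r] & cal$muscle == mm$muscle[r], ]
      ap_m <- stats::rnorm(1, mm$ap_medial[r], spec$tf_sd) + icpt["ap_medial"]
      ap_l <- stats::rnorm(1, mm$ap_lateral[r], spec$tf_sd) + icpt["ap_lateral"]
      vals <- vapply(pf, function(p)
        stats::rnorm(1, mm[[p]][r], cr[[paste0(p, "_sd")]]) + icpt[p], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s%02d", toupper(substr(spec$group, 1, 1)), i),
        group = spec$group, flexion = mm$flexion[r], muscle = mm$muscle[r],
        ap_medial = ap_m, ap_lateral = ap_l,
        ap_central = (ap_m + ap_l) / 2,
        rotation = derived_rotation(ap_m, ap_l, spec$shape$condyle_offset),
        height = vals["height"], pf_angle = vals["pf_angle"],
        tilt = vals["tilt"], shift = vals["shift"])
    }
  }
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  structure(list(spec = spec, params = params), class = "knee_cohort")
}

#' Build the scene for one cohort row
#'
#' @param cohort a `knee_cohort`.
#' @param row row index into `cohort$params`.
#' @return a `knee_scene`.
#' @export
cohort_scene <- function(cohort, row) {
  p <- cohort$params[row, ]
  generate_knee(shape = cohort$spec$shape,
                flexion = p$flexion, muscle = p$muscle,
                params = list(ap_medial = p$ap_medial, ap_lateral = p$ap_lateral,
                              height = p$height, pf_angle = p$pf_angle,
                              tilt = p$tilt, shift = p$shift),
                subject = p$subject, group = p$group)
}

#' Loading torque of the muscle-activity protocol
#'
#' Torque produced by hanging a mass on a lever: `mass * g * lever`. With
#' the study's 3 kg at 0.35 m this is 10.3 Nm, i.e. the nominal 10 Nm
#' extending torque that elicits isometric flexor activity.
#'
#' @param mass_kg applied mass (kg), > 0.
#' @param lever_m lever arm (m), > 0.
#' @param g gravitational acceleration (m/s^2).
#' @return torque in Nm.
#' @export
loading_torque <- function(mass_kg = 3, lever_m = 0.35, g = 9.81) {
  if (any(c(mass_kg, lever_m, g) <= 0) || any(!is.finite(c(mass_kg, lever_m, g))))
    stop("mass, lever and g must be positive", call. = FALSE)
  mass_kg * g * lever_m
}
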