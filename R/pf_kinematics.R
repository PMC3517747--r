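# Patellofemoral measurements: the patella-based coordinate system (PBCS)
# and the four parameters reported per condition — patellar height,
# patellofemoral angle, patellar tilt and patellar shift.
#
# PBCS convention: origin C at the patellar volume centroid, Px lateral +,
# Py superior + (long axis), Pz anterior +, right-handed (Px x Py = Pz).
# The PBCS transverse plane is Px-Pz.

#' Build the patella-based coordinate system
#'
#' C is the centroid of the volume enclosed by the (closed) patellar mesh,
#' computed by the divergence theorem so it is robust to non-uniform
#' meshing. Py is the first principal direction of the vertices (sign
#' towards `hints$superior`), Px the second (sign towards `hints$lateral`)
#' and Pz completes the right-handed frame. The inferior patellar pole IPP
#' is the mesh vertex minimizing the Py coordinate.
#'
#' @param patella closed `surface_mesh` of the patella.
#' @param hints an [orientation_hints()] record.
#' @param tie_tol relative eigenvalue gap below which the principal
#'   directions are declared degenerate.
#' @return a `patellar_frame` (subclass of `anat_frame`) with extra fields
#'   `ipp` (mm) and `volume` (mm^3).
#' @export
build_patellar_frame <- function(patella, hints = orientation_hints(),
                                 tie_tol = 0.02) {
  vc <- mesh_volume_centroid(patella)
  v <- patella$vertices
  eg <- solid_principal_axes(patella, fallback = FALSE)
  lam <- eg$values
  if ((lam[1] - lam[2]) / lam[1] < tie_tol ||
      (lam[2] - lam[3]) / max(lam[2], 1e-12) < tie_tol)
    stop("degenerate principal directions of the patella", call. = FALSE)
  Py <- eg$vectors[, 1]
  if (sum(Py * hints$superior) < 0) Py <- -Py
  Px <- eg$vectors[, 2]
  if (sum(Px * hints$lateral) < 0) Px <- -Px
  Pz <- cross3(Px, Py)
  fr <- anat_frame(vc$centroid, rbind(Px, Py, Pz), class = "patellar_frame")
  s <- as.numeric(v %*% Py)
  fr$ipp <- v[which.min(s), ]
  fr$volume <- vc$volume
  fr
}

#' Patellar height
#'
#' Euclidean distance from the inferior patellar pole to the line through
#' the tibial frame origin along the tibial medio-lateral axis.
#'
#' @param frame a `patellar_frame`.
#' @param tibial a `tibial_frame`.
#' @return height in mm (non-negative).
#' @export
patellar_height <- function(frame, tibial) {
  w <- frame$ipp - tibial$origin
  x <- tibial$axes["x", ]
  vec_norm(w - sum(w * x) * x)
}

#' Patellofemoral angle
#'
#' Angle between the patellar long axis Py and the femoral longitudinal
#' axis, in [0, 180] degrees; with both axes oriented proximally/superiorly
#' it increases with knee flexion.
#'
#' @param frame a `patellar_frame`.
#' @param femoral_axis a `femoral_long_axis` (or unit 3-vector).
#' @return angle in degrees.
#' @export
patellofemoral_angle <- function(frame, femoral_axis) {
  f <- if (inherits(femoral_axis, "femoral_long_axis"))
    femoral_axis$direction else unitize(femoral_axis)
  d <- sum(frame$axes["y", ] * f)
  rad2deg(acos(max(-1, min(1, d))))
}

#' Trochlear-groove landmarks in the PBCS
#'
#' The trochlear vertices are expressed in the patella-based system. The
#' sulcus-floor curve is the per-slab (along Py) posterior-most vertex of
#' the groove; its median medio-lateral position anchors a groove midplane
#' parallel to the PBCS y-z plane. Facet vertices medial/lateral of that
#' midplane give `pmin1` (medial) and `pmin2` (lateral) as the per-facet
#' vertices closest to the midplane (ties broken by proximity to the
#' patellar equator), and `pmax` is the sulcus-floor vertex farthest from
#' the PBCS y-z plane (x = 0), which carries the medio-lateral offset of
#' the groove relative to the patellar centre.
#'
#' @param trochlea `surface_mesh` of the trochlear articular surface.
#' @param frame a `patellar_frame`.
#' @param slab_mm slab width along Py for the sulcus-floor search (mm).
#' @param band_mm two-sided medio-lateral band (mm, distances from the
#'   groove midplane) of facet surface used for the trochlear reference
#'   direction; the default keeps clear of the groove crease and the facet
#'   rims.
#' @return object of class `trochlear_landmarks`: world-space `pmin1`,
#'   `pmin2`, `pmax` (all vertices of the input mesh), the local midplane
#'   offset `x0`, the sulcus-floor vertex indices, and `ref_dir_local`, the
#'   unit trochlear reference direction (medial to lateral) in the PBCS
#'   transverse plane.
#' @export
trochlear_landmarks <- function(trochlea, frame, slab_mm = 2.5,
                                band_mm = c(3, 7)) {
  v <- trochlea$vertices
  if (nrow(v) < 3L) stop("trochlear mesh too small", call. = FALSE)
  loc <- express_in_frame(v, frame)
  # dislocation guard: the patellar midplane must lie over (or near) the
  # trochlear surface for the groove landmarks to be meaningful
  xspan <- range(loc[, 1])
  xhalf <- diff(xspan) / 2
  if (xspan[1] > xhalf || xspan[2] < -xhalf)
    stop("one trochlear facet is empty: patella dislocated beyond the trochlea",
         call. = FALSE)
  slab <- floor(round((loc[, 2] - min(loc[, 2])) / slab_mm, 9))
  slabs <- split(seq_len(nrow(v)), slab)
  # Floor curve and groove orientation are solved together: in the frame
  # rotated by the groove tilt, the sulcus floor is the per-slab posterior
  # extreme and the facets are symmetric about it. A coarse search over
  # candidate rotations picks the one whose floor curve is most tightly
  # clustered medio-laterally (the crease is a straight line), and the
  # estimate is then refined from the facet slopes. This stays well-posed
  # when the tilt approaches the facet opening angle, where a fixed
  # posterior direction would slide the floor search up a facet.
  floor_at <- function(tau) {
    ct <- cos(tau); st <- sin(tau)
    zr <- loc[, 3] * ct - loc[, 1] * st
    fi <- vapply(slabs, function(ii) ii[which.min(zr[ii])], integer(1))
    zf <- zr[fi]
    fi <- fi[zf <= stats::median(zf) + 2]
    list(idx = unname(fi), xr_all = loc[, 1] * ct + loc[, 3] * st)
  }
  cand <- deg2rad(seq(-40, 40, by = 5))
  score <- vapply(cand, function(tau) {
    fl <- floor_at(tau)
    xf <- fl$xr_all[fl$idx]
    # the true crease is straight (small medio-lateral spread), posterior,
    # and has facet surface rising on BOTH sides; a facet rim line can be
    # straight and even posterior-most at extreme tilt, but is one-sided
    xr <- fl$xr_all - stats::median(xf)
    excl <- max(abs(xr[fl$idx])) + 1e-9
    frac <- min(sum(xr < -excl), sum(xr > excl)) / length(xr)
    if (frac < 0.05) return(Inf)
    mean(loc[fl$idx, 3]) + stats::mad(xf, constant = 1) + 1e-3 * abs(tau)
  }, 0)
  if (!any(is.finite(score)))
    stop("one trochlear facet is empty: patella dislocated beyond the trochlea",
         call. = FALSE)
  tau <- cand[which.min(score)]
  # binned midsurface profile of one facet arm -> arm angle relative to the
  # rotated frame. Binning removes surface-sampling density and
  # shell-thickness artifacts of voxel-derived meshes; on clean meshes the
  # bin points lie exactly on the facet lines.
  arm_angle <- function(side, xr, zr) {
    sel <- side[abs(xr[side]) >= band_mm[1] & abs(xr[side]) <= band_mm[2]]
    if (length(sel) < 2L) sel <- side[order(abs(xr[side]))[1:2]]
    bin <- floor(xr[sel])
    bx <- tapply(xr[sel], bin, mean)
    bz <- tapply(zr[sel], bin, mean)
    if (length(bx) < 2L) {
      d <- eigen(stats::cov(cbind(xr[sel], zr[sel])), symmetric = TRUE)$vectors[, 1]
      return(atan(d[2] / d[1]))
    }
    atan(stats::cov(bx, bz) / stats::var(bx))
  }
  fl <- NULL; med <- lat <- integer(0); x0 <- 0
  for (iter in 1:3) {
    fl <- floor_at(tau)
    ct <- cos(tau); st <- sin(tau)
    xrot <- fl$xr_all
    zrot <- loc[, 3] * ct - loc[, 1] * st
    x0 <- stats::median(xrot[fl$idx])
    xr <- xrot - x0
    excl <- max(abs(xr[fl$idx])) + 1e-9
    med <- which(xr < -excl)
    lat <- which(xr > excl)
    if (length(med) == 0L || length(lat) == 0L)
      stop("one trochlear facet is empty: patella dislocated beyond the trochlea",
           call. = FALSE)
    tau <- tau + (arm_angle(lat, xr, zrot) + arm_angle(med, xr, zrot)) / 2
  }
  ct <- cos(tau); st <- sin(tau)
  xr <- loc[, 1] * ct + loc[, 3] * st - x0
  pick <- function(side) {
    ax <- abs(xr[side])
    cand <- side[ax < min(ax) + 1e-9]
    cand[which.min(abs(loc[cand, 2] - stats::median(loc[, 2])))]
  }
  i1 <- pick(med); i2 <- pick(lat)
  imax <- fl$idx[which.max(abs(loc[fl$idx, 1]))]
  structure(list(pmin1 = v[i1, ], pmin2 = v[i2, ], pmax = v[imax, ],
                 x0 = x0, floor_idx = fl$idx,
                 ref_dir_local = c(cos(tau), sin(tau))),
            class = "trochlear_landmarks")
}

#' Patellar tilt
#'
#' Signed angle, in the PBCS transverse plane, between the trochlear
#' reference line (through the facet points adjacent to the groove midplane,
#' oriented medial to lateral) and the patellar medio-lateral axis Px.
#' Positive when the angle opens to the medial side (the patellar lateral
#' edge rotated posteriorly relative to the trochlear line).
#'
#' @param lm a `trochlear_landmarks` record.
#' @param frame a `patellar_frame`; must be the frame the landmarks were
#'   computed in.
#' @return tilt angle in degrees.
#' @export
patellar_tilt <- function(lm, frame) {
  if (vec_norm(lm$pmin2 - lm$pmin1) < 1e-9)
    stop("coincident trochlear landmarks", call. = FALSE)
  d <- lm$ref_dir_local
  if (vec_norm(d) < 1e-12)
    stop("trochlear reference line is orthogonal to the transverse plane",
         call. = FALSE)
  rad2deg(atan2(d[2], d[1]))
}

#' Patellar shift
#'
#' Medio-lateral displacement of the patellar centre relative to the
#' deepest trochlear-groove reference point, projected on the tibial
#' medio-lateral axis; lateral positive.
#'
#' @param frame a `patellar_frame`.
#' @param lm a `trochlear_landmarks` record.
#' @param tibial a `tibial_frame`.
#' @return shift in mm (lateral +).
#' @export
patellar_shift <- function(frame, lm, tibial) {
  sum((frame$origin - lm$pmax) * tibial$axes["x", ])
}
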