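# Tibia-based anatomical coordinate system.
#
# The tibial frame is the reference for every tibiofemoral measurement:
# origin at the area-centroid of the tibial-plateau articular surface,
# x pointing lateral, y anterior, z proximal (right-handed). Axes come from
# a principal-component decomposition of the plateau vertices: the
# smallest-variance direction is the plateau normal (z), the largest
# in-plane spread is medio-lateral (x); signs are disambiguated by rough
# world-space direction hints, which any scan orientation provides.

#' Orientation hints for frame construction
#'
#' Rough world-space directions used only to fix axis signs (and to break
#' near-circular-plateau ties); they need not be accurate beyond a
#' hemisphere.
#'
#' @param proximal approximate proximal (up-the-tibia) direction.
#' @param lateral approximate lateral direction.
#' @param femur_proximal approximate direction of the femoral shaft
#'   (towards the hip); used by [femoral_long_axis()].
#' @param superior approximate superior direction of the patellar long axis;
#'   defaults to `proximal`.
#' @return list of unit hint vectors, class `orientation_hints`.
#' @export
orientation_hints <- function(proximal = c(0, 0, 1), lateral = c(1, 0, 0),
                              femur_proximal = proximal, superior = proximal) {
  h <- list(proximal = unitize(proximal), lateral = unitize(lateral),
            femur_proximal = unitize(femur_proximal), superior = unitize(superior))
  if (abs(sum(h$proximal * h$lateral)) > 0.99)
    stop("contradictory hints: proximal and lateral are (anti)parallel",
         call. = FALSE)
  structure(h, class = "orientation_hints")
}

#' Area-weighted centroid of a surface mesh
#'
#' Area-weighted mean of triangle centroids; this is the "area-centroid"
#' used as the tibial frame origin.
#'
#' @param surface a `surface_mesh` with positive total area.
#' @return length-3 point (mm).
#' @export
area_centroid <- function(surface) {
  ar <- triangle_areas(surface)
  tot <- sum(ar)
  if (!is.finite(tot) || tot <= 0)
    stop("mesh has zero total area", call. = FALSE)
  tc <- triangle_corners(surface)
  ctr <- (tc$a + tc$b + tc$c) / 3
  colSums(ctr * ar) / tot
}

# Internal constructor for an orthonormal anatomical frame.
# axes: 3x3 matrix with rows x, y, z (unit, right-handed).
anat_frame <- function(origin, axes, class = "anat_frame") {
  axes <- as.matrix(axes)
  rownames(axes) <- c("x", "y", "z")
  G <- axes %*% t(axes)
  if (max(abs(G - diag(3))) > 1e-9)
    stop("frame axes are not orthonormal", call. = FALSE)
  if (max(abs(cross3(axes[1, ], axes[2, ]) - axes[3, ])) > 1e-9)
    stop("frame is not right-handed (x cross y != z)", call. = FALSE)
  structure(list(origin = as.numeric(origin), axes = axes),
            class = unique(c(class, "anat_frame")))
}

#' @export
print.anat_frame <- function(x, ...) {
  cat(sprintf("%s\n  origin: %s mm\n", class(x)[1],
              paste(sprintf("%.3f", x$origin), collapse = ", ")))
  for (r in rownames(x$axes))
    cat(sprintf("  %s: %s\n", r,
                paste(sprintf("%+.6f", x$axes[r, ]), collapse = " ")))
  invisible(x)
}

#' Build the tibia-based coordinate system from the plateau surface
#'
#' Origin = [area_centroid()] of the plateau; z = plateau normal (smallest
#' principal component, sign towards `hints$proximal`); x = largest in-plane
#' vertex spread (sign towards `hints$lateral`); y completes the
#' right-handed frame and points anterior. For near-circular plateaus
#' (in-plane eigenvalues within `tie_tol` relative difference) the
#' medio-lateral axis falls back to the hint's lateral direction projected
#' into the plateau plane, so repeated acquisitions of one subject cannot
#' flip axes.
#'
#' @param plateau `surface_mesh` of the tibial-plateau articular surface
#'   (>= 10 vertices spanning 3D).
#' @param hints an [orientation_hints()] record.
#' @param tie_tol relative in-plane eigenvalue gap below which the lateral
#'   hint fallback is used.
#' @return a `tibial_frame` (subclass of `anat_frame`).
#' @export
build_tibial_frame <- function(plateau, hints = orientation_hints(),
                               tie_tol = 0.05) {
  v <- plateau$vertices
  if (nrow(v) < 10L) stop("plateau mesh must have >= 10 vertices", call. = FALSE)
  origin <- area_centroid(plateau)
  eg <- mesh_principal_axes(plateau)   # values descending
  if (eg$values[2] < 1e-9 * eg$values[1])
    stop("degenerate plateau: vertices are collinear", call. = FALSE)
  z <- eg$vectors[, 3]
  if (sum(z * hints$proximal) < 0) z <- -z
  lam <- eg$values
  if ((lam[1] - lam[2]) / lam[1] < tie_tol) {
    x <- hints$lateral - sum(hints$lateral * z) * z
    if (vec_norm(x) < 1e-6)
      stop("contradictory hints: lateral direction is normal to the plateau",
           call. = FALSE)
    x <- unitize(x)
  } else {
    x <- eg$vectors[, 1]
    x <- unitize(x - sum(x * z) * z)   # exact in-plane
    if (sum(x * hints$lateral) < 0) x <- -x
  }
  y <- cross3(z, x)
  anat_frame(origin, rbind(x, y, z), class = "tibial_frame")
}

#' Serialize a frame as a structured text record
#'
#' @param frame an `anat_frame`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  lines <- c(paste("class:", class(frame)[1]),
             paste("origin_mm:", paste(sprintf("%.12g", frame$origin), collapse = " ")),
             sprintf("axis_%s: %s", rownames(frame$axes),
                     apply(frame$axes, 1, function(r)
                       paste(sprintf("%.12g", r), collapse = " "))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a frame record written by [write_frame()]
#' @param path text file path.
#' @return an `anat_frame`.
#' @export
read_frame <- function(path) {
  ln <- readLines(path)
  get <- function(key) {
    hit <- grep(paste0("^", key, ":"), ln, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub("^[^:]+:", "", hit)), "\\s+")[[1]])
  }
  cls <- trimws(sub("^class:", "", grep("^class:", ln, value = TRUE)[1]))
  anat_frame(get("origin_mm"),
             rbind(get("axis_x"), get("axis_y"), get("axis_z")), class = cls)
}
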