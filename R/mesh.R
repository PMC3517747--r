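# Triangulated surface container and mesh utilities.
#
# A surface_mesh is the common currency of the measurement pipeline: every
# anatomical structure (tibial plateau, condylar facets, patella, ...) is a
# triangle mesh in world millimetres, either built parametrically by the
# synthetic generator or extracted from a segmented label volume.

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param tag optional character tag naming the structure.
#' @param clean drop zero-area (degenerate) triangles after validation.
#' @return object of class `surface_mesh` with elements `vertices`, `faces`,
#'   `tag`.
#' @export
surface_mesh <- function(vertices, faces, tag = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  m <- structure(list(vertices = vertices, faces = faces,
                      tag = tag), class = "surface_mesh")
  if (clean) m <- drop_degenerate_faces(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh%s: %d vertices, %d faces, area %.2f mm^2\n",
              if (is.null(x$tag)) "" else paste0(" [", x$tag, "]"),
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

# Per-triangle corner coordinate matrices (list of three m x 3 matrices).
triangle_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Per-triangle areas of a mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  tc <- triangle_corners(mesh)
  u <- tc$b - tc$a
  v <- tc$c - tc$a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @inheritParams triangle_areas
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

# Remove triangles whose area is (numerically) zero.
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  keep <- triangle_areas(mesh) > tol
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

# Merge vertices closer than `tol` (on a rounded-coordinate key) and reindex
# faces. Needed after isosurface extraction, where cell-local triangles
# duplicate shared edge vertices.
weld_vertices <- function(mesh, tol = 1e-7) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  mesh$vertices <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  # drop faces collapsed by welding
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  mesh$faces <- f[ok, , drop = FALSE]
  storage.mode(mesh$faces) <- "integer"
  drop_degenerate_faces(mesh)
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param rotation 3x3 matrix applied to vertex coordinates.
#' @param translation length-3 offset added after rotation (mm).
#' @return transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2, -translation)
  mesh
}

#' Euler characteristic of a mesh
#'
#' V - E + F on the welded mesh; 2 for a closed surface of genus 0.
#'
#' @inheritParams triangle_areas
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  mesh <- weld_vertices(mesh)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

# Area-weighted principal axes of a surface.
#
# Covariance of triangle centroids weighted by triangle area, approximating
# the continuous surface integral. Preferred over vertex PCA because vertex
# density on extracted isosurfaces depends on local surface orientation,
# which biases unweighted eigenvectors.
mesh_principal_axes <- function(mesh) {
  ar <- triangle_areas(mesh)
  tot <- sum(ar)
  if (tot <= 0) stop("mesh has zero total area", call. = FALSE)
  tc <- triangle_corners(mesh)
  ctr <- (tc$a + tc$b + tc$c) / 3
  mu <- colSums(ctr * ar) / tot
  cc <- sweep(ctr, 2, mu)
  cv <- crossprod(cc * ar, cc) / tot
  eg <- eigen(cv, symmetric = TRUE)
  list(center = mu, values = eg$values, vectors = eg$vectors)
}

# Principal axes of the enclosed solid: eigen-decomposition of the central
# second-moment tensor of the volume bounded by a closed mesh, accumulated
# per origin-tetrahedron by the divergence theorem. For extracted
# isosurfaces this is markedly more stable than surface moments because
# signed contributions of surface staircase cancel. Falls back to
# mesh_principal_axes() for open meshes when `fallback` is TRUE.
solid_principal_axes <- function(mesh, fallback = TRUE) {
  closed <- tryCatch(abs(euler_characteristic(mesh)) == 2,
                     error = function(e) FALSE)
  if (!closed) {
    if (fallback) return(mesh_principal_axes(mesh))
    stop("solid principal axes require a closed mesh", call. = FALSE)
  }
  tc <- triangle_corners(mesh)
  a <- tc$a; b <- tc$b; cc <- tc$c
  v6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(v6) / 6
  if (abs(vol) < 1e-9) stop("mesh encloses no volume", call. = FALSE)
  mu <- colSums((a + b + cc) / 4 * v6 / 6) / vol
  s <- a + b + cc
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    mij <- sum((a[, i] * a[, j] + b[, i] * b[, j] + cc[, i] * cc[, j] +
                  s[, i] * s[, j]) * v6 / 120)
    M[i, j] <- M[j, i] <- mij
  }
  M <- (M - vol * outer(mu, mu)) / vol
  eg <- eigen(M, symmetric = TRUE)
  list(center = mu, values = eg$values, vectors = eg$vectors)
}

#' Signed enclosed volume and volume centroid of a closed mesh
#'
#' Divergence-theorem accumulation over tetrahedra spanned by the origin and
#' each triangle. The result is orientation-independent up to a global sign,
#' which is removed.
#'
#' @inheritParams triangle_areas
#' @return list with `volume` (mm^3) and `centroid` (mm).
#' @export
mesh_volume_centroid <- function(mesh) {
  if (abs(euler_characteristic(mesh)) != 2)
    stop("volume centroid requires a closed (genus-0) mesh", call. = FALSE)
  tc <- triangle_corners(mesh)
  a <- tc$a; b <- tc$b; cc <- tc$c
  # signed tet volumes against origin
  v6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(v6) / 6
  if (abs(vol) < 1e-9) stop("mesh encloses no volume", call. = FALSE)
  centroid <- colSums((a + b + cc) / 4 * v6 / 6) / vol
  list(volume = abs(vol), centroid = centroid)
}
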