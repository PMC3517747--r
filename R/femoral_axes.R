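# Epicondylar axis from a least-squares cylinder fit to the posterior
# femoral condylar surfaces, plus the femoral shaft axis.
#
# The cylinder axis is the femoral reference axis of the pipeline: the
# medial and lateral condylar reference points are surface centroids
# projected onto it, and their midpoint is the central reference point.

#' Least-squares cylinder fit
#'
#' Fits an infinite cylinder minimizing the sum of squared differences
#' between point-to-axis distances and the radius. The axis direction is
#' parameterized as a smooth two-parameter perturbation of an initial
#' direction (from the principal components of the points, or from `init`),
#' the anchor as a 2D point in the plane orthogonal to the direction, and
#' the radius is profiled out analytically (for fixed axis the optimal
#' radius is the mean point-to-axis distance). The reduced 4-parameter
#' problem is solved with BFGS after an algebraic (Kasa) circle fit
#' provides the anchor start.
#'
#' @param points n x 3 matrix of surface points (mm), n >= 6, not coplanar.
#' @param init optional length-3 initial axis direction guess.
#' @param lateral_hint optional direction used to canonicalize the axis to
#'   point medial-to-lateral.
#' @return object of class `cylinder_fit`: `anchor` (point on axis, mm),
#'   `direction` (unit), `radius` (mm), `rms` (mm, RMS of the minimized
#'   residuals), `n` points used.
#' @export
fit_cylinder <- function(points, init = NULL, lateral_hint = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  n <- nrow(points)
  if (n < 6L) stop("insufficient points: cylinder fit needs >= 6", call. = FALSE)
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * eg$values[1])
    stop("degenerate points: collinear point set", call. = FALSE)
  if (eg$values[3] < 1e-10 * eg$values[1])
    stop("degenerate points: coplanar point set", call. = FALSE)
  d0 <- if (!is.null(init)) unitize(init) else eg$vectors[, 1]
  # fixed orthonormal complement of d0 (chart for direction and anchor)
  seed <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(seed - sum(seed * d0) * d0)
  e2 <- cross3(d0, e1)
  ctr <- colMeans(points)
  pc <- sweep(points, 2, ctr)
  axis_of <- function(par) unitize(d0 + par[1] * e1 + par[2] * e2)
  resid_of <- function(par) {
    u <- axis_of(par)
    f1 <- unitize(e1 - sum(e1 * u) * u)
    f2 <- cross3(u, f1)
    s <- pc %*% f1 - par[3]
    t <- pc %*% f2 - par[4]
    di <- sqrt(s^2 + t^2)
    di - mean(di)
  }
  obj <- function(par) sum(resid_of(par)^2)
  # Kasa algebraic circle fit in the initial projection plane
  s0 <- pc %*% e1; t0 <- pc %*% e2
  A <- cbind(2 * s0, 2 * t0, 1)
  ab <- tryCatch(solve(crossprod(A), crossprod(A, s0^2 + t0^2)),
                 error = function(e) matrix(c(0, 0, 0), 3))
  start <- c(0, 0, ab[1], ab[2])
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  if (fit$convergence != 0 && fit$value > 1e-8 * n)
    stop("cylinder fit did not converge", call. = FALSE)
  par <- fit$par
  u <- axis_of(par)
  f1 <- unitize(e1 - sum(e1 * u) * u)
  f2 <- cross3(u, f1)
  di <- sqrt((pc %*% f1 - par[3])^2 + (pc %*% f2 - par[4])^2)
  r <- mean(di)
  if (!is.null(lateral_hint) && sum(u * lateral_hint) < 0) u <- -u
  anchor <- ctr + par[3] * f1 + par[4] * f2
  structure(list(anchor = as.numeric(anchor), direction = as.numeric(u),
                 radius = r, rms = sqrt(mean((di - r)^2)), n = n),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder_fit: r = %.4f mm, rms = %.2e mm (n = %d)\n  axis (%s) through (%s)\n",
              x$radius, x$rms, x$n,
              paste(sprintf("%+.4f", x$direction), collapse = ", "),
              paste(sprintf("%.2f", x$anchor), collapse = ", ")))
  invisible(x)
}

# Orthogonal projection of points (rows) onto the cylinder axis.
project_on_axis <- function(cyl, p) {
  p <- rbind(p)
  s <- (p - matrix(cyl$anchor, nrow(p), 3, byrow = TRUE)) %*% cyl$direction
  sweep(outer(as.numeric(s), cyl$direction), 2, -cyl$anchor)
}

#' Medial, lateral and central femoral reference points
#'
#' The medial (lateral) reference point is the orthogonal projection of the
#' medial (lateral) condylar surface area-centroid onto the epicondylar
#' cylinder axis; the central point is their midpoint. All three are
#' collinear with the axis by construction.
#'
#' @param cyl a `cylinder_fit` for the epicondylar axis.
#' @param medial_surface,lateral_surface condylar `surface_mesh` objects.
#' @return object of class `femoral_reference_points` with `medial`,
#'   `lateral`, `central` points (mm) and the generating cylinder.
#' @export
condylar_reference_points <- function(cyl, medial_surface, lateral_surface) {
  for (m in list(medial_surface, lateral_surface))
    if (nrow(m$vertices) == 0L) stop("empty condylar surface", call. = FALSE)
  med <- project_on_axis(cyl, area_centroid(medial_surface))[1, ]
  lat <- project_on_axis(cyl, area_centroid(lateral_surface))[1, ]
  structure(list(medial = med, lateral = lat, central = (med + lat) / 2,
                 cylinder = cyl),
            class = "femoral_reference_points")
}

#' @export
print.femoral_reference_points <- function(x, ...) {
  for (nm in c("medial", "lateral", "central"))
    cat(sprintf("  %-7s (%s) mm\n", nm,
                paste(sprintf("%.2f", x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Longitudinal axis of the femoral shaft
#'
#' First principal direction of the shaft surface vertices; requires a
#' clearly elongated point cloud (largest principal extent at least twice
#' the second). The sign is chosen towards `hints$femur_proximal`.
#'
#' @param shaft `surface_mesh` of the femoral shaft.
#' @param hints an [orientation_hints()] record.
#' @return object of class `femoral_long_axis` with unit `direction`.
#' @export
femoral_long_axis <- function(shaft, hints = orientation_hints()) {
  v <- shaft$vertices
  eg <- solid_principal_axes(shaft)
  ext <- apply(v %*% eg$vectors, 2, function(s) diff(range(s)))
  if (ext[1] < 2 * ext[2])
    stop("shaft mesh is not elongated (extent ratio < 2)", call. = FALSE)
  u <- eg$vectors[, 1]
  if (sum(u * hints$femur_proximal) < 0) u <- -u
  structure(list(direction = as.numeric(u)), class = "femoral_long_axis")
}
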