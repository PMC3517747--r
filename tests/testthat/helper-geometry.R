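# Shared fixtures: all geometry is generated in code at test time.

# Voxelized solid sphere as a label volume.
sphere_volume <- function(r = 10, spacing = 1, label = 2L, pad = 3) {
  g <- seq(-(r + pad), r + pad, by = spacing)
  n <- length(g)
  arr <- array(0L, c(n, n, n))
  for (k in seq_len(n))
    arr[, , k] <- (outer(g^2, g^2, "+") + g[k]^2 <= r^2) * label
  label_volume(arr, spacing = rep(spacing, 3), origin = rep(g[1], 3))
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Flat unit-square plate meshed as two triangles in the z = 0 plane.
unit_square_plate <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# L-shaped plate: unit square plus a half-size square attached at +x.
l_shaped_plate <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(1.5, 0, 0), c(1.5, 0.5, 0), c(1, 0.5, 0))
  f <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L), c(2L, 5L, 6L), c(2L, 6L, 7L))
  surface_mesh(v, f)
}

# Exact points on a cylinder surface (no noise unless sigma > 0).
cylinder_points <- function(n = 200, r = 20, axis = c(1, 0, 0),
                            anchor = c(0, 0, 0), half_len = 30, sigma = 0) {
  u <- axis / sqrt(sum(axis^2))
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  s <- stats::runif(n, -half_len, half_len)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- outer(s, u) + r * (outer(cos(th), e1) + outer(sin(th), e2))
  pts <- sweep(pts, 2, -anchor)
  if (sigma > 0) pts <- pts + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
  pts
}

# Motion-model row as a parameter list, for overriding single parameters.
model_params <- function(group = "healthy", flexion = 0, muscle = "relaxed") {
  mm <- default_motion_model(group)
  as.list(mm[mm$flexion == flexion & mm$muscle == muscle,
             c("ap_medial", "ap_lateral", "height", "pf_angle", "tilt", "shift")])
}
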