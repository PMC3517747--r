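# Small linear-algebra helpers shared across the geometry modules.
# All coordinates are millimetres; all angle arguments are degrees unless
# a function name says otherwise.

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps * 100)
    stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: right-handed rotation by `angle_deg` degrees about the
#' (not necessarily unit) 3-vector `axis`.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Wrap an angle in degrees to (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Deterministic string hash (djb2), used for run manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
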