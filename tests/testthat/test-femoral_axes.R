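# Cylinder fit, condylar reference points, femoral long axis.

test_that("exact cylinder points are recovered to numerical tolerance", {
  set.seed(11)
  pts <- cylinder_points(200, r = 20, axis = c(1, 0, 0))
  fit <- fit_cylinder(pts)
  expect_lt(abs(fit$radius - 20), 1e-6)
  expect_lt(abs(abs(sum(fit$direction * c(1, 0, 0))) - 1), 1e-9)
  expect_lt(fit$rms, 1e-6)
})

test_that("recovery is exact for random axis orientations", {
  set.seed(12)
  for (rep in 1:20) {
    ax <- unitize_test <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    anchor <- stats::rnorm(3, 0, 15)
    pts <- cylinder_points(150, r = 12, axis = ax, anchor = anchor)
    fit <- fit_cylinder(pts)
    expect_lt(abs(fit$radius - 12), 1e-5)
    expect_lt(acos(min(1, abs(sum(fit$direction * ax)))) * 180 / pi, 1e-3)
  }
})

test_that("noisy cylinder fit agrees with a dense grid-search oracle", {
  set.seed(13)
  pts <- cylinder_points(200, r = 20, axis = c(1, 0, 0), sigma = 0.2)
  fit <- fit_cylinder(pts)
  expect_lt(abs(fit$radius - 20), 0.1)
  expect_lt(acos(min(1, abs(fit$direction[1]))) * 180 / pi, 0.5)
  # oracle: coarse-to-fine grid search over axis direction; for each
  # candidate, project points and fit a circle algebraically
  grid_obj <- function(u) {
    u <- u / sqrt(sum(u^2))
    seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- seed - sum(seed * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    s <- pts %*% e1; t <- pts %*% e2
    A <- cbind(2 * s, 2 * t, 1)
    ab <- solve(crossprod(A), crossprod(A, s^2 + t^2))
    di <- sqrt((s - ab[1])^2 + (t - ab[2])^2)
    c(sum((di - mean(di))^2), mean(di))
  }
  best <- c(Inf, NA); best_u <- NULL
  for (th in seq(-10, 10, by = 1)) for (ph in seq(-10, 10, by = 1)) {
    u <- c(cos(th * pi / 180) * cos(ph * pi / 180),
           sin(th * pi / 180), cos(th * pi / 180) * sin(ph * pi / 180))
    o <- grid_obj(u)
    if (o[1] < best[1]) { best <- o; best_u <- u }
  }
  expect_lt(acos(min(1, abs(sum(fit$direction * best_u)))) * 180 / pi, 1.5)
  expect_lt(abs(fit$radius - best[2]), 0.1)
})

test_that("cylinder fit rejects degenerate inputs", {
  expect_error(fit_cylinder(cylinder_points(5)), "insufficient")
  flat <- cbind(stats::runif(50), stats::runif(50), 0)
  expect_error(fit_cylinder(flat), "coplanar")
  line <- cbind(seq_len(20), 0, 0)
  expect_error(fit_cylinder(line), "collinear")
})

test_that("fit residual is invariant under rigid transformation", {
  set.seed(14)
  pts <- cylinder_points(150, r = 18, sigma = 0.3)
  f0 <- fit_cylinder(pts)
  for (rep in 1:3) {
    R <- random_rotation(); tr <- stats::rnorm(3, 0, 30)
    f1 <- fit_cylinder(sweep(pts %*% t(R), 2, -tr))
    expect_equal(f1$rms, f0$rms, tolerance = 1e-4)
    expect_equal(f1$radius, f0$radius, tolerance = 1e-4)
  }
})

test_that("condylar reference points are axis projections and midpoint", {
  sc <- generate_knee(flexion = 0)
  pts <- rbind(sc$meshes$condyle_medial$vertices,
               sc$meshes$condyle_lateral$vertices)
  cyl <- fit_cylinder(pts, lateral_hint = c(1, 0, 0))
  ref <- condylar_reference_points(cyl, sc$meshes$condyle_medial,
                                   sc$meshes$condyle_lateral)
  expect_equal(ref$central, (ref$medial + ref$lateral) / 2, tolerance = 1e-12)
  # brute-force projection oracle: minimise distance to the axis by 1D search
  for (nm in c("medial", "lateral")) {
    ctr <- area_centroid(sc$meshes[[paste0("condyle_", nm)]])
    sgrid <- seq(-80, 80, by = 1e-3)
    cand <- outer(sgrid, cyl$direction)
    cand <- sweep(cand, 2, -cyl$anchor)
    d2 <- rowSums(sweep(cand, 2, ctr)^2)
    expect_lt(sqrt(sum((ref[[nm]] - cand[which.min(d2), ])^2)), 5e-3)
  }
  # collinearity with the axis
  for (nm in c("medial", "lateral", "central")) {
    w <- ref[[nm]] - cyl$anchor
    perp <- w - sum(w * cyl$direction) * cyl$direction
    expect_lt(sqrt(sum(perp^2)), 1e-6)
  }
  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(condylar_reference_points(cyl, empty, sc$meshes$condyle_lateral),
               "empty")
})

test_that("mirror-symmetric condyles give a centred reference point", {
  sc <- generate_knee(flexion = 0,
                      params = list(ap_medial = 0, ap_lateral = 0, height = 16,
                                    pf_angle = 6, tilt = 0, shift = 0))
  rec <- measure_scene(sc)
  expect_lt(abs(rec$ap_central), 1e-9)
  expect_lt(abs(rec$rotation), 1e-9)
})

test_that("femoral long axis: canonical direction, equivariance, contract", {
  sc <- generate_knee(flexion = 0)
  fl <- femoral_long_axis(sc$meshes$femur_shaft, sc$hints)
  expect_equal(fl$direction, c(0, 0, 1), tolerance = 1e-6)
  set.seed(15)
  R <- random_rotation()
  m2 <- transform_mesh(sc$meshes$femur_shaft, R)
  h2 <- orientation_hints(femur_proximal = R %*% c(0, 0, 1))
  fl2 <- femoral_long_axis(m2, h2)
  expect_equal(fl2$direction, as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-6)
  ball <- generate_knee(flexion = 0)$meshes$patella  # 25/20/10: ratio < 2
  expect_error(femoral_long_axis(ball), "not elongated")
})
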