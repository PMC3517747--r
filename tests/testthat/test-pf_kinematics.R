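# Patella-based coordinate system and the four patellofemoral parameters.

test_that("patellar frame of a canonical ellipsoid", {
  m <- kneekin:::mesh_ellipsoid(c(0, 0, 0), c(20, 25, 10))  # ML, SI, AP
  # canonical orientation: long axis along y (superior), ML along x
  fr <- build_patellar_frame(m, orientation_hints(superior = c(0, 1, 0),
                                                  lateral = c(1, 0, 0)))
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(unname(fr$axes["y", ])), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(abs(unname(fr$axes["x", ])), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$ipp, c(0, -25, 0), tolerance = 1e-9)
  G <- fr$axes %*% t(fr$axes)
  expect_lt(max(abs(G - diag(3))), 1e-9)
})

test_that("patellar frame is equivariant under rotation", {
  set.seed(31)
  for (rep in 1:5) {
    R <- random_rotation()
    m <- kneekin:::mesh_ellipsoid(c(0, 0, 0), c(20, 25, 10), axes = R)
    fr <- build_patellar_frame(m, orientation_hints(
      proximal = R %*% c(0, 0, 1), superior = R %*% c(0, 1, 0),
      lateral = R %*% c(1, 0, 0)))
    expect_equal(unname(fr$axes["y", ]), as.numeric(R %*% c(0, 1, 0)),
                 tolerance = 1e-6)
    expect_equal(unname(fr$axes["x", ]), as.numeric(R %*% c(1, 0, 0)),
                 tolerance = 1e-6)
    expect_equal(fr$ipp, as.numeric(R %*% c(0, -25, 0)), tolerance = 1e-6)
  }
})

test_that("open meshes and degenerate shapes are rejected", {
  expect_error(build_patellar_frame(unit_square_plate()), "closed")
  ball <- kneekin:::mesh_ellipsoid(c(0, 0, 0), c(10, 10, 10))
  expect_error(build_patellar_frame(ball), "degenerate")
})

test_that("patellar height: point on line, 3-4-5 case, sampling oracle", {
  tib <- build_tibial_frame(generate_knee(flexion = 0)$meshes$tibia_plateau)
  mk_frame <- function(ipp) {
    fr <- build_patellar_frame(
      kneekin:::mesh_ellipsoid(ipp + c(0, 25, 0), c(20, 25, 10)),
      orientation_hints(superior = c(0, 1, 0)))
    fr
  }
  expect_equal(patellar_height(mk_frame(c(12, 0, 0)), tib), 0, tolerance = 1e-9)
  fr <- mk_frame(c(5, 3, 4))
  expect_equal(patellar_height(fr, tib), 5, tolerance = 1e-9)
  # brute force: minimum distance over densely sampled line points
  s <- seq(-50, 50, by = 1e-3)
  line <- outer(s, tib$axes["x", ])
  d <- sqrt(colSums((t(line) - (fr$ipp - tib$origin))^2))
  expect_lt(abs(patellar_height(fr, tib) - min(d)), 1e-5)
})

test_that("patellofemoral angle: parallel, orthogonal, constructed 30 deg", {
  fr <- build_patellar_frame(kneekin:::mesh_ellipsoid(c(0, 0, 0), c(20, 25, 10)),
                             orientation_hints(superior = c(0, 1, 0)))
  py <- fr$axes["y", ]
  expect_equal(patellofemoral_angle(fr, py), 0, tolerance = 1e-9)
  expect_equal(patellofemoral_angle(fr, c(1, 0, 0)), 90, tolerance = 1e-9)
  rot <- rotation_about(c(1, 0, 0), 30) %*% py
  expect_equal(patellofemoral_angle(fr, as.numeric(rot)), 30, tolerance = 1e-9)
})

test_that("trochlear landmarks: symmetry, membership, dislocation error", {
  sc <- generate_knee(flexion = 0,
                      params = list(ap_medial = 0, ap_lateral = 0, height = 16,
                                    pf_angle = 6, tilt = 0, shift = 0))
  pfr <- build_patellar_frame(sc$meshes$patella, sc$hints)
  lm <- trochlear_landmarks(sc$meshes$trochlea, pfr)
  # landmark outputs are vertices of the input mesh
  vkeys <- paste(round(sc$meshes$trochlea$vertices[, 1], 9),
                 round(sc$meshes$trochlea$vertices[, 2], 9),
                 round(sc$meshes$trochlea$vertices[, 3], 9))
  for (p in list(lm$pmin1, lm$pmin2, lm$pmax))
    expect_true(paste(round(p[1], 9), round(p[2], 9), round(p[3], 9)) %in% vkeys)
  # mirror symmetry of pmin pair about the midplane for a centred patella
  loc1 <- express_in_frame(lm$pmin1, pfr)
  loc2 <- express_in_frame(lm$pmin2, pfr)
  expect_equal(loc1[1], -loc2[1], tolerance = 1e-6)
  expect_lt(abs(lm$x0), 1e-6)
  # a patella far beyond the groove has no facet on one side
  far <- generate_knee(flexion = 0,
                       params = list(ap_medial = 0, ap_lateral = 0, height = 16,
                                     pf_angle = 6, tilt = 0, shift = 40))
  pfr_far <- build_patellar_frame(far$meshes$patella, far$hints)
  expect_error(trochlear_landmarks(far$meshes$trochlea, pfr_far),
               "facet is empty")
})

test_that("tilt: zero at symmetry, exact recovery, antisymmetric in sign", {
  base <- list(ap_medial = 0, ap_lateral = 0, height = 16, pf_angle = 6,
               tilt = 0, shift = 0)
  tilt_of <- function(tl) {
    p <- base; p$tilt <- tl
    measure_scene(generate_knee(flexion = 0, params = p))$tilt
  }
  expect_equal(tilt_of(0), 0, tolerance = 1e-9)
  expect_equal(tilt_of(10), 10, tolerance = 0.5)
  expect_equal(tilt_of(-10), -tilt_of(10), tolerance = 1e-6)
})

test_that("shift: centred zero, imposed lateral offset, projection property", {
  base <- list(ap_medial = 0, ap_lateral = 0, height = 16, pf_angle = 6,
               tilt = 0, shift = 0)
  shift_of <- function(s) {
    p <- base; p$shift <- s
    measure_scene(generate_knee(flexion = 0, params = p))$shift
  }
  expect_equal(shift_of(0), 0, tolerance = 1e-9)
  expect_equal(shift_of(6), 6, tolerance = 0.5)
  # invariance to displacement parallel to y_t / z_t: move the whole
  # patella-trochlea pair anteriorly and proximally
  sc <- generate_knee(flexion = 0, params = base)
  tib <- build_tibial_frame(sc$meshes$tibia_plateau, sc$hints)
  for (mv in list(c(0, 5, 0), c(0, 0, 5))) {
    pat <- transform_mesh(sc$meshes$patella, translation = mv)
    tro <- transform_mesh(sc$meshes$trochlea, translation = mv)
    pfr <- build_patellar_frame(pat, sc$hints)
    lm <- trochlear_landmarks(tro, pfr)
    expect_equal(patellar_shift(pfr, lm, tib), 0, tolerance = 1e-9)
  }
})

test_that("all four parameters are invariant under a common rigid motion", {
  set.seed(32)
  sc <- generate_knee(flexion = 90)
  ref <- measure_scene(sc)
  for (rep in 1:3) {
    R <- random_rotation(); tr <- stats::rnorm(3, 0, 40)
    rec <- measure_scene(transform_scene(sc, R, tr))
    for (p in c("height", "pf_angle", "tilt", "shift", "ap_medial",
                "ap_lateral", "rotation"))
      expect_equal(rec[[p]], ref[[p]], tolerance = 1e-6, label = p)
  }
})

test_that("parameter recovery on generator knees within stated tolerances", {
  for (g in c("healthy", "pcl")) {
    mm <- default_motion_model(g)
    for (i in seq_len(nrow(mm))) {
      sc <- generate_knee(motion = mm, flexion = mm$flexion[i],
                          muscle = mm$muscle[i], group = g)
      rec <- measure_scene(sc)
      gt <- sc$ground_truth
      expect_lt(abs(rec$height - gt$height), 0.5)
      expect_lt(abs(rec$shift - gt$shift), 0.5)
      expect_lt(abs(rec$pf_angle - gt$pf_angle), 0.5)
      expect_lt(abs(rec$tilt - gt$tilt), 0.5)
    }
  }
})
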