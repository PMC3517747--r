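# Synthetic knee generator: ground-truth fidelity, cohorts, voxelization.

test_that("shape parameters validate their invariants", {
  expect_error(knee_shape_params(condyle_radius = -1), "positive")
  expect_error(knee_shape_params(trochlea_halfwidth = 40,
                                 trochlea_opening = 45),
               "groove depth")
})

test_that("identity motion at 0 degrees measures as the reference pose", {
  p0 <- list(ap_medial = 0, ap_lateral = 0, height = 16, pf_angle = 6,
             tilt = 0, shift = 0)
  r0 <- measure_scene(generate_knee(flexion = 0, params = p0))
  expect_lt(abs(r0$ap_medial), 0.05)
  expect_lt(abs(r0$ap_lateral), 0.05)
  expect_lt(abs(r0$rotation), 0.05)
})

test_that("imposed medial translation is recovered through the pipeline", {
  mm <- default_motion_model("pcl")
  r30 <- measure_scene(generate_knee(motion = mm, flexion = 30,
                                     muscle = "relaxed", group = "pcl"))
  r90 <- measure_scene(generate_knee(motion = mm, flexion = 90,
                                     muscle = "relaxed", group = "pcl"))
  gt <- mm$ap_medial[mm$flexion == 90 & mm$muscle == "relaxed"] -
    mm$ap_medial[mm$flexion == 30 & mm$muscle == "relaxed"]
  expect_equal(r90$ap_medial - r30$ap_medial, gt, tolerance = 0.3)
  expect_gte(gt, 5)  # the default model imposes the paradox pattern
})

test_that("motion model invariants hold for the default groups", {
  h <- default_motion_model("healthy")
  p <- default_motion_model("pcl")
  h_rel <- h[h$muscle == "relaxed", ]
  p_rel <- p[p$muscle == "relaxed", ]
  # healthy: lateral posterior translation 0->90 exceeds medial
  expect_gt(-(h_rel$ap_lateral[h_rel$flexion == 90] -
                h_rel$ap_lateral[h_rel$flexion == 0]),
            -(h_rel$ap_medial[h_rel$flexion == 90] -
                h_rel$ap_medial[h_rel$flexion == 0]))
  # PCL: medial anterior paradox >= 5 mm from 30 to 90
  expect_gte(p_rel$ap_medial[p_rel$flexion == 90] -
               p_rel$ap_medial[p_rel$flexion == 30], 5)
  # flexor activity increases the paradox at 90 degrees
  expect_gt(p$ap_medial[p$flexion == 90 & p$muscle == "active"],
            p$ap_medial[p$flexion == 90 & p$muscle == "relaxed"])
  # healthy group unaffected by muscle state
  expect_identical(h$ap_medial[h$muscle == "active"],
                   h$ap_medial[h$muscle == "relaxed"])
})

test_that("cohort sampling is bit-reproducible under a fixed seed", {
  a <- sample_cohort(cohort_spec("pcl", seed = 42))
  b <- sample_cohort(cohort_spec("pcl", seed = 42))
  expect_identical(a$params, b$params)
  c2 <- sample_cohort(cohort_spec("pcl", seed = 43))
  expect_false(identical(a$params, c2$params))
  expect_error(cohort_spec("pcl", n = 1), "n >= 2")
})

test_that("generator ground truth converges to the calibration mean", {
  spec <- cohort_spec("healthy", n = 2000, seed = 5)
  co <- sample_cohort(spec)
  g <- co$params[co$params$flexion == 90 & co$params$muscle == "relaxed", ]
  # healthy 90-deg tilt cell: mean 7.5, SD 3.5 -> SE at n=2000 is 0.078
  expect_lt(abs(mean(g$tilt) - 7.5), 0.2)
  expect_lt(abs(stats::sd(g$tilt) - 3.5), 0.2)
})

test_that("a measured cohort recovers its specification means end-to-end", {
  co <- sample_cohort(cohort_spec("healthy", n = 20, seed = 8))
  rec <- measure_cohort(co, flexion = 90, muscle = "relaxed")
  cal <- pf_calibration("healthy")
  cell <- cal[cal$flexion == 90 & cal$muscle == "relaxed", ]
  for (p in c("height", "pf_angle", "tilt", "shift")) {
    se <- cell[[paste0(p, "_sd")]] / sqrt(20)
    expect_lt(abs(mean(rec[[p]]) - cell[[paste0(p, "_mean")]]), 2 * se + 0.05,
              label = p)
  }
})

test_that("loading torque reproduces the study protocol and is linear", {
  expect_equal(round(loading_torque(3, 0.35, 9.81), 1), 10.3)
  expect_equal(round(loading_torque(3, 0.35, 9.81)), 10)
  expect_equal(loading_torque(1, 1, 9.81), 9.81)
  expect_equal(loading_torque(2, 0.35), 2 * loading_torque(1, 0.35))
  expect_error(loading_torque(0, 0.35), "positive")
})

test_that("voxelized scene re-measures within 1.5 mm and 2 degrees", {
  sc <- generate_knee(motion = default_motion_model("pcl"), flexion = 90,
                      muscle = "relaxed", group = "pcl")
  vol <- voxelize_knee(sc, spacing = 1)
  expect_s3_class(vol, "label_volume")
  expect_true(all(knee_labels()[c("femur", "tibia", "patella", "tibia_plateau",
                                  "trochlea", "femur_shaft", "condyle_medial",
                                  "condyle_lateral")] %in% vol$labels))
  rec <- measure_volume(vol, hints = sc$hints, flexion = 90, group = "pcl")
  mesh_rec <- measure_scene(sc)
  gt <- sc$ground_truth
  for (p in c("ap_medial", "ap_lateral", "ap_central", "height", "shift")) {
    expect_lt(abs(rec[[p]] - gt[[p]]), 1.5, label = p)
    expect_lt(abs(rec[[p]] - mesh_rec[[p]]), 1.5, label = p)
  }
  for (p in c("rotation", "pf_angle", "tilt")) {
    expect_lt(abs(rec[[p]] - gt[[p]]), 2, label = p)
    expect_lt(abs(rec[[p]] - mesh_rec[[p]]), 2, label = p)
  }
})
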