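# Summaries and paired/unpaired comparisons.

fake_records <- function(values, group = "healthy", flexion = 90,
                         muscle = "relaxed", parameter = "tilt") {
  n <- length(values)
  df <- data.frame(subject = sprintf("S%02d", seq_len(n)), group = group,
                   flexion = flexion, muscle = muscle)
  df[[parameter]] <- values
  df
}

test_that("summaries match hand-computed and brute-force values", {
  rec <- rbind(fake_records(c(1, 2, 3)),
               fake_records(c(5, 5, 5, 5), flexion = 0))
  s <- summarize_kinematics(rec, parameters = "tilt")
  c90 <- s[s$flexion == 90, ]
  expect_equal(c90$mean, 2); expect_equal(c90$sd, 1); expect_equal(c90$n, 3L)
  c0 <- s[s$flexion == 0, ]
  expect_equal(c0$sd, 0)
  # brute-force two-pass oracle on random data
  set.seed(41)
  x <- stats::rnorm(37, 5, 2)
  s2 <- summarize_kinematics(fake_records(x), parameters = "tilt")
  mu <- sum(x) / length(x)
  expect_equal(s2$mean, mu, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((x - mu)^2) / (length(x) - 1)),
               tolerance = 1e-12)
  expect_error(summarize_kinematics(fake_records(1)), "fewer than 2")
})

test_that("paired comparison: null case, degenerate variance, basic values", {
  x <- c(10, 12, 9, 14, 11)
  rec <- rbind(fake_records(x, flexion = 0), fake_records(x, flexion = 90))
  r <- paired_compare(rec, list(flexion = 0, muscle = "relaxed"),
                      list(flexion = 90, muscle = "relaxed"), "tilt")
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_false(r$significant)
  # constant nonzero differences: degenerate signal, not a crash
  rec2 <- rbind(fake_records(x, flexion = 0), fake_records(x + 1, flexion = 90))
  r2 <- paired_compare(rec2, list(flexion = 0, muscle = "relaxed"),
                       list(flexion = 90, muscle = "relaxed"), "tilt")
  expect_true(r2$degenerate)
  expect_equal(r2$estimate, 1)
  # unmatched subjects
  rec3 <- rbind(fake_records(x, flexion = 0), fake_records(x[1:4], flexion = 90))
  expect_error(paired_compare(rec3, list(flexion = 0, muscle = "relaxed"),
                              list(flexion = 90, muscle = "relaxed"), "tilt"),
               "unmatched")
})

test_that("paired comparison agrees with stats::t.test", {
  set.seed(42)
  a <- stats::rnorm(12, 10, 2); b <- stats::rnorm(12, 11, 2)
  rec <- rbind(fake_records(a, flexion = 30), fake_records(b, flexion = 90))
  r <- paired_compare(rec, list(flexion = 30, muscle = "relaxed"),
                      list(flexion = 90, muscle = "relaxed"), "tilt")
  tt <- stats::t.test(b - a)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r$df, 11)
})

test_that("unpaired comparison: null, label swap, permutation oracle", {
  x <- c(4, 5, 6, 7)
  rec <- rbind(fake_records(x, group = "healthy"),
               fake_records(x, group = "pcl"))
  r <- unpaired_compare(rec, "healthy", "pcl",
                        list(flexion = 90, muscle = "relaxed"), "tilt")
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # swapping group labels negates t, keeps p
  a <- c(3.1, 4.2, 5.3, 2.8); b <- c(5.9, 6.4, 7.7, 6.1)
  rec2 <- rbind(fake_records(a, group = "healthy"),
                fake_records(b, group = "pcl"))
  r_ab <- unpaired_compare(rec2, "healthy", "pcl",
                           list(flexion = 90, muscle = "relaxed"), "tilt")
  r_ba <- unpaired_compare(rec2, "pcl", "healthy",
                           list(flexion = 90, muscle = "relaxed"), "tilt")
  expect_equal(r_ab$t, -r_ba$t, tolerance = 1e-12)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
  # exhaustive permutation oracle on n = 4 + 4
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  combos <- utils::combn(8, 4)
  perm_stats <- apply(combos, 2, function(ix)
    abs(mean(pool[ix]) - mean(pool[-ix])))
  p_perm <- mean(perm_stats >= obs - 1e-12)
  expect_lt(abs(r_ab$p - p_perm), 0.15)
  expect_lt(r_ab$p, 0.05)  # clearly separated samples
  expect_error(unpaired_compare(rec2[-(1:3), ], "healthy", "pcl",
                                list(flexion = 90, muscle = "relaxed"), "tilt"),
               "n >= 2")
})

test_that("Welch option changes degrees of freedom but not symmetry", {
  set.seed(43)
  a <- stats::rnorm(20, 0, 1); b <- stats::rnorm(12, 0, 4)
  rec <- rbind(fake_records(a, group = "healthy"),
               fake_records(b, group = "pcl"))
  rp <- unpaired_compare(rec, "healthy", "pcl",
                         list(flexion = 90, muscle = "relaxed"), "tilt",
                         var_equal = TRUE)
  rw <- unpaired_compare(rec, "healthy", "pcl",
                         list(flexion = 90, muscle = "relaxed"), "tilt",
                         var_equal = FALSE)
  expect_equal(rp$df, 30)
  expect_lt(rw$df, 30)
})

test_that("summary table mirrors the study layout", {
  set.seed(44)
  co <- sample_cohort(cohort_spec("healthy", n = 4, seed = 3))
  s <- summarize_kinematics(cbind(co$params))
  tab <- kinematics_table(s, "healthy")
  expect_identical(dim(tab), c(8L, 6L))
  expect_true(all(grepl("±", tab)))
})
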