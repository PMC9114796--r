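test_that("default profiles realize the reported group orderings", {
  p <- make_default_profiles()
  m <- function(g, f) p[[g]]$mean[[f]]
  # forward extent: young > older > mild > advanced
  L <- vapply(c("healthy_young", "healthy_older", "mild_pd", "advanced_pd"),
              m, numeric(1), f = "stride_length")
  expect_true(all(diff(L) < 0))
  # vertical: mild PD largest on every height, advanced smallest
  for (f in c("max_clearance", "toe_off_height", "terminal_height")) {
    v <- vapply(c("mild_pd", "healthy_young", "healthy_older", "advanced_pd"),
                m, numeric(1), f = f)
    expect_true(all(diff(v) < 0), label = f)
  }
  expect_gt(m("mild_pd", "max_clearance"), m("healthy_older", "max_clearance"))
  expect_lt(m("advanced_pd", "stride_length"), m("mild_pd", "stride_length"))
  for (g in names(p)) {
    expect_true(all(unlist(p[[g]]$between_subject_sd) >= 0))
    expect_true(all(unlist(p[[g]]$within_subject_sd) >= 0))
  }
})

test_that("stride parameter validation enforces the domain", {
  expect_error(stride_params(1, 0.1, 0.2, 0.02, 1), "max_clearance")
  expect_error(stride_params(1, 0.1, 0.05, 0.02, -1), "stride_duration")
  expect_error(
    stride_params(1, 0.1, 0.05, 0.02, 1, stance_fraction = 0.8,
                  clearance_phase = 0.7),
    "stance_fraction"
  )
  expect_error(stride_params_sd(stride_length = -1), ">= 0")
})

test_that("single-stride kinematics honours its boundary conditions", {
  p <- stride_params(1.3, 0.15, 0.08, 0.05, 1.1)
  k <- simulate_stride_kinematics(p, fs = 200)
  x <- k$position[, 1]; z <- k$position[, 3]
  expect_equal(x[1], 0)
  expect_equal(max(x), 1.3, tolerance = 1e-9)
  expect_true(all(diff(x) >= -1e-12)) # forward position non-decreasing
  expect_equal(z[1], 0)
  expect_equal(z[length(z)], 0, tolerance = 1e-9) # settles at foot-flat
  # vertical peak = max_clearance, attained at clearance_phase * duration
  expect_equal(max(z), 0.15, tolerance = 1e-3) # grid misses the exact peak
  expect_equal(k$time[which.max(z)], 0.76 * 1.1, tolerance = 0.01)
  # toe-off height read off the curve at the stance fraction
  expect_equal(approx(k$time, z, k$events$toe_off)$y, 0.08, tolerance = 1e-3)
  # terminal height at the terminal heel strike
  expect_equal(approx(k$time, z, k$events$terminal_heel_strike)$y, 0.05,
               tolerance = 1e-3)
})

test_that("degenerate stride parameters yield a constant position", {
  p <- stride_params(0, 0, 0, 0, 1)
  k <- simulate_stride_kinematics(p, fs = 100)
  expect_true(all(abs(k$position[, 1]) < 1e-12))
  expect_true(all(abs(k$position[, 3]) < 1e-12))
})

test_that("acceleration is consistent with position (second derivative)", {
  p <- stride_params(1.2, 0.14, 0.07, 0.04, 1.0)
  k <- simulate_stride_kinematics(p, fs = 400)
  h <- 1 / 400
  n <- nrow(k$position)
  fd <- (k$position[3:n, ] - 2 * k$position[2:(n - 1), ] +
           k$position[1:(n - 2), ]) / h^2
  # away from the piecewise knots the analytic acceleration matches a
  # second difference to discretization accuracy
  err <- abs(fd - k$accel[2:(n - 1), ])
  expect_lt(median(err), 0.05)
  expect_lt(unname(quantile(err, 0.9)), 1) # only the few knots differ
})

test_that("render_imu on static kinematics returns gravity only", {
  n <- 200
  kin <- list(
    time = seq(0, by = 0.01, length.out = n),
    position = matrix(0, n, 3), accel = matrix(0, n, 3),
    pitch = numeric(n), yaw = numeric(n), fs = 100,
    heel_strike_times = numeric(0)
  )
  s <- render_imu(kin, sensor_noise_none(), seed = 1)
  expect_equal(sqrt(rowSums(s$accel^2)), rep(9.80665, n), tolerance = 1e-9)
  expect_true(all(abs(s$gyro) < 1e-9))
})

test_that("rendering and simulation are reproducible given the seed", {
  p <- stride_params(1.2, 0.14, 0.07, 0.04, 1.0)
  k <- simulate_stride_kinematics(p, fs = 100)
  k$heel_strike_times <- k$heel_strike_times
  a <- render_imu(k, sensor_noise(), seed = 9)
  b <- render_imu(k, sensor_noise(), seed = 9)
  expect_identical(a$accel, b$accel)
  expect_identical(a$gyro, b$gyro)

  s1 <- simulate_session(make_default_profiles()$healthy_older, cohort_spec(),
                         seed = 4)
  s2 <- simulate_session(make_default_profiles()$healthy_older, cohort_spec(),
                         seed = 4)
  expect_identical(s1$session$left$accel, s2$session$left$accel)
  expect_identical(s1$truth$strides, s2$truth$strides)
})

test_that("session ground truth flags exactly the configured turn strides", {
  spec <- cohort_spec(strides_per_session = 70, turn_indices = c(12, 13))
  sim <- simulate_session(make_default_profiles()$mild_pd, spec, seed = 2)
  st <- sim$truth$strides
  for (side in c("left", "right")) {
    expect_identical(st$stride[st$side == side & st$turn], c(12L, 13L))
  }
})

test_that("zero within-subject variance gives identical non-turn strides", {
  prof <- make_default_profiles()$healthy_older
  prof$within_subject_sd <- stride_params_sd()
  sim <- simulate_session(prof, cohort_spec(), seed = 6)
  st <- sim$truth$strides
  keep <- st$side == "left" & !st$turn
  expect_equal(diff(range(st$stride_length[keep])), 0, tolerance = 1e-12)
  expect_equal(diff(range(st$V2[keep])), 0, tolerance = 1e-12)
})

test_that("simulate_cohort is reproducible and sized correctly", {
  spec <- cohort_spec(counts = c(mild_pd = 2, healthy_older = 2), seed = 8)
  a <- simulate_cohort(make_default_profiles(), spec)
  b <- simulate_cohort(make_default_profiles(), spec)
  expect_length(a$sessions, 4L)
  expect_identical(a$truth_features, b$truth_features)
  expect_equal(nrow(a$truth_features), 4L)
  # empty cohort: empty outputs, no error
  none <- simulate_cohort(make_default_profiles(),
                          cohort_spec(counts = c(mild_pd = 0), seed = 1))
  expect_length(none$sessions, 0L)
})

test_that("analytic feature table reproduces the built-in group orderings", {
  tt <- simulate_truth_features(n = 40, seed = 12)
  gm <- group_means(tt)
  expect_true(gm["healthy_young", "F3"] > gm["healthy_older", "F3"])
  expect_true(gm["healthy_older", "F3"] > gm["mild_pd", "F3"])
  expect_true(gm["mild_pd", "F3"] > gm["advanced_pd", "F3"])
  expect_true(gm["mild_pd", "V2"] > gm["healthy_young", "V2"])
  expect_true(gm["advanced_pd", "V2"] < gm["healthy_older", "V2"])
})
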