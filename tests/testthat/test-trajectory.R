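test_that("heel-strike detection: degenerate inputs and refractory rule", {
  expect_length(detect_heel_strikes(numeric(300), 100), 0L)

  # two transients 0.2 s apart inside the refractory period: the larger wins
  set.seed(4)
  fs <- 100
  g <- rnorm(10 * fs, 0, 0.05)
  ricker <- function(t0, A) {
    idx <- which(abs(seq_along(g) / fs - t0) < 0.06)
    u2 <- ((idx / fs - t0) / 0.02)^2
    g[idx] <<- g[idx] + A * (1 - 2 * u2) * exp(-u2)
  }
  ricker(4.0, 5); ricker(4.2, 9)
  hs <- detect_heel_strikes(g, fs)
  expect_length(hs, 1L)
  expect_equal(hs / fs, 4.2, tolerance = 0.02)
})

test_that("heel strikes of a simulated session are recovered (>=95%, 30 ms)", {
  for (fix in list(fixture_session_clean(), fixture_session_noisy())) {
    for (side in c("left", "right")) {
      truth <- fix$truth$kinematics[[side]]$heel_strike_times
      det <- detect_heel_strikes(fix$session[[side]]$gyro[, 2], 100)
      tdet <- fix$session[[side]]$time[det]
      hits <- vapply(truth, function(t) any(abs(tdet - t) <= 0.03), logical(1))
      expect_gte(mean(hits), 0.95)
      # no duplicates: every detection near at most one truth event
      expect_lte(length(tdet), length(truth))
    }
  }
})

test_that("stride windowing: fencepost, partition, and anchor placement", {
  fix <- fixture_session_clean()
  series <- fix$session$left
  hs <- detect_heel_strikes(series$gyro[, 2], 100)
  series$gyro <- despike_gyro(series$gyro, hs, 0.10, 100)

  expect_length(segment_strides(series, hs[1]), 0L)
  segs5 <- segment_strides(series, hs[1:5])
  expect_length(segs5, 4L)
  segs5_hs <- segment_strides(series, hs[1:5],
                              estimation_config(segmentation = "heelstrike"))
  expect_length(segs5_hs, 4L)

  segs <- segment_strides(series, hs)
  starts <- vapply(segs, `[[`, integer(1), "start")
  ends <- vapply(segs, `[[`, integer(1), "end")
  expect_identical(starts[-1], ends[-length(ends)]) # disjoint, contiguous
  for (s in segs) {
    expect_true(s$heel_strike_index >= s$start && s$heel_strike_index < s$end)
    expect_true(s$mid_stance_index >= s$start && s$mid_stance_index < s$end)
  }

  # anchors land at the true quasi-static mid-stance (+/- 50 ms)
  truth <- fix$truth$strides
  tl <- truth[truth$side == "left", ]
  err <- c()
  for (s in segs) {
    t_anchor <- series$time[s$mid_stance_index]
    err <- c(err, min(abs(tl$mid_stance - t_anchor)))
  }
  expect_lt(stats::median(err), 0.05)
  expect_lt(mean(err <= 0.05), 1 + 1e-9) # guard: all finite
  expect_gte(mean(err <= 0.05), 0.9)
})

test_that("gravity alignment maps the measured vector to +z", {
  g <- 9.80665
  expect_equal(estimate_initial_orientation(c(0, 0, g)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  # gravity rotated 10 degrees about the sagittal (y) axis
  th <- 10 * pi / 180
  a <- c(sin(th) * g, 0, cos(th) * g)
  q <- estimate_initial_orientation(a)
  back <- gaitpath:::quat_rotate(q, a)
  expect_equal(back, c(0, 0, g), tolerance = 1e-9)
  expect_error(estimate_initial_orientation(c(0, 0, 0)), "quasi-static")
  expect_error(estimate_initial_orientation(c(0, 0, 0.5 * g)), "quasi-static")
})

test_that("orientation propagation matches closed forms", {
  n <- 101
  dt <- 0.01
  q0 <- c(1, 0, 0, 0)
  # zero gyro: constant orientation
  q <- propagate_orientation(matrix(0, n, 3), q0, 1L, dt)
  expect_equal(q[n, ], q0, tolerance = 1e-12)
  # constant pitch rate omega for time t -> pitch angle omega*t
  w <- 0.7
  q <- propagate_orientation(cbind(0, rep(w, n), 0), q0, 1L, dt)
  expect_equal(2 * atan2(q[n, 3], q[n, 1]), w * (n - 1) * dt, tolerance = 1e-6)
  # group inverse: integrating the sign-reversed gyro returns to the start
  set.seed(7)
  gyro <- matrix(rnorm(3 * n, 0, 2), n, 3)
  qf <- propagate_orientation(gyro, q0, 1L, dt)
  rev_gyro <- rbind(-gyro[rev(seq_len(n - 1L)), , drop = FALSE], c(0, 0, 0))
  qb <- propagate_orientation(rev_gyro, qf[n, ], 1L, dt)
  # compare rotations (q and -q are the same rotation)
  qe <- qb[n, ] * sign(qb[n, 1])
  expect_equal(qe, q0, tolerance = 1e-9)
})

test_that("world acceleration: rotation + gravity removal", {
  n <- 10
  q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  accel <- matrix(rep(c(0, 0, 9.80665), each = n), n, 3)
  aw <- world_acceleration(accel, q)
  expect_true(all(abs(aw) < 1e-12))
  # rotations preserve the norm before gravity subtraction
  set.seed(8)
  accel <- matrix(rnorm(3 * n), n, 3)
  q <- t(vapply(seq_len(n), function(i) {
    gaitpath:::quat_from_rotvec(rnorm(3)) }, numeric(4)))
  rotated <- sweep(world_acceleration(accel, q), 2, c(0, 0, 9.80665), `+`)
  expect_equal(sqrt(rowSums(rotated^2)), sqrt(rowSums(accel^2)),
               tolerance = 1e-9)
})

test_that("drift-cancelling integration: closed-form oracles", {
  fs <- 100
  n <- 101
  # zero acceleration
  res <- dedrift_integrate(matrix(0, n, 3), fs)
  expect_true(all(abs(res$velocity) < 1e-15))
  expect_true(all(abs(res$position) < 1e-15))
  # constant bias c: (1 - t/T) c t + (t/T) c (t - T) = 0 exactly
  res <- dedrift_integrate(matrix(0.3, n, 3), fs)
  expect_true(all(abs(res$velocity) < 1e-12))
  # sinusoid with true zero endpoint velocity: closed-form double integral
  tt <- (seq_len(n) - 1) / fs
  a <- cbind(sin(2 * pi * tt), 0, 0)
  res <- dedrift_integrate(a, fs)
  p_true <- (1 / (2 * pi)) * (tt - sin(2 * pi * tt) / (2 * pi))
  expect_lt(max(abs(res$position[, 1] - p_true)), 1e-4)
  expect_error(dedrift_integrate(matrix(0, 3, 3), fs), "short")
})

test_that("stride frame: forward axis, rotation invariance, degeneracy", {
  n <- 50
  tt <- seq(0, 1, length.out = n)
  pos <- cbind(tt, 0 * tt, 0.1 * sin(pi * tt))
  vel <- cbind(rep(1, n), 0, 0.1 * pi * cos(pi * tt))
  base <- rotate_to_stride_frame(list(time = tt, position = pos, velocity = vel))
  expect_equal(base$position[, "forward"], tt, tolerance = 1e-12)
  expect_true(all(abs(base$position[, "lateral"]) < 1e-12))

  phi <- 37 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2, byrow = TRUE)
  pos2 <- pos; pos2[, 1:2] <- pos[, 1:2] %*% t(R)
  vel2 <- vel; vel2[, 1:2] <- vel[, 1:2] %*% t(R)
  rot <- rotate_to_stride_frame(list(time = tt, position = pos2, velocity = vel2))
  expect_equal(rot$position, base$position, tolerance = 1e-9)
  expect_equal(rot$velocity, base$velocity, tolerance = 1e-9)

  still <- list(time = tt, position = matrix(0, n, 3),
                velocity = matrix(0, n, 3))
  expect_error(rotate_to_stride_frame(still), "degenerate")
})

test_that("noise-free round trip recovers stride length within 1%", {
  fix <- fixture_session_clean()
  pairs <- stride_length_pairs(fix)
  expect_gt(nrow(pairs), 30)
  rel <- abs(pairs$est - pairs$true) / pairs$true
  expect_true(all(rel[!pairs$turn] < 0.01))
})

test_that("per-stride trajectories satisfy the endpoint constraints", {
  fix <- fixture_session_noisy()
  est <- estimate_trajectories(fix$session)
  n_checked <- 0
  for (side in c("left", "right")) {
    for (e in est[[side]]) {
      tr <- e$trajectory
      n <- nrow(tr$position)
      expect_true(all(abs(tr$position[1, ]) == 0))
      expect_true(all(abs(tr$velocity[1, ]) < 1e-9))
      expect_true(all(abs(tr$velocity[n, ]) < 1e-9))
      expect_lt(abs(tr$position[1, "vertical"]), 1e-9)
      expect_lt(abs(tr$position[n, "vertical"]), 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 60)
})

test_that("a static recording yields no usable strides, with reasons", {
  n <- 1500
  kin <- list(
    time = seq(0, by = 0.01, length.out = n),
    position = matrix(0, n, 3), accel = matrix(0, n, 3),
    pitch = numeric(n), yaw = numeric(n), fs = 100,
    heel_strike_times = numeric(0)
  )
  s <- render_imu(kin, sensor_noise(), seed = 11)
  session <- walk_session("static", "healthy_older", s,
                          render_imu(kin, sensor_noise(), seed = 12,
                                     side = "right"))
  est <- estimate_trajectories(session)
  expect_length(est$left, 0L)
  expect_length(est$right, 0L)
})

test_that("a constant accelerometer bias changes stride length by < 2%", {
  fix <- fixture_session_clean()
  base <- stride_length_pairs(fix)
  biased <- fix
  for (side in c("left", "right")) {
    biased$session[[side]]$accel <- fix$session[[side]]$accel +
      matrix(rep(c(0.05, 0.05, 0.05), each = nrow(fix$session[[side]]$accel)),
             ncol = 3)
  }
  shifted <- stride_length_pairs(biased)
  m <- merge(base, shifted, by = "true")
  expect_gt(nrow(m), 20)
  expect_true(all(abs(m$est.y - m$est.x) / m$true < 0.02))
})

test_that("doubling the sampling rate changes stride length by < 0.5%", {
  prof <- make_default_profiles()$healthy_older
  spec <- cohort_spec(strides_per_session = 24, turn_indices = c(6, 7), seed = 1)
  sims <- lapply(c(100, 200), function(fs) {
    simulate_session(prof, spec, sensor_noise_none(), seed = 21, fs = fs)
  })
  p1 <- stride_length_pairs(sims[[1]], selected_only = FALSE)
  p2 <- stride_length_pairs(sims[[2]], selected_only = FALSE)
  m <- merge(p1[!p1$turn, ], p2[!p2$turn, ], by = "true")
  expect_gt(nrow(m), 5)
  expect_true(all(abs(m$est.y - m$est.x) / m$true < 0.005))
})
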