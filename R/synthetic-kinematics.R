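# Closed-form stride kinematics and the world->sensor IMU renderer.
#
# Stride timeline (phase u = t / stride_duration, u = 0 at the onset heel
# strike):
#   [0, lambda]        landing: ankle descends from the previous stride's
#                      terminal height to the foot-flat level 0 (raised cosine)
#   [lambda, u_r]      foot-flat stance: position constant, shank quasi-static
#   [u_r, c]           heel-rise + swing ascent: vertical raised-cosine rise to
#                      max_clearance at clearance phase c, passing through
#                      toe_off_height at the toe-off phase s (u_r solved for
#                      that); forward progression follows a quintic smoothstep
#   [c, 1]             swing descent to terminal_height at the next heel strike
# Forward position uses a quintic smoothstep over [u_r, 1], so velocity and
# acceleration vanish at both ends of the moving interval. Acceleration is
# the exact analytic second derivative of each closed-form segment (the
# documented choice; position is C1 at the segment knots, so acceleration has
# bounded jumps there, as a real foot's does at contact events).
#
# The shank pitch-rate waveform is a sum of raised-cosine lobes: a loading
# lobe after heel strike, a terminal-stance lobe, a sharp negative toe-off
# lobe at phase s (the standard shank-gyro toe-off signature), and a large
# positive mid-swing lobe. Lobe areas are balanced so the pitch angle is
# periodic; the loading and terminal lobes meet at the mid-stance phase, so
# |pitch rate| has a unique minimum there (the gravity anchor).

LANDING_FRACTION <- 0.25 # stride fraction needed to settle onto foot-flat

#' Geometry derived from stride parameters
#' @noRd
stride_geometry <- function(p, lambda_base = LANDING_FRACTION) {
  s <- p$stance_fraction
  c <- p$clearance_phase
  ratio <- if (p$max_clearance > 0) min(p$toe_off_height / p$max_clearance, 0.95) else 0
  qp <- acos(1 - 2 * ratio) / pi
  rho <- qp * (c - s) / (1 - qp)
  u_r <- max(s - rho, 0.30 * s)
  # forward progression begins a fixed heel-rise lead before toe-off,
  # independent of how high the foot is lifted (decouples the forward
  # features from the vertical ones within a subject)
  u_x <- max(s - 0.15, 0.30 * s)
  lambda <- min(lambda_base, 0.6 * min(u_r, u_x))
  u_ms <- min(max(0.32, lambda + 0.04), min(u_r, u_x) - 0.04)
  if (u_ms <= lambda) u_ms <- (lambda + min(u_r, u_x)) / 2
  list(s = s, c = c, u_r = u_r, u_x = u_x, lambda = lambda, u_ms = u_ms)
}

#' Vertical ankle position at stride phase u (m above foot-flat level)
#' @noRd
z_eval <- function(u, p, geom, h_prev = 0) {
  s <- geom$s; c <- geom$c; u_r <- geom$u_r; lambda <- geom$lambda
  h <- p$max_clearance; ht <- p$terminal_height
  z <- numeric(length(u))
  i1 <- u < lambda
  z[i1] <- h_prev * (1 + cos(pi * u[i1] / lambda)) / 2
  i3 <- u >= u_r & u < c
  z[i3] <- h * (1 - cos(pi * (u[i3] - u_r) / (c - u_r))) / 2
  i4 <- u >= c
  z[i4] <- ht + (h - ht) * (1 + cos(pi * pmin(u[i4] - c, 1 - c) / (1 - c))) / 2
  z
}

#' Forward ankle position at stride phase u (m from stride onset)
#' @noRd
x_eval <- function(u, p, geom) {
  p$stride_length * smoothstep5((u - geom$u_x) / (1 - geom$u_x))
}

#' Analytic vertical acceleration (m/s^2) at stride phase u
#' @noRd
z_accel_eval <- function(u, p, geom, h_prev = 0) {
  s <- geom$s; c <- geom$c; u_r <- geom$u_r; lambda <- geom$lambda
  h <- p$max_clearance; ht <- p$terminal_height
  Tsq <- p$stride_duration^2
  a <- numeric(length(u))
  i1 <- u < lambda
  a[i1] <- -h_prev / 2 * (pi / lambda)^2 * cos(pi * u[i1] / lambda) / Tsq
  i3 <- u >= u_r & u < c
  d <- c - u_r
  a[i3] <- h / 2 * (pi / d)^2 * cos(pi * (u[i3] - u_r) / d) / Tsq
  i4 <- u >= c & u <= 1
  d <- 1 - c
  a[i4] <- -(h - ht) / 2 * (pi / d)^2 * cos(pi * (u[i4] - c) / d) / Tsq
  a
}

#' Analytic forward acceleration (m/s^2) at stride phase u
#' @noRd
x_accel_eval <- function(u, p, geom) {
  span <- 1 - geom$u_x
  w <- (u - geom$u_x) / span
  a <- numeric(length(u))
  inside <- w > 0 & w < 1
  wi <- w[inside]
  a[inside] <- p$stride_length * (60 * wi - 180 * wi^2 + 120 * wi^3) /
    (span^2 * p$stride_duration^2)
  a
}

# Cumulative integral of a unit hann lobe from 0 to u (vectorized in u >= 0).
hann_cumint <- function(u, c, w) {
  lo <- c - w / 2
  hi <- c + w / 2
  F <- function(v) 0.5 * (v + (w / (2 * pi)) * sin(2 * pi * (v - c) / w))
  x <- pmin(pmax(u, lo), hi)
  x0 <- min(max(0, lo), hi)
  F(x) - F(x0)
}

#' Shank pitch model for one stride
#'
#' Returns closed-form pitch rate (rad/s) and pitch angle (rad) as functions
#' of stride phase. `scale` attenuates the waveform for shuffling turn
#' strides.
#' @noRd
make_pitch_model <- function(p, geom, scale = 1) {
  s <- geom$s
  Tdur <- p$stride_duration
  # The shank is quiet immediately around contact (settling before the next
  # heel strike from ~88% of the stride, and until ~12% after it): the
  # loading-response lobe develops once the foot is flat and ends at
  # mid-stance, the terminal lobe starts there, so |pitch rate| has its
  # unique minimum at u_ms and the heel-strike neighbourhood carries no
  # rotational signal of its own (only the impact transient lives there).
  lobes <- list(
    load  = list(c = (0.12 + geom$u_ms) / 2, w = geom$u_ms - 0.12),
    term  = list(c = geom$u_ms + 0.22, w = 0.44),
    to    = list(c = s, w = 0.08),
    swing = list(c = (s + 0.88) / 2, w = 0.92 * (0.88 - s))
  )
  I <- vapply(lobes, function(l) hann_lobe_int(0, 1, l$c, l$w), numeric(1))
  P <- 0.75 * scale / (I[["swing"]] * Tdur) # swing angle 0.75 rad
  Q <- 0.10 * scale / (I[["to"]] * Tdur)    # toe-off lobe angle 0.10 rad
  R <- (P * I[["swing"]] - Q * I[["to"]]) / (I[["load"]] + I[["term"]])
  omega <- function(u) { # rad/s
    P * hann_lobe(u, lobes$swing$c, lobes$swing$w) -
      Q * hann_lobe(u, lobes$to$c, lobes$to$w) -
      R * (hann_lobe(u, lobes$load$c, lobes$load$w) +
             hann_lobe(u, lobes$term$c, lobes$term$w))
  }
  theta <- function(u) { # rad, theta(0) = 0, periodic
    Tdur * (P * hann_cumint(u, lobes$swing$c, lobes$swing$w) -
              Q * hann_cumint(u, lobes$to$c, lobes$to$w) -
              R * (hann_cumint(u, lobes$load$c, lobes$load$w) +
                     hann_cumint(u, lobes$term$c, lobes$term$w)))
  }
  list(omega = omega, theta = theta, lobes = lobes)
}

#' Simulate ground-truth kinematics for a single stride
#'
#' World-frame ankle kinematics for one stride starting at the onset heel
#' strike (vertical position 0: the landing of the previous stride has
#' settled) and extending one landing fraction past the terminal heel strike,
#' so the vertical profile ends at `terminal_height` and then returns to 0 at
#' foot-flat.
#'
#' @param params a [stride_params()].
#' @param fs sampling rate (Hz).
#' @return list with `time` (s), `position` (n x 3: forward, lateral,
#'   vertical; m), `accel` (n x 3 world linear acceleration, m/s^2, the
#'   exact analytic second derivative of position), `pitch` (rad, 0),
#'   `yaw` (rad, 0), `events`
#'   (toe-off, max-clearance, terminal heel-strike, mid-stance times),
#'   `heel_strike_times`, and the generating `params`/geometry.
#' @export
simulate_stride_kinematics <- function(params, fs) {
  if (!inherits(params, "stride_params")) params <- do.call(stride_params, params)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  geom <- stride_geometry(params)
  Tdur <- params$stride_duration
  time <- seq(0, (1 + geom$lambda) * Tdur, by = 1 / fs)
  u <- time / Tdur
  in_stride <- u <= 1
  z <- numeric(length(u))
  z[in_stride] <- z_eval(u[in_stride], params, geom, h_prev = 0)
  z[!in_stride] <- z_eval(u[!in_stride] - 1, params, geom,
                          h_prev = params$terminal_height)
  x <- x_eval(pmin(u, 1), params, geom)
  pitch_model <- make_pitch_model(params, geom)
  pitch <- numeric(length(u))
  pitch[in_stride] <- pitch_model$theta(u[in_stride])
  pitch[!in_stride] <- pitch_model$theta(u[!in_stride] - 1)
  az <- numeric(length(u))
  az[in_stride] <- z_accel_eval(u[in_stride], params, geom, h_prev = 0)
  az[!in_stride] <- z_accel_eval(u[!in_stride] - 1, params, geom,
                                 h_prev = params$terminal_height)
  ax <- x_accel_eval(pmin(u, 1), params, geom)
  position <- cbind(forward = x, lateral = 0, vertical = z)
  list(
    time = time,
    position = position,
    accel = cbind(ax, 0, az),
    pitch = pitch,
    yaw = numeric(length(u)),
    fs = fs,
    params = params,
    geometry = geom,
    events = list(
      toe_off = geom$s * Tdur,
      max_clearance = geom$c * Tdur,
      terminal_heel_strike = Tdur,
      mid_stance = geom$u_ms * Tdur
    ),
    heel_strike_times = c(0, Tdur)
  )
}

#' Second-order central finite-difference acceleration
#' @noRd
fd_accel <- function(position, dt) {
  n <- nrow(position)
  a <- matrix(0, n, 3)
  if (n >= 3L) {
    a[2:(n - 1L), ] <- (position[3:n, ] - 2 * position[2:(n - 1L), ] +
                          position[1:(n - 2L), ]) / dt^2
    a[1L, ] <- a[2L, ]
    a[n, ] <- a[n - 1L, ]
  }
  a
}

#' Render world-frame kinematics into a sensor-frame IMU series
#'
#' The sensor-frame acceleration is the orientation-inverse of the world
#' linear acceleration plus gravity (magnitude 9.80665 m/s^2, pointing down);
#' the gyroscope is the discrete body rate consistent with the yaw/pitch
#' orientation sequence (rotation-vector logarithm of successive orientation
#' increments, so a first-order exponential integrator reproduces the
#' orientation exactly). Sensor imperfections are then applied: constant
#' biases, white noise, and a zero-mean windowed-sine transient in the
#' sagittal gyro channel at each heel strike.
#'
#' @param kinematics output of [simulate_stride_kinematics()] (or any list
#'   with `time`, `position`, `accel`, `pitch`, `yaw`, `heel_strike_times`).
#' @param noise a [sensor_noise()].
#' @param seed integer; fixing it fixes every output byte.
#' @param side which leg label to attach.
#' @param spec sensor spec; defaults to the kinematics sampling rate.
#' @return an [imu_series()].
#' @export
render_imu <- function(kinematics, noise = sensor_noise(), seed = 1,
                       side = "left", spec = NULL) {
  k <- kinematics
  n <- length(k$time)
  fs <- k$fs %||% (1 / stats::median(diff(k$time)))
  if (is.null(spec)) spec <- sensor_spec(sampling_rate = fs)
  g <- spec$gravity
  q <- quat_normalize(quat_yaw_pitch(k$yaw, k$pitch))
  gyro <- body_rates(q, 1 / fs)
  spec_acc <- sweep(k$accel, 2L, c(0, 0, g), `+`)
  accel <- quat_rotate(quat_conj(q), spec_acc)
  # Heel-strike transient: Ricker (Mexican-hat) wavelet, the second
  # derivative of a Gaussian. Symmetric, so the detected spike peak falls on
  # the true heel-strike instant; and because both its integral (net
  # rotation) and the integral of its integral (net velocity impulse after
  # gravity leakage) vanish, it does not bias the strapdown estimator.
  if (noise$hs_spike_amplitude > 0) {
    sigma <- noise$hs_spike_width / 3
    scales <- k$hs_spike_scale %||% rep(1, length(k$heel_strike_times))
    for (i in seq_along(k$heel_strike_times)) {
      t0 <- k$heel_strike_times[i]
      idx <- which(abs(k$time - t0) < noise$hs_spike_width)
      if (length(idx)) {
        u2 <- ((k$time[idx] - t0) / sigma)^2
        gyro[idx, 2] <- gyro[idx, 2] +
          scales[i] * noise$hs_spike_amplitude * (1 - 2 * u2) * exp(-u2)
      }
    }
  }
  with_seed(seed, {
    accel <- accel + matrix(stats::rnorm(3L * n, 0, noise$accel_noise_sd), n, 3)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, noise$gyro_noise_sd), n, 3)
  })
  accel <- sweep(accel, 2L, noise$accel_bias, `+`)
  gyro <- sweep(gyro, 2L, noise$gyro_bias, `+`)
  imu_series(side, k$time, accel, gyro, spec, validate = FALSE)
}

#' Discrete body rates from an orientation quaternion sequence
#'
#' omega_k = log(q_k^-1 * q_{k+1}) / dt, assigned to sample k (last sample
#' repeats). Vectorized quaternion product and logarithm.
#' @noRd
body_rates <- function(q, dt) {
  n <- nrow(q)
  if (n < 2L) return(matrix(0, n, 3))
  a <- quat_conj(q[-n, , drop = FALSE])
  b <- q[-1L, , drop = FALSE]
  dq <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  flip <- dq[, 1] < 0
  dq[flip, ] <- -dq[flip, ]
  s <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  th <- 2 * atan2(s, dq[, 1])
  fac <- ifelse(s < 1e-12, 2, th / s)
  omega <- dq[, 2:4, drop = FALSE] * fac / dt
  rbind(omega, omega[n - 1L, , drop = FALSE])
}
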