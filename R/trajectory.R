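# Stride-by-stride foot-trajectory estimation from shank IMU signals:
# spike-based heel-strike detection on the sagittal gyro, stride windowing
# anchored at the quasi-static mid-stance instant (minimum |pitch rate|),
# gravity-based orientation initialization, strapdown orientation propagation,
# rotation of acceleration to the world frame, and drift-cancelling
# forward/backward double integration under zero endpoint velocity and zero
# endpoint vertical position constraints.

#' Default estimation configuration
#'
#' @param segmentation `"midstance"` (default): integration windows run from
#'   one mid-stance to the next, where the foot is flat and static, so the
#'   zero endpoint constraints hold physically; each window contains one full
#'   swing, its terminal heel strike and the following support change.
#'   `"heelstrike"`: windows run heel strike to heel strike and the gravity
#'   anchor is searched inside the window.
#' @param band heel-strike detector pass band (Hz). The default sits above
#'   the locomotor band (< ~6 Hz), so the MAD threshold adapts to sensor
#'   noise and impact residue rather than to the gait waveform itself.
#' @param k_mad adaptive threshold multiplier (threshold = k_mad * MAD of the
#'   band-passed sagittal channel).
#' @param min_stride_time refractory period between heel strikes (s).
#' @param ms_window mid-stance search window as fractions of the stride.
#' @param accel_norm_tol relative tolerance on |accel| vs gravity at the
#'   anchor (quasi-static check).
#' @param weight forward/backward blending weight: `"linear"` ramp w(t) = t/T
#'   (cancels constant accelerometer bias exactly) or `"smoothstep"`.
#' @param min_displacement minimum net horizontal displacement (m) below
#'   which a stride is considered degenerate (standing or turning in place).
#' @param toe_off_method `"gyro"` (negative sagittal-gyro peak preceding the
#'   swing peak) or `"vertical_velocity"` (last negative-to-positive zero
#'   crossing of vertical velocity before the clearance peak).
#' @param support_change_convention see [detect_support_change()].
#' @param turn_axis_deg azimuth deviation from the corridor axis (degrees)
#'   beyond which a stride is flagged as a turn.
#' @param quota per-leg retained-stride quota for the selection protocol.
#' @export
estimation_config <- function(segmentation = c("midstance", "heelstrike"),
                              band = c(8, 25), k_mad = 4,
                              min_stride_time = 0.6,
                              ms_window = c(0.05, 0.5),
                              accel_norm_tol = 0.2,
                              weight = c("linear", "smoothstep"),
                              min_displacement = 1e-3,
                              toe_off_method = c("gyro", "vertical_velocity"),
                              support_change_convention =
                                c("contralateral_toe_off_after_terminal_hs",
                                  "terminal_heel_strike"),
                              turn_axis_deg = 30,
                              quota = 20,
                              despike_halfwidth = 0.10) {
  list(
    segmentation = match.arg(segmentation),
    band = band, k_mad = k_mad, min_stride_time = min_stride_time,
    ms_window = ms_window, accel_norm_tol = accel_norm_tol,
    weight = match.arg(weight), min_displacement = min_displacement,
    toe_off_method = match.arg(toe_off_method),
    support_change_convention = match.arg(support_change_convention),
    turn_axis_deg = turn_axis_deg, quota = quota,
    despike_halfwidth = despike_halfwidth
  )
}

#' Mask heel-strike impact transients in the gyroscope
#'
#' The impact spike that makes heel strikes detectable also corrupts
#' strapdown orientation integration (it is rotational noise, not shank
#' motion). After detection, every gyro channel is linearly interpolated
#' across +/- `halfwidth` seconds around each heel strike; the underlying
#' gait waveform is smooth there (late landing / early loading), so the
#' interpolation error is negligible.
#'
#' @param gyro n x 3 gyro matrix (rad/s).
#' @param heel_strikes heel-strike sample indices.
#' @param halfwidth mask half-width (s).
#' @param fs sampling rate (Hz).
#' @return gyro matrix with masked windows.
#' @export
despike_gyro <- function(gyro, heel_strikes, halfwidth, fs) {
  if (!length(heel_strikes) || halfwidth <= 0) return(gyro)
  n <- nrow(gyro)
  hw <- round(halfwidth * fs)
  for (h in heel_strikes) {
    lo <- max(1L, h - hw)
    hi <- min(n, h + hw)
    if (hi - lo < 2L) next
    span <- hi - lo
    w <- (seq(lo, hi) - lo) / span
    for (c in 1:3) {
      gyro[lo:hi, c] <- gyro[lo, c] * (1 - w) + gyro[hi, c] * w
    }
  }
  gyro
}

#' Detect heel strikes from the sagittal shank gyro
#'
#' Heel strikes appear as sharp transients ("spikes") superimposed on the
#' smooth gait waveform. The channel is zero-phase band-pass filtered, local
#' maxima of the absolute filtered signal above an adaptive threshold
#' (`k_mad` times the MAD) are collected, and a refractory rule keeps the
#' largest peak within any `min_stride_time` neighbourhood.
#'
#' @param gyro_sagittal numeric vector (rad/s).
#' @param fs sampling rate (Hz).
#' @param config an [estimation_config()].
#' @return strictly increasing integer sample indices (possibly empty).
#' @export
detect_heel_strikes <- function(gyro_sagittal, fs, config = estimation_config()) {
  n <- length(gyro_sagittal)
  if (n < 8L) return(integer(0))
  filt <- fft_bandpass(gyro_sagittal, fs, config$band)
  a <- abs(filt)
  thr <- config$k_mad * stats::mad(filt, center = 0)
  if (thr <= 0) return(integer(0))
  core <- 2:(n - 1L)
  peaks <- core[a[core] > thr & a[core] >= a[core - 1L] & a[core] > a[core + 1L]]
  if (!length(peaks)) return(integer(0))
  refractory <- round(config$min_stride_time * fs)
  keep <- logical(length(peaks))
  suppressed <- logical(length(peaks))
  for (i in order(a[peaks], decreasing = TRUE)) {
    if (suppressed[i]) next
    keep[i] <- TRUE
    suppressed[abs(peaks - peaks[i]) < refractory] <- TRUE
  }
  sort(peaks[keep])
}

#' Divide a series into stride windows
#'
#' With `segmentation = "midstance"` each window runs from the quasi-static
#' mid-stance instant following one heel strike to the one following the
#' next (the division at the steadiest shank instant, i.e. the lowest pitch
#' velocity); a leading anchor before the first heel strike is used when
#' enough samples precede it. With `"heelstrike"` the windows are the heel
#' strike intervals themselves. Either way each segment records the heel
#' strike it contains and its integration anchor (`mid_stance_index`, the
#' argmin of |pitch rate| over the configured stance search window).
#'
#' @param series an [imu_series()].
#' @param heel_strikes integer sample indices from [detect_heel_strikes()].
#' @param config an [estimation_config()].
#' @return list of `stride_segment` lists with fields `side`, `start`, `end`
#'   (half-open), `heel_strike_index`, `mid_stance_index`; empty if fewer
#'   than 2 heel strikes.
#' @export
segment_strides <- function(series, heel_strikes, config = estimation_config()) {
  h <- as.integer(heel_strikes)
  if (length(h) < 2L) return(list())
  gy <- series$gyro[, 2]
  n <- length(gy)
  w <- config$ms_window
  # Quasi-static score: |pitch rate| plus the gravity residual ||a| - g|.
  # The pure argmin-|pitch rate| criterion is ambiguous when the shank is
  # rotationally quiet while the foot is still landing; requiring the
  # accelerometer to read pure gravity as well pins the anchor to true
  # foot-flat, which is exactly the assumption the gravity alignment needs.
  grav_resid <- abs(sqrt(rowSums(series$accel^2)) - series$spec$gravity)
  # smooth the gravity residual (~120 ms) so an instantaneous zero crossing
  # of vertical acceleration mid-landing cannot masquerade as foot-flat
  k <- max(3L, 2L * round(0.06 * series$spec$sampling_rate) + 1L)
  grav_smooth <- stats::filter(grav_resid, rep(1 / k, k), sides = 2)
  grav_smooth[is.na(grav_smooth)] <- grav_resid[is.na(grav_smooth)]
  score <- abs(gy) + as.numeric(grav_smooth)
  # samples inside a heel-strike despike mask are artificially quiet and must
  # not win the steadiest-instant (mid-stance) search
  masked <- logical(n)
  hw <- round(config$despike_halfwidth * series$spec$sampling_rate)
  for (hh in h) masked[max(1L, hh - hw):min(n, hh + hw)] <- TRUE
  argmin_abs <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi <= lo) return(NA_integer_)
    cand <- lo:hi
    free <- cand[!masked[cand]]
    if (length(free)) cand <- free
    cand[which.min(score[cand])]
  }
  if (config$segmentation == "heelstrike") {
    segs <- lapply(seq_len(length(h) - 1L), function(k) {
      len <- h[k + 1L] - h[k]
      ms <- argmin_abs(h[k] + round(w[1] * len), h[k] + round(w[2] * len))
      list(side = series$side, start = h[k], end = h[k + 1L],
           heel_strike_index = h[k], mid_stance_index = ms,
           segmentation = "heelstrike")
    })
    return(segs)
  }
  # midstance mode: anchor after each heel strike, plus a leading anchor
  anchors <- integer(0)
  d1 <- h[2] - h[1]
  lead <- argmin_abs(h[1] - round(0.45 * d1), h[1] - round(0.05 * d1))
  if (!is.na(lead)) anchors <- lead
  for (k in seq_len(length(h) - 1L)) {
    len <- h[k + 1L] - h[k]
    ms <- argmin_abs(h[k] + round(w[1] * len), h[k] + round(w[2] * len))
    if (!is.na(ms)) anchors <- c(anchors, ms)
  }
  if (length(anchors) < 2L) return(list())
  segs <- list()
  for (j in seq_len(length(anchors) - 1L)) {
    inside <- h[h >= anchors[j] & h < anchors[j + 1L]]
    if (!length(inside)) next
    segs[[length(segs) + 1L]] <- list(
      side = series$side, start = anchors[j], end = anchors[j + 1L],
      heel_strike_index = inside[1], mid_stance_index = anchors[j],
      segmentation = "midstance"
    )
  }
  segs
}

#' Orientation from the gravity direction at a quasi-static instant
#'
#' Returns the sensor-to-world rotation (unit quaternion) that maps the
#' measured specific force to (0, 0, +g): the minimal rotation aligning the
#' measured gravity with world vertical, followed by the yaw that puts the
#' sensor sagittal (pitch) axis into the world lateral axis. Yaw is
#' unobservable from gravity; this convention makes the output deterministic
#' and is absorbed downstream by the net-displacement stride frame.
#'
#' @param accel_at_midstance length-3 specific force (m/s^2).
#' @param gravity gravity magnitude (m/s^2).
#' @param tol relative norm tolerance for the quasi-static check.
#' @return unit quaternion c(w, x, y, z).
#' @export
estimate_initial_orientation <- function(accel_at_midstance,
                                         gravity = GRAVITY, tol = 0.2) {
  a <- as.numeric(accel_at_midstance)
  nr <- sqrt(sum(a^2))
  if (nr < (1 - tol) * gravity || nr > (1 + tol) * gravity) {
    stop(sprintf(
      "not quasi-static: |accel| = %.3f m/s^2 outside [%.2f, %.2f]",
      nr, (1 - tol) * gravity, (1 + tol) * gravity
    ), call. = FALSE)
  }
  ahat <- a / nr
  ez <- c(0, 0, 1)
  d <- sum(ahat * ez)
  if (d > 1 - 1e-12) {
    q <- c(1, 0, 0, 0)
  } else if (d < -1 + 1e-12) {
    q <- c(0, 1, 0, 0) # 180 deg about x
  } else {
    axis <- cross3(ahat, ez)
    axis <- axis / sqrt(sum(axis^2))
    q <- quat_from_rotvec(axis * acos(d))
  }
  # yaw convention: sensor y (sagittal axis) -> world lateral (+y)
  v <- quat_rotate(q, c(0, 1, 0))
  if (sqrt(v[1]^2 + v[2]^2) > 1e-9) {
    delta <- pi / 2 - atan2(v[2], v[1])
    q <- quat_mul(quat_from_rotvec(c(0, 0, delta)), q)
  }
  quat_normalize(q)
}

#' Propagate orientation across a stride from the mid-stance anchor
#'
#' First-order rotation-vector exponential per step, integrated outward in
#' both time directions from the anchor, with per-sample renormalization.
#'
#' @param gyro n x 3 body rates (rad/s) over the stride window.
#' @param init unit quaternion at `anchor_index`.
#' @param anchor_index sample index (1-based, within the window) of the
#'   quasi-static anchor.
#' @param dt sample interval (s).
#' @return n x 4 matrix of unit quaternions (sensor -> world).
#' @export
propagate_orientation <- function(gyro, init, anchor_index, dt) {
  n <- nrow(gyro)
  q <- matrix(0, n, 4)
  q[anchor_index, ] <- init
  if (anchor_index < n) {
    for (k in anchor_index:(n - 1L)) {
      q[k + 1L, ] <- quat_normalize(
        quat_mul(q[k, ], quat_from_rotvec(gyro[k, ] * dt))
      )
    }
  }
  if (anchor_index > 1L) {
    for (k in anchor_index:2L) {
      q[k - 1L, ] <- quat_normalize(
        quat_mul(q[k, ], quat_from_rotvec(-gyro[k - 1L, ] * dt))
      )
    }
  }
  q
}

#' Rotate sensor acceleration to the world frame and remove gravity
#'
#' @param accel n x 3 sensor-frame specific force (m/s^2).
#' @param orientation n x 4 quaternions (sensor -> world).
#' @param gravity gravity magnitude (m/s^2).
#' @return n x 3 world linear acceleration.
#' @export
world_acceleration <- function(accel, orientation, gravity = GRAVITY) {
  stopifnot(nrow(accel) == nrow(orientation))
  sweep(quat_rotate(orientation, accel), 2L, c(0, 0, gravity), `-`)
}

#' Drift-cancelling double integration over one stride
#'
#' Velocity is the weighted average of a forward integration (zero initial
#' velocity) and a backward integration (zero final velocity):
#' v(t) = (1 - w(t)) v_f(t) + w(t) v_b(t). With the default linear ramp
#' w(t) = t/T a constant acceleration bias cancels exactly. Position
#' integrates the blended velocity from zero; the vertical channel is then
#' linearly detrended so the terminal vertical position is zero (the minimal
#' correction consistent with the zero-height assumption).
#'
#' @param world_accel n x 3 world linear acceleration over one stride.
#' @param fs sampling rate (Hz).
#' @param weight `"linear"` or `"smoothstep"`.
#' @return list with `time` (s from window start), `velocity`, `position`
#'   (n x 3 each).
#' @export
dedrift_integrate <- function(world_accel, fs, weight = "linear") {
  n <- nrow(world_accel)
  if (n < 4L) stop("stride too short to integrate (< 4 samples)", call. = FALSE)
  dt <- 1 / fs
  tt <- (seq_len(n) - 1L) * dt
  Tend <- tt[n]
  vf <- cumtrapz(world_accel, dt)
  w <- if (identical(weight, "smoothstep")) smoothstep3(tt / Tend) else tt / Tend
  # backward integration on a uniform grid equals vf(t) - vf(T)
  v <- vf - outer(w, vf[n, ])
  pos <- cumtrapz(v, dt)
  pos[, 3] <- pos[, 3] - tt / Tend * pos[n, 3]
  list(time = tt, velocity = v, position = pos)
}

#' Rotate a de-drifted trajectory into the stride frame
#'
#' The forward axis is the direction of net horizontal displacement over the
#' stride; lateral is the horizontal orthogonal; vertical is unchanged. The
#' resulting trajectory is invariant to the (unobservable) world yaw.
#'
#' @param integrated output of [dedrift_integrate()].
#' @param min_displacement degenerate-stride threshold (m).
#' @return `stride_trajectory`: list with `time`, `position`, `velocity`
#'   (columns forward/lateral/vertical) and `azimuth` (rad).
#' @export
rotate_to_stride_frame <- function(integrated, min_displacement = 1e-3) {
  pos <- integrated$position
  n <- nrow(pos)
  d <- pos[n, 1:2] - pos[1L, 1:2]
  if (sqrt(sum(d^2)) < min_displacement) {
    stop("degenerate stride: net horizontal displacement < threshold",
         call. = FALSE)
  }
  phi <- atan2(d[2], d[1])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- function(m) {
    out <- m
    out[, 1:2] <- m[, 1:2] %*% R
    colnames(out) <- c("forward", "lateral", "vertical")
    out
  }
  structure(
    list(time = integrated$time, position = rot(pos),
         velocity = rot(integrated$velocity), azimuth = phi),
    class = "stride_trajectory"
  )
}

#' Estimate per-stride foot trajectories for a whole session
#'
#' Composes heel-strike detection, stride windowing, gravity-anchored
#' orientation, world-frame rotation, and drift-cancelling integration,
#' independently per stride so that error cannot accumulate across strides.
#' Strides failing any stage are dropped and logged with a reason.
#'
#' @param session a [walk_session()].
#' @param config an [estimation_config()].
#' @return list with per-side lists of `list(segment, trajectory)` entries, a
#'   `dropped` data frame (side, stride ordinal, reason), and the `config`.
#' @export
estimate_trajectories <- function(session, config = estimation_config()) {
  out <- list(left = list(), right = list(),
              dropped = data.frame(side = character(), ordinal = integer(),
                                   reason = character(), stringsAsFactors = FALSE),
              config = config)
  fs <- session$spec$sampling_rate
  out$gyro_clean <- list()
  for (side in c("left", "right")) {
    series <- session[[side]]
    hs <- detect_heel_strikes(series$gyro[, 2], fs, config)
    series$gyro <- despike_gyro(series$gyro, hs, config$despike_halfwidth, fs)
    out$gyro_clean[[side]] <- series$gyro
    segs <- segment_strides(series, hs, config)
    entries <- list()
    for (j in seq_along(segs)) {
      seg <- segs[[j]]
      res <- tryCatch(
        estimate_one_stride(series, seg, fs, config),
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        out$dropped <- rbind(out$dropped, data.frame(
          side = side, ordinal = j, reason = res, stringsAsFactors = FALSE
        ))
      } else {
        entries[[length(entries) + 1L]] <- list(segment = seg, trajectory = res)
      }
    }
    out[[side]] <- entries
  }
  out
}

estimate_one_stride <- function(series, seg, fs, config) {
  idx <- seg$start:(seg$end - 1L)
  if (length(idx) < 4L) stop("stride window too short", call. = FALSE)
  if (is.na(seg$mid_stance_index)) stop("no mid-stance anchor", call. = FALSE)
  accel <- series$accel[idx, , drop = FALSE]
  gyro <- series$gyro[idx, , drop = FALSE]
  anchor <- seg$mid_stance_index - seg$start + 1L
  # a short average around the anchor tames white accelerometer noise
  a_win <- max(1L, anchor - 5L):min(length(idx), anchor + 5L)
  a_ms <- colMeans(accel[a_win, , drop = FALSE])
  q0 <- estimate_initial_orientation(a_ms, series$spec$gravity,
                                     tol = config$accel_norm_tol)
  q <- propagate_orientation(gyro, q0, anchor, 1 / fs)
  aw <- world_acceleration(accel, q, series$spec$gravity)
  integ <- dedrift_integrate(aw, fs, weight = config$weight)
  rotate_to_stride_frame(integ, config$min_displacement)
}
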