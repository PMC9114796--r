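# Whole-session and cohort simulation: back-and-forth corridor walking with
# alternating left/right half-cycle phase, direction-change (turn) strides,
# and a full ground-truth record (per-stride parameters, event times, flags,
# and the sampled world kinematics for round-trip oracles).

TURN_LENGTH_SCALE <- 0.45 # turn strides are short ...
TURN_HEIGHT_SCALE <- 0.70 # ... with reduced clearance
TURN_PITCH_SCALE <- 0.60  # ... and attenuated shank rotation

#' Simulate one participant's walking session
#'
#' Renders both legs of a corridor walk into sensor-frame IMU series with a
#' shared clock. Left and right legs are offset by half a stride cycle. Turn
#' strides at the configured per-leg indices reverse the walking heading over
#' the turn block, are rendered as short low-amplitude strides, and are
#' flagged in the ground truth.
#'
#' @param profile a [group_profile()].
#' @param spec a [cohort_spec()] (only `strides_per_leg`, `turn_indices` are
#'   used here).
#' @param noise a [sensor_noise()].
#' @param phase_offset right-leg phase lag in stride cycles (default 0.5).
#' @param seed integer seed; fixes every output byte.
#' @param participant_id id string stored in the session.
#' @param fs sampling rate (Hz).
#' @return list with `session` (a [walk_session()]) and `truth` (list with
#'   per-stride data frame `strides`, per-leg sampled kinematics, and the
#'   drawn subject-level parameters).
#' @export
simulate_session <- function(profile, spec = cohort_spec(),
                             noise = sensor_noise(), phase_offset = 0.5,
                             seed = 1, participant_id = "p01", fs = 100) {
  n_strides <- spec$strides_per_leg
  turn_idx <- spec$turn_indices
  with_seed(seed, {
    subject_centre <- draw_subject_centre(profile)
    leg_params <- lapply(c(left = "left", right = "right"), function(side) {
      lapply(seq_len(n_strides), function(j) {
        p <- draw_stride_params(subject_centre, profile$within_subject_sd)
        if (j %in% turn_idx) {
          p$stride_length <- p$stride_length * TURN_LENGTH_SCALE
          p$max_clearance <- p$max_clearance * TURN_HEIGHT_SCALE
          p$toe_off_height <- min(p$toe_off_height * TURN_HEIGHT_SCALE,
                                  p$max_clearance)
          p$terminal_height <- min(p$terminal_height * TURN_HEIGHT_SCALE,
                                   p$max_clearance)
        }
        p
      })
    })
    # bipedal timing is coupled: both legs share each stride's duration (the
    # right adds only a small jitter), so the half-cycle phase offset between
    # legs persists instead of drifting over the session
    for (j in seq_len(n_strides)) {
      leg_params$right[[j]]$stride_duration <-
        max(leg_params$left[[j]]$stride_duration + stats::rnorm(1L, 0, 0.01), 0.4)
    }
    noise_seeds <- stats::runif(2L, 1, 2^30)
  })
  headings <- stride_headings(n_strides, turn_idx)
  lead <- list(left = 1.5,
               right = 1.5 + phase_offset * subject_centre$stride_duration)
  legs <- list()
  for (side in c("left", "right")) {
    legs[[side]] <- build_leg_kinematics(
      leg_params[[side]], headings, lead[[side]], fs,
      turn_idx = turn_idx
    )
  }
  # common grid: pad the shorter leg with its final static pose
  t_end <- max(legs$left$time[length(legs$left$time)],
               legs$right$time[length(legs$right$time)])
  legs <- lapply(legs, extend_static, t_end = t_end, fs = fs)

  sensor <- sensor_spec(sampling_rate = fs)
  series <- list(
    left = render_imu(legs$left, noise, seed = floor(noise_seeds[1]),
                      side = "left", spec = sensor),
    right = render_imu(legs$right, noise, seed = floor(noise_seeds[2]),
                       side = "right", spec = sensor)
  )
  strides <- rbind(
    stride_truth_table("left", leg_params$left, legs$left, turn_idx),
    stride_truth_table("right", leg_params$right, legs$right, turn_idx)
  )
  strides <- add_support_change_truth(strides)
  session <- walk_session(participant_id, profile$group,
                          series$left, series$right, sensor)
  list(
    session = session,
    truth = list(
      strides = strides,
      kinematics = list(left = legs$left, right = legs$right),
      subject_centre = subject_centre,
      seed = seed
    )
  )
}

# Heading (rad) per stride: 0 for the first bout, pi after an odd number of
# turn blocks; turn strides interpolate across their block.
stride_headings <- function(n_strides, turn_idx) {
  psi <- numeric(n_strides)
  if (!length(turn_idx)) return(psi)
  blocks <- split(turn_idx, cumsum(c(1, diff(turn_idx) != 1)))
  current <- 0
  for (b in blocks) {
    target <- current + pi
    m <- length(b)
    psi[b] <- current + seq_len(m) / (m + 1) * pi
    if (max(b) < n_strides) psi[(max(b) + 1):n_strides] <- target
    current <- target
  }
  psi
}

#' Build one leg's sampled world kinematics from per-stride parameters
#' @noRd
build_leg_kinematics <- function(params_list, headings, lead, fs, turn_idx) {
  n_strides <- length(params_list)
  geoms <- lapply(params_list, stride_geometry)
  durations <- vapply(params_list, `[[`, numeric(1), "stride_duration")
  hs_times <- lead + c(0, cumsum(durations)) # heel strikes t_0 .. t_N
  tail_land <- geoms[[n_strides]]$lambda * durations[n_strides]
  t_total <- hs_times[n_strides + 1L] + tail_land + 1.0
  time <- seq(0, t_total, by = 1 / fs)
  n <- length(time)
  z <- numeric(n)
  az <- numeric(n)
  pitch <- numeric(n)
  yaw <- numeric(n)
  pos_xy <- matrix(0, n, 2)
  acc_xy <- matrix(0, n, 2)
  # cumulative world xy at each stride onset
  origins <- matrix(0, n_strides + 1L, 2)
  for (j in seq_len(n_strides)) {
    dir <- c(cos(headings[j]), sin(headings[j]))
    origins[j + 1L, ] <- origins[j, ] + params_list[[j]]$stride_length * dir
  }
  pitch_models <- lapply(seq_len(n_strides), function(j) {
    make_pitch_model(params_list[[j]], geoms[[j]],
                     scale = if (j %in% turn_idx) TURN_PITCH_SCALE else 1)
  })
  stride_of <- findInterval(time, hs_times) # 0 = lead-in, N+1 = tail
  psi_prev_all <- c(headings[1], headings)
  for (j in seq_len(n_strides)) {
    idx <- which(stride_of == j)
    if (!length(idx)) next
    p <- params_list[[j]]; geom <- geoms[[j]]
    u <- (time[idx] - hs_times[j]) / p$stride_duration
    h_prev <- if (j == 1L) 0 else params_list[[j - 1L]]$terminal_height
    z[idx] <- z_eval(u, p, geom, h_prev = h_prev)
    az[idx] <- z_accel_eval(u, p, geom, h_prev = h_prev)
    xl <- x_eval(u, p, geom)
    axl <- x_accel_eval(u, p, geom)
    dir <- c(cos(headings[j]), sin(headings[j]))
    pos_xy[idx, ] <- matrix(origins[j, ], length(idx), 2, byrow = TRUE) +
      outer(xl, dir)
    acc_xy[idx, ] <- outer(axl, dir)
    pitch[idx] <- pitch_models[[j]]$theta(u)
    # yaw ramps smoothly across most of the stride (the ankle path heading
    # is set per stride; the shank simply pivots towards it), keeping yaw
    # rates within the gyroscope range
    psi0 <- psi_prev_all[j]; psi1 <- headings[j]
    if (abs(psi1 - psi0) > 1e-12) {
      ramp <- smoothstep3((u - geom$lambda) / (0.9 - geom$lambda))
      yaw[idx] <- psi0 + ramp * (psi1 - psi0)
    } else {
      yaw[idx] <- psi1
    }
  }
  # lead-in: quiet standing at the first stride's onset pose
  idx <- which(stride_of == 0L)
  if (length(idx)) yaw[idx] <- headings[1]
  # tail: landing of the final heel strike, then quiet standing
  idx <- which(stride_of == n_strides + 1L)
  if (length(idx)) {
    pN <- params_list[[n_strides]]; geomN <- geoms[[n_strides]]
    u <- pmin((time[idx] - hs_times[n_strides + 1L]) / pN$stride_duration,
              geomN$lambda)
    z[idx] <- z_eval(u, pN, geomN, h_prev = pN$terminal_height)
    az[idx] <- ifelse(u < geomN$lambda,
                      z_accel_eval(u, pN, geomN, h_prev = pN$terminal_height),
                      0)
    pos_xy[idx, ] <- matrix(origins[n_strides + 1L, ], length(idx), 2, byrow = TRUE)
    pitch[idx] <- pitch_models[[n_strides]]$theta(u)
    yaw[idx] <- headings[n_strides]
  }
  position <- cbind(pos_xy[, 1], pos_xy[, 2], z)
  colnames(position) <- c("x", "y", "z")
  # heel-strike impact intensity scales with walking speed; the transient at
  # heel strike i terminates stride i (index i+1 in hs_times)
  speeds <- vapply(params_list, function(p) p$stride_length / p$stride_duration,
                   numeric(1))
  spike_scale <- pmin(pmax(c(speeds[1], speeds) / 1.25, 0.7), 1.5)
  list(
    time = time, position = position, accel = cbind(acc_xy, az),
    hs_spike_scale = spike_scale,
    pitch = pitch, yaw = yaw, fs = fs,
    heel_strike_times = hs_times,
    geoms = geoms, durations = durations, origins = origins
  )
}

extend_static <- function(leg, t_end, fs) {
  last <- length(leg$time)
  if (leg$time[last] >= t_end - 1e-9) return(leg)
  extra <- seq(leg$time[last] + 1 / fs, t_end, by = 1 / fs)
  m <- length(extra)
  leg$time <- c(leg$time, extra)
  leg$position <- rbind(leg$position,
                        matrix(leg$position[last, ], m, 3, byrow = TRUE))
  leg$accel <- rbind(leg$accel, matrix(0, m, 3))
  leg$pitch <- c(leg$pitch, rep(leg$pitch[last], m))
  leg$yaw <- c(leg$yaw, rep(leg$yaw[last], m))
  leg
}

#' Per-stride ground-truth rows for one leg
#' @noRd
stride_truth_table <- function(side, params_list, leg, turn_idx) {
  n_strides <- length(params_list)
  rows <- lapply(seq_len(n_strides), function(j) {
    p <- params_list[[j]]; geom <- leg$geoms[[j]]
    t0 <- leg$heel_strike_times[j]
    Tdur <- p$stride_duration
    data.frame(
      side = side, stride = j,
      onset_hs = t0, terminal_hs = t0 + Tdur,
      toe_off = t0 + geom$s * Tdur,
      max_clearance = t0 + geom$c * Tdur,
      mid_stance = t0 + geom$u_ms * Tdur,
      support_change = NA_real_,
      stride_length = p$stride_length,
      stride_duration = Tdur,
      F1 = x_eval(geom$s, p, geom),
      F2 = x_eval(geom$c, p, geom),
      F3 = p$stride_length,
      V1 = z_eval(geom$s, p, geom),
      V2 = p$max_clearance,
      V3 = NA_real_,
      terminal_height = p$terminal_height,
      turn = j %in% turn_idx,
      initial = FALSE, final = FALSE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$initial <- out$stride <= 5
  out$final <- out$stride > n_strides - 5
  out
}

# Fill support-change times (first contralateral toe-off after the terminal
# heel strike) and the vertical displacement V3 at that instant. The ankle is
# still descending through its landing arc there, so V3 sits between 0 and
# terminal_height.
add_support_change_truth <- function(strides) {
  for (side in c("left", "right")) {
    other <- setdiff(c("left", "right"), side)
    contra_to <- sort(strides$toe_off[strides$side == other])
    rows <- which(strides$side == side)
    for (i in rows) {
      hs_end <- strides$terminal_hs[i]
      after <- contra_to[contra_to > hs_end]
      if (!length(after)) next
      sc <- after[1]
      strides$support_change[i] <- sc
      # landing arc of the *next* cycle carries this stride's terminal height
      j <- strides$stride[i]
      nxt <- which(strides$side == side & strides$stride == j + 1L)
      lambda_T <- if (length(nxt)) {
        0.25 * strides$stride_duration[nxt] # LANDING_FRACTION default
      } else {
        0.25 * strides$stride_duration[i]
      }
      frac <- (sc - hs_end) / lambda_T
      strides$V3[i] <- if (frac >= 1) 0 else
        strides$terminal_height[i] * (1 + cos(pi * frac)) / 2
    }
  }
  strides
}

#' Simulate a multi-group cohort
#'
#' One session per participant, with per-participant seeds derived from the
#' cohort seed. Also computes the ground-truth feature table: per-participant
#' means of the analytic F1-F3/V1-V3 over the strides the selection protocol
#' retains (initial/final five and turn strides excluded, per-leg quota).
#'
#' @param profiles named list of [group_profile()] (e.g.
#'   [make_default_profiles()]).
#' @param spec a [cohort_spec()]; `spec$counts` names must exist in
#'   `profiles`.
#' @param noise a [sensor_noise()].
#' @param quota per-leg retained-stride quota for the truth feature table.
#' @param fs sampling rate (Hz).
#' @return list with `sessions` (list of simulate_session outputs) and
#'   `truth_features` (data frame participant_id, group, F1..V3).
#' @export
simulate_cohort <- function(profiles, spec = cohort_spec(),
                            noise = sensor_noise(), quota = 20, fs = 100) {
  sessions <- list()
  truth_rows <- list()
  i <- 0L
  for (grp in names(spec$counts)) {
    cnt <- spec$counts[[grp]]
    if (cnt == 0) next
    if (is.null(profiles[[grp]])) stop("no profile for group ", grp, call. = FALSE)
    for (k in seq_len(cnt)) {
      i <- i + 1L
      pid <- sprintf("%s_%02d", grp, k)
      sim <- simulate_session(
        profiles[[grp]], spec, noise,
        seed = spec$seed + 7919L * i, participant_id = pid, fs = fs
      )
      sessions[[pid]] <- sim
      truth_rows[[pid]] <- true_participant_features(sim, quota = quota)
    }
  }
  truth_features <- do.call(rbind, truth_rows)
  list(sessions = sessions, truth_features = truth_features)
}

#' Ground-truth participant-mean features from a simulated session
#' @noRd
true_participant_features <- function(sim, quota = 20) {
  st <- sim$truth$strides
  sel <- select_strides(data.frame(
    side = st$side, stride = st$stride,
    initial = st$initial, final = st$final,
    turn = st$turn, failed = !is.finite(st$V3)
  ), quota = quota, warn = FALSE)
  keep <- st[sel$selected, c("F1", "F2", "F3", "V1", "V2", "V3")]
  out <- as.data.frame(as.list(colMeans(keep)))
  out$participant_id <- sim$session$participant_id
  out$group <- sim$session$group
  out$n_strides <- nrow(keep)
  out[, c("participant_id", "group", "F1", "F2", "F3", "V1", "V2", "V3", "n_strides")]
}
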