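# Parameter types for the synthetic gait generator, and the default group
# profiles. The defaults encode the qualitative group orderings reported for
# the four cohorts (mild PD, advanced PD, healthy older, healthy young):
# forward extent ordered young > older > mild > advanced, vertical
# displacements ordered mild > young > older > advanced. Absolute magnitudes
# are plausible adult-gait values (ankle-point kinematics), not measurements.

STRIDE_PARAM_FIELDS <- c(
  "stride_length", "max_clearance", "toe_off_height", "terminal_height",
  "stride_duration", "stance_fraction", "clearance_phase"
)

#' Ground-truth stride parameters
#'
#' @param stride_length forward extent of one stride (m).
#' @param max_clearance peak ankle height above foot-flat level during swing (m).
#' @param toe_off_height ankle height at toe-off (m).
#' @param terminal_height ankle height at the terminal heel strike, relative to
#'   the foot-flat (mid-stance) level (m).
#' @param stride_duration heel-strike to heel-strike duration (s).
#' @param stance_fraction fraction of the stride spent in stance (toe-off
#'   phase), in (0, 1).
#' @param clearance_phase stride fraction at which the vertical peak occurs,
#'   in (stance_fraction, 1).
#' @return object of class `stride_params`.
#' @export
stride_params <- function(stride_length, max_clearance, toe_off_height,
                          terminal_height, stride_duration,
                          stance_fraction = 0.62, clearance_phase = 0.76) {
  p <- list(
    stride_length = stride_length, max_clearance = max_clearance,
    toe_off_height = toe_off_height, terminal_height = terminal_height,
    stride_duration = stride_duration, stance_fraction = stance_fraction,
    clearance_phase = clearance_phase
  )
  problems <- validate_stride_params(p)
  if (length(problems)) {
    stop("invalid stride_params: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(p, class = "stride_params")
}

validate_stride_params <- function(p) {
  out <- character(0)
  for (f in c("stride_length", "max_clearance", "toe_off_height", "terminal_height")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) out <- c(out, sprintf("%s must be >= 0", f))
  }
  if (!is.finite(p$stride_duration) || p$stride_duration <= 0) {
    out <- c(out, "stride_duration must be > 0")
  }
  if (!(p$stance_fraction > 0 && p$stance_fraction < p$clearance_phase &&
        p$clearance_phase < 1)) {
    out <- c(out, "need 0 < stance_fraction < clearance_phase < 1")
  }
  if (is.finite(p$max_clearance) &&
      p$max_clearance < max(p$toe_off_height, p$terminal_height) - 1e-12) {
    out <- c(out, "max_clearance must be >= max(toe_off_height, terminal_height)")
  }
  out
}

#' Per-field variability with the same shape as [stride_params()]
#'
#' Unlike [stride_params()] these are standard deviations, so the only
#' requirement is non-negativity.
#' @param ... named numeric fields; unnamed fields default to 0.
#' @export
stride_params_sd <- function(stride_length = 0, max_clearance = 0,
                             toe_off_height = 0, terminal_height = 0,
                             stride_duration = 0, stance_fraction = 0,
                             clearance_phase = 0) {
  p <- list(
    stride_length = stride_length, max_clearance = max_clearance,
    toe_off_height = toe_off_height, terminal_height = terminal_height,
    stride_duration = stride_duration, stance_fraction = stance_fraction,
    clearance_phase = clearance_phase
  )
  if (any(!vapply(p, is.finite, logical(1))) || any(unlist(p) < 0)) {
    stop("all spread fields must be finite and >= 0", call. = FALSE)
  }
  structure(p, class = "stride_params_sd")
}

#' A group-level gait profile
#'
#' @param group group label.
#' @param mean a [stride_params()] of group-mean values.
#' @param between_subject_sd,within_subject_sd [stride_params_sd()] spreads:
#'   between-subject variation is drawn once per participant, within-subject
#'   variation once per stride.
#' @export
group_profile <- function(group, mean, between_subject_sd, within_subject_sd) {
  stopifnot(inherits(mean, "stride_params"))
  structure(
    list(group = group, mean = mean,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd),
    class = "group_profile"
  )
}

#' Sensor imperfection model
#'
#' @param accel_noise_sd white-noise SD per accelerometer axis (m/s^2).
#' @param gyro_noise_sd white-noise SD per gyroscope axis (rad/s).
#' @param accel_bias length-3 constant accelerometer bias (m/s^2).
#' @param gyro_bias length-3 constant gyroscope bias (rad/s).
#' @param hs_spike_amplitude amplitude of the heel-strike transient injected
#'   into the sagittal gyro channel (rad/s). The transient is a Ricker
#'   (Mexican-hat) wavelet: symmetric about the heel-strike instant, zero
#'   net rotation, zero net velocity impulse.
#' @param hs_spike_width duration of the transient (s).
#' @export
sensor_noise <- function(accel_noise_sd = 0.08, gyro_noise_sd = 0.02,
                         accel_bias = c(0.02, -0.015, 0.01),
                         gyro_bias = c(0.002, -0.001, 0.0015),
                         hs_spike_amplitude = 10, hs_spike_width = 0.06) {
  stopifnot(accel_noise_sd >= 0, gyro_noise_sd >= 0, hs_spike_width > 0,
            length(accel_bias) == 3L, length(gyro_bias) == 3L)
  structure(
    list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
         accel_bias = accel_bias, gyro_bias = gyro_bias,
         hs_spike_amplitude = hs_spike_amplitude,
         hs_spike_width = hs_spike_width),
    class = "sensor_noise"
  )
}

#' Zero-imperfection sensor model (useful for round-trip oracles)
#'
#' No noise and no bias. The heel-strike transient is kept by default: it is
#' a deliberate signal feature the event detector relies on, and being a
#' zero-mean wavelet it carries no net rotation, so it does not perturb the
#' integration oracle.
#' @param hs_spike_amplitude set to 0 to silence the heel-strike transient.
#' @export
sensor_noise_none <- function(hs_spike_amplitude = 10) {
  sensor_noise(0, 0, c(0, 0, 0), c(0, 0, 0), hs_spike_amplitude, 0.06)
}

#' Cohort / session specification
#'
#' @param counts named integer vector of participants per group (names drawn
#'   from `mild_pd`, `advanced_pd`, `healthy_older`, `healthy_young`).
#' @param strides_per_session total strides per session over both legs (> 60
#'   when emulating the corridor protocol; default 72 = 36 per leg).
#' @param turn_indices per-leg stride indices rendered and flagged as
#'   direction-change strides; `NULL` picks a single mid-session turn of two
#'   strides.
#' @param seed integer seed controlling every random draw.
#' @export
cohort_spec <- function(counts = c(mild_pd = 2, advanced_pd = 2,
                                   healthy_older = 2, healthy_young = 2),
                        strides_per_session = 72, turn_indices = NULL,
                        seed = 1) {
  if (any(counts < 0)) stop("participant counts must be >= 0", call. = FALSE)
  if (strides_per_session %% 2 != 0) {
    stop("strides_per_session must be even (both legs stride)", call. = FALSE)
  }
  per_leg <- strides_per_session / 2
  if (is.null(turn_indices)) {
    mid <- floor(per_leg / 2)
    turn_indices <- c(mid, mid + 1L)
  }
  if (length(turn_indices) && (min(turn_indices) < 1 || max(turn_indices) > per_leg)) {
    stop("turn_indices out of range", call. = FALSE)
  }
  structure(
    list(counts = counts, strides_per_session = strides_per_session,
         strides_per_leg = per_leg, turn_indices = sort(unique(turn_indices)),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default group profiles
#'
#' Means realize the reported group orderings: forward extent (stride length,
#' hence F1-F3) young > older > mild PD > advanced PD; vertical displacements
#' (toe-off height, maximum clearance, terminal height, hence V1-V3) mild PD >
#' young > older > advanced PD. Magnitudes are typical ankle-point values for
#' adult corridor walking.
#'
#' @return named list of [group_profile()] objects.
#' @export
make_default_profiles <- function() {
  bsd <- stride_params_sd(
    stride_length = 0.15, max_clearance = 0.023, toe_off_height = 0.014,
    terminal_height = 0.007, stride_duration = 0.07,
    stance_fraction = 0.004, clearance_phase = 0.004
  )
  wsd <- stride_params_sd(
    stride_length = 0.03, max_clearance = 0.006, toe_off_height = 0.005,
    terminal_height = 0.003, stride_duration = 0.04,
    stance_fraction = 0.008, clearance_phase = 0.008
  )
  mk <- function(group, L, hmc, hto, hterm, Tdur, s) {
    group_profile(
      group,
      stride_params(
        stride_length = L, max_clearance = hmc, toe_off_height = hto,
        terminal_height = hterm, stride_duration = Tdur,
        stance_fraction = s, clearance_phase = 0.76
      ),
      bsd, wsd
    )
  }
  list(
    mild_pd       = mk("mild_pd",       1.08, 0.170, 0.098, 0.062, 1.15, 0.63),
    advanced_pd   = mk("advanced_pd",   0.94, 0.094, 0.048, 0.029, 1.25, 0.65),
    healthy_older = mk("healthy_older", 1.24, 0.110, 0.058, 0.034, 1.05, 0.62),
    healthy_young = mk("healthy_young", 1.38, 0.128, 0.068, 0.041, 1.00, 0.60)
  )
}

#' Analytic subject-level feature table (no sensor simulation)
#'
#' Draws subject-level stride parameters from each group profile and reads
#' the six features straight off the closed-form stride geometry: the
#' population the IMU pipeline estimates, without rendering or estimation
#' noise. Used for distribution-level checks (PCA block structure, component
#' retention) where large cohorts would make full sensor simulation
#' needlessly slow. V3 is evaluated at the nominal support-change instant
#' (half-way down the landing arc).
#'
#' @param profiles named list of [group_profile()].
#' @param n participants per group.
#' @param seed integer seed.
#' @return `feature_table` data frame (participant_id, group, F1..V3).
#' @export
simulate_truth_features <- function(profiles = make_default_profiles(),
                                    n = 25, seed = 1) {
  rows <- with_seed(seed, {
    out <- list()
    for (g in names(profiles)) {
      for (i in seq_len(n)) {
        sc <- draw_subject_centre(profiles[[g]])
        geom <- stride_geometry(sc)
        out[[length(out) + 1L]] <- data.frame(
          participant_id = sprintf("%s_%03d", g, i), group = g,
          F1 = x_eval(geom$s, sc, geom),
          F2 = x_eval(geom$c, sc, geom),
          F3 = sc$stride_length,
          V1 = z_eval(geom$s, sc, geom),
          V2 = sc$max_clearance,
          V3 = sc$terminal_height / 2,
          stringsAsFactors = FALSE
        )
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("feature_table", class(tab))
  tab
}

VERTICAL_SCALE_SD <- 0.04 # per-subject coherent scaling of all three heights

#' Draw a subject's central stride parameters
#'
#' Between-subject variation is structured: stride length, duration and the
#' phase parameters vary independently, while the three height parameters
#' share a common per-subject scale factor (people who lift the foot higher
#' do so at toe-off, mid-swing and landing alike) plus small independent
#' jitter. This is what gives the feature table its two-block
#' (forward/vertical) correlation structure.
#' @noRd
draw_subject_centre <- function(profile) {
  centre <- profile$mean
  sd <- profile$between_subject_sd
  draw <- list(
    stride_length = centre$stride_length + stats::rnorm(1L, 0, sd$stride_length),
    stride_duration = centre$stride_duration + stats::rnorm(1L, 0, sd$stride_duration),
    stance_fraction = centre$stance_fraction + stats::rnorm(1L, 0, sd$stance_fraction),
    clearance_phase = centre$clearance_phase + stats::rnorm(1L, 0, sd$clearance_phase)
  )
  vfac <- 1 + VERTICAL_SCALE_SD * stats::rnorm(1L)
  for (f in c("max_clearance", "toe_off_height", "terminal_height")) {
    draw[[f]] <- centre[[f]] * vfac + stats::rnorm(1L, 0, sd[[f]])
  }
  clamp_stride_params(draw)
}

#' Draw stride parameters around a centre with clamping to the valid domain
#' @noRd
draw_stride_params <- function(centre, sd) {
  draw <- lapply(STRIDE_PARAM_FIELDS, function(f) {
    centre[[f]] + stats::rnorm(1L, 0, sd[[f]])
  })
  names(draw) <- STRIDE_PARAM_FIELDS
  clamp_stride_params(draw)
}

clamp_stride_params <- function(draw) {
  # clamp into the valid domain rather than reject, to keep the draw count
  # deterministic for a given seed
  draw$stride_length <- max(draw$stride_length, 0.05)
  draw$stride_duration <- max(draw$stride_duration, 0.4)
  draw$stance_fraction <- min(max(draw$stance_fraction, 0.45), 0.72)
  draw$clearance_phase <- min(max(draw$clearance_phase, draw$stance_fraction + 0.05), 0.95)
  draw$toe_off_height <- max(draw$toe_off_height, 0.003)
  draw$terminal_height <- max(draw$terminal_height, 0.003)
  draw$max_clearance <- max(draw$max_clearance,
                            max(draw$toe_off_height, draw$terminal_height) + 0.01)
  do.call(stride_params, draw)
}
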