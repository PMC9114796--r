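# In-stride event detection (toe-off, maximum clearance, change of supporting
# leg), the six spatial features F1-F3/V1-V3, the stride-selection protocol
# (drop initial/final five and direction-change strides, keep 20 per leg),
# and aggregation to one feature vector per participant.

#' Detect toe-off within a stride
#'
#' Default method `"gyro"`: the most negative sagittal gyro sample in the
#' window preceding the swing-phase positive peak (the standard shank-gyro
#' toe-off signature). Alternative `"vertical_velocity"`: the last
#' negative-to-positive zero crossing of vertical velocity before the
#' clearance peak (onset of sustained foot lift; note this marks lift onset,
#' at which the vertical displacement is still ~0).
#'
#' @param trajectory a `stride_trajectory`.
#' @param gyro_sagittal sagittal gyro slice over the same window (rad/s);
#'   required for the `"gyro"` method.
#' @param method detector choice.
#' @param search_back fraction-of-window length searched before the swing
#'   peak (gyro method).
#' @return toe-off time (s, relative to the window start), or `NA_real_` if
#'   no lift is detected (stride should be flagged failed).
#' @export
detect_toe_off <- function(trajectory, gyro_sagittal = NULL,
                           method = c("gyro", "vertical_velocity"),
                           search_back = 0.3) {
  method <- match.arg(method)
  tt <- trajectory$time
  if (method == "gyro") {
    if (is.null(gyro_sagittal)) stop("gyro slice required for method 'gyro'",
                                     call. = FALSE)
    peak <- which.max(gyro_sagittal)
    span <- tt[length(tt)] - tt[1]
    lo <- which(tt >= tt[peak] - search_back * span)[1]
    if (is.na(lo) || lo >= peak) return(NA_real_)
    seg <- lo:peak
    cand <- seg[which.min(gyro_sagittal[seg])]
    if (gyro_sagittal[cand] >= 0) return(NA_real_)
    return(tt[cand])
  }
  z <- trajectory$position[, "vertical"]
  vz <- trajectory$velocity[, "vertical"]
  mc <- which.max(z)
  if (mc < 3L || max(z) <= 1e-4) return(NA_real_)
  sgn <- sign(vz[1:mc])
  crossings <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0)
  if (!length(crossings)) return(NA_real_)
  k <- crossings[length(crossings)]
  # linear interpolation of the crossing instant
  if (vz[k + 1L] == vz[k]) return(tt[k])
  tt[k] + (0 - vz[k]) / (vz[k + 1L] - vz[k]) * (tt[k + 1L] - tt[k])
}

#' Detect the maximum-clearance instant
#'
#' Argmax of the vertical channel over the swing (after toe-off when known);
#' ties broken by the earliest sample.
#'
#' @param trajectory a `stride_trajectory`.
#' @param after_t only consider samples at or after this time (s); usually
#'   the toe-off time.
#' @return time of the vertical maximum (s, relative to window start).
#' @export
detect_max_clearance <- function(trajectory, after_t = NULL) {
  tt <- trajectory$time
  z <- trajectory$position[, "vertical"]
  keep <- if (is.null(after_t)) seq_along(tt) else which(tt >= after_t)
  if (!length(keep)) keep <- seq_along(tt)
  tt[keep[which.max(z[keep])]]
}

#' Detect the change-of-supporting-leg instant
#'
#' Default convention `"contralateral_toe_off_after_terminal_hs"`: the first
#' contralateral toe-off following this stride's terminal heel strike,
#' clamped to the stride window. Fallback convention
#' `"terminal_heel_strike"` (also used when no qualifying contralateral event
#' exists): the terminal heel strike instant itself. The convention actually
#' applied is recorded in the result.
#'
#' @param terminal_hs_t terminal heel-strike time (absolute, s).
#' @param contra_toe_off_times absolute contralateral toe-off times (s); may
#'   be empty.
#' @param window_end_t absolute end time of the stride window (s).
#' @param convention requested convention.
#' @return list with `time` (absolute, s) and `convention` (applied).
#' @export
detect_support_change <- function(terminal_hs_t, contra_toe_off_times = numeric(0),
                                  window_end_t = Inf,
                                  convention =
                                    c("contralateral_toe_off_after_terminal_hs",
                                      "terminal_heel_strike")) {
  convention <- match.arg(convention)
  if (convention == "contralateral_toe_off_after_terminal_hs") {
    after <- contra_toe_off_times[contra_toe_off_times > terminal_hs_t]
    if (length(after)) {
      return(list(time = min(min(after), window_end_t),
                  convention = "contralateral_toe_off_after_terminal_hs"))
    }
  }
  list(time = terminal_hs_t, convention = "terminal_heel_strike")
}

#' Extract the six spatial features from a stride trajectory
#'
#' F_i and V_i are the forward and vertical displacements from the stride
#' origin (the onset heel strike reference) to toe-off (1), maximum
#' clearance (2), and change of supporting leg (3), read off the trajectory
#' with linear interpolation between samples.
#'
#' @param trajectory a `stride_trajectory`.
#' @param events list with `toe_off_t`, `max_clearance_t`, `support_change_t`
#'   (s, relative to the window start) and optionally `heel_strike_t`
#'   (reference instant, default 0 = window origin).
#' @return named numeric vector F1, F2, F3, V1, V2, V3 (m).
#' @export
extract_features <- function(trajectory, events) {
  tt <- trajectory$time
  hs <- events$heel_strike_t %||% 0
  ev <- c(events$toe_off_t, events$max_clearance_t, events$support_change_t)
  if (anyNA(ev) || any(ev < tt[1] - 1e-9) || any(ev > tt[length(tt)] + 1e-9) ||
      hs < tt[1] - 1e-9 || hs > tt[length(tt)] + 1e-9) {
    stop("event times outside the stride window", call. = FALSE)
  }
  fw <- trajectory$position[, "forward"]
  vt <- trajectory$position[, "vertical"]
  f0 <- interp_at(tt, fw, hs)
  v0 <- interp_at(tt, vt, hs)
  c(
    F1 = interp_at(tt, fw, ev[1]) - f0,
    F2 = interp_at(tt, fw, ev[2]) - f0,
    F3 = interp_at(tt, fw, ev[3]) - f0,
    V1 = interp_at(tt, vt, ev[1]) - v0,
    V2 = interp_at(tt, vt, ev[2]) - v0,
    V3 = interp_at(tt, vt, ev[3]) - v0
  )
}

#' Apply the stride-selection protocol
#'
#' Per leg (ordered strides): drop the first `n_edge` and last `n_edge`
#' strides, drop turn-flagged and failed strides, then keep the first
#' `quota` remaining. If fewer than `quota` remain, all remaining strides
#' are kept and a shortfall warning is emitted (never silently padded).
#'
#' @param strides data frame with columns `side`, `stride` (per-leg temporal
#'   order), `turn`, `failed` (logicals).
#' @param quota per-leg quota (default 20).
#' @param n_edge number of initial and final strides excluded (default 5).
#' @param warn emit shortfall warnings.
#' @return the input with added logical columns `initial`, `final`,
#'   `selected`, plus attribute `retained` (named per-side counts).
#' @export
select_strides <- function(strides, quota = 20, n_edge = 5, warn = TRUE) {
  stopifnot(all(c("side", "stride", "turn", "failed") %in% names(strides)))
  strides$initial <- FALSE
  strides$final <- FALSE
  strides$selected <- FALSE
  retained <- c()
  for (side in unique(strides$side)) {
    rows <- which(strides$side == side)
    rows <- rows[order(strides$stride[rows])]
    k <- length(rows)
    ranks <- seq_len(k)
    strides$initial[rows] <- ranks <= n_edge
    strides$final[rows] <- ranks > k - n_edge
    eligible <- rows[!strides$initial[rows] & !strides$final[rows] &
                       !strides$turn[rows] & !strides$failed[rows]]
    keep <- utils::head(eligible, quota)
    strides$selected[keep] <- TRUE
    retained[side] <- length(keep)
    if (warn && length(keep) < quota) {
      warning(sprintf("side %s: only %d strides available (quota %d)",
                      side, length(keep), quota), call. = FALSE)
    }
  }
  attr(strides, "retained") <- retained
  strides
}

#' Aggregate per-stride features to one participant row
#'
#' @param stride_features data frame with columns F1..V3 (one row per
#'   stride) aligned with `selection`.
#' @param selection output of [select_strides()] (same row order).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return one-row data frame F1..V3 plus `n_strides`, or `NULL` (with a
#'   message) when no stride was selected.
#' @export
participant_features <- function(stride_features, selection,
                                 aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  keep <- which(selection$selected)
  if (!length(keep)) {
    message("participant excluded: no selected strides")
    return(NULL)
  }
  m <- as.matrix(stride_features[keep, c("F1", "F2", "F3", "V1", "V2", "V3")])
  agg <- if (aggregate == "mean") colMeans(m) else apply(m, 2L, stats::median)
  out <- as.data.frame(as.list(agg))
  out$n_strides <- length(keep)
  out
}

#' Flag direction-change strides from their azimuths
#'
#' Corridor walking alternates between two opposite headings on one axis;
#' the dominant axis is estimated by the double-angle circular mean and any
#' stride whose azimuth deviates from that axis by more than
#' `turn_axis_deg` degrees is flagged as a turn.
#' @noRd
flag_turns_by_azimuth <- function(azimuths, turn_axis_deg = 30) {
  if (!length(azimuths)) return(logical(0))
  axis <- atan2(mean(sin(2 * azimuths)), mean(cos(2 * azimuths))) / 2
  dev <- (azimuths - axis) %% pi
  dev <- pmin(dev, pi - dev)
  dev > turn_axis_deg * pi / 180
}

#' Per-stride features and selection for an estimated session
#'
#' Runs event detection on every estimated stride of both legs (toe-off and
#' maximum clearance on the ipsilateral signals, change of supporting leg
#' against the contralateral toe-off stream), extracts F1-F3/V1-V3, flags
#' turns by stride azimuth and failures by event detection, and applies the
#' selection protocol.
#'
#' @param session a [walk_session()].
#' @param est output of [estimate_trajectories()] for that session; computed
#'   here when `NULL`.
#' @param config an [estimation_config()].
#' @return list with `strides` (per-stride features, flags, selection),
#'   `participant` (one-row aggregate or NULL), `convention` metadata.
#' @export
session_features <- function(session, est = NULL,
                             config = estimation_config()) {
  if (is.null(est)) est <- estimate_trajectories(session, config)
  fs <- session$spec$sampling_rate
  per_side <- list()
  for (side in c("left", "right")) {
    entries <- est[[side]]
    if (!length(entries)) {
      per_side[[side]] <- NULL
      next
    }
    series <- session[[side]]
    gyro_clean <- est$gyro_clean[[side]] %||% series$gyro
    rows <- lapply(seq_along(entries), function(j) {
      e <- entries[[j]]
      idx <- e$segment$start:(e$segment$end - 1L)
      gy <- gyro_clean[idx, 2]
      t_start <- series$time[e$segment$start]
      to_t <- detect_toe_off(e$trajectory, gy, method = config$toe_off_method)
      mc_t <- if (is.na(to_t)) NA_real_ else detect_max_clearance(e$trajectory, to_t)
      data.frame(
        side = side, ordinal = j,
        window_start = t_start,
        window_end = series$time[e$segment$end - 1L],
        hs_t = series$time[e$segment$heel_strike_index],
        toe_off_t = to_t, max_clearance_t = mc_t,
        azimuth = e$trajectory$azimuth,
        stringsAsFactors = FALSE
      )
    })
    per_side[[side]] <- list(table = do.call(rbind, rows), entries = entries)
  }
  all_rows <- list()
  convention_used <- character(0)
  for (side in c("left", "right")) {
    if (is.null(per_side[[side]])) next
    other <- setdiff(c("left", "right"), side)
    contra_to <- if (!is.null(per_side[[other]])) {
      tab <- per_side[[other]]$table
      ok <- !is.na(tab$toe_off_t)
      sort(tab$window_start[ok] + tab$toe_off_t[ok])
    } else numeric(0)
    tab <- per_side[[side]]$table
    entries <- per_side[[side]]$entries
    feats <- matrix(NA_real_, nrow(tab), 6,
                    dimnames = list(NULL, c("F1", "F2", "F3", "V1", "V2", "V3")))
    failed <- logical(nrow(tab))
    sc_abs <- rep(NA_real_, nrow(tab))
    for (j in seq_len(nrow(tab))) {
      if (is.na(tab$toe_off_t[j])) {
        failed[j] <- TRUE
        next
      }
      sc <- detect_support_change(
        terminal_hs_t = tab$hs_t[j],
        contra_toe_off_times = contra_to,
        window_end_t = tab$window_end[j],
        convention = config$support_change_convention
      )
      convention_used <- union(convention_used, sc$convention)
      sc_abs[j] <- sc$time
      ev <- list(
        toe_off_t = tab$toe_off_t[j],
        max_clearance_t = tab$max_clearance_t[j],
        support_change_t = sc$time - tab$window_start[j]
      )
      f <- tryCatch(extract_features(entries[[j]]$trajectory, ev),
                    error = function(e) NULL)
      if (is.null(f)) failed[j] <- TRUE else feats[j, ] <- f
    }
    turn <- flag_turns_by_azimuth(tab$azimuth, config$turn_axis_deg)
    all_rows[[side]] <- cbind(
      data.frame(side = side, stride = tab$ordinal,
                 window_start_t = tab$window_start,
                 hs_t = tab$hs_t,
                 toe_off_t = tab$toe_off_t,
                 max_clearance_t = tab$max_clearance_t,
                 support_change_t = sc_abs,
                 turn = turn, failed = failed, stringsAsFactors = FALSE),
      as.data.frame(feats)
    )
  }
  strides <- do.call(rbind, all_rows)
  if (is.null(strides) || !nrow(strides)) {
    return(list(strides = NULL, participant = NULL,
                convention = config$support_change_convention))
  }
  sel <- select_strides(strides, quota = config$quota, warn = FALSE)
  part <- participant_features(strides, sel)
  list(strides = sel, participant = part,
       convention = paste(convention_used, collapse = "+"))
}

#' Participant feature table for a list of sessions
#'
#' @param sessions list of [walk_session()] objects (or simulate_session
#'   outputs, from which `$session` is taken).
#' @param config an [estimation_config()].
#' @return `feature_table` data frame: participant_id, group, F1..V3,
#'   n_strides.
#' @export
cohort_features <- function(sessions, config = estimation_config()) {
  rows <- lapply(sessions, function(s) {
    if (!inherits(s, "walk_session") && !is.null(s$session)) s <- s$session
    sf <- session_features(s, config = config)
    if (is.null(sf$participant)) return(NULL)
    cbind(data.frame(participant_id = s$participant_id, group = s$group,
                     stringsAsFactors = FALSE),
          sf$participant)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  class(out) <- c("feature_table", class(out))
  out
}
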