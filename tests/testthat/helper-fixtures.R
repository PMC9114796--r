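# Shared fixtures, memoized so the expensive simulations run once per suite.
# All fixture seeds were fixed when the tests were written.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# one healthy-young session, noise-free sensors (round-trip oracles)
fixture_session_clean <- function() {
  memo("session_clean", function() {
    simulate_session(make_default_profiles()$healthy_young, cohort_spec(),
                     sensor_noise_none(), seed = 3)
  })
}

# one mild-PD session with default sensor imperfections (event detection)
fixture_session_noisy <- function() {
  memo("session_noisy", function() {
    simulate_session(make_default_profiles()$mild_pd, cohort_spec(),
                     sensor_noise(), seed = 5)
  })
}

# default cohort, 20 per group, estimated end-to-end (orderings, PCA, SVM)
fixture_cohort <- function() {
  memo("cohort", function() {
    spec <- cohort_spec(
      counts = c(mild_pd = 20, advanced_pd = 20, healthy_older = 20,
                 healthy_young = 20),
      seed = 42
    )
    coh <- simulate_cohort(make_default_profiles(), spec)
    ft <- cohort_features(lapply(coh$sessions, function(x) x$session))
    list(features = ft, truth = coh$truth_features, sessions = coh$sessions)
  })
}

# estimator-fidelity cohort: 20 participants (5 per group), default noise
fixture_t1 <- function() {
  memo("t1", function() {
    spec <- cohort_spec(
      counts = c(mild_pd = 5, advanced_pd = 5, healthy_older = 5,
                 healthy_young = 5),
      seed = 101
    )
    simulate_cohort(make_default_profiles(), spec)
  })
}

#' Matched (true, estimated) per-stride stride lengths for one session
#'
#' Estimated stride length = net forward displacement of the stride window;
#' matched to ground truth by the detected terminal heel-strike time
#' (within 50 ms). Only strides the selection protocol retains are used
#' when `selected_only = TRUE`.
stride_length_pairs <- function(sim, config = estimation_config(),
                                selected_only = TRUE) {
  session <- sim$session
  est <- estimate_trajectories(session, config)
  sf <- session_features(session, est, config)
  st <- sim$truth$strides
  rows <- list()
  for (side in c("left", "right")) {
    entries <- est[[side]]
    truth_side <- st[st$side == side, ]
    sel <- sf$strides[sf$strides$side == side, ]
    for (j in seq_along(entries)) {
      if (selected_only) {
        srow <- sel[sel$stride == j, ]
        if (!nrow(srow) || !srow$selected) next
      }
      e <- entries[[j]]
      hs_t <- session[[side]]$time[e$segment$heel_strike_index]
      m <- which.min(abs(truth_side$terminal_hs - hs_t))
      if (abs(truth_side$terminal_hs[m] - hs_t) > 0.05) next
      n <- nrow(e$trajectory$position)
      rows[[length(rows) + 1L]] <- data.frame(
        true = truth_side$stride_length[m],
        est = e$trajectory$position[n, "forward"],
        turn = truth_side$turn[m]
      )
    }
  }
  do.call(rbind, rows)
}

group_means <- function(ft) {
  gm <- aggregate(ft[, c("F1", "F2", "F3", "V1", "V2", "V3")],
                  list(group = ft$group), mean)
  rownames(gm) <- gm$group
  gm
}
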