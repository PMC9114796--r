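# helpers building tiny analytic stride trajectories
toy_trajectory <- function(n = 101, L = 1.2, h = 0.15, dur = 1.0) {
  tt <- seq(0, dur, length.out = n)
  u <- tt / dur
  z <- h * sin(pi * pmax(u - 0.4, 0) / 0.6)^2
  x <- L * (3 * u^2 - 2 * u^3)
  vz <- c(diff(z) / diff(tt), 0)
  structure(
    list(time = tt,
         position = cbind(forward = x, lateral = 0, vertical = z),
         velocity = cbind(forward = 0 * tt, lateral = 0, vertical = vz),
         azimuth = 0),
    class = "stride_trajectory"
  )
}

test_that("toe-off and support-change match the generator truth (30 ms)", {
  fix <- fixture_session_noisy()
  sf <- session_features(fix$session)
  st <- sf$strides
  truth <- fix$truth$strides
  to_err <- c(); sc_err <- c()
  for (i in which(st$selected)) {
    tl <- truth[truth$side == st$side[i], ]
    to_abs <- st$window_start_t[i] + st$toe_off_t[i]
    to_err <- c(to_err, min(abs(tl$toe_off - to_abs)))
    sc_err <- c(sc_err, min(abs(tl$support_change - st$support_change_t[i]),
                            na.rm = TRUE))
  }
  expect_gte(mean(to_err <= 0.03), 0.95)
  expect_gte(mean(sc_err <= 0.03), 0.95)
})

test_that("vertical-velocity toe-off variant flags flat strides", {
  flat <- toy_trajectory(h = 0)
  expect_true(is.na(detect_toe_off(flat, method = "vertical_velocity")))
  # invariant to adding a constant to the forward channel
  tr <- toy_trajectory()
  t1 <- detect_toe_off(tr, method = "vertical_velocity")
  tr$position[, "forward"] <- tr$position[, "forward"] + 5
  expect_identical(detect_toe_off(tr, method = "vertical_velocity"), t1)
  expect_false(is.na(t1))
})

test_that("maximum clearance is the (earliest) vertical argmax", {
  tr <- toy_trajectory(n = 201, h = 0.12)
  mc <- detect_max_clearance(tr)
  expect_equal(unname(tr$position[which.max(tr$position[, "vertical"]), "vertical"]),
               approx(tr$time, tr$position[, "vertical"], mc)$y)
  expect_equal(mc, 0.7, tolerance = 0.01) # peak of sin^2 at u = 0.7

  # plateaued peak: earliest sample of the plateau wins
  tt <- seq(0, 1, length.out = 11)
  z <- c(0, 0.2, 0.5, 1, 1, 1, 0.5, 0.2, 0.1, 0, 0)
  tr2 <- structure(list(time = tt,
                        position = cbind(forward = tt, lateral = 0, vertical = z),
                        velocity = cbind(0 * tt, 0, 0 * tt), azimuth = 0),
                   class = "stride_trajectory")
  expect_equal(detect_max_clearance(tr2), tt[4])
})

test_that("support-change conventions behave and fall back as documented", {
  sc <- detect_support_change(10.0, contra_toe_off_times = c(9.5, 10.12, 11.1),
                              window_end_t = 10.4)
  expect_equal(sc$time, 10.12)
  expect_identical(sc$convention, "contralateral_toe_off_after_terminal_hs")
  # clamped to the stride window
  sc <- detect_support_change(10.0, contra_toe_off_times = c(10.6),
                              window_end_t = 10.4)
  expect_equal(sc$time, 10.4)
  # no qualifying contralateral event: terminal heel strike fallback
  sc <- detect_support_change(10.0, contra_toe_off_times = numeric(0))
  expect_equal(sc$time, 10.0)
  expect_identical(sc$convention, "terminal_heel_strike")
})

test_that("support change follows max clearance on simulated strides", {
  fix <- fixture_session_noisy()
  sf <- session_features(fix$session)
  st <- sf$strides[sf$strides$selected, ]
  expect_true(all(st$V2 >= st$V1 - 1e-9))
  expect_true(all(st$V2 >= st$V3 - 1e-9))
  expect_true(all(st$F1 <= st$F2 + 1e-9 & st$F2 <= st$F3 + 1e-9))
})

test_that("feature extraction reads displacements by interpolation", {
  tr <- toy_trajectory(n = 401, L = 1.0, h = 0.2)
  ev <- list(toe_off_t = 0.45, max_clearance_t = 0.7, support_change_t = 0.95)
  f <- extract_features(tr, ev)
  expect_equal(unname(f["V2"]), 0.2, tolerance = 1e-3)
  expect_equal(unname(f["F2"]), 3 * 0.7^2 - 2 * 0.7^3, tolerance = 1e-3)
  expect_true(f["V2"] >= f["V1"] && f["V2"] >= f["V3"])

  zero <- toy_trajectory(L = 0, h = 0)
  fz <- extract_features(zero, ev)
  expect_true(all(abs(fz) < 1e-12))

  expect_error(extract_features(tr, list(toe_off_t = -0.5,
                                         max_clearance_t = 0.7,
                                         support_change_t = 0.9)),
               "outside")
  expect_error(extract_features(tr, list(toe_off_t = 0.45,
                                         max_clearance_t = 0.7,
                                         support_change_t = 2)),
               "outside")
})

make_selection_input <- function(n_per_leg, turns = integer(0),
                                 failed = integer(0)) {
  do.call(rbind, lapply(c("left", "right"), function(side) {
    data.frame(side = side, stride = seq_len(n_per_leg),
               turn = seq_len(n_per_leg) %in% turns,
               failed = seq_len(n_per_leg) %in% failed)
  }))
}

test_that("selection protocol: 35 clean strides per leg -> 40 in total", {
  sel <- select_strides(make_selection_input(35))
  expect_identical(unname(attr(sel, "retained")), c(20L, 20L))
  expect_equal(sum(sel$selected), 40L)
  # first/last five never selected
  expect_false(any(sel$selected[sel$stride <= 5 | sel$stride > 30]))
})

test_that("selection shortfall keeps the remainder and warns", {
  expect_warning(sel <- select_strides(make_selection_input(12)),
                 "only 2 strides")
  expect_equal(sum(sel$selected), 4L) # 12 - 10 = 2 per leg
})

test_that("turn and failed strides are never selected", {
  sel <- select_strides(make_selection_input(35, turns = c(17, 18),
                                             failed = 20), warn = FALSE)
  expect_false(any(sel$selected & (sel$turn | sel$failed)))
  expect_equal(sum(sel$selected), 40L) # enough clean strides remain
})

test_that("selection is idempotent and order-independent", {
  inp <- make_selection_input(30, turns = c(15, 16))
  a <- select_strides(inp, warn = FALSE)
  shuffled <- inp[sample(nrow(inp)), ]
  b <- select_strides(shuffled, warn = FALSE)
  b <- b[order(b$side, b$stride), ]
  a <- a[order(a$side, a$stride), ]
  expect_identical(a$selected, b$selected)
  again <- select_strides(a[, c("side", "stride", "turn", "failed")],
                          warn = FALSE)
  expect_identical(again$selected, a$selected)
})

test_that("participant aggregation is the mean over selected strides", {
  feats <- data.frame(F1 = c(1, 1), F2 = c(2, 2), F3 = c(1.0, 1.2),
                      V1 = c(0.1, 0.1), V2 = c(0.2, 0.2), V3 = c(0.05, 0.05))
  sel <- data.frame(selected = c(TRUE, TRUE))
  out <- participant_features(feats, sel)
  expect_equal(out$F3, 1.1)
  expect_equal(out$n_strides, 2L)

  none <- data.frame(selected = c(FALSE, FALSE))
  expect_message(out0 <- participant_features(feats, none), "excluded")
  expect_null(out0)
})

test_that("participant means agree with generator truth within 3 SE", {
  fix <- fixture_session_noisy()
  sf <- session_features(fix$session)
  truth <- fix$truth$strides
  tsel <- select_strides(data.frame(
    side = truth$side, stride = truth$stride, turn = truth$turn,
    failed = !is.finite(truth$V3)
  ), warn = FALSE)
  tmean <- colMeans(truth[tsel$selected, c("F1", "F2", "F3", "V1", "V2", "V3")])
  tsd <- apply(truth[tsel$selected, c("F1", "F2", "F3", "V1", "V2", "V3")],
               2, sd)
  se <- tsd / sqrt(sum(tsel$selected))
  for (f in c("F2", "F3", "V2", "V3")) {
    # small detector biases are tolerated for F1/V1 (toe-off timing)
    expect_lt(abs(sf$participant[[f]] - tmean[[f]]), 3 * se[[f]] + 0.01)
  }
})
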