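# Internal numeric helpers shared across the pipeline.

GRAVITY <- 9.80665 # m/s^2, standard gravity

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Cumulative trapezoidal integral on a uniform grid
#'
#' @param y numeric vector or matrix (columns integrated independently).
#' @param dt sample interval (s).
#' @return same shape as `y`; first element 0.
#' @noRd
cumtrapz <- function(y, dt) {
  if (is.matrix(y)) {
    apply(y, 2L, cumtrapz, dt = dt)
  } else {
    n <- length(y)
    if (n == 0L) return(numeric(0))
    c(0, cumsum((y[-n] + y[-1L]) / 2) * dt)
  }
}

# Quintic smoothstep: s(0)=0, s(1)=1, zero first and second derivative at both
# ends (so a displacement profile built on it has continuous acceleration).
smoothstep5 <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  p^3 * (10 - 15 * p + 6 * p^2)
}

smoothstep3 <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  p^2 * (3 - 2 * p)
}

# Raised-cosine (Hann) lobe of unit peak, centre `c`, full width `w`; zero
# outside the support. Used as the building block for the synthetic shank
# pitch-rate waveform.
hann_lobe <- function(u, c, w) {
  d <- abs(u - c)
  out <- numeric(length(u))
  inside <- d < w / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * (u[inside] - c) / w))
  out
}

# Definite integral of hann_lobe over [a, b] (closed form, support-clipped).
hann_lobe_int <- function(a, b, c, w) {
  lo <- pmax(a, c - w / 2)
  hi <- pmin(b, c + w / 2)
  if (hi <= lo) return(0)
  F <- function(u) 0.5 * (u + (w / (2 * pi)) * sin(2 * pi * (u - c) / w))
  F(hi) - F(lo)
}

# --- quaternion helpers -----------------------------------------------------
# Quaternions are length-4 numeric vectors c(w, x, y, z) (scalar first) or
# n x 4 matrices for series. All rotations are sensor -> world (active).

quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

quat_mul <- function(a, b) {
  # supports vector x vector; used in tight loops, keep scalar
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conj <- function(q) {
  if (is.matrix(q)) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4]) else c(q[1], -q[2], -q[3], -q[4])
}

#' Rotation-vector exponential map: rotvec (rad, length 3) -> unit quaternion
#' @noRd
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) {
    quat_normalize(c(1, v / 2))
  } else {
    c(cos(th / 2), sin(th / 2) * v / th)
  }
}

#' Logarithm map: unit quaternion -> rotation vector (rad)
#' @noRd
quat_to_rotvec <- function(q) {
  if (q[1] < 0) q <- -q # principal branch
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) {
    2 * q[2:4]
  } else {
    2 * atan2(s, q[1]) * q[2:4] / s
  }
}

#' Rotate 3-vectors by a quaternion
#'
#' @param q unit quaternion c(w,x,y,z), or n x 4 matrix matching `v`'s rows.
#' @param v length-3 vector or n x 3 matrix.
#' @noRd
quat_rotate <- function(q, v) {
  single_q <- !is.matrix(q)
  if (single_q && !is.matrix(v)) {
    t <- 2 * cross3(q[2:4], v)
    return(v + q[1] * t + cross3(q[2:4], t))
  }
  if (single_q) q <- matrix(q, nrow(v), 4, byrow = TRUE)
  if (!is.matrix(v)) v <- matrix(v, nrow(q), 3, byrow = TRUE)
  qv <- q[, 2:4, drop = FALSE]
  t <- 2 * cross3_rows(qv, v)
  v + q[, 1] * t + cross3_rows(qv, t)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

cross3_rows <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' Quaternion for yaw (about world z) then pitch (about the lateral y axis)
#'
#' R = Rz(yaw) %*% Ry(pitch), sensor -> world.
#' @noRd
quat_yaw_pitch <- function(yaw, pitch) {
  # vectorized over equal-length yaw/pitch
  cy <- cos(yaw / 2); sy <- sin(yaw / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cbind(cy * cp, -sy * sp, cy * sp, sy * cp)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Zero-phase FFT band-pass filter
#'
#' Brick-wall magnitude response with raised-cosine roll-off edges
#' (`edge_width` Hz wide), applied symmetrically so there is no phase
#' distortion. Adequate for event detection on short uniformly sampled series
#' and dependency-free.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric, pass band in Hz.
#' @param edge_width transition width in Hz.
#' @noRd
fft_bandpass <- function(x, fs, band, edge_width = 1.5) {
  n <- length(x)
  if (n < 8L) return(x - mean(x))
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  gain_hi <- ifelse(
    f <= band[1] - edge_width, 0,
    ifelse(f >= band[1] + edge_width, 1,
      0.5 * (1 + sin(pi * (f - band[1]) / (2 * edge_width)))
    )
  )
  if (band[1] <= 0) gain_hi <- rep(1, n)
  gain_lo <- ifelse(
    f >= band[2] + edge_width, 0,
    ifelse(f <= band[2] - edge_width, 1,
      0.5 * (1 - sin(pi * (f - band[2]) / (2 * edge_width)))
    )
  )
  Re(stats::fft(X * gain_hi * gain_lo, inverse = TRUE)) / n
}

#' Linear interpolation of a sampled channel at an arbitrary time
#' @noRd
interp_at <- function(time, values, t) {
  stats::approx(time, values, xout = t, rule = 2)$y
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
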