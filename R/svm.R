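# Soft-margin kernel support vector machine, solved in the dual by
# sequential minimal optimization (SMO). Implemented in-package: cohort sizes
# here are tens of subjects, for which the textbook SMO with a deterministic
# maximal-|E_i - E_j| second-choice heuristic converges in a handful of
# sweeps. No randomness is used, so fits are reproducible by construction.

svm_kernel <- function(kernel, scale, degree = 3) {
  switch(kernel,
    linear = function(a, b) a %*% t(b),
    rbf = function(a, b) {
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
      exp(-pmax(d2, 0) / (2 * scale^2))
    },
    polynomial = function(a, b) (1 + a %*% t(b) / scale^2)^degree,
    stop("unknown kernel: ", kernel, call. = FALSE)
  )
}

#' Classifier specification
#'
#' @param kernel `"rbf"` (default; soft-margin kernel SVM with curved
#'   boundaries), `"linear"`, or `"polynomial"`.
#' @param box_constraint soft-margin box constraint C (> 0).
#' @param kernel_scale positive bandwidth, or `"auto"` for the median
#'   pairwise training distance heuristic.
#' @param standardize z-score features using training-fold statistics.
#' @param seed integer seed (used for fold assignment).
#' @export
classifier_spec <- function(kernel = c("rbf", "linear", "polynomial"),
                            box_constraint = 1, kernel_scale = "auto",
                            standardize = TRUE, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(box_constraint > 0)
  if (is.numeric(kernel_scale)) stopifnot(kernel_scale > 0)
  list(kernel = kernel, box_constraint = box_constraint,
       kernel_scale = kernel_scale, standardize = standardize,
       seed = as.integer(seed))
}

#' Fit a soft-margin kernel SVM (binary)
#'
#' @param x n x p numeric feature matrix.
#' @param y labels coercible to two levels; the first level of
#'   `factor(y)` is the positive class (+1).
#' @param spec a [classifier_spec()].
#' @param tol KKT tolerance.
#' @param max_sweeps sweep cap for the SMO loop.
#' @return object of class `gait_svm` with the support-vector expansion.
#' @export
svm_fit <- function(x, y, spec = classifier_spec(), tol = 1e-3,
                    max_sweeps = 300) {
  x <- as.matrix(x)
  f <- factor(y)
  if (nlevels(f) != 2L) stop("need exactly two classes", call. = FALSE)
  yy <- ifelse(as.integer(f) == 1L, 1, -1)
  n <- nrow(x)
  scale <- spec$kernel_scale
  if (identical(scale, "auto")) {
    d <- stats::dist(x)
    scale <- stats::median(d[d > 0])
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  kern <- svm_kernel(spec$kernel, scale)
  K <- kern(x, x)
  C <- spec$box_constraint
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.numeric(K %*% (alpha * yy)) + b
  for (sweep in seq_len(max_sweeps)) {
    changed <- 0L
    E <- fcache() - yy
    for (i in seq_len(n)) {
      Ei <- sum(K[, i] * alpha * yy) + b - yy[i]
      if (!((yy[i] * Ei < -tol && alpha[i] < C) ||
            (yy[i] * Ei > tol && alpha[i] > 0))) next
      E <- fcache() - yy
      j <- which.max(abs(E - E[i]) + ifelse(seq_len(n) == i, -Inf, 0))
      if (j == i) next
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (yy[i] != yy[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (H - L < 1e-12) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= -1e-12) next
      aj <- aj_old - yy[j] * (E[i] - E[j]) / eta
      aj <- min(max(aj, L), H)
      if (abs(aj - aj_old) < 1e-7) next
      ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
      alpha[i] <- ai; alpha[j] <- aj
      b1 <- b - E[i] - yy[i] * (ai - ai_old) * K[i, i] -
        yy[j] * (aj - aj_old) * K[i, j]
      b2 <- b - E[j] - yy[i] * (ai - ai_old) * K[i, j] -
        yy[j] * (aj - aj_old) * K[j, j]
      b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
      changed <- changed + 1L
    }
    if (changed == 0L) break
  }
  sv <- which(alpha > 1e-8)
  structure(
    list(x = x[sv, , drop = FALSE], y = yy[sv], alpha = alpha[sv], b = b,
         levels = levels(f), kernel = spec$kernel, scale = scale,
         spec = spec),
    class = "gait_svm"
  )
}

#' Decision scores of a fitted SVM (positive -> first class level)
#' @param object a `gait_svm`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.gait_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!nrow(object$x)) return(rep(object$b, nrow(newdata)))
  kern <- svm_kernel(object$kernel, object$scale)
  as.numeric(kern(newdata, object$x) %*% (object$alpha * object$y)) + object$b
}

#' Predicted class labels
#' @param object a `gait_svm`.
#' @param newdata feature matrix.
#' @export
svm_classify <- function(object, newdata) {
  s <- predict(object, newdata)
  factor(ifelse(s >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}
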