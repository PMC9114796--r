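# Group-level statistics: one-way ANOVA, Shaffer sequentially rejective
# pairwise post hoc tests, PCA on the feature table (correlation matrix,
# loadings as component-variable correlations), and Horn-style parallel
# analysis for component retention.

#' One-way ANOVA
#'
#' Classical between/within sums-of-squares decomposition with the p-value
#' from the F distribution.
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return list with `F`, `df_between`, `df_within`, `p`, and the sums of
#'   squares `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(values) {
  if (length(values) < 2L || any(vapply(values, length, integer(1)) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  all_v <- unlist(values, use.names = FALSE)
  if (anyNA(all_v)) stop("missing values not allowed", call. = FALSE)
  grand <- mean(all_v)
  n_i <- vapply(values, length, integer(1))
  m_i <- vapply(values, mean, numeric(1))
  ss_b <- sum(n_i * (m_i - grand)^2)
  ss_w <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- length(values) - 1L
  df_w <- length(all_v) - length(values)
  Fstat <- if (ss_w == 0) Inf else (ss_b / df_b) / (ss_w / df_w)
  list(
    F = Fstat, df_between = df_b, df_within = df_w,
    p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
    ss_between = ss_b, ss_within = ss_w
  )
}

#' Shaffer critical t-sequence for k groups
#'
#' t_j is the largest number of pairwise null hypotheses among k group means
#' that can simultaneously be true given that j - 1 of them are false. The
#' achievable truth counts are the values of sum(choose(b, 2)) over integer
#' partitions b of k (groups tied within blocks), so
#' t_j = max(s in S : s <= choose(k,2) - (j-1)).
#'
#' @param k number of groups.
#' @return integer vector of length choose(k, 2).
#' @export
shaffer_t_sequence <- function(k) {
  achievable <- sort(unique(vapply(
    integer_partitions(k),
    function(b) sum(choose(b, 2L)),
    numeric(1)
  )))
  m <- choose(k, 2L)
  vapply(seq_len(m), function(j) {
    as.integer(max(achievable[achievable <= m - (j - 1L)]))
  }, integer(1))
}

# All integer partitions of n (non-increasing parts), recursively.
integer_partitions <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

#' Shaffer sequentially rejective pairwise post hoc tests
#'
#' All pairwise two-sample t tests (pooled variance by default, Welch
#' optionally), p-values sorted ascending, the j-th hypothesis tested at
#' alpha / t_j with the Shaffer t-sequence; rejection stops at the first
#' non-rejection. Shaffer-adjusted p-values are the running maximum of
#' p_j * t_j, capped at 1.
#'
#' @param values named list of numeric vectors per group (>= 3 groups).
#' @param alpha family-wise significance level.
#' @param pooled pooled-variance t test (TRUE, default) or Welch.
#' @return data frame of comparisons in rejection order: `group1`, `group2`,
#'   `t`, `p_raw`, `t_j` (critical denominator), `alpha_j`, `p_adjusted`,
#'   `reject`.
#' @export
shaffer_posthoc <- function(values, alpha = 0.05, pooled = TRUE) {
  k <- length(values)
  if (k < 3L) stop("Shaffer post hoc needs >= 3 groups", call. = FALSE)
  nm <- names(values) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    x <- values[[ij[1]]]; y <- values[[ij[2]]]
    ht <- stats::t.test(x, y, var.equal = pooled)
    c(t = unname(ht$statistic), p = ht$p.value)
  })
  ord <- order(res["p", ])
  tj <- shaffer_t_sequence(k)
  p_sorted <- res["p", ord]
  p_adj <- pmin(cummax(p_sorted * tj), 1)
  reject_seq <- p_sorted <= alpha / tj
  # sequential: stop at the first non-rejection
  first_fail <- which(!reject_seq)
  if (length(first_fail)) {
    reject_seq[first_fail[1]:length(reject_seq)] <- FALSE
  }
  data.frame(
    group1 = nm[pairs[1, ord]], group2 = nm[pairs[2, ord]],
    t = unname(res["t", ord]), p_raw = p_sorted,
    t_j = tj, alpha_j = alpha / tj,
    p_adjusted = p_adj, reject = reject_seq,
    stringsAsFactors = FALSE
  )
}

#' Principal component analysis of a feature table
#'
#' Columns are centred and (by default) scaled to unit variance, so the
#' decomposition is of the correlation matrix. Loadings are reported as
#' component-variable correlations (eigenvector times component standard
#' deviation for standardized data). Deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix or data frame (participants x variables); for a
#'   `feature_table`, the six feature columns are used.
#' @param standardize scale columns to unit variance.
#' @return list with `sdev`, `variance_proportion`,
#'   `cumulative_proportion`, `loadings` (variables x components,
#'   correlation scale), `rotation` (unit eigenvectors), `scores`, `center`,
#'   `scale`.
#' @export
gait_pca <- function(x, standardize = TRUE) {
  m <- feature_matrix(x)
  if (nrow(m) < 2L) stop("need >= 2 rows", call. = FALSE)
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pr <- stats::prcomp(m, center = TRUE, scale. = standardize)
  # sign convention
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  var_prop <- pr$sdev^2 / sum(pr$sdev^2)
  loadings <- sweep(pr$rotation, 2L, pr$sdev, `*`)
  if (!standardize) {
    # correlation scale: divide by each variable's own standard deviation
    loadings <- sweep(loadings, 1L, apply(m, 2L, stats::sd), `/`)
  }
  list(
    sdev = pr$sdev,
    variance_proportion = var_prop,
    cumulative_proportion = cumsum(var_prop),
    loadings = loadings,
    rotation = pr$rotation,
    scores = pr$x,
    center = pr$center,
    scale = if (standardize) pr$scale else rep(1, ncol(m))
  )
}

feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    feat_cols <- intersect(c("F1", "F2", "F3", "V1", "V2", "V3"), names(x))
    if (length(feat_cols) == 6L) {
      return(as.matrix(x[, feat_cols]))
    }
    return(as.matrix(x[, vapply(x, is.numeric, logical(1))]))
  }
  as.matrix(x)
}

#' Horn-style parallel analysis
#'
#' Observed correlation-matrix eigenvalues are compared rank-wise with the
#' chosen percentile of eigenvalues from `reps` standard-normal datasets of
#' the same shape; the retained count is the number of leading ranks whose
#' observed eigenvalue exceeds its threshold, stopping at the first failure.
#'
#' @param x matrix / data frame as in [gait_pca()].
#' @param reps number of simulated noise datasets (>= 100 recommended).
#' @param percentile percentile of the simulated eigenvalue distribution.
#' @param seed integer seed for the noise draws.
#' @return list with `n_components`, `observed` eigenvalues, `thresholds`,
#'   `reps`, `percentile`, `seed`.
#' @export
parallel_analysis <- function(x, reps = 1000, percentile = 95, seed = 1) {
  m <- feature_matrix(x)
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  if (reps < 100) warning("reps < 100: thresholds will be unstable")
  n <- nrow(m); p <- ncol(m)
  observed <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  sim <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      z <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thresholds <- apply(sim, 1L, stats::quantile, probs = percentile / 100,
                      names = FALSE)
  exceeds <- observed > thresholds
  n_comp <- if (!exceeds[1]) 0L else {
    fails <- which(!exceeds)
    if (length(fails)) fails[1] - 1L else p
  }
  list(
    n_components = as.integer(n_comp), observed = observed,
    thresholds = thresholds, reps = reps, percentile = percentile,
    seed = seed
  )
}

#' Synthetic feature table with a two-factor block structure
#'
#' Six indicators driven by two independent standard-normal latent factors
#' (three indicators each, common loading), plus unit-variance-complement
#' noise. Mirrors the forward/vertical two-block structure of the gait
#' feature set and serves as the fixture for component-retention checks.
#'
#' @param n rows.
#' @param loading common factor loading in (0, 1).
#' @param seed integer seed.
#' @return n x 6 numeric matrix with columns X1..X6 (factor 1 drives X1-X3).
#' @export
simulate_two_factor_table <- function(n = 100, loading = 0.9, seed = 1) {
  with_seed(seed, {
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * 6L), n, 6L) * sqrt(1 - loading^2)
    m <- cbind(
      loading * f1 + e[, 1], loading * f1 + e[, 2], loading * f1 + e[, 3],
      loading * f2 + e[, 4], loading * f2 + e[, 5], loading * f2 + e[, 6]
    )
    colnames(m) <- paste0("X", 1:6)
    m
  })
}

#' Full per-variable group analysis of a feature table
#'
#' One-way ANOVA plus Shaffer post hoc per feature, PCA of the table, and
#' parallel analysis.
#'
#' @param table a `feature_table` (participant rows, F1..V3 + group).
#' @param alpha significance level.
#' @param reps,percentile parallel-analysis settings.
#' @param seed seed for parallel analysis.
#' @export
analyze_features <- function(table, alpha = 0.05, reps = 1000,
                             percentile = 95, seed = 1) {
  feats <- c("F1", "F2", "F3", "V1", "V2", "V3")
  per_variable <- lapply(feats, function(f) {
    vals <- split(table[[f]], table$group)
    list(
      anova = one_way_anova(vals),
      posthoc = if (length(vals) >= 3L) shaffer_posthoc(vals, alpha = alpha)
    )
  })
  names(per_variable) <- feats
  list(
    per_variable = per_variable,
    pca = gait_pca(table),
    parallel = parallel_analysis(table, reps = reps,
                                 percentile = percentile, seed = seed),
    alpha = alpha
  )
}
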