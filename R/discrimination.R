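# Group discrimination: stratified 10-fold cross-validated soft-margin
# kernel SVM on pairs of groups, with accuracy defined as the unweighted
# mean of fold accuracies, row-normalized confusion matrices, ROC/AUC, and
# 2-D decision-boundary grids in principal-component space.

#' Stratified k-fold assignments
#'
#' Class proportions per fold are within one subject of the global
#' proportions; deterministic given the seed.
#'
#' @param labels class labels (length n).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per subject (1..k).
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  f <- factor(labels)
  n <- length(f)
  if (n < k) stop("need at least k subjects", call. = FALSE)
  if (any(table(f) < k)) {
    warning("some class has fewer than k members; folds as balanced as possible")
  }
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (lev in levels(f)) {
      idx <- which(f == lev)
      idx <- idx[sample.int(length(idx))]
      # rotate the fold order per class so small classes spread evenly
      fold_order <- as.integer(((seq_along(idx) - 1L + offset) %% k) + 1L)
      folds[idx] <- fold_order
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Cross-validated SVM discrimination of two groups
#'
#' Per fold: features standardized with training-fold statistics only, a
#' soft-margin kernel SVM fitted on the training subjects, the held-out
#' subjects scored. Accuracy is the unweighted mean of fold accuracies (in
#' percent); the confusion matrix is row-normalized per true class.
#'
#' @param table `feature_table` restricted to two groups (or any data frame
#'   with a `group` column and numeric feature columns).
#' @param features character vector of feature column names to use.
#' @param spec a [classifier_spec()].
#' @param k folds.
#' @return `cv_result`: list with `fold`, `fold_accuracy`, `accuracy` (%),
#'   `recall` (% per class), `confusion` (row-normalized %), `scores`
#'   (decision score per subject, positive -> first group), `labels`,
#'   `levels`.
#' @export
svm_cross_validate <- function(table, features, spec = classifier_spec(),
                               k = 10) {
  f <- factor(table$group)
  f <- droplevels(f)
  if (nlevels(f) != 2L) stop("need exactly two groups", call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  k <- min(k, length(f)) # fewer subjects than folds -> leave-one-out
  folds <- make_folds(f, k = k, seed = spec$seed)
  scores <- numeric(length(f))
  pred <- factor(rep(levels(f)[1], length(f)), levels = levels(f))
  fold_acc <- numeric(k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    te <- !tr
    if (!any(te)) {
      fold_acc[fold] <- NA_real_
      next
    }
    xtr <- x[tr, , drop = FALSE]
    ctr <- colMeans(xtr)
    str_ <- apply(xtr, 2L, stats::sd)
    str_[str_ == 0 | !is.finite(str_)] <- 1
    std <- function(m) sweep(sweep(m, 2L, ctr), 2L, str_, `/`)
    if (!spec$standardize) std <- identity
    fit <- svm_fit(std(xtr), f[tr], spec)
    s <- predict(fit, std(x[te, , drop = FALSE]))
    scores[te] <- s
    p <- factor(ifelse(s >= 0, fit$levels[1], fit$levels[2]),
                levels = levels(f))
    pred[te] <- p
    fold_acc[fold] <- mean(p == f[te]) * 100
  }
  conf <- table(true = f, predicted = pred)
  conf_pct <- sweep(conf, 1L, pmax(rowSums(conf), 1L), `/`) * 100
  structure(
    list(
      fold = folds,
      fold_accuracy = fold_acc,
      accuracy = mean(fold_acc, na.rm = TRUE),
      recall = diag(as.matrix(conf_pct)),
      confusion = conf_pct,
      scores = scores,
      labels = f,
      levels = levels(f)
    ),
    class = "cv_result"
  )
}

PAPER_PAIRS <- list(
  c("mild_pd", "healthy_older"),
  c("mild_pd", "healthy_young"),
  c("healthy_older", "healthy_young"),
  c("mild_pd", "advanced_pd")
)

#' Run the pair-by-feature-set discrimination suite
#'
#' For each group pair: the six spatial variables, the first two principal
#' components of the cohort PC plane (see `pca_scope`), and each single
#' vertical variable. Missing groups skip the pair with a log entry.
#'
#' @param table full `feature_table`.
#' @param pairs list of length-2 character vectors.
#' @param feature_sets named list; `NULL` gives
#'   `all6`, `pc2`, `V1`, `V2`, `V3`.
#' @param spec a [classifier_spec()].
#' @param k folds.
#' @param pca_scope `"full"` (default): the PC plane is the full cohort's
#'   PCA, the same axes for every pair (as when one scatter of all subjects
#'   is classified pairwise); `"pair"`: PCA recomputed on each pair's pooled
#'   data. Either way the PCA sees the pooled data before fold splitting --
#'   a documented leakage caveat of mirroring the original design.
#' @return list with `results` (nested pair -> feature set -> `cv_result`),
#'   `accuracy` (pairs x feature-set matrix, %), `pair_pca` (PCA per pair),
#'   `skipped`.
#' @export
run_pair_suite <- function(table, pairs = PAPER_PAIRS, feature_sets = NULL,
                           spec = classifier_spec(), k = 10,
                           pca_scope = c("full", "pair")) {
  pca_scope <- match.arg(pca_scope)
  if (is.null(feature_sets)) {
    feature_sets <- list(
      all6 = c("F1", "F2", "F3", "V1", "V2", "V3"),
      pc2 = "pc2", V1 = "V1", V2 = "V2", V3 = "V3"
    )
  }
  full_pca <- if (pca_scope == "full") gait_pca(table) else NULL
  results <- list()
  pair_pca <- list()
  skipped <- character(0)
  acc <- matrix(NA_real_, length(pairs), length(feature_sets),
                dimnames = list(
                  vapply(pairs, paste, character(1), collapse = " vs "),
                  names(feature_sets)
                ))
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    pname <- paste(pair, collapse = " vs ")
    if (!all(pair %in% table$group)) {
      skipped <- c(skipped, pname)
      next
    }
    keep <- table$group %in% pair
    sub <- table[keep, , drop = FALSE]
    sub$group <- factor(sub$group, levels = pair)
    if (pca_scope == "full") {
      pca <- full_pca
      sub$PC1 <- full_pca$scores[keep, 1]
      sub$PC2 <- full_pca$scores[keep, 2]
    } else {
      pca <- gait_pca(sub)
      sub$PC1 <- pca$scores[, 1]
      sub$PC2 <- pca$scores[, 2]
    }
    pair_pca[[pname]] <- pca
    results[[pname]] <- list()
    for (si in seq_along(feature_sets)) {
      fset <- feature_sets[[si]]
      cols <- if (identical(fset, "pc2")) c("PC1", "PC2") else fset
      cv <- svm_cross_validate(sub, cols, spec = spec, k = k)
      results[[pname]][[names(feature_sets)[si]]] <- cv
      acc[pi, si] <- cv$accuracy
    }
  }
  list(results = results, accuracy = acc, pair_pca = pair_pca,
       skipped = skipped)
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores; AUC by the trapezoid rule, which
#' equals the normalized Mann-Whitney U statistic (ties counted half).
#'
#' @param scores numeric decision scores (larger -> more positive).
#' @param labels logical/two-level labels; `TRUE` / first level = positive.
#' @return `roc_result`: list with `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else {
    f <- factor(labels)
    if (nlevels(f) != 2L) stop("need two classes", call. = FALSE)
    as.integer(f) == 1L
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores so ties appear as diagonal ROC segments
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr, auc = auc),
    class = "roc_result"
  )
}

#' Decision grid of a 2-D classifier for boundary plotting
#'
#' @param fit a `gait_svm` fitted on exactly two features.
#' @param xlim,ylim ranges of the two features.
#' @param n grid resolution per axis.
#' @return list with `x`, `y` axis vectors, `score` matrix (n x n, rows = x)
#'   and `label` matrix of predicted classes.
#' @export
decision_boundary_grid <- function(fit, xlim, ylim, n = 100) {
  if (ncol(fit$x) != 2L) stop("model must use exactly 2 features", call. = FALSE)
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  grid <- as.matrix(expand.grid(xs, ys))
  s <- predict(fit, grid)
  score <- matrix(s, n, n) # rows follow xs, columns ys
  list(
    x = xs, y = ys, score = score,
    label = matrix(ifelse(s >= 0, fit$levels[1], fit$levels[2]), n, n)
  )
}
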