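#' Regression metrics for predicted vs experimental ddG
#'
#' Computes the three correlation coefficients (Pearson, Spearman, Kendall
#' tau-b) and two error measures (RMSE, MAE) between paired predicted and
#' observed values. Pairs with a missing member are dropped. With
#' zero-variance input the correlations are undefined and returned as `NA`
#' with a diagnostic message.
#'
#' @param pred Numeric vector of predictions (kcal/mol).
#' @param obs Numeric vector of observations (kcal/mol).
#' @return A `regression_metrics` list: `pearson_r`, `spearman_rho`,
#'   `kendall_tau`, `rmse`, `mae`, `n`.
#' @export
regression_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]
  n <- length(pred)
  if (n < 2) stop("regression_metrics: need at least 2 complete pairs",
                  call. = FALSE)
  err <- pred - obs
  if (sd(pred) == 0 || sd(obs) == 0) {
    message("regression_metrics: zero-variance input, correlations undefined")
    rp <- rs <- kt <- NA_real_
  } else {
    rp <- cor(pred, obs, method = "pearson")
    rs <- cor(pred, obs, method = "spearman")
    kt <- cor(pred, obs, method = "kendall")  # tau-b, tie-corrected
  }
  structure(list(
    pearson_r = rp,
    spearman_rho = rs,
    kendall_tau = kt,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    n = n
  ), class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("n = %d | r_P = %.3f | rho_S = %.3f | tau = %.3f | RMSE = %.3f | MAE = %.3f\n",
              x$n, x$pearson_r, x$spearman_rho, x$kendall_tau, x$rmse, x$mae))
  invisible(x)
}

#' Confusion matrix and classification metrics at a threshold
#'
#' Scores strictly greater than `threshold` are predicted positive (the
#' single strict-inequality convention used throughout the package, matching
#' the strict destabilization label rule). Accuracy is reported in percent;
#' MCC uses the standard four-count formula with the convention MCC = 0 when
#' any marginal is zero.
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector of true classes.
#' @param threshold Decision threshold in score units.
#' @return A `classification_metrics` list: `threshold`, `tp`, `fp`, `tn`,
#'   `fn`, `accuracy` (percent), `mcc`, `tpr`, `tnr`, and `auc` (`NA` unless
#'   both classes are present).
#' @export
confusion_at <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (length(scores) == 0) stop("confusion_at: empty input", call. = FALSE)
  pred <- scores > threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  structure(list(
    threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
    mcc = mcc_from_counts(tp, fp, tn, fn),
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (any(labels) && any(!labels)) auc_score(scores, labels) else NA_real_
  ), class = "classification_metrics")
}

#' Matthews correlation coefficient from confusion counts
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return MCC in \[-1, 1\]; 0 when any marginal sum is zero.
#' @export
mcc_from_counts <- function(tp, fp, tn, fn) {
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting one
#' half. Invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector of true classes; both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("auc_score: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Optimize a classification threshold by balancing TPR and TNR
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' scores, plus one candidate below the minimum and one above the maximum)
#' and returns the candidate minimizing |TPR - TNR|. Ties are broken by
#' larger MCC, then by smaller threshold, making the result deterministic
#' and independent of input ordering.
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector of true classes; both classes must occur.
#' @return A `threshold_search` list: `threshold`, `criterion_value`
#'   (= |TPR - TNR| at the optimum), `fold_thresholds` (`NULL` here), `seed`.
#' @export
optimize_threshold <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (!any(labels) || !any(!labels)) {
    stop("optimize_threshold: both classes must be present", call. = FALSE)
  }
  u <- sort(unique(scores))
  span <- if (length(u) > 1) diff(range(u)) else max(abs(u), 1)
  cand <- c(u[1] - 0.5 * span,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 0.5 * span)
  best <- NULL
  for (th in cand) {
    cm <- confusion_at(scores, labels, th)
    crit <- abs(cm$tpr - cm$tnr)
    if (is.null(best) ||
        crit < best$crit - 1e-12 ||
        (abs(crit - best$crit) <= 1e-12 && cm$mcc > best$mcc + 1e-12) ||
        (abs(crit - best$crit) <= 1e-12 && abs(cm$mcc - best$mcc) <= 1e-12 &&
         th < best$threshold)) {
      best <- list(threshold = th, crit = crit, mcc = cm$mcc)
    }
  }
  structure(list(
    threshold = best$threshold,
    criterion_value = best$crit,
    fold_thresholds = NULL,
    seed = NA_integer_
  ), class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("threshold = %.4g (|TPR-TNR| = %.4g)\n",
              x$threshold, x$criterion_value))
  if (!is.null(x$fold_thresholds)) {
    cat("fold thresholds:", paste(signif(x$fold_thresholds, 4), collapse = ", "),
        sprintf(" [seed %d]\n", x$seed))
  }
  invisible(x)
}

# Stratified fold assignment: permutes each class with the given seed and
# deals records round-robin so every fold gets both classes when possible.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx) > 0) {
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

#' Cross-validated threshold selection
#'
#' Splits the data into `k` stratified folds (random assignment under
#' `seed`), runs [optimize_threshold()] on each set of k-1 training folds,
#' and returns the median of the k fold thresholds. Every training split
#' must contain both classes.
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector of true classes.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `threshold_search` list with `fold_thresholds` and `seed` set.
#' @export
cv_threshold <- function(scores, labels, k = 5, seed = 1L) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n <- length(scores)
  if (n < k) stop("cv_threshold: need at least k observations", call. = FALSE)
  if (min(sum(labels), sum(!labels)) < k) {
    stop("cv_threshold: a class has fewer than k members; use a smaller k",
         call. = FALSE)
  }
  fold <- stratified_folds(labels, k, seed)
  fold_th <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    optimize_threshold(scores[tr], labels[tr])$threshold
  }, numeric(1))
  final <- median(fold_th)
  cm <- confusion_at(scores, labels, final)
  structure(list(
    threshold = final,
    criterion_value = abs(cm$tpr - cm$tnr),
    fold_thresholds = fold_th,
    seed = as.integer(seed)
  ), class = "threshold_search")
}
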