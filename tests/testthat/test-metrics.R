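test_that("regression metrics match the defining formulas", {
  # identity
  rm <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rm$pearson_r, 1.0)
  expect_equal(rm$rmse, 0)
  expect_equal(rm$mae, 0)
  # frozen values from the closed-form oracle: pred=(0,1,2,4), obs=(0,1,2,2)
  rm <- regression_metrics(c(0, 1, 2, 4), c(0, 1, 2, 2))
  expect_equal(rm$rmse, 1)      # errors (0,0,0,2): sqrt(4/4)
  expect_equal(rm$mae, 0.5)
  expect_equal(rm$pearson_r, oracle_pearson(c(0, 1, 2, 4), c(0, 1, 2, 2)))
  expect_equal(rm$n, 4)
  # pairs with a missing member are dropped
  rm2 <- regression_metrics(c(0, 1, 2, 4, NA), c(0, 1, 2, 2, 7))
  expect_equal(rm2$n, 4)
  expect_equal(rm2$rmse, rm$rmse)
})

test_that("regression metrics handle degenerate input", {
  expect_error(regression_metrics(1, 1), "at least 2")
  msgs <- capture_messages(rm <- regression_metrics(c(1, 1, 1), c(1, 2, 3)))
  expect_match(paste(msgs, collapse = ""), "zero-variance")
  expect_true(is.na(rm$pearson_r))
  expect_false(is.na(rm$rmse))
})

test_that("RMSE >= MAE universally, linear transforms give r = 1", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    pred <- rnorm(n, sd = runif(1, 0.1, 5))
    obs <- rnorm(n, sd = runif(1, 0.1, 5))
    rm <- regression_metrics(pred, obs)
    expect_gte(rm$rmse, rm$mae)
    a <- runif(1, 0.1, 3); b <- rnorm(1)
    expect_equal(regression_metrics(a * obs + b, obs)$pearson_r, 1.0)
  }
  # equality iff all absolute errors equal
  expect_equal(regression_metrics(c(1, 2, 3), c(0, 1, 2))$rmse,
               regression_metrics(c(1, 2, 3), c(0, 1, 2))$mae)
})

test_that("confusion metrics agree with direct count recomputation", {
  # (tp, fp, fn, tn) = (3, 1, 1, 5) at threshold 0
  scores <- c(1, 1, 1, -1, 1, -1, -1, -1, -1, -1)
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cm <- confusion_at(scores, labels, 0)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(3, 1, 1, 5))
  expect_equal(cm$accuracy, 80)
  expect_equal(cm$mcc, 14 / 24)
  # perfectly separated scores with a threshold in the gap
  cm2 <- confusion_at(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(cm2$accuracy, 100)
  expect_equal(cm2$mcc, 1.0)
  expect_error(confusion_at(numeric(0), logical(0), 1), "empty")
})

test_that("MCC/accuracy equal formula recomputation on random tables", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    scores <- rnorm(n)
    labels <- runif(n) < 0.5
    th <- quantile(scores, runif(1))
    cm <- confusion_at(scores, labels, th)
    tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
    expect_equal(cm$accuracy, 100 * (tp + tn) / n)
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    expected_mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
    expect_equal(cm$mcc, expected_mcc)
  }
  # zero-marginal convention
  expect_equal(mcc_from_counts(0, 0, 5, 5), 0)
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(auc_score(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  expect_equal(auc_score(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auc_score(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    scores <- sample(rnorm(n %/% 2 + 1), n, replace = TRUE)  # force some ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(3)
  scores <- rnorm(40)
  labels <- c(TRUE, FALSE, runif(38) < 0.4)
  base <- auc_score(scores, labels)
  for (f in list(function(x) 2 * x + 3, exp, function(x) x^3,
                 function(x) atan(x))) {
    expect_equal(auc_score(f(scores), labels), base)
  }
})

test_that("AUC matches the independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, labels), ref)
})

test_that("threshold optimization matches the brute-force scan oracle", {
  # perfectly separated classes: gap midpoint, rates balanced exactly
  res <- optimize_threshold(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$threshold, 5)
  expect_equal(res$criterion_value, 0)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    res <- optimize_threshold(scores, labels)
    expect_equal(res$threshold, oracle_optimize(scores, labels))
    # independent of input ordering
    perm <- sample(n)
    expect_equal(optimize_threshold(scores[perm], labels[perm])$threshold,
                 res$threshold)
  }
  expect_error(optimize_threshold(1:4, rep(TRUE, 4)), "both classes")
})

test_that("cross-validated threshold selection is stratified and reproducible", {
  # homogeneous classes: every training split yields the same threshold
  scores <- rep(c(0, 1), each = 10)
  labels <- rep(c(FALSE, TRUE), each = 10)
  cv <- cv_threshold(scores, labels, k = 5, seed = 9)
  expect_equal(cv$threshold, optimize_threshold(scores, labels)$threshold)
  expect_length(cv$fold_thresholds, 5)
  # determinism under a fixed seed
  set.seed(31)
  scores <- rnorm(60); labels <- runif(60) < 0.4
  labels[1:10] <- TRUE
  cv1 <- cv_threshold(scores, labels, k = 5, seed = 123)
  cv2 <- cv_threshold(scores, labels, k = 5, seed = 123)
  expect_identical(cv1, cv2)
  expect_equal(cv1$threshold, median(cv1$fold_thresholds))
  # fold thresholds stay within the candidate range of the data
  expect_true(all(cv1$fold_thresholds >= min(scores) - diff(range(scores)) &
                  cv1$fold_thresholds <= max(scores) + diff(range(scores))))
  # class too small for stratification
  expect_error(cv_threshold(1:10, c(TRUE, rep(FALSE, 9)), k = 5, seed = 1),
               "smaller k")
})
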