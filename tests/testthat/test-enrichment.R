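test_that("Fisher exact test matches enumeration on frozen tables", {
  expect_equal(fisher_2x2(matrix(1, 2, 2))$p_value, 1.0)
  # margins (2,2)/(2,2): table probabilities {1,4,1}/6, two-sided p = 1/3
  expect_equal(fisher_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_error(fisher_2x2(matrix(c(1, -1, 0, 2), 2)), "nonnegative")
  expect_error(fisher_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_2x2(matrix(0, 2, 2)), "positive")
})

test_that("Fisher p-values equal the full-enumeration oracle", {
  set.seed(17)
  for (i in 1:60) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_2x2(tab)$p_value, oracle_fisher(tab),
                 tolerance = 1e-10)
  }
})

test_that("two-sample KS statistic behaves as the ECDF supremum", {
  set.seed(2)
  x <- rnorm(20)
  expect_equal(ks_two_sample(x, x)$aux$D, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$aux$D, 1)
  expect_lt(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$p_value, 0.15)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
  # D invariant under strictly increasing transforms of both samples
  y <- rnorm(15, 1)
  base <- ks_two_sample(x, y)$aux$D
  for (f in list(exp, function(v) 3 * v - 2, function(v) v^3)) {
    expect_equal(ks_two_sample(f(x), f(y))$aux$D, base)
  }
})

test_that("class means split scores by label and reject empty classes", {
  cm <- class_means(c(0.5, 0.7, 0.2, 0.4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(cm), c(0.6, 0.3))
  expect_error(class_means(c(0.5, 0.7), c(TRUE, TRUE)), "both classes")
})

test_that("quadrant corner assignment follows the boundary rules", {
  rec <- toy_records()[1, ]
  rec$rsa <- 0.1; rec$f_wt <- 80
  ds1 <- variant_dataset(rec)
  qs <- quadrant_spec()  # rsa cut 0.2 (boundary low), f_wt cut 50 (boundary low)
  qc <- quadrant_counts(ds1, qs, TRUE)
  expect_equal(qc$n[!qc$x_high & qc$y_high], 1)  # buried & conserved
  expect_equal(sum(qc$n), 1)
  # records exactly on both cuts: boundary belongs to the low side
  rec$rsa <- 0.2; rec$f_wt <- 50
  qc2 <- quadrant_counts(variant_dataset(rec), qs, TRUE)
  expect_equal(qc2$n[!qc2$x_high & !qc2$y_high], 1)
  # "high" boundary rule moves the same record to the high side
  qs_hi <- quadrant_spec(x_boundary = "high", y_boundary = "high")
  qc3 <- quadrant_counts(variant_dataset(rec), qs_hi, TRUE)
  expect_equal(qc3$n[qc3$x_high & qc3$y_high], 1)
  expect_error(quadrant_counts(ds1, quadrant_spec(x_feature = "nope"), TRUE),
               "absent")
})

test_that("quadrant counts equal the per-record classification oracle", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    rec <- toy_records()[rep(1, n), ]
    rec$position <- seq_len(n)
    rec$rsa <- round(runif(n), 2)
    rec$f_wt <- round(runif(n, 0, 100))
    ds <- variant_dataset(rec)
    lab <- runif(n) < 0.3
    qs <- quadrant_spec(x_cut = 0.2, y_cut = 50)
    qc <- quadrant_counts(ds, qs, lab)
    xh <- rec$rsa > 0.2; yh <- rec$f_wt > 50
    for (j in seq_len(4)) {
      sel <- xh == qc$x_high[j] & yh == qc$y_high[j]
      expect_equal(qc$n[j], sum(sel))
      expect_equal(qc$k[j], sum(lab[sel]))
    }
    expect_equal(sum(qc$n), n)  # corners partition the records
  }
})

test_that("binomial corner tests equal direct pmf summation", {
  expect_equal(binomial_corner_test(10, 10, 0.5, "enrichment")$p_value, 2^-10)
  expect_equal(binomial_corner_test(0, 20, 0.247, "depletion")$p_value,
               (1 - 0.247)^20)
  set.seed(19)
  for (i in 1:40) {
    n <- sample(1:60, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    dir <- sample(c("enrichment", "depletion"), 1)
    expect_equal(binomial_corner_test(k, n, p0, dir)$p_value,
                 oracle_binom_tail(k, n, p0, dir), tolerance = 1e-12)
  }
  expect_error(binomial_corner_test(2, 10, 0), "p0")
  expect_error(binomial_corner_test(11, 10, 0.5), "k <= n")
})

test_that("binomial tails are complementary and monotone in k", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:50, 1); k <- sample(1:n, 1); p0 <- runif(1, 0.1, 0.9)
    expect_equal(binomial_corner_test(k, n, p0, "enrichment")$p_value +
                   binomial_corner_test(k - 1, n, p0, "depletion")$p_value, 1)
  }
  p_seq <- vapply(0:20, function(k) {
    binomial_corner_test(k, 20, 0.3, "enrichment")$p_value
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 0))
  expect_true(all(p_seq > 0 & p_seq <= 1))
})

test_that("burial fractions match a hand count", {
  rec <- toy_records()[1:4, ]
  rec$rsa <- c(0.1, 0.2, 0.5, 0.3)
  ds <- variant_dataset(rec)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  bf <- burial_fractions(ds, lab)
  expect_equal(unname(bf), c(1.0, 1.0))  # both positives <= 0.2; both negatives > 0.2
  lab2 <- c(TRUE, FALSE, TRUE, FALSE)
  bf2 <- burial_fractions(ds, lab2)
  expect_equal(unname(bf2), c(0.5, 0.5))
  expect_error(burial_fractions(ds, rep(TRUE, 4)), "both classes")
})
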