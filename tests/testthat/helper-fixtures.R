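# Small in-code fixtures shared across test files.

toy_records <- function() {
  tibble::tibble(
    protein_id = c("p53-DBD", "p53-DBD", "BRCA1", "BRCA1", "PGK1", "PGK1"),
    structure_id = c("2ocj", "2ocj", "1jnx", "1jnx", "2zgv", "2zgv"),
    wt_aa = c("R", "R", "M", "G", "R", "L"),
    position = c(175L, 282L, 1775L, 1788L, 38L, 62L),
    mut_aa = c("H", "W", "R", "V", "M", "P"),
    ddg_exp = c(3.5, 3.0, 1.4, 2.7, 1.1, 0.5),
    dtm = c(-8.1, NA, -2.0, NA, NA, 1.2),
    ddg_pred = c(4.0, 3.6, 2.1, 15.2, 0.9, 0.2),
    patho_score = c(0.91, 0.85, 0.62, 0.55, 0.48, 0.20),
    rsa = c(0.05, 0.12, 0.30, 0.18, 0.45, 0.60),
    f_wt = c(95, 88, 60, 40, 35, 20),
    cmc = c("TIER1", "TIER2", "OTHER", "OTHER", "OTHER", "UNANNOTATED"),
    n_tumor_samples = c(120L, 90L, 4L, 2L, NA_integer_, NA_integer_),
    is_training = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

toy_dataset <- function() variant_dataset(toy_records())

write_toy_table <- function(path = tempfile(fileext = ".tsv"), delim = "\t") {
  write_variant_table(toy_dataset(), path, delim = delim)
  path
}

# Independent oracles ------------------------------------------------------

# Pearson correlation by the explicit product-moment formula.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# AUC by exhaustive positive/negative pair counting, ties = 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of tables with fixed margins,
# probability-ordering definition with a relative tie tolerance.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided binomial tail by direct pmf summation.
oracle_binom_tail <- function(k, n, p0, direction) {
  if (direction == "enrichment") {
    sum(dbinom(k:n, n, p0))
  } else {
    sum(dbinom(0:k, n, p0))
  }
}

# Balanced-rate threshold search by brute force over the same candidate set.
oracle_optimize <- function(scores, labels) {
  u <- sort(unique(scores))
  span <- if (length(u) > 1) diff(range(u)) else max(abs(u), 1)
  cand <- c(u[1] - 0.5 * span,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 0.5 * span)
  stats <- t(vapply(cand, function(th) {
    pred <- scores > th
    tp <- sum(pred & labels); fn <- sum(!pred & labels)
    tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
    mcc <- varstab::mcc_from_counts(tp, fp, tn, fn)
    c(crit = abs(tp / (tp + fn) - tn / (tn + fp)), mcc = mcc)
  }, numeric(2)))
  best <- which(abs(stats[, "crit"] - min(stats[, "crit"])) <= 1e-12)
  best <- best[order(-stats[best, "mcc"], cand[best])][1]
  cand[best]
}
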