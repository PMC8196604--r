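#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the probability-ordering definition: the
#' sum of hypergeometric probabilities of all tables with fixed margins no
#' more probable than the observed one (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return An `enrichment_result` list: `test = "fisher"`, `k` (top-left
#'   cell), `n` (grand total), `p_value`, `aux$odds_ratio` (conditional MLE).
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_2x2: need a 2x2 table",
                                      call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_2x2: counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("fisher_2x2: grand total must be positive",
                          call. = FALSE)
  ft <- fisher.test(tab, alternative = "two.sided")
  enrichment_result(test = "fisher", k = tab[1, 1], n = sum(tab),
                    p0 = NA_real_, direction = NA_character_,
                    p_value = ft$p.value,
                    aux = list(odds_ratio = unname(ft$estimate)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample of the absolute difference of
#' the two empirical CDFs. The p-value is exact for small tie-free samples
#' (both n <= 25) and asymptotic (with the effective-n correction) otherwise.
#'
#' @param x,y Nonempty numeric samples.
#' @return An `enrichment_result` with `test = "ks"`, `aux$D`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("ks_two_sample: both samples must be nonempty", call. = FALSE)
  }
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !anyDuplicated(c(x, y))
  kt <- suppressWarnings(ks.test(x, y, exact = exact))
  enrichment_result(test = "ks", k = length(x), n = length(x) + length(y),
                    p0 = NA_real_, direction = NA_character_,
                    p_value = kt$p.value,
                    aux = list(D = unname(kt$statistic)))
}

#' Per-class arithmetic means of a score
#'
#' @param scores Numeric vector.
#' @param labels Logical vector of classes; both must be nonempty.
#' @return Named numeric vector `c(mean_pos=, mean_neg=)`.
#' @export
class_means <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (!any(labels) || !any(!labels)) {
    stop("class_means: both classes must be nonempty", call. = FALSE)
  }
  c(mean_pos = mean(scores[labels]), mean_neg = mean(scores[!labels]))
}

#' Specify a feature-plane quadrant
#'
#' Defines the cut point and boundary rule on each of two features. The four
#' corners produced by the two cuts partition all records having both
#' features. `x_high`/`y_high` select the corner: `TRUE` means the corner on
#' the high side of the cut. Boundary rules state whether a value exactly at
#' the cut belongs to the *low* side (`"low"`) or the *high* side (`"high"`).
#' The defaults encode the burial/conservation convention: buried means
#' RSA <= 0.2 (boundary to the low side), conserved means f_WT > 50
#' (boundary to the low side).
#'
#' @param x_feature,y_feature Column names in the variant records.
#' @param x_cut,y_cut Cut points in feature units.
#' @param x_boundary,y_boundary `"low"` or `"high"`: which side a value
#'   exactly at the cut belongs to.
#' @return A `quadrant_spec` list.
#' @export
quadrant_spec <- function(x_feature = "rsa", y_feature = "f_wt",
                          x_cut = 0.2, y_cut = 50,
                          x_boundary = c("low", "high"),
                          y_boundary = c("low", "high")) {
  structure(list(
    x_feature = x_feature, y_feature = y_feature,
    x_cut = x_cut, y_cut = y_cut,
    x_boundary = match.arg(x_boundary),
    y_boundary = match.arg(y_boundary)
  ), class = "quadrant_spec")
}

side_of_cut <- function(v, cut, boundary) {
  if (boundary == "low") v > cut else v >= cut
}

#' Corner counts of positives in a feature plane
#'
#' Assigns every record with both features present to one of the four
#' corners defined by `spec` and counts, per corner, the number of records
#' (`n`) and the number of positive-labelled records (`k`). Records missing
#' either feature are dropped and their count reported via a message.
#'
#' @param ds A [variant_dataset()].
#' @param spec A [quadrant_spec()].
#' @param labels Logical vector aligned with the records.
#' @return Tibble with columns `corner` (e.g. `"x_low&y_high"`), `x_high`,
#'   `y_high`, `k`, `n`.
#' @export
quadrant_counts <- function(ds, spec, labels) {
  r <- ds$records
  for (f in c(spec$x_feature, spec$y_feature)) {
    if (!f %in% names(r)) stop("quadrant_counts: feature '", f,
                               "' absent from dataset", call. = FALSE)
  }
  x <- r[[spec$x_feature]]; y <- r[[spec$y_feature]]
  ok <- !is.na(x) & !is.na(y) & !is.na(labels)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message(sprintf("quadrant_counts: dropped %d record(s) missing %s/%s",
                    n_drop, spec$x_feature, spec$y_feature))
  }
  x <- x[ok]; y <- y[ok]; lab <- as.logical(labels[ok])
  xh <- side_of_cut(x, spec$x_cut, spec$x_boundary)
  yh <- side_of_cut(y, spec$y_cut, spec$y_boundary)
  grid <- expand.grid(x_high = c(FALSE, TRUE), y_high = c(FALSE, TRUE))
  tibble::tibble(
    corner = paste0("x_", ifelse(grid$x_high, "high", "low"),
                    "&y_", ifelse(grid$y_high, "high", "low")),
    x_high = grid$x_high,
    y_high = grid$y_high,
    k = mapply(function(a, b) sum(lab[xh == a & yh == b]),
               grid$x_high, grid$y_high),
    n = mapply(function(a, b) sum(xh == a & yh == b),
               grid$x_high, grid$y_high)
  )
}

#' One-sided exact binomial corner test
#'
#' Tests whether `k` positives among `n` corner records is more (enrichment,
#' p = P\[X >= k\]) or fewer (depletion, p = P\[X <= k\]) than expected under
#' X ~ Binomial(n, p0), where `p0` is the background positive fraction. The
#' tail is an exact pmf summation.
#'
#' @param k Successes in the corner.
#' @param n Corner size.
#' @param p0 Background success probability, in (0, 1).
#' @param direction `"enrichment"` or `"depletion"`.
#' @return An `enrichment_result` with `test = "binomial"`.
#' @export
binomial_corner_test <- function(k, n, p0,
                                 direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  if (!(p0 > 0 && p0 < 1)) stop("binomial_corner_test: p0 must be in (0, 1)",
                                call. = FALSE)
  if (k < 0 || k > n) stop("binomial_corner_test: need 0 <= k <= n",
                           call. = FALSE)
  p <- if (direction == "enrichment") {
    pbinom(k - 1, n, p0, lower.tail = FALSE)  # P[X >= k]
  } else {
    pbinom(k, n, p0)                          # P[X <= k]
  }
  enrichment_result(test = "binomial", k = k, n = n, p0 = p0,
                    direction = direction, p_value = p, aux = list())
}

#' Buried/exposed fractions by class
#'
#' Fraction of positive-labelled records that are buried (RSA <= `rsa_cut`)
#' and fraction of negative-labelled records that are exposed
#' (RSA > `rsa_cut`).
#'
#' @param ds A [variant_dataset()].
#' @param labels Logical vector aligned with the records.
#' @param rsa_cut Burial cutoff on relative solvent accessibility.
#' @return Named numeric vector `c(frac_pos_buried=, frac_neg_exposed=)`.
#' @export
burial_fractions <- function(ds, labels, rsa_cut = 0.2) {
  rsa <- ds$records$rsa
  ok <- !is.na(rsa) & !is.na(labels)
  rsa <- rsa[ok]; lab <- as.logical(labels[ok])
  if (!any(lab) || !any(!lab)) {
    stop("burial_fractions: both classes must be nonempty", call. = FALSE)
  }
  c(frac_pos_buried = mean(rsa[lab] <= rsa_cut),
    frac_neg_exposed = mean(rsa[!lab] > rsa_cut))
}

enrichment_result <- function(test, k, n, p0, direction, p_value, aux) {
  structure(list(test = test, k = k, n = n, p0 = p0, direction = direction,
                 p_value = p_value, aux = aux),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  extra <- if (length(x$aux) > 0) {
    paste0(" | ", paste(names(x$aux), signif(unlist(x$aux), 4),
                        sep = " = ", collapse = ", "))
  } else ""
  dir <- if (is.na(x$direction)) "" else paste0(" (", x$direction, ")")
  cat(sprintf("%s test%s: k = %d / n = %d, p = %.3g%s\n",
              x$test, dir, x$k, x$n, x$p_value, extra))
  invisible(x)
}
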