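#' Analysis configuration
#'
#' Bundles every tunable of the full evaluation. The fixed decision
#' thresholds are the conventional operating points for the two predictors:
#' 1.2 kcal/mol (predicted ddG vs the 2 kcal/mol destabilization label),
#' 0.66 (pathogenicity score vs the destabilization label), 0.71
#' (pathogenicity score vs driver annotation), 2.7 kcal/mol (predicted ddG
#' vs driver annotation) and 0.5 (pathogenicity cut in the feature-plane
#' quadrant analysis). The balanced-rate optimizer is always run alongside
#' the fixed thresholds, and both results are reported.
#'
#' @param input Path to a variant table, or `NULL` to use the synthetic
#'   study-shaped preset.
#' @param outlier_keys Variants excluded from the "filtered" regression
#'   summary, as `"protein p.XnY"` strings.
#' @param destab_cut Experimental ddG cut defining the destabilization
#'   label (kcal/mol, strict `>`).
#' @param foldx_destab_threshold,metasnp_destab_threshold Fixed decision
#'   thresholds for the destabilization task.
#' @param foldx_pcv_threshold,metasnp_pcv_threshold Fixed decision
#'   thresholds for the driver (PCV) task.
#' @param quadrant_patho_cut Pathogenicity cut used in the quadrant
#'   analysis.
#' @param rsa_cut,fwt_cut Burial and conservation cuts (RSA fraction,
#'   percent).
#' @param per_protein_groups Protein groups given protein-specific
#'   thresholds in the destabilization task.
#' @param cv_folds Folds for cross-validated threshold selection.
#' @param seed Integer seed (fold assignment; synthetic preset).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL,
                            outlier_keys = "BRCA1 p.G1788V",
                            destab_cut = 2.0,
                            foldx_destab_threshold = 1.2,
                            metasnp_destab_threshold = 0.66,
                            foldx_pcv_threshold = 2.7,
                            metasnp_pcv_threshold = 0.71,
                            quadrant_patho_cut = 0.5,
                            rsa_cut = 0.2,
                            fwt_cut = 50,
                            per_protein_groups = c("p53-DBD", "BRCA1"),
                            cv_folds = 5,
                            seed = 1L) {
  structure(list(input = input, outlier_keys = outlier_keys,
                 destab_cut = destab_cut,
                 foldx_destab_threshold = foldx_destab_threshold,
                 metasnp_destab_threshold = metasnp_destab_threshold,
                 foldx_pcv_threshold = foldx_pcv_threshold,
                 metasnp_pcv_threshold = metasnp_pcv_threshold,
                 quadrant_patho_cut = quadrant_patho_cut,
                 rsa_cut = rsa_cut, fwt_cut = fwt_cut,
                 per_protein_groups = per_protein_groups,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "analysis_config")
}

regression_row <- function(slice, rm) {
  tibble::tibble(slice = slice, n = rm$n, pearson_r = rm$pearson_r,
                 spearman_rho = rm$spearman_rho, kendall_tau = rm$kendall_tau,
                 rmse = rm$rmse, mae = rm$mae)
}

classification_row <- function(predictor, slice, threshold_type, cm) {
  tibble::tibble(predictor = predictor, slice = slice,
                 threshold_type = threshold_type, threshold = cm$threshold,
                 tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                 accuracy = cm$accuracy, mcc = cm$mcc, auc = cm$auc,
                 tpr = cm$tpr, tnr = cm$tnr)
}

#' Stability-prediction evaluation
#'
#' Regression metrics of predicted vs experimental ddG: pooled over all
#' records with both values, pooled after excluding the configured outlier
#' variants, and per protein group. Groups with fewer than two complete
#' pairs are skipped with a message. Outlier keys absent from the dataset
#' (e.g. on synthetic data) are skipped with a message rather than an
#' error.
#'
#' @param ds A [variant_dataset()].
#' @param cfg An [analysis_config()].
#' @return Tibble with one row per slice (see `regression_metrics`).
#' @export
run_stability_eval <- function(ds, cfg) {
  r <- ds$records
  out <- list(regression_row("pooled",
                             regression_metrics(r$ddg_pred, r$ddg_exp)))
  keys_present <- tryCatch({
    ds_f <- exclude_outliers(ds, cfg$outlier_keys); TRUE
  }, error = function(e) FALSE)
  if (length(cfg$outlier_keys) > 0 && keys_present) {
    rf <- ds_f$records
    out <- c(out, list(regression_row("pooled_filtered",
                                      regression_metrics(rf$ddg_pred,
                                                         rf$ddg_exp))))
  } else if (length(cfg$outlier_keys) > 0) {
    message("run_stability_eval: outlier key(s) not in dataset; ",
            "filtered slice skipped")
  }
  for (p in unique(r$protein_id)) {
    g <- r[r$protein_id == p, ]
    n_ok <- sum(!is.na(g$ddg_pred) & !is.na(g$ddg_exp))
    if (n_ok < 2) {
      message("run_stability_eval: group '", p, "' has n < 2, skipped")
      next
    }
    out <- c(out, list(regression_row(p, regression_metrics(g$ddg_pred,
                                                            g$ddg_exp))))
  }
  dplyr::bind_rows(out)
}

eval_predictor <- function(scores, labels, predictor, slice, fixed, cfg) {
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]; l <- labels[ok]
  if (!any(l) || !any(!l)) {
    message("run classification: slice '", slice, "' (", predictor,
            ") has a single class, skipped")
    return(tibble::tibble())
  }
  rows <- list(classification_row(predictor, slice, "fixed",
                                  confusion_at(s, l, fixed)))
  opt <- optimize_threshold(s, l)
  rows <- c(rows, list(classification_row(predictor, slice, "optimized",
                                          confusion_at(s, l, opt$threshold))))
  if (min(sum(l), sum(!l)) >= cfg$cv_folds) {
    cv <- cv_threshold(s, l, k = cfg$cv_folds, seed = cfg$seed)
    rows <- c(rows, list(classification_row(predictor, slice, "cv",
                                            confusion_at(s, l, cv$threshold))))
  }
  dplyr::bind_rows(rows)
}

#' Destabilization-classification evaluation
#'
#' Binary classification of highly destabilizing variants (experimental
#' ddG > `destab_cut`) from (a) the predicted ddG and (b) the pathogenicity
#' score. For each predictor the fixed threshold, the balanced-rate
#' optimized threshold and (when both classes allow) the cross-validated
#' threshold are reported, pooled and — for the predicted ddG — per
#' configured protein group. Because the relation between the pathogenicity
#' score and the destabilization label can be summarized either against the
#' binary label or against the continuous ddG, both Pearson coefficients
#' are attached as attributes (`score_vs_label_r`, `score_vs_ddg_r`).
#'
#' @param ds A [variant_dataset()].
#' @param cfg An [analysis_config()].
#' @return Tibble with one row per (predictor, slice, threshold type).
#' @export
run_destab_classification <- function(ds, cfg) {
  r <- ds$records
  labels <- suppressMessages(label_destabilizing(ds, cfg$destab_cut))
  out <- list(
    eval_predictor(r$ddg_pred, labels, "foldx", "pooled",
                   cfg$foldx_destab_threshold, cfg),
    eval_predictor(r$patho_score, labels, "metasnp", "pooled",
                   cfg$metasnp_destab_threshold, cfg)
  )
  for (p in intersect(cfg$per_protein_groups, unique(r$protein_id))) {
    sel <- r$protein_id == p
    out <- c(out, list(eval_predictor(r$ddg_pred[sel], labels[sel], "foldx",
                                      p, cfg$foldx_destab_threshold, cfg)))
  }
  res <- dplyr::bind_rows(out)
  ok <- !is.na(r$patho_score) & !is.na(labels)
  attr(res, "score_vs_label_r") <-
    if (sum(ok) >= 2 && length(unique(labels[ok])) == 2) {
      cor(r$patho_score[ok], as.numeric(labels[ok]))
    } else NA_real_
  ok2 <- !is.na(r$patho_score) & !is.na(r$ddg_exp)
  attr(res, "score_vs_ddg_r") <-
    if (sum(ok2) >= 2 && sd(r$patho_score[ok2]) > 0 && sd(r$ddg_exp[ok2]) > 0) {
      cor(r$patho_score[ok2], r$ddg_exp[ok2])
    } else NA_real_
  res
}

#' Driver-variant (PCV) classification evaluation
#'
#' Classification of Tier 1-3 (putative cancer-driving) vs "Other"
#' (treated-as-benign) variants on the CMC-annotated subset with
#' predictor-training variants removed: the pathogenicity score at its
#' fixed threshold and the predicted ddG at its fixed threshold, each also
#' with the balanced-rate optimized threshold.
#'
#' @param ds A [variant_dataset()].
#' @param cfg An [analysis_config()].
#' @return Tibble with one row per (predictor, threshold type).
#' @export
run_pcv_classification <- function(ds, cfg) {
  sub <- exclude_training_variants(filter_cmc_annotated(ds))
  labels <- label_pcv(sub)
  r <- sub$records
  dplyr::bind_rows(
    eval_predictor(r$patho_score, labels, "metasnp", "cmc_eval",
                   cfg$metasnp_pcv_threshold, cfg),
    eval_predictor(r$ddg_pred, labels, "foldx", "cmc_eval",
                   cfg$foldx_pcv_threshold, cfg)
  )
}

#' Enrichment and distribution-comparison analyses
#'
#' On the CMC-annotated subset: Fisher exact test of driver annotation
#' (Tier 1-3) against destabilization (experimental ddG > `destab_cut`);
#' two-sample Kolmogorov-Smirnov comparison and class means of the
#' pathogenicity score between Tier 1-3 and "Other" (both on the
#' training-excluded subset, so the score comparison is not circular);
#' buried/exposed fractions by class; and four one-sided exact binomial
#' corner tests in two feature planes — burial x conservation
#' (RSA <= `rsa_cut` and f_WT > `fwt_cut`: enrichment in the
#' buried-conserved corner, depletion in the exposed-unconserved corner)
#' and destabilization x pathogenicity (ddG > `destab_cut` and
#' score > `quadrant_patho_cut`). The binomial background `p0` is the
#' Tier 1-3 fraction of the annotated subset.
#'
#' @param ds A [variant_dataset()].
#' @param cfg An [analysis_config()].
#' @return Tibble with columns `test`, `slice`, `k`, `n`, `p0`,
#'   `statistic`, `direction`, `p_value`; class means and burial fractions
#'   are attached as attributes (`class_means`, `burial_fractions`).
#' @export
run_enrichment <- function(ds, cfg) {
  ann <- filter_cmc_annotated(ds)
  lab_ann <- label_pcv(ann)
  r <- ann$records
  destab <- suppressMessages(label_destabilizing(ann, cfg$destab_cut))
  rows <- list()
  # Fisher: driver annotation x destabilization
  ok <- !is.na(destab)
  tab <- matrix(c(sum(lab_ann[ok] & destab[ok]), sum(lab_ann[ok] & !destab[ok]),
                  sum(!lab_ann[ok] & destab[ok]), sum(!lab_ann[ok] & !destab[ok])),
                nrow = 2, byrow = TRUE)
  fi <- fisher_2x2(tab)
  rows <- c(rows, list(tibble::tibble(
    test = "fisher", slice = "tier_x_destab", k = fi$k, n = fi$n,
    p0 = NA_real_, statistic = fi$aux$odds_ratio,
    direction = NA_character_, p_value = fi$p_value)))
  # KS + class means of the pathogenicity score, training variants removed
  ev <- exclude_training_variants(ann)
  lab_ev <- label_pcv(ev)
  sc <- ev$records$patho_score
  ks <- ks_two_sample(sc[lab_ev], sc[!lab_ev])
  rows <- c(rows, list(tibble::tibble(
    test = "ks", slice = "patho_by_tier", k = ks$k, n = ks$n,
    p0 = NA_real_, statistic = ks$aux$D,
    direction = NA_character_, p_value = ks$p_value)))
  cm <- class_means(sc, lab_ev)
  bf <- burial_fractions(ann, lab_ann, rsa_cut = cfg$rsa_cut)
  # quadrant tests; p0 = driver fraction of the annotated subset
  p0 <- mean(lab_ann)
  corner_row <- function(slice, counts, x_high, y_high, direction) {
    cr <- counts[counts$x_high == x_high & counts$y_high == y_high, ]
    bt <- binomial_corner_test(cr$k, cr$n, p0, direction)
    tibble::tibble(test = "binomial", slice = slice, k = bt$k, n = bt$n,
                   p0 = p0, statistic = NA_real_, direction = direction,
                   p_value = bt$p_value)
  }
  qs1 <- quadrant_spec("rsa", "f_wt", cfg$rsa_cut, cfg$fwt_cut)
  qc1 <- suppressMessages(quadrant_counts(ann, qs1, lab_ann))
  rows <- c(rows, list(
    corner_row("buried_conserved", qc1, FALSE, TRUE, "enrichment"),
    corner_row("exposed_unconserved", qc1, TRUE, FALSE, "depletion")))
  qs2 <- quadrant_spec("ddg_exp", "patho_score",
                       cfg$destab_cut, cfg$quadrant_patho_cut)
  qc2 <- suppressMessages(quadrant_counts(ann, qs2, lab_ann))
  rows <- c(rows, list(
    corner_row("destab_pathogenic", qc2, TRUE, TRUE, "enrichment"),
    corner_row("stable_benign", qc2, FALSE, FALSE, "depletion")))
  res <- dplyr::bind_rows(rows)
  attr(res, "class_means") <- cm
  attr(res, "burial_fractions") <- bf
  res
}

#' Run the full evaluation pipeline
#'
#' Loads the input table (or generates the synthetic study-shaped preset
#' when `cfg$input` is `NULL`), runs the four analysis sections in order —
#' stability regression, destabilization classification, driver (PCV)
#' classification, enrichment — and optionally writes one tidy CSV per
#' section plus a markdown report and a provenance file under `out_dir`.
#' Identical config and seed give byte-identical report bodies.
#'
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return An `analysis_report` list: `stability`, `destab_classification`,
#'   `pcv_classification`, `enrichment`, `provenance`.
#' @export
run_all <- function(cfg = analysis_config(), out_dir = NULL) {
  if (is.null(cfg$input)) {
    ds <- paper_shaped_dataset(cfg$seed)$dataset
  } else {
    ds <- read_variant_table(cfg$input)
  }
  report <- structure(list(
    stability = run_stability_eval(ds, cfg),
    destab_classification = suppressMessages(run_destab_classification(ds, cfg)),
    pcv_classification = suppressMessages(run_pcv_classification(ds, cfg)),
    enrichment = suppressMessages(run_enrichment(ds, cfg)),
    provenance = list(config = unclass(cfg), dataset = ds$provenance,
                      n_records = n_variants(ds))
  ), class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' One CSV per section, a human-readable markdown summary, and the config
#' echoed as JSON.
#'
#' @param report An `analysis_report` from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$stability, file.path(out_dir, "stability.csv"))
  readr::write_csv(report$destab_classification,
                   file.path(out_dir, "destab_classification.csv"))
  readr::write_csv(report$pcv_classification,
                   file.path(out_dir, "pcv_classification.csv"))
  readr::write_csv(report$enrichment, file.path(out_dir, "enrichment.csv"))
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  md <- c("# Variant stability & pathogenicity evaluation", "",
          sprintf("Records analysed: %d", report$provenance$n_records), "",
          "## Stability regression",
          report_table_md(report$stability), "",
          "## Destabilization classification",
          report_table_md(report$destab_classification), "",
          "## Driver (PCV) classification",
          report_table_md(report$pcv_classification), "",
          "## Enrichment",
          report_table_md(report$enrichment), "",
          sprintf("Pathogenicity class means (driver/benign): %.3f / %.3f",
                  attr(report$enrichment, "class_means")[["mean_pos"]],
                  attr(report$enrichment, "class_means")[["mean_neg"]]),
          sprintf("Buried fraction of drivers: %.3f; exposed fraction of benign: %.3f",
                  attr(report$enrichment, "burial_fractions")[["frac_pos_buried"]],
                  attr(report$enrichment, "burial_fractions")[["frac_neg_exposed"]]))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_table_md <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  fmt <- df
  fmt[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(row) {
    paste0("| ", paste(as.character(row), collapse = " | "), " |")
  })
  c(header, sep, body)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  records: %d\n", x$provenance$n_records))
  cat(sprintf("  stability slices: %d | classification rows: %d + %d | enrichment tests: %d\n",
              nrow(x$stability), nrow(x$destab_classification),
              nrow(x$pcv_classification), nrow(x$enrichment)))
  invisible(x)
}
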