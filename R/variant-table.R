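#' @importFrom rlang .data
#' @importFrom stats median sd cor ks.test fisher.test pbinom dbinom qnorm
#'   pnorm runif rnorm rbeta rbinom quantile setNames
#' @importFrom utils head
NULL

# Canonical one-letter amino acid codes
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CMC_LEVELS <- c("TIER1", "TIER2", "TIER3", "OTHER", "UNANNOTATED")

VARIANT_COLUMNS <- c("protein_id", "structure_id", "variant", "ddg_exp",
                     "dtm", "ddg_pred", "patho_score", "rsa", "f_wt",
                     "cmc", "n_tumor_samples", "is_training")

#' Construct a variant dataset
#'
#' A `variant_dataset` couples a tibble of single amino acid variant (SAV)
#' records with a provenance trail of the filters applied to it. One row is
#' one missense variant with experimental folding free energy change
#' (`ddg_exp`, kcal/mol, positive = destabilizing), optional melting
#' temperature shift (`dtm`, degrees C), predicted ddG (`ddg_pred`),
#' pathogenicity score in \[0,1\] (`patho_score`), relative solvent
#' accessibility (`rsa`, fraction), wild-type residue conservation
#' (`f_wt`, percent), and a Cancer Mutation Census annotation (`cmc`, one of
#' TIER1/TIER2/TIER3/OTHER/UNANNOTATED).
#'
#' @param records Tibble with columns `protein_id`, `structure_id`, `wt_aa`,
#'   `position`, `mut_aa`, `ddg_exp`, `dtm`, `ddg_pred`, `patho_score`,
#'   `rsa`, `f_wt`, `cmc`, `n_tumor_samples`, `is_training`.
#' @param provenance Character vector describing filters already applied.
#' @return An object of class `variant_dataset`.
#' @export
variant_dataset <- function(records, provenance = character()) {
  records <- tibble::as_tibble(records)
  validate_variant_records(records)
  structure(list(records = records, provenance = provenance),
            class = "variant_dataset")
}

validate_variant_records <- function(records, where = "record") {
  needed <- c("protein_id", "wt_aa", "position", "mut_aa", "ddg_exp", "cmc")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("variant records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  chk <- function(ok, what) {
    bad <- which(!ok & !is.na(ok))
    if (length(bad) > 0) {
      stop(sprintf("%s %d: %s", where, bad[1], what), call. = FALSE)
    }
  }
  chk(records$wt_aa %in% AA_CODES, "wild-type residue not a canonical amino acid")
  chk(records$mut_aa %in% AA_CODES, "mutant residue not a canonical amino acid")
  chk(records$wt_aa != records$mut_aa, "wild-type and mutant residues identical")
  chk(records$position >= 1, "residue position must be >= 1")
  if ("rsa" %in% names(records)) {
    chk(records$rsa >= 0 & records$rsa <= 1, "rsa outside [0, 1]")
  }
  if ("patho_score" %in% names(records)) {
    chk(records$patho_score >= 0 & records$patho_score <= 1,
        "patho_score outside [0, 1]")
  }
  if ("f_wt" %in% names(records)) {
    chk(records$f_wt >= 0 & records$f_wt <= 100, "f_wt outside [0, 100]")
  }
  chk(records$cmc %in% CMC_LEVELS,
      paste("cmc annotation not one of", paste(CMC_LEVELS, collapse = "/")))
  key <- variant_key(records)
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    stop("duplicate variant key: ", dup, call. = FALSE)
  }
  invisible(records)
}

variant_key <- function(records) {
  paste(records$protein_id, records$wt_aa, records$position, records$mut_aa,
        sep = "|")
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat(sprintf("<variant_dataset> %d variants, %d proteins\n",
              nrow(x$records), length(unique(x$records$protein_id))))
  if (length(x$provenance) > 0) {
    cat("provenance:\n")
    for (p in x$provenance) cat(" -", p, "\n")
  }
  print(x$records, ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.variant_dataset <- function(x, ...) x$records

#' Number of variant records
#' @param ds A `variant_dataset`.
#' @return Integer count of records.
#' @export
n_variants <- function(ds) nrow(ds$records)

append_provenance <- function(ds, entry) {
  ds$provenance <- c(ds$provenance, entry)
  ds
}

#' Parse a protein-level variant token
#'
#' Accepts tokens like `"p.M1775R"` or `"R38M"`: an optional `"p."` prefix,
#' a one-letter wild-type residue, a 1-based position, and a one-letter
#' mutant residue.
#'
#' @param token Character scalar (or vector) to parse.
#' @return A tibble with columns `wt_aa`, `position`, `mut_aa`.
#' @examples
#' parse_variant_notation("p.M1775R")
#' parse_variant_notation("R38M")
#' @export
parse_variant_notation <- function(token) {
  stopifnot(is.character(token), length(token) >= 1)
  m <- regmatches(token, regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", token))
  out <- lapply(seq_along(token), function(i) {
    g <- m[[i]]
    if (length(g) != 4) {
      stop("malformed variant token: '", token[i], "'", call. = FALSE)
    }
    wt <- toupper(g[2]); mut <- toupper(g[4]); pos <- as.integer(g[3])
    if (!(wt %in% AA_CODES)) {
      stop("non-canonical wild-type residue in token: '", token[i], "'",
           call. = FALSE)
    }
    if (!(mut %in% AA_CODES)) {
      stop("non-canonical mutant residue in token: '", token[i], "'",
           call. = FALSE)
    }
    if (pos < 1) {
      stop("position must be >= 1 in token: '", token[i], "'", call. = FALSE)
    }
    if (wt == mut) {
      stop("wild-type and mutant residues identical in token: '", token[i],
           "'", call. = FALSE)
    }
    list(wt_aa = wt, position = pos, mut_aa = mut)
  })
  tibble::tibble(
    wt_aa = vapply(out, `[[`, character(1), "wt_aa"),
    position = vapply(out, `[[`, integer(1), "position"),
    mut_aa = vapply(out, `[[`, character(1), "mut_aa")
  )
}

#' Format a variant triple in protein (p.) notation
#'
#' @param wt_aa,position,mut_aa Vectors of wild-type residue, position and
#'   mutant residue.
#' @return Character vector like `"p.M1775R"`.
#' @export
format_variant_notation <- function(wt_aa, position, mut_aa) {
  paste0("p.", wt_aa, position, mut_aa)
}

#' Read a delimited variant table
#'
#' Reads a UTF-8 comma- or tab-separated file (delimiter auto-detected from
#' the header) with mandatory columns `protein_id` and `variant` and the
#' optional columns `structure_id`, `ddg_exp`, `dtm`, `ddg_pred`,
#' `patho_score`, `rsa`, `f_wt`, `cmc`, `n_tumor_samples`, `is_training`.
#' Empty cells become missing values, never zeros. Duplicate variant keys
#' and out-of-range values are hard errors reported with their row number.
#'
#' @param path Path to the delimited file.
#' @return A [variant_dataset()].
#' @export
read_variant_table <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("\t", header)) "\t" else ","
  col_spec <- list(
    protein_id = readr::col_character(),
    structure_id = readr::col_character(),
    variant = readr::col_character(),
    ddg_exp = readr::col_double(),
    dtm = readr::col_double(),
    ddg_pred = readr::col_double(),
    patho_score = readr::col_double(),
    rsa = readr::col_double(),
    f_wt = readr::col_double(),
    cmc = readr::col_character(),
    n_tumor_samples = readr::col_integer(),
    is_training = readr::col_logical()
  )
  present <- strsplit(header, delim, fixed = TRUE)[[1]]
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = do.call(readr::cols, col_spec[intersect(names(col_spec),
                                                        present)]),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  required <- c("protein_id", "variant")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(VARIANT_COLUMNS, names(raw))) {
    raw[[col]] <- switch(col,
      structure_id = NA_character_,
      cmc = "UNANNOTATED",
      n_tumor_samples = NA_integer_,
      is_training = FALSE,
      NA_real_)
  }
  parsed <- parse_variant_notation(raw$variant)
  records <- tibble::tibble(
    protein_id = raw$protein_id,
    structure_id = ifelse(is.na(raw$structure_id), "", raw$structure_id),
    wt_aa = parsed$wt_aa,
    position = parsed$position,
    mut_aa = parsed$mut_aa,
    ddg_exp = raw$ddg_exp,
    dtm = raw$dtm,
    ddg_pred = raw$ddg_pred,
    patho_score = raw$patho_score,
    rsa = raw$rsa,
    f_wt = raw$f_wt,
    cmc = ifelse(is.na(raw$cmc), "UNANNOTATED", toupper(raw$cmc)),
    n_tumor_samples = raw$n_tumor_samples,
    is_training = ifelse(is.na(raw$is_training), FALSE, raw$is_training)
  )
  validate_variant_records(records, where = "row")
  variant_dataset(records,
                  provenance = sprintf("read_variant_table(%s)", basename(path)))
}

#' Write a variant dataset to a delimited file
#'
#' Emits the fixed column layout of [read_variant_table()], with variants in
#' `p.` notation. Round-trips all non-missing values.
#'
#' @param ds A [variant_dataset()].
#' @param path Output file path.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(ds, path, delim = "\t") {
  r <- ds$records
  out <- tibble::tibble(
    protein_id = r$protein_id,
    structure_id = r$structure_id,
    variant = format_variant_notation(r$wt_aa, r$position, r$mut_aa),
    ddg_exp = r$ddg_exp,
    dtm = r$dtm,
    ddg_pred = r$ddg_pred,
    patho_score = r$patho_score,
    rsa = r$rsa,
    f_wt = r$f_wt,
    cmc = r$cmc,
    n_tumor_samples = r$n_tumor_samples,
    is_training = r$is_training
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Keep only CMC-annotated variants
#'
#' Retains records annotated in the Cancer Mutation Census as Tier 1-3 or
#' "Other"; unannotated records are dropped. The applied filter is recorded
#' in the dataset provenance.
#'
#' @param ds A [variant_dataset()].
#' @return The filtered `variant_dataset`.
#' @export
filter_cmc_annotated <- function(ds) {
  keep <- ds$records$cmc %in% c("TIER1", "TIER2", "TIER3", "OTHER")
  ds$records <- ds$records[keep, , drop = FALSE]
  append_provenance(ds, sprintf("filter_cmc_annotated(kept=%d)", sum(keep)))
}

#' Exclude predictor training variants
#'
#' Removes records flagged `is_training = TRUE`, i.e. variants used to train
#' the pathogenicity meta-predictor, so its evaluation is not circular.
#'
#' @param ds A [variant_dataset()].
#' @return The filtered `variant_dataset`.
#' @export
exclude_training_variants <- function(ds) {
  keep <- !ds$records$is_training
  ds$records <- ds$records[keep, , drop = FALSE]
  append_provenance(ds,
                    sprintf("exclude_training_variants(removed=%d)", sum(!keep)))
}

#' Label highly destabilizing variants
#'
#' A variant is labelled destabilizing when its experimental ddG strictly
#' exceeds `cut` kcal/mol (records at exactly `cut` are negative). Records
#' with missing `ddg_exp` get `NA` and their count is reported via a
#' warning-level message.
#'
#' @param ds A [variant_dataset()].
#' @param cut Destabilization cutoff in kcal/mol (default 2.0).
#' @return Logical vector aligned with the records (`NA` where `ddg_exp`
#'   is missing).
#' @export
label_destabilizing <- function(ds, cut = 2.0) {
  x <- ds$records$ddg_exp
  n_missing <- sum(is.na(x))
  if (n_missing > 0) {
    message(sprintf("label_destabilizing: %d record(s) lack ddg_exp and are unlabelled",
                    n_missing))
  }
  x > cut
}

#' Label putative cancer-driving variants (PCVs)
#'
#' CMC Tier 1-3 records are positive (putative drivers); "Other" records are
#' negative (treated as benign). Unannotated records violate the contract:
#' apply [filter_cmc_annotated()] first.
#'
#' @param ds A [variant_dataset()].
#' @return Logical vector aligned with the records.
#' @export
label_pcv <- function(ds) {
  cmc <- ds$records$cmc
  if (any(cmc == "UNANNOTATED")) {
    stop("label_pcv: dataset contains UNANNOTATED records; ",
         "apply filter_cmc_annotated() first", call. = FALSE)
  }
  cmc %in% c("TIER1", "TIER2", "TIER3")
}

#' Remove named outlier variants
#'
#' Drops records whose `(protein_id, variant)` keys appear in `keys`, e.g.
#' predictor failure cases excluded from regression summaries. Unknown keys
#' are an error.
#'
#' @param ds A [variant_dataset()].
#' @param keys Character vector like `"BRCA1 p.G1788V"` (protein id, space,
#'   variant token).
#' @return The filtered `variant_dataset`.
#' @export
exclude_outliers <- function(ds, keys) {
  if (length(keys) == 0) return(ds)
  r <- ds$records
  have <- paste(r$protein_id,
                format_variant_notation(r$wt_aa, r$position, r$mut_aa))
  norm_key <- function(k) {
    parts <- strsplit(k, "\\s+")[[1]]
    if (length(parts) != 2) stop("outlier key must be 'protein variant': '",
                                 k, "'", call. = FALSE)
    p <- parse_variant_notation(parts[2])
    paste(parts[1], format_variant_notation(p$wt_aa, p$position, p$mut_aa))
  }
  wanted <- vapply(keys, norm_key, character(1))
  unknown <- setdiff(wanted, have)
  if (length(unknown) > 0) {
    stop("unknown outlier key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(have %in% wanted)
  ds$records <- ds$records[keep, , drop = FALSE]
  append_provenance(ds, sprintf("exclude_outliers(%s)",
                                paste(wanted, collapse = "; ")))
}
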