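test_that("variant notation parses and round-trips", {
  p <- parse_variant_notation("p.M1775R")
  expect_equal(p$wt_aa, "M")
  expect_equal(p$position, 1775L)
  expect_equal(p$mut_aa, "R")
  # prefix optional on input
  expect_equal(parse_variant_notation("R38M"),
               parse_variant_notation("p.R38M"))
  # round trip through formatting
  toks <- c("p.M1775R", "p.R38M", "p.G1788V")
  p <- parse_variant_notation(toks)
  expect_equal(format_variant_notation(p$wt_aa, p$position, p$mut_aa), toks)
})

test_that("malformed variant tokens are rejected with the offending token", {
  expect_error(parse_variant_notation("p.A0G"), "A0G")
  expect_error(parse_variant_notation("p.M12M"), "identical")
  expect_error(parse_variant_notation("p.X10R"), "non-canonical")
  expect_error(parse_variant_notation("M17"), "malformed")
  expect_error(parse_variant_notation("p.M17.5R"), "malformed")
})

test_that("variant tables round-trip through read/write", {
  path <- write_toy_table()
  ds <- read_variant_table(path)
  expect_equal(n_variants(ds), 6)
  expect_equal(ds$records, toy_records())
  # comma dialect auto-detected too
  path2 <- write_toy_table(delim = ",")
  expect_equal(read_variant_table(path2)$records, toy_records())
})

test_that("missing cells load as missing values, never zeros", {
  ds <- read_variant_table(write_toy_table())
  expect_true(is.na(ds$records$dtm[2]))
  expect_equal(sum(!is.na(ds$records$dtm)), 3)
  expect_false(any(ds$records$dtm == 0, na.rm = TRUE))
})

test_that("loader rejects bad input with located errors", {
  # out-of-range rsa
  bad <- toy_records()
  bad$rsa[3] <- 1.3
  p <- tempfile(fileext = ".tsv")
  write_variant_table(variant_dataset(toy_records()), p)
  lines <- readLines(p)
  lines[4] <- sub("0.3", "1.3", lines[4])
  writeLines(lines, p)
  expect_error(read_variant_table(p), "rsa")
  # duplicate key
  dup <- toy_records()[c(1:6, 1), ]
  expect_error(variant_dataset(dup), "duplicate")
  # missing required column
  p2 <- tempfile(fileext = ".tsv")
  tab <- readr::read_tsv(write_toy_table(), show_col_types = FALSE)
  readr::write_tsv(tab[setdiff(names(tab), "variant")], p2)
  expect_error(read_variant_table(p2), "variant")
})

test_that("CMC filtering keeps annotated records and logs provenance", {
  ds <- toy_dataset()
  ann <- filter_cmc_annotated(ds)
  expect_equal(n_variants(ann), 5)
  expect_true(all(ann$records$cmc != "UNANNOTATED"))
  expect_match(ann$provenance[length(ann$provenance)], "filter_cmc_annotated")
  # empty annotation set -> empty dataset
  none <- toy_records()
  none$cmc <- "UNANNOTATED"
  expect_equal(n_variants(filter_cmc_annotated(variant_dataset(none))), 0)
})

test_that("training-variant exclusion works and commutes with CMC filter", {
  ds <- toy_dataset()
  ex <- exclude_training_variants(ds)
  expect_equal(n_variants(ex), 5)
  expect_false(any(ex$records$is_training))
  a <- exclude_training_variants(filter_cmc_annotated(ds))
  b <- filter_cmc_annotated(exclude_training_variants(ds))
  expect_setequal(
    paste(a$records$protein_id, a$records$position),
    paste(b$records$protein_id, b$records$position)
  )
  # no flags -> identity; all flags -> empty
  none <- toy_records(); none$is_training <- FALSE
  expect_equal(n_variants(exclude_training_variants(variant_dataset(none))), 6)
  all_tr <- toy_records(); all_tr$is_training <- TRUE
  expect_equal(n_variants(exclude_training_variants(variant_dataset(all_tr))), 0)
})

test_that("destabilization labels use a strict cut and partition the set", {
  ds <- toy_dataset()
  lab <- label_destabilizing(ds)
  expect_equal(sum(lab), 3)  # 3.5, 3.0, 2.7
  # value exactly at the cut is negative
  at_cut <- toy_records(); at_cut$ddg_exp[1] <- 2.0
  expect_false(label_destabilizing(variant_dataset(at_cut))[1])
  # cut below the minimum labels everything positive
  expect_true(all(label_destabilizing(ds, cut = min(ds$records$ddg_exp) - 1)))
  # positives + negatives + missing = dataset size, for any cut
  with_na <- toy_records(); with_na$ddg_exp[4] <- NA
  dna <- variant_dataset(with_na)
  for (cut in c(-1, 0.5, 2, 10)) {
    l <- suppressMessages(label_destabilizing(dna, cut))
    expect_equal(sum(l, na.rm = TRUE) + sum(!l, na.rm = TRUE) + sum(is.na(l)),
                 n_variants(dna))
  }
  expect_message(label_destabilizing(dna), "1 record")
})

test_that("PCV labels map tiers to positive and reject unannotated input", {
  ann <- filter_cmc_annotated(toy_dataset())
  lab <- label_pcv(ann)
  expect_equal(sum(lab), 2)
  expect_equal(lab, ann$records$cmc %in% c("TIER1", "TIER2", "TIER3"))
  all_other <- toy_records(); all_other$cmc <- "OTHER"
  expect_false(any(label_pcv(variant_dataset(all_other))))
  expect_error(label_pcv(toy_dataset()), "UNANNOTATED")
})

test_that("named outliers are removed and unknown keys rejected", {
  ds <- toy_dataset()
  out <- exclude_outliers(ds, "BRCA1 p.G1788V")
  expect_equal(n_variants(out), 5)
  expect_false(any(out$records$position == 1788))
  expect_equal(exclude_outliers(ds, character(0)), ds)
  expect_error(exclude_outliers(ds, "BRCA1 p.A99G"), "unknown")
})
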