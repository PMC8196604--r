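# Residue-type maximum accessible surface areas (A^2) for RSA normalization.
# "tien2013": theoretical maxima of Tien et al. (2013), the most widely used
# scale. "sander1994": the Sander-Rost scale.
MAX_ASA <- list(
  tien2013 = c(
    A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
  ),
  sander1994 = c(
    A = 106.0, R = 248.0, N = 157.0, D = 163.0, C = 135.0,
    E = 194.0, Q = 198.0, G = 84.0, H = 184.0, I = 169.0,
    L = 164.0, K = 205.0, M = 188.0, F = 197.0, P = 136.0,
    S = 130.0, T = 142.0, W = 227.0, Y = 222.0, V = 142.0
  )
)

#' Relative solvent accessibility from absolute accessibility
#'
#' Divides the absolute solvent-accessible surface area (as computed by
#' DSSP) by the residue-type maximum from a published scale, clamped to
#' \[0, 1\].
#'
#' @param residue One-letter amino acid code(s).
#' @param asa Absolute accessible surface area in square Angstroms (>= 0).
#' @param scale `"tien2013"` (default) or `"sander1994"`.
#' @return RSA fraction(s) in \[0, 1\].
#' @export
rsa_from_asa <- function(residue, asa, scale = c("tien2013", "sander1994")) {
  scale <- match.arg(scale)
  maxasa <- MAX_ASA[[scale]][toupper(residue)]
  if (any(is.na(maxasa))) {
    bad <- residue[is.na(maxasa)][1]
    stop("rsa_from_asa: unknown residue code '", bad, "'", call. = FALSE)
  }
  if (any(asa < 0, na.rm = TRUE)) {
    stop("rsa_from_asa: asa must be >= 0", call. = FALSE)
  }
  pmin(asa / unname(maxasa), 1)
}

#' Classify a residue as buried or exposed
#'
#' Buried means RSA <= `cut`; the boundary value itself is buried.
#'
#' @param rsa RSA fraction(s) in \[0, 1\].
#' @param cut Burial cutoff (default 0.2).
#' @return Character vector `"buried"`/`"exposed"`.
#' @export
burial_class <- function(rsa, cut = 0.2) {
  stopifnot(all(rsa >= 0 & rsa <= 1, na.rm = TRUE))
  ifelse(rsa <= cut, "buried", "exposed")
}

#' Wild-type residue frequency in an alignment column
#'
#' Percent frequency of the wild-type residue among the non-gap symbols of
#' one multiple-sequence-alignment column. Gap symbols (`"-"`) are excluded
#' from the denominator.
#'
#' @param residues Character vector of one-letter codes and `"-"` gaps.
#' @param wt_aa The wild-type residue.
#' @return Percent in \[0, 100\].
#' @export
wt_frequency <- function(residues, wt_aa) {
  if (length(residues) == 0) stop("wt_frequency: empty column", call. = FALSE)
  res <- toupper(residues)
  non_gap <- res[res != "-"]
  if (length(non_gap) == 0) stop("wt_frequency: all-gap column", call. = FALSE)
  100 * sum(non_gap == toupper(wt_aa)) / length(non_gap)
}

#' Parse per-residue accessibility from a DSSP output file
#'
#' Reads the per-residue block of a DSSP file (the fixed-width section after
#' the `#  RESIDUE AA` header line) and extracts the residue number, chain,
#' amino acid and ACC column, adding RSA via [rsa_from_asa()]. Chain breaks
#' (`!` rows) are skipped.
#'
#' @param path Path to a DSSP-format file.
#' @param scale Max-ASA scale passed to [rsa_from_asa()].
#' @return Tibble with columns `position`, `chain`, `residue`, `asa`, `rsa`.
#' @export
read_dssp_acc <- function(path, scale = "tien2013") {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("read_dssp_acc: no per-residue header in '",
                             path, "'", call. = FALSE)
  body <- lines[(hdr[1] + 1):length(lines)]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & nzchar(trimws(substr(body, 6, 10)))
  body <- body[keep]; aa <- aa[keep]
  # lowercase letters mark SS-bonded cysteines in DSSP
  aa <- ifelse(aa %in% letters, "C", aa)
  pos <- as.integer(trimws(substr(body, 6, 10)))
  chain <- trimws(substr(body, 12, 12))
  asa <- as.numeric(trimws(substr(body, 35, 38)))
  tibble::tibble(
    position = pos, chain = chain, residue = aa, asa = asa,
    rsa = rsa_from_asa(aa, asa, scale = scale)
  )
}

#' Per-site conservation from a FASTA alignment
#'
#' Reads an aligned FASTA file (all sequences equal length) and returns, for
#' each requested site, the wild-type residue frequency of the
#' first-sequence (reference) column, computed with [wt_frequency()].
#' Positions index the reference sequence without counting its gaps.
#'
#' @param path Path to an aligned FASTA file.
#' @param positions Integer vector of 1-based reference positions (default:
#'   every reference residue).
#' @return Tibble with columns `position`, `wt_aa`, `f_wt`.
#' @export
alignment_conservation <- function(path, positions = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("alignment_conservation requires the Biostrings package",
         call. = FALSE)
  }
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0) stop("alignment_conservation: empty alignment",
                             call. = FALSE)
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  ref <- mat[1, ]
  ref_cols <- which(ref != "-")
  if (is.null(positions)) positions <- seq_along(ref_cols)
  if (any(positions < 1 | positions > length(ref_cols))) {
    stop("alignment_conservation: position outside reference sequence",
         call. = FALSE)
  }
  cols <- ref_cols[positions]
  tibble::tibble(
    position = positions,
    wt_aa = ref[cols],
    f_wt = vapply(seq_along(cols), function(i) {
      wt_frequency(mat[, cols[i]], ref[cols[i]])
    }, numeric(1))
  )
}
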