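## GWAS summary statistics: reading, allele harmonization against a panel,
## and variant filtering.

SUMSTATS_ALIASES <- list(
  id   = c("SNP", "ID", "RSID", "MARKERNAME", "VARIANT_ID"),
  chrom = c("CHR", "CHROM", "CHROMOSOME"),
  pos  = c("BP", "POS", "POSITION", "BASE_PAIR_LOCATION"),
  a1   = c("A1", "EA", "EFFECT_ALLELE", "ALLELE1"),
  a2   = c("A2", "OA", "OTHER_ALLELE", "ALLELE2", "ALLELE0"),
  z    = c("Z", "ZSCORE", "Z_STAT"),
  beta = c("BETA", "B", "EFFECT"),
  se   = c("SE", "STDERR", "STANDARD_ERROR"),
  n    = c("N", "NEFF", "N_TOTAL"),
  info = c("INFO", "IMPINFO", "IMPUTATION_QUALITY"),
  freq = c("FRQ", "FREQ", "EAF", "AF1", "EFFECT_ALLELE_FREQUENCY"))

#' Read one GWAS summary-statistics table
#'
#' Whitespace- or tab-delimited text with a header.  Standard column names
#' (LDSC / GWAS-SSF style) are recognized automatically; `column_map` can
#' rename non-standard headers, e.g. `c(z = "ZSTAT", id = "MARKER")`.  When
#' no z column is present, `z = beta / se` is computed.  Rows with missing
#' required fields are dropped and counted in the attached log.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   (id, chrom, pos, a1, a2, z, beta, se, n, info, freq) to file headers.
#' @param n_const constant sample size to use when the file has no N column.
#' @return data.frame of class `sumstats` with columns id, chrom, pos, a1,
#'   a2, z, n (and info / freq when present); attribute `log` holds drop
#'   counts.
#' @export
read_sumstats <- function(path, column_map = NULL, n_const = NULL) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(tab) == 0) stop("no parseable rows in ", path)
  hdr <- toupper(names(tab))
  col_idx <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      i <- match(toupper(column_map[[canon]]), hdr)
      if (is.na(i)) stop("column_map names absent column '",
                         column_map[[canon]], "' for field ", canon)
      return(i)
    }
    match(TRUE, hdr %in% SUMSTATS_ALIASES[[canon]])
  }
  idx <- lapply(setNames(nm = names(SUMSTATS_ALIASES)), col_idx)
  if (is.na(idx$z) && (is.na(idx$beta) || is.na(idx$se)))
    stop("no association statistic found in ", path,
         ": need Z, or both BETA and SE")
  need <- c("id", "chrom", "pos", "a1", "a2")
  missing_req <- need[vapply(idx[need], is.na, TRUE)]
  if (length(missing_req))
    stop("required column(s) not found in ", path, ": ",
         paste(toupper(missing_req), collapse = ", "))

  out <- data.frame(id = as.character(tab[[idx$id]]),
                    chrom = suppressWarnings(as.integer(tab[[idx$chrom]])),
                    pos = suppressWarnings(as.integer(tab[[idx$pos]])),
                    a1 = toupper(as.character(tab[[idx$a1]])),
                    a2 = toupper(as.character(tab[[idx$a2]])),
                    stringsAsFactors = FALSE)
  out$z <- if (!is.na(idx$z)) as.numeric(tab[[idx$z]]) else
    as.numeric(tab[[idx$beta]]) / as.numeric(tab[[idx$se]])
  out$n <- if (!is.na(idx$n)) as.numeric(tab[[idx$n]]) else
    if (!is.null(n_const)) rep(as.numeric(n_const), nrow(out)) else
      stop("no sample-size column in ", path,
           " and no constant N supplied (n_const)")
  if (!is.na(idx$info)) out$info <- as.numeric(tab[[idx$info]])
  if (!is.na(idx$freq)) out$freq <- as.numeric(tab[[idx$freq]])

  n_in <- nrow(out)
  incomplete <- !stats::complete.cases(out[c("id", "chrom", "pos", "a1",
                                             "a2", "z", "n")]) |
    !is.finite(out$z) | out$n <= 0
  out <- out[!incomplete, , drop = FALSE]
  dup <- duplicated(out$id)
  out <- out[!dup, , drop = FALSE]
  if (nrow(out) == 0) stop("no usable rows in ", path)
  if (any(!is.na(out$info) & (out$info < -1e-9 | out$info > 1 + 1e-6)))
    stop("INFO values outside [0, 1] in ", path)
  attr(out, "log") <- list(rows_in = n_in, dropped_incomplete = sum(incomplete),
                           dropped_duplicate_id = sum(dup),
                           rows_out = nrow(out))
  class(out) <- c("sumstats", "data.frame")
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize three summary-statistics tables against a variant panel
#'
#' Keeps variants present in all three tables and in the panel.  When a
#' table's allele pair equals the panel's in swapped order, the z sign is
#' flipped; strand-ambiguous (A/T, C/G) variants are dropped, as are allele
#' mismatches.  Applying the result to itself is the identity.
#'
#' @param tables list of three `sumstats` tables.
#' @param panel_variants data.frame with columns id, a1, a2 (an
#'   `ld_panel$variants` works directly).
#' @return list with `idx` (panel indices of retained variants), `z` and
#'   `n` (matrices, one column per trait), `info` (matrix, NA when a table
#'   has no INFO), and `log` (per-reason drop counts).
#' @export
harmonize_sumstats <- function(tables, panel_variants) {
  stopifnot(length(tables) == 3)
  pv <- panel_variants
  pa1 <- toupper(pv$a1); pa2 <- toupper(pv$a2)
  n_panel <- nrow(pv)
  keep <- rep(TRUE, n_panel)
  zs <- ns <- infos <- matrix(NA_real_, n_panel, 3)
  log <- list()
  for (i in 1:3) {
    t <- tables[[i]]
    m <- match(pv$id, t$id)
    present <- !is.na(m)
    same <- present & t$a1[m] == pa1 & t$a2[m] == pa2
    swap <- present & t$a1[m] == pa2 & t$a2[m] == pa1
    palin <- present & is_palindromic(t$a1[m], t$a2[m])
    ok <- (same | swap) & !palin
    log[[paste0("trait", i)]] <-
      list(absent = sum(!present),
           allele_mismatch = sum(present & !(same | swap)),
           palindromic = sum(palin & (same | swap)))
    keep <- keep & ok
    sgn <- ifelse(swap, -1, 1)
    zs[, i] <- sgn * t$z[m]
    ns[, i] <- t$n[m]
    if (!is.null(t$info)) infos[, i] <- t$info[m]
  }
  if (!any(keep)) stop("no variants shared by all three tables and the panel")
  list(idx = which(keep),
       z = zs[keep, , drop = FALSE],
       n = ns[keep, , drop = FALSE],
       info = infos[keep, , drop = FALSE],
       log = c(log, list(retained = sum(keep))))
}

#' Variant filter configuration
#'
#' Thresholds are inclusive for retention: a variant is kept when
#' `MAF >= maf_thresh`, `INFO >= info_thresh` (ignored where INFO is
#' missing), `|z| <= z_thresh` in all three traits, and its position lies
#' outside every exclude region (1-based inclusive coordinates).
#'
#' @param maf_thresh minor-allele-frequency threshold in \[0, 0.5\].
#' @param info_thresh imputation-quality threshold in \[0, 1\].
#' @param z_thresh absolute z-score ceiling (> 0).
#' @param exclude_regions list of `c(chrom, start, end)` triples; the
#'   default masks the major histocompatibility complex on hg19.
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_thresh = 0.05, info_thresh = 0.8,
                          z_thresh = 32,
                          exclude_regions = list(c(6, 25e6, 34e6))) {
  stopifnot(maf_thresh >= 0, maf_thresh <= 0.5,
            info_thresh >= 0, info_thresh <= 1, z_thresh > 0)
  for (r in exclude_regions)
    if (length(r) != 3 || r[2] > r[3])
      stop("exclude regions must be (chrom, start, end) with start <= end")
  structure(list(maf_thresh = maf_thresh, info_thresh = info_thresh,
                 z_thresh = z_thresh, exclude_regions = exclude_regions),
            class = "filter_config")
}

#' Apply variant filters to harmonized data
#'
#' Frequencies are taken from the LD panel (the same genotypes the r2
#' estimates come from), not from the summary statistics.
#'
#' @param aligned result of [harmonize_sumstats].
#' @param cfg a [filter_config].
#' @param panel the `ld_panel` the data were harmonized against (supplies
#'   freq, chrom, pos for the aligned variants).
#' @return list with `idx` (retained panel indices, a subset of
#'   `aligned$idx`), `keep` (logical over aligned rows) and `log`.
#' @export
apply_filters <- function(aligned, cfg, panel) {
  v <- panel$variants[aligned$idx, , drop = FALSE]
  if (anyNA(v$freq)) stop("panel frequencies missing for aligned variants")
  maf_ok <- pmin(v$freq, 1 - v$freq) >= cfg$maf_thresh
  info <- aligned$info
  info_ok <- apply(is.na(info) | info >= cfg$info_thresh, 1, all)
  z_ok <- apply(abs(aligned$z) <= cfg$z_thresh, 1, all)
  region_ok <- rep(TRUE, nrow(v))
  for (r in cfg$exclude_regions)
    region_ok <- region_ok &
      !(v$chrom == r[1] & v$pos >= r[2] & v$pos <= r[3])
  keep <- maf_ok & info_ok & z_ok & region_ok
  list(idx = aligned$idx[keep], keep = keep,
       log = list(n_in = nrow(v),
                  dropped_maf = sum(!maf_ok),
                  dropped_info = sum(maf_ok & !info_ok),
                  dropped_z = sum(maf_ok & info_ok & !z_ok),
                  dropped_region = sum(maf_ok & info_ok & z_ok & !region_ok),
                  n_out = sum(keep)))
}
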