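## LD reference panel: pairwise r2 neighbor lists, heterozygosity,
## random pruning and tag-variant subsetting.
##
## Neighborhoods are stored in compressed sparse row form (nbr_ptr /
## nbr_idx / nbr_r2) over the panel variant order; every variant is its own
## neighbor with r2 = 1, and lists are symmetric by construction.  Only r2
## is kept: each mixture component is zero-mean, so the characteristic
## function depends on r_jk only through its square — signed LD is not
## needed on the fitting side.

#' Heterozygosity of a variant
#'
#' `h = 2 f (1 - f)` for allele frequency `f`; weights a variant's
#' contribution to the z-scores of its LD neighbors.
#'
#' @param freq allele frequency in \[0, 1\] (vectorized).
#' @return heterozygosity in \[0, 0.5\].
#' @examples heterozygosity(c(0.5, 0.1, 0))
#' @export
heterozygosity <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("allele frequency outside [0, 1]")
  2 * freq * (1 - freq)
}

#' Assemble an LD panel from variant metadata and symmetric pair lists
#'
#' Internal constructor shared by the text reader and the simulator.
#' `pairs` rows are (i, j, r2) with i != j, each unordered pair listed once.
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2, freq.
#' @param pairs data.frame/list with integer columns i, j and numeric r2.
#' @param dedupe drop duplicated (i, j) rows with a warning.
#' @return object of class `ld_panel`.
#' @export
ld_panel <- function(variants, pairs = NULL, dedupe = TRUE) {
  stopifnot(all(c("id", "chrom", "pos", "a1", "a2", "freq") %in%
                  names(variants)))
  n <- nrow(variants)
  if (anyDuplicated(variants$id))
    stop("duplicated variant IDs in panel metadata")
  if (is.null(pairs) || length(pairs$i) == 0) {
    i <- integer(0); j <- integer(0); r2 <- numeric(0)
  } else {
    i <- as.integer(pairs$i); j <- as.integer(pairs$j)
    r2 <- as.numeric(pairs$r2)
    if (any(i < 1 | i > n | j < 1 | j > n)) stop("pair index out of range")
    if (any(i == j)) stop("self-pairs are implicit; do not list them")
    if (any(r2 <= 0 | r2 > 1 + 1e-9)) stop("r2 must lie in (0, 1]")
    r2 <- pmin(r2, 1)
    key <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key)) {
      if (!dedupe) stop("duplicated variant pairs")
      warning(sum(duplicated(key)), " duplicated pair row(s) dropped")
      keep <- !duplicated(key)
      i <- i[keep]; j <- j[keep]; r2 <- r2[keep]
    }
  }
  ## symmetrize and add self-pairs
  src <- c(seq_len(n), i, j)
  dst <- c(seq_len(n), j, i)
  val <- c(rep(1, n), r2, r2)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; val <- val[o]
  ptr <- cumsum(c(0L, tabulate(src, nbins = n)))
  structure(list(variants = variants,
                 het = heterozygosity(variants$freq),
                 nbr_ptr = ptr, nbr_idx = dst, nbr_r2 = val),
            class = "ld_panel")
}

#' @exportS3Method base::print
print.ld_panel <- function(x, ...) {
  n <- nrow(x$variants)
  cat(sprintf(
    "LD panel: %d variants, %d stored pairs (incl. self), mean neighborhood size %.2f\n",
    n, length(x$nbr_idx), length(x$nbr_idx) / n))
  invisible(x)
}

#' Neighborhood of one variant
#'
#' @param panel an `ld_panel`.
#' @param j variant index.
#' @return list with `idx` (neighbor indices, self included) and `r2`.
#' @export
ld_neighbors <- function(panel, j) {
  sel <- (panel$nbr_ptr[j] + 1L):panel$nbr_ptr[j + 1L]
  list(idx = panel$nbr_idx[sel], r2 = panel$nbr_r2[sel])
}

#' Read an LD panel from PLINK-style r2 text tables
#'
#' Accepts one file per chromosome in the PLINK `--r2` text dialect
#' (whitespace-delimited, header `CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2`),
#' plus a variant metadata table carrying allele frequencies.  Pairs below
#' the r2 floor used when the files were produced are simply absent and are
#' treated as r2 = 0.
#'
#' @param paths character vector of per-chromosome pair files.
#' @param panel_meta data.frame with columns id, chrom, pos, a1, a2, freq
#'   (column names as in [read_sumstats] metadata: ID/SNP, CHR, BP, A1, A2,
#'   FRQ also accepted).
#' @return an `ld_panel`.
#' @export
load_ld_text <- function(paths, panel_meta) {
  panel_meta <- normalize_panel_meta(panel_meta)
  idx_of <- setNames(seq_len(nrow(panel_meta)), panel_meta$id)
  ii <- integer(0); jj <- integer(0); rr <- numeric(0)
  for (p in paths) {
    tab <- data.table::fread(p, header = TRUE, data.table = FALSE)
    need <- c("SNP_A", "SNP_B", "R2")
    if (!all(need %in% names(tab)))
      stop("LD pair file ", p, " lacks required columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    if (nrow(tab) == 0) next
    bad <- !is.finite(tab$R2) | tab$R2 <= 0 | tab$R2 > 1 + 1e-9
    if (any(bad))
      stop(sprintf("malformed r2 value in %s at data line %d", p,
                   which(bad)[1]))
    a <- idx_of[as.character(tab$SNP_A)]
    b <- idx_of[as.character(tab$SNP_B)]
    if (anyNA(a) || anyNA(b)) {
      miss <- c(tab$SNP_A[is.na(a)], tab$SNP_B[is.na(b)])[1]
      stop("LD pair file ", p, " references unknown variant ID: ", miss)
    }
    ii <- c(ii, a); jj <- c(jj, b); rr <- c(rr, pmin(tab$R2, 1))
  }
  ld_panel(panel_meta, list(i = ii, j = jj, r2 = rr))
}

normalize_panel_meta <- function(meta) {
  nm <- toupper(names(meta))
  pick <- function(cands, required = TRUE) {
    hit <- which(nm %in% cands)[1]
    if (is.na(hit)) {
      if (required) stop("panel metadata lacks column: ",
                         paste(cands, collapse = "/"))
      return(NULL)
    }
    meta[[hit]]
  }
  data.frame(id = as.character(pick(c("ID", "SNP"))),
             chrom = as.integer(pick(c("CHROM", "CHR"))),
             pos = as.integer(pick(c("POS", "BP"))),
             a1 = toupper(as.character(pick(c("A1", "EA")))),
             a2 = toupper(as.character(pick(c("A2", "OA")))),
             freq = as.numeric(pick(c("FREQ", "FRQ", "EAF", "MAF"))),
             stringsAsFactors = FALSE)
}

#' Write neighbor pairs in the PLINK r2 text dialect
#'
#' Emits each unordered pair once (self-pairs omitted), so the output
#' round-trips through [load_ld_text].
#'
#' @param panel an `ld_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ld_text <- function(panel, path) {
  n <- nrow(panel$variants)
  src <- rep.int(seq_len(n), diff(panel$nbr_ptr))
  keep <- src < panel$nbr_idx
  v <- panel$variants
  a <- src[keep]; b <- panel$nbr_idx[keep]
  out <- data.frame(CHR_A = v$chrom[a], BP_A = v$pos[a], SNP_A = v$id[a],
                    CHR_B = v$chrom[b], BP_B = v$pos[b], SNP_B = v$id[b],
                    R2 = signif(panel$nbr_r2[keep], 8))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Randomly prune a panel at an r2 threshold
#'
#' Variants are visited in a seeded random order; a variant is kept iff no
#' already-kept variant is in LD with it at `r2 >= r2_thresh`.  The result
#' is maximal for the visit order and deterministic given
#' (panel, threshold, seed).
#'
#' @param panel an `ld_panel`.
#' @param r2_thresh pruning threshold in (0, 1].
#' @param seed integer seed; drives the visit order.
#' @param within optional candidate indices (e.g. filter survivors); only
#'   these are visited and only conflicts among them count.
#' @return list with `kept` (indices in panel order) and `seed`.
#' @export
random_prune <- function(panel, r2_thresh = 0.8, seed = 1L, within = NULL) {
  stopifnot(r2_thresh > 0, r2_thresh <= 1)
  n <- nrow(panel$variants)
  cand <- if (is.null(within)) seq_len(n) else sort(unique(as.integer(within)))
  ord <- with_seed_local(seed, cand[sample.int(length(cand))])
  kept <- logical(n)
  ptr <- panel$nbr_ptr; idx <- panel$nbr_idx; r2 <- panel$nbr_r2
  for (j in ord) {
    sel <- (ptr[j] + 1L):ptr[j + 1L]
    nb <- idx[sel]
    if (!any(kept[nb] & r2[sel] >= r2_thresh & nb != j)) kept[j] <- TRUE
  }
  list(kept = which(kept), seed = as.integer(seed))
}

#' Random subset of tag variants for optimization
#'
#' Uniform sample without replacement of `min(n_random, |kept|)` indices.
#' The same seed drives both the pruning and the subsetting stage, so a
#' single `rand_prune_seed` reproduces a run's variant selection.
#'
#' @param kept integer vector of candidate indices (typically
#'   `random_prune(...)$kept`).
#' @param n_random requested subset size (>= 1).
#' @param seed integer seed.
#' @return sorted integer vector of selected indices.
#' @export
select_subset <- function(kept, n_random, seed = 1L) {
  stopifnot(n_random >= 1)
  if (n_random >= length(kept)) return(sort(kept))
  sort(with_seed_local(seed + 0.5, kept[sample.int(length(kept),
                                                   n_random)]))
}

## Evaluate expr under a deterministic RNG state without touching the
## caller's stream.  Non-integer seeds are hashed onto the integer range so
## stage seeds derived from one user seed stay distinct.
with_seed_local <- function(seed, expr) {
  seed <- as.integer((as.numeric(seed) * 2654435761) %% 2147483647)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
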