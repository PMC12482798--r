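## Euler decomposition of the trivariate overlap, feasibility bounds,
## maximum-entropy baseline, and pattern utilities.

#' Feasible interval for the triple overlap
#'
#' Given univariate polygenicities `pi_u = (pi1u, pi2u, pi3u)` and bivariate
#' overlaps `pi_b = (pi12b, pi13b, pi23b)`, the triple overlap is constrained
#' to `[lo, hi]` with
#' `lo = max(0, pi12b + pi13b - pi1u, pi12b + pi23b - pi2u,
#'           pi13b + pi23b - pi3u)` and `hi = min(pi_b)`.
#'
#' @param pi_u numeric(3) univariate polygenicities.
#' @param pi_b numeric(3) bivariate overlaps, `pi_b[k] <= min` of the two
#'   univariate polygenicities it links.
#' @return list with elements `lo` and `hi` (`0 <= lo <= hi`).
#' @export
pi123_bounds <- function(pi_u, pi_b) {
  stopifnot(length(pi_u) == 3, length(pi_b) == 3)
  if (any(pi_b < -1e-15)) stop("bivariate overlaps must be non-negative")
  lo <- max(0,
            pi_b[1] + pi_b[2] - pi_u[1],
            pi_b[1] + pi_b[3] - pi_u[2],
            pi_b[2] + pi_b[3] - pi_u[3])
  hi <- min(pi_b)
  if (lo > hi + 1e-12)
    stop(sprintf(paste0("infeasible univariate/bivariate combination: ",
                        "pi123 lower bound %.3g exceeds upper bound %.3g ",
                        "(pi_u = %s; pi_b = %s)"),
                 lo, hi, paste(signif(pi_u, 4), collapse = ","),
                 paste(signif(pi_b, 4), collapse = ",")))
  list(lo = lo, hi = max(lo, hi))
}

#' Decompose univariate/bivariate polygenicities into the Euler pattern
#'
#' Applies the identities `pi_ij = pi_ij^b - pi123` and
#' `pi_i = pi_i^u - pi_ij - pi_ik - pi123` to produce the seven disjoint
#' components.  Negative components within numerical noise (|x| < 1e-10)
#' are clipped to zero; larger violations are an error.
#'
#' @inheritParams pi123_bounds
#' @param pi123 scalar triple overlap, within [pi123_bounds].
#' @param source one of `"fitted"`, `"naive"`, `"truth"`.
#' @return an `overlap_pattern`: list with `pi7` (named numeric(7)),
#'   `union` (sum of the seven), `source`.
#' @export
decompose_overlap <- function(pi_u, pi_b, pi123, source = "fitted") {
  stopifnot(length(pi123) == 1)
  pair <- pi_b - pi123
  spec <- c(pi_u[1] - pair[1] - pair[2] - pi123,
            pi_u[2] - pair[1] - pair[3] - pi123,
            pi_u[3] - pair[2] - pair[3] - pi123)
  pi7 <- setNames(c(spec, pair, pi123), PI7_NAMES)
  bad <- pi7 < -1e-10
  if (any(bad))
    stop(sprintf("infeasible decomposition: component(s) %s negative (%s)",
                 paste(PI7_NAMES[bad], collapse = ","),
                 paste(signif(pi7[bad], 4), collapse = ",")))
  pi7[pi7 < 0] <- 0
  structure(list(pi7 = pi7, union = sum(pi7),
                 source = match.arg(source, c("fitted", "naive", "truth"))),
            class = "overlap_pattern")
}

#' @exportS3Method base::print
print.overlap_pattern <- function(x, ...) {
  cat(sprintf("Overlap pattern (%s), union = %.4g\n", x$source, x$union))
  pct <- euler_percentages(x)
  for (i in seq_along(PI7_NAMES))
    cat(sprintf("  %-6s %.4g  (%d%% of union)\n", PI7_NAMES[i], x$pi7[i],
                pct$rounded[i]))
  invisible(x)
}

## Feasibility-clipped decomposition for runs whose univariate/bivariate
## estimates are jointly infeasible: negative components are floored at
## zero and the violation is recorded.  Margins of the result are inexact;
## callers flag such runs.
clipped_pattern <- function(pi_u, pi_b, pi123, source = "fitted") {
  pair <- pmax(pi_b - pi123, 0)
  spec <- pmax(c(pi_u[1] - pair[1] - pair[2] - pi123,
                 pi_u[2] - pair[1] - pair[3] - pi123,
                 pi_u[3] - pair[2] - pair[3] - pi123), 0)
  pi7 <- setNames(c(spec, pair, pi123), PI7_NAMES)
  structure(list(pi7 = pi7, union = sum(pi7), source = source,
                 clipped = TRUE),
            class = "overlap_pattern")
}

#' Shannon entropy of an overlap pattern
#'
#' `H = sum over the seven components of -p * log(p)` with natural log and
#' the convention `0 * log 0 = 0`.  Computed on the raw (unnormalized)
#' proportions, exactly as the maximum-entropy baseline is defined.
#'
#' @param pattern an `overlap_pattern`, or a numeric(7) of components.
#' @return non-negative scalar.
#' @export
overlap_entropy <- function(pattern) {
  p <- if (inherits(pattern, "overlap_pattern")) pattern$pi7 else pattern
  stopifnot(length(p) == 7, all(p >= 0))
  nz <- p > 0
  sum(-p[nz] * log(p[nz]))
}

#' Maximum-entropy (naive) expectation of the triple overlap
#'
#' Without further information, the expected trivariate pattern for given
#' univariate and bivariate polygenicities is the one whose seven-component
#' pattern, viewed as a relative distribution (components divided by their
#' sum), has maximal Shannon entropy over the feasible `pi123` interval.
#' Normalization matters: the components' total itself varies with `pi123`,
#' and the entropy of the raw proportions is inflated by total mass alone,
#' so its argmax rewards larger overlap even for a perfectly balanced
#' pattern.  On the relative scale a balanced pattern (all seven components
#' equal) is its own maximum-entropy expectation, which is the property the
#' baseline is meant to have.  The argmax is found by a grid pre-scan
#' followed by local refinement.
#'
#' @inheritParams pi123_bounds
#' @param n_scan number of pre-scan grid points.
#' @return an `overlap_pattern` with `source = "naive"` and an extra element
#'   `pi123` (the argmax).
#' @export
naive_max_entropy <- function(pi_u, pi_b, n_scan = 201) {
  b <- pi123_bounds(pi_u, pi_b)
  if (b$hi - b$lo < .Machine$double.eps) {
    pat <- decompose_overlap(pi_u, pi_b, b$lo, source = "naive")
    pat$pi123 <- b$lo
    return(pat)
  }
  h_of <- function(x) {
    p7 <- decompose_overlap(pi_u, pi_b, x)$pi7
    overlap_entropy(p7 / sum(p7))
  }
  grid <- seq(b$lo, b$hi, length.out = n_scan)
  i0 <- which.max(vapply(grid, h_of, 0))
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(n_scan, i0 + 1)]
  opt <- optimize(h_of, interval = c(lo, hi), maximum = TRUE,
                  tol = (b$hi - b$lo) * 1e-9 + 1e-15)
  pat <- decompose_overlap(pi_u, pi_b, opt$maximum, source = "naive")
  pat$pi123 <- opt$maximum
  pat
}

#' Express a pattern as percentages of the polygenic union
#'
#' The figure convention: each of the seven components as a percentage of
#' the combined total (union) polygenicity, reported rounded to the nearest
#' integer alongside full precision.  An optional reference union allows
#' percentages of a naive pattern to be expressed relative to the fitted
#' union, as done when fitted and naive diagrams are compared.
#'
#' @param pattern an `overlap_pattern`.
#' @param union reference union; defaults to the pattern's own.
#' @return list with `percent` (numeric(7)), `rounded` (integer(7)).
#' @export
euler_percentages <- function(pattern, union = NULL) {
  u <- if (is.null(union)) pattern$union else union
  if (u <= 0) stop("union must be positive")
  pct <- 100 * pattern$pi7 / u
  list(percent = pct, rounded = as.integer(round(pct)))
}

#' Reconstruct univariate and bivariate polygenicities from a pattern
#'
#' Inverse of [decompose_overlap]: `pi_i^u = pi_i + pi_ij + pi_ik + pi123`,
#' `pi_ij^b = pi_ij + pi123`.
#'
#' @param pattern an `overlap_pattern`.
#' @return list with `pi_u` (numeric(3)) and `pi_b` (numeric(3)).
#' @export
pattern_margins <- function(pattern) {
  p <- pattern$pi7
  list(pi_u = c(p[["pi1"]] + p[["pi12"]] + p[["pi13"]] + p[["pi123"]],
                p[["pi2"]] + p[["pi12"]] + p[["pi23"]] + p[["pi123"]],
                p[["pi3"]] + p[["pi13"]] + p[["pi23"]] + p[["pi123"]]),
       pi_b = c(p[["pi12"]] + p[["pi123"]],
                p[["pi13"]] + p[["pi123"]],
                p[["pi23"]] + p[["pi123"]]))
}

#' Pearson correlation between two polygenicity parameter vectors
#'
#' Used to compare runs (e.g. the same data analysed with two different LD
#' reference panels): each run is summarized by the vector
#' `(pi1u, pi2u, pi3u, pi12b, pi13b, pi23b, pi123)` and pairs of runs are
#' correlated.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Pearson correlation coefficient.
#' @export
param_vector_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0)
    stop("parameter vector with zero variance: correlation undefined")
  cor(a, b)
}
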