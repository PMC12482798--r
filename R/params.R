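## Model parameters: the 19-parameter trivariate causal mixture.

#' Names of the seven non-null mixture components
#'
#' Order used throughout the package: phenotype-specific (1, 2, 3),
#' pair-specific (12, 13, 23), shared by all three (123).
#' @export
PI7_NAMES <- c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")

#' Construct and validate the 19-parameter mixture model
#'
#' The trivariate causal mixture model describes the direct (non-LD-induced)
#' allelic effects of each variant on three phenotypes as a mixture of eight
#' Gaussian components: a null component with probability `pi0 = 1 - sum(pi)`
#' and seven phenotype-influencing components.  Within each component the
#' active effects are zero-mean Gaussian with per-trait standard deviations
#' `sigma` (discoverability scale, per-allele units) and, within shared
#' components, effect-size correlations `rho`.  Residual z-score noise is
#' `N(0, Sigma0)` with per-trait standard deviations `sigma0` (z-score
#' units, 1 = no inflation) and cross-trait correlations `rho0` (e.g. from
#' sample overlap).
#'
#' @param pi numeric(7), mixture proportions in the order of [PI7_NAMES].
#' @param sigma numeric(3), per-trait effect-size standard deviations (> 0).
#' @param sigma0 numeric(3), per-trait residual standard deviations (> 0).
#' @param rho numeric(3), effect correlations (rho12, rho13, rho23) in (-1, 1).
#' @param rho0 numeric(3), residual correlations (rho012, rho013, rho023).
#' @return An object of class `mixture_params` (a named list).
#' @examples
#' p <- mixture_params(pi = c(rep(5e-4, 7)), sigma = rep(0.05, 3))
#' p$pi0
#' @export
mixture_params <- function(pi = rep(0, 7), sigma = rep(0.05, 3),
                           sigma0 = rep(1, 3), rho = rep(0, 3),
                           rho0 = rep(0, 3)) {
  stopifnot(length(pi) == 7, length(sigma) == 3, length(sigma0) == 3,
            length(rho) == 3, length(rho0) == 3)
  pi <- setNames(as.numeric(pi), PI7_NAMES)
  if (any(pi < 0)) stop("mixture proportions must be non-negative")
  if (sum(pi) > 1 + 1e-12) stop("sum of mixture proportions exceeds 1")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(sigma0 <= 0)) stop("sigma0 must be positive")
  if (any(abs(rho) >= 1) || any(abs(rho0) >= 1))
    stop("correlations must lie in (-1, 1)")
  obj <- structure(list(pi = pi, pi0 = max(0, 1 - sum(pi)),
                        sigma = as.numeric(sigma),
                        sigma0 = as.numeric(sigma0),
                        rho = as.numeric(rho), rho0 = as.numeric(rho0)),
                   class = "mixture_params")
  ## the triple-overlap component carries all three rho's jointly: require PSD
  if (min(eigen(component_covs(obj)[[7]], symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stop("effect correlations (rho12, rho13, rho23) give a non-PSD ",
         "covariance for the triple-overlap component")
  if (min(eigen(sigma0_cov(obj), symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stop("residual correlations give a non-PSD residual covariance")
  obj
}

#' @exportS3Method base::print
print.mixture_params <- function(x, ...) {
  cat("Trivariate causal mixture parameters\n")
  cat("  pi:    ", paste(sprintf("%s=%.3g", PI7_NAMES, x$pi), collapse = " "),
      "\n  pi0:   ", format(x$pi0, digits = 6),
      "\n  sigma: ", paste(sprintf("%.3g", x$sigma), collapse = " "),
      "\n  sigma0:", paste(sprintf("%.3g", x$sigma0), collapse = " "),
      "\n  rho:   ", paste(sprintf("%.3g", x$rho), collapse = " "),
      "\n  rho0:  ", paste(sprintf("%.3g", x$rho0), collapse = " "), "\n")
  invisible(x)
}

#' Covariance matrices of the seven phenotype-influencing components
#'
#' Returns the list of 3x3 effect covariance matrices in [PI7_NAMES] order.
#' Component `S` has `sigma_i^2` on the diagonal for each trait `i` in `S`,
#' `rho_ij sigma_i sigma_j` off-diagonal for pairs within `S`, zero
#' elsewhere.
#'
#' @param params a [mixture_params] object.
#' @return list of seven 3x3 matrices.
#' @export
component_covs <- function(params) {
  s <- params$sigma; r <- params$rho
  members <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  rho_full <- matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3, 3)
  lapply(members, function(m) {
    cov <- matrix(0, 3, 3)
    cov[m, m] <- rho_full[m, m, drop = FALSE] *
      tcrossprod(s[m])
    cov
  })
}

#' Residual covariance matrix Sigma0
#'
#' @param params a [mixture_params] object.
#' @return 3x3 covariance of the residual z-score noise.
#' @export
sigma0_cov <- function(params) {
  s <- params$sigma0; r <- params$rho0
  rho_full <- matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3, 3)
  rho_full * tcrossprod(s)
}

#' Marginalize the eight-component mixture onto a subset of traits
#'
#' Restricting the model to `active` traits collapses components whose
#' restricted covariance matrices coincide.  For the pair \{1,2\} the
#' effective components are: shared (`pi12 + pi123`), trait-1-specific
#' (`pi1 + pi13`), trait-2-specific (`pi2 + pi23`) and null
#' (`pi0 + pi3`); for a single trait the non-null weight is the
#' univariate polygenicity `pi_i^u`.  This is the exact marginal of the
#' printed eight-component mixture.
#'
#' @param params a [mixture_params] object.
#' @param active integer vector, non-empty subset of `1:3`.
#' @return list with `pi0` (effective null weight), `pis` (numeric vector of
#'   effective non-null weights), `covs` (list of dxd effect covariances),
#'   `sigma0` (dxd residual covariance), where `d = length(active)`.
#' @export
collapse_components <- function(params, active = 1:3) {
  active <- sort(unique(as.integer(active)))
  stopifnot(length(active) >= 1, all(active %in% 1:3))
  covs3 <- component_covs(params)
  restr <- lapply(covs3, function(m) m[active, active, drop = FALSE])
  keys <- vapply(restr, function(m) paste(signif(c(m), 12), collapse = ","),
                 "")
  zero_key <- paste(signif(rep(0, length(active)^2), 12), collapse = ",")
  pi0 <- params$pi0 + sum(params$pi[keys == zero_key])
  keep <- which(keys != zero_key)
  grp <- match(keys[keep], unique(keys[keep]))
  pis <- as.numeric(tapply(params$pi[keep], grp, sum))
  covs <- lapply(unique(keys[keep]), function(k) restr[keep][[match(k, keys[keep])]])
  list(pi0 = pi0, pis = pis, covs = covs,
       sigma0 = sigma0_cov(params)[active, active, drop = FALSE],
       active = active)
}

#' Per-variant likelihood context
#'
#' Bundles what the characteristic function needs to know about one tag
#' variant: the heterozygosity-weighted LD neighborhood and the GWAS sample
#' sizes.
#'
#' @param w numeric vector of neighborhood weights `w_k = h_k * r2_jk`
#'   (self-term included, all > 0).
#' @param n per-trait GWAS sample sizes for this variant (length 3, or the
#'   number of active traits).
#' @return object of class `variant_ctx`.
#' @export
variant_ctx <- function(w, n) {
  w <- as.numeric(w); n <- as.numeric(n)
  if (length(w) < 1 || any(w <= 0)) stop("weights must be a non-empty positive vector")
  if (any(n <= 0)) stop("sample sizes must be positive")
  structure(list(w = w, n = n), class = "variant_ctx")
}
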