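# Random valid parameter sets, neighborhoods and observations used across
# the model-core and acceptance tests.  Scales are kept in the regime the
# estimator works in: per-neighbor signal variances O(1-30), residual SDs
# near 1.

random_params <- function(allow_rho = TRUE) {
  repeat {
    p <- try(mixture_params(
      pi = runif(7, 0, 0.05),
      sigma = runif(3, 0.02, 0.12),
      sigma0 = runif(3, 0.9, 1.2),
      rho = if (allow_rho) runif(3, -0.45, 0.45) else rep(0, 3),
      rho0 = if (allow_rho) runif(3, -0.3, 0.3) else rep(0, 3)),
      silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

random_ctx <- function(M = sample(1:4, 1)) {
  variant_ctx(w = runif(M, 0.02, 0.5), n = runif(3, 500, 3000))
}

## conservative grid for oracle comparisons: margin generous enough that
## aliasing is far below the comparison tolerance
oracle_grid <- function(z, params, ctx, d) {
  sw <- max_component_sd(params, seq_len(d), ctx$n[seq_len(d)], max(ctx$w))
  cf_grid(max(abs(z)), d = d, sigma0_hint = 0.8,
          margin = max(8, 4 * sw), tail = 7)
}

## draw z from the mixture itself (independent simulation oracle):
## per neighbor pick a component, add its scaled multinormal effect, then
## residual noise
sample_z_oracle <- function(nrep, params, ctx, subset = 1:3) {
  cc <- collapse_components(params, subset)
  d <- length(cc$active)
  nvec <- if (length(ctx$n) == 3) ctx$n[cc$active] else ctx$n
  z <- matrix(0, nrep, d)
  probs <- c(cc$pi0, cc$pis)
  dsc <- diag(sqrt(nvec), d)
  for (k in seq_along(ctx$w)) {
    comp <- sample.int(length(probs), nrep, replace = TRUE, prob = probs)
    for (s in seq_along(cc$pis)) {
      rows <- which(comp == s + 1L)
      if (!length(rows)) next
      cv <- ctx$w[k] * dsc %*% cc$covs[[s]] %*% dsc
      ev <- eigen(cv, symmetric = TRUE)
      rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*%
        t(ev$vectors)
      z[rows, ] <- z[rows, ] + matrix(rnorm(length(rows) * d),
                                      length(rows)) %*% rt
    }
  }
  s0 <- cc$sigma0
  z + matrix(rnorm(nrep * d), nrep) %*% chol(s0)
}
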