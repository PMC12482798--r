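## Stepwise maximum-likelihood estimation: univariate -> bivariate ->
## trivariate, multi-run orchestration and run aggregation.

PAIRS <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))

default_opt <- function(opt = list()) {
  modifyList(list(maxit = 250, reltol = 1e-7,
                  bi_maxit = 100, bi_reltol = 1e-6,
                  pi_starts = c(1e-4, 1e-3, 1e-2),
                  bi_frac_starts = c(0.5, 0.1),
                  tri_scan = 4, tri_tol_frac = 0.05,
                  strata = c(4, 8, 16, 32, Inf), margin = 4,
                  tail = c(6, 6, 5), sigw_factor = 0.9), opt)
}

## Barrier against mixture components wider than the retained z range: a
## component whose marginal SD exceeds ~the data's max |z| cannot be
## resolved by the inversion grid (only its aliasing images would be seen)
## and is outside the data's support anyway.
sigw_cap <- function(data, subset, opt) {
  max(8, opt$sigw_factor * max(abs(data$z[, subset])))
}

uni_params <- function(trait, pi_u, sigma2, sigma0) {
  pi <- rep(0, 7); pi[trait] <- pi_u
  sigma <- rep(0.05, 3); sigma[trait] <- sqrt(sigma2)
  s0 <- rep(1, 3); s0[trait] <- sigma0
  mixture_params(pi = pi, sigma = sigma, sigma0 = s0)
}

#' Fit the univariate mixture for one trait
#'
#' Maximizes the univariate log-likelihood over `(pi_u, sigma^2, sigma0)`
#' with a derivative-free simplex on log coordinates, from three log-spaced
#' polygenicity starts (discoverability initialized by moment matching at
#' each start).  Non-convergence is flagged, not thrown.
#'
#' @param data a `joint_dataset`.
#' @param trait trait index (1-3).
#' @param opt optimizer options, see `default_opt` entries `maxit`,
#'   `reltol`, `pi_starts`.
#' @return list with `pi_u`, `sigma`, `sigma0`, `loglik`, `loglik0`
#'   (at the best starting point), `trait`, `converged`.
#' @export
fit_univariate <- function(data, trait, opt = list()) {
  opt <- default_opt(opt)
  z <- data$z[, trait]
  wsum <- as.numeric(rowsum(data$wb$cnt * data$wmid[data$wb$bin + 1L],
                            rep.int(seq_along(data$wb$ptr[-1]),
                                    diff(data$wb$ptr))))
  wbar <- mean(wsum)
  nbar <- median(data$n[, trait])
  s0_start <- sqrt(max(0.5, median(z^2) / qchisq(0.5, 1)))
  m2 <- mean(z^2)
  cap <- sigw_cap(data, trait, opt)
  wmax <- max(data$wmid)
  nll <- function(x) {
    pi_u <- 10^x[1]
    if (pi_u > 0.5) return(1e10)
    p <- uni_params(trait, pi_u, exp(x[2]), exp(x[3]))
    if (max_component_sd(p, trait, nbar, wmax) > cap) return(1e10)
    -loglik(data, p, subset = trait, strata = opt$strata,
            margin = opt$margin, tail = opt$tail[1])
  }
  best <- NULL
  for (pi0 in opt$pi_starts) {
    s2 <- max(m2 - s0_start^2, 0.05) / (nbar * pi0 * wbar)
    s2 <- min(s2, (0.8 * cap^2 - s0_start^2) / (nbar * wmax))
    x0 <- c(log10(pi0), log(s2), log(s0_start))
    fit <- optim(x0, nll, method = "Nelder-Mead",
                 control = list(maxit = opt$maxit, reltol = opt$reltol))
    fit$ll0 <- -nll(x0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## parsimony tie-break: on signal-free data the likelihood surface is a
  ## ridge trading pi * sigma^2 against sigma0, so compare against an
  ## explicit null model (pi at the floor, sigma0 free); adopt it unless
  ## the mixture improves the fit by more than a 2-parameter margin
  null_opt <- optimize(function(ls0) nll(c(-6, log(1e-4), ls0)),
                       interval = log(c(0.7, 1.6)))
  if (null_opt$objective <= best$value + 2) {
    best$par <- c(-6, log(1e-4), null_opt$minimum)
    best$value <- null_opt$objective
    best$convergence <- 0
  }
  list(pi_u = 10^best$par[1], sigma = sqrt(exp(best$par[2])),
       sigma0 = exp(best$par[3]), loglik = -best$value, loglik0 = best$ll0,
       trait = as.integer(trait), converged = best$convergence == 0)
}

bi_params <- function(pair, uni_i, uni_j, pi_b, rho, rho0) {
  pair_slot <- 3L + which(vapply(PAIRS, identical, TRUE, as.integer(pair)))
  pi <- rep(0, 7)
  pi[pair_slot] <- pi_b
  pi[pair[1]] <- uni_i$pi_u - pi_b
  pi[pair[2]] <- uni_j$pi_u - pi_b
  sigma <- rep(0.05, 3); s0 <- rep(1, 3)
  sigma[pair[1]] <- uni_i$sigma; sigma[pair[2]] <- uni_j$sigma
  s0[pair[1]] <- uni_i$sigma0; s0[pair[2]] <- uni_j$sigma0
  rho3 <- rep(0, 3); rho3[pair_slot - 3L] <- rho
  rho03 <- rep(0, 3); rho03[pair_slot - 3L] <- rho0
  mixture_params(pi = pi, sigma = sigma, sigma0 = s0, rho = rho3,
                 rho0 = rho03)
}

#' Fit the bivariate overlap for one pair of traits
#'
#' Maximizes the bivariate log-likelihood over `(pi_b, rho, rho0)` with
#' univariate parameters fixed; `pi_b` is box-constrained to
#' `[0, min(pi_i^u, pi_j^u)]` via a logistic transform and the correlations
#' via `atanh`.
#'
#' @param data a `joint_dataset`.
#' @param pair integer pair, e.g. `c(1, 2)`.
#' @param uni_i,uni_j fixed univariate fits for the two traits.
#' @param opt optimizer options.
#' @return list with `pi_b`, `rho`, `rho0`, `loglik`, `loglik0`, `pair`,
#'   `converged`.
#' @export
fit_bivariate <- function(data, pair, uni_i, uni_j, opt = list()) {
  opt <- default_opt(opt)
  pair <- as.integer(pair)
  pi_max <- min(uni_i$pi_u, uni_j$pi_u)
  z <- data$z[, pair, drop = FALSE]
  nullish <- abs(z[, 1]) < 2 & abs(z[, 2]) < 2
  rho0_start <- if (sum(nullish) > 30)
    max(-0.9, min(0.9, cor(z[nullish, 1], z[nullish, 2]))) else 0
  rho_start <- max(-0.9, min(0.9, cor(z[, 1], z[, 2])))
  nll <- function(x) {
    p <- bi_params(pair, uni_i, uni_j, pi_max * plogis(x[1]), tanh(x[2]),
                   tanh(x[3]))
    -loglik(data, p, subset = pair, strata = opt$strata,
            margin = opt$margin, tail = opt$tail[2])
  }
  best <- NULL
  for (fr in opt$bi_frac_starts) {
    x0 <- c(qlogis(fr), atanh(rho_start), atanh(rho0_start))
    fit <- optim(x0, nll, method = "Nelder-Mead",
                 control = list(maxit = opt$bi_maxit, reltol = opt$bi_reltol))
    fit$ll0 <- -nll(x0)
    if (is.null(best) || fit$value < best$value) best <- fit
    ## a second start is only needed when the first collapses onto a
    ## boundary of the overlap box (suspect local optimum)
    frac <- plogis(fit$par[1])
    if (frac > 0.02 && frac < 0.98) break
  }
  ## parsimony tie-break: genuinely disjoint traits leave the profile in
  ## pi_b nearly flat, so prefer the no-overlap model unless the overlap
  ## improves the fit by more than a 2-parameter margin
  cand <- c(qlogis(1e-4), 0, best$par[3])
  v <- nll(cand)
  if (v <= best$value + 2) {
    best$par <- cand
    best$value <- v
    best$convergence <- 0
  }
  list(pi_b = pi_max * plogis(best$par[1]), rho = tanh(best$par[2]),
       rho0 = tanh(best$par[3]), loglik = -best$value, loglik0 = best$ll0,
       pair = pair, converged = best$convergence == 0)
}

## The three pairwise effect correlations are estimated separately and can
## be jointly infeasible as a 3x3 correlation matrix; shrink the triple
## toward zero just enough to restore positive definiteness.
shrink_rho_psd <- function(rho, eps = 1e-6) {
  R <- matrix(c(1, rho[1], rho[2], rho[1], 1, rho[3], rho[2], rho[3], 1),
              3, 3)
  mu <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (mu >= eps) return(rho)
  rho * (1 - eps) / (1 - mu)
}

tri_params <- function(unis, bis, pi123) {
  pi_u <- vapply(unis, `[[`, 0, "pi_u")
  pi_b <- vapply(bis, `[[`, 0, "pi_b")
  pat <- decompose_overlap(pi_u, pi_b, pi123)
  mixture_params(pi = pat$pi7,
                 sigma = vapply(unis, `[[`, 0, "sigma"),
                 sigma0 = vapply(unis, `[[`, 0, "sigma0"),
                 rho = shrink_rho_psd(vapply(bis, `[[`, 0, "rho")),
                 rho0 = shrink_rho_psd(vapply(bis, `[[`, 0, "rho0")))
}

#' Fit the triple overlap with all other parameters fixed
#'
#' Scalar bounded search for `pi123` inside its feasibility interval:
#' a coarse pre-scan brackets the maximum, golden-section/parabolic search
#' refines it.  Degenerate bounds return the clipped point with a warning.
#'
#' @param data a `joint_dataset`.
#' @param unis list of three univariate fits.
#' @param bis list of three bivariate fits (pairs 12, 13, 23).
#' @param opt optimizer options.
#' @return list with `pi123`, `bounds`, `loglik`, `converged`.
#' @export
fit_trivariate <- function(data, unis, bis, opt = list()) {
  opt <- default_opt(opt)
  pi_u <- vapply(unis, `[[`, 0, "pi_u")
  pi_b <- vapply(bis, `[[`, 0, "pi_b")
  b <- tryCatch(pi123_bounds(pi_u, pi_b), error = function(e) NULL)
  if (is.null(b)) {
    ## jointly infeasible univariate/bivariate estimates: no pi123
    ## satisfies every constraint; return the pairwise ceiling and let
    ## the caller clip the pattern (run is flagged non-converged)
    warning("degenerate pi123 bounds; returning the clipped point")
    pt <- min(pi_b)
    return(list(pi123 = pt, bounds = list(lo = pt, hi = pt), loglik = NA,
                converged = FALSE))
  }
  ll <- function(x) loglik(data, tri_params(unis, bis, x), subset = 1:3,
                           strata = opt$strata, margin = opt$margin,
                           tail = opt$tail[3])
  if (b$hi - b$lo < 1e-9)
    return(list(pi123 = b$lo, bounds = b,
                loglik = tryCatch(ll(b$lo), error = function(e) NA_real_),
                converged = TRUE))
  grid <- seq(b$lo, b$hi, length.out = opt$tri_scan)
  vals <- vapply(grid, ll, 0)
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  o <- optimize(ll, c(lo, hi), maximum = TRUE,
                tol = (b$hi - b$lo) * opt$tri_tol_frac)
  if (o$objective >= vals[i0])
    list(pi123 = o$maximum, bounds = b, loglik = o$objective,
         loglik0 = vals[1], converged = TRUE)
  else
    list(pi123 = grid[i0], bounds = b, loglik = vals[i0],
         loglik0 = vals[1], converged = TRUE)
}

#' Run the full estimation pipeline for one seed
#'
#' filters -> random pruning (seeded) -> random subsetting (same seed) ->
#' three univariate fits -> three bivariate fits -> trivariate fit ->
#' Euler decomposition.  Deterministic given (inputs, seed).
#'
#' @param aligned harmonized data from [harmonize_sumstats].
#' @param panel the `ld_panel`.
#' @param cfg a [filter_config].
#' @param seed `rand_prune_seed` for this run.
#' @param n_random optimization subset size.
#' @param do_pruning logical; skip the pruning stage when `FALSE`.
#' @param r2_prune_thresh pruning threshold.
#' @param n_bins weight bins for the batched likelihood.
#' @param opt optimizer options.
#' @param verbose print per-stage progress.
#' @return a `run_result` list: `seed`, `uni`, `bi`, `tri`, `pattern`,
#'   `pi_u`, `pi_b`, `pi123`, `selected_variants`, `logliks`, `flags`.
#' @export
run_pipeline <- function(aligned, panel, cfg = filter_config(), seed = 1L,
                         n_random = 2e4, do_pruning = TRUE,
                         r2_prune_thresh = 0.8, n_bins = 128, opt = list(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  filt <- apply_filters(aligned, cfg, panel)
  say("filters: %d -> %d variants", filt$log$n_in, filt$log$n_out)
  cand <- filt$idx
  if (do_pruning) {
    pr <- random_prune(panel, r2_prune_thresh, seed, within = cand)
    cand <- pr$kept
    say("pruning (r2 >= %.2f, seed %d): %d kept", r2_prune_thresh, seed,
        length(cand))
  } else say("pruning skipped")
  sel_panel <- select_subset(cand, n_random, seed)
  say("subset: %d tag variants", length(sel_panel))
  sel_rows <- match(sel_panel, aligned$idx)
  data <- build_joint_dataset(aligned$z, aligned$n, panel, aligned$idx,
                              sel = sel_rows, n_bins = n_bins)
  uni <- lapply(1:3, function(i) {
    f <- fit_univariate(data, i, opt)
    say("univariate trait %d: pi_u=%.3g sigma=%.3g sigma0=%.3g ll=%.1f",
        i, f$pi_u, f$sigma, f$sigma0, f$loglik)
    f
  })
  bi <- lapply(PAIRS, function(pr2) {
    f <- fit_bivariate(data, pr2, uni[[pr2[1]]], uni[[pr2[2]]], opt)
    say("bivariate %d-%d: pi_b=%.3g rho=%.3g rho0=%.3g ll=%.1f",
        pr2[1], pr2[2], f$pi_b, f$rho, f$rho0, f$loglik)
    f
  })
  tri <- fit_trivariate(data, uni, bi, opt)
  say("trivariate: pi123=%.3g in [%.3g, %.3g]", tri$pi123, tri$bounds$lo,
      tri$bounds$hi)
  pi_u <- vapply(uni, `[[`, 0, "pi_u")
  pi_b <- vapply(bi, `[[`, 0, "pi_b")
  pattern <- tryCatch(decompose_overlap(pi_u, pi_b, tri$pi123),
                      error = function(e) {
                        warning("pattern clipped to feasibility: ",
                                conditionMessage(e))
                        clipped_pattern(pi_u, pi_b, tri$pi123)
                      })
  flags <- c(uni = all(vapply(uni, `[[`, TRUE, "converged")),
             bi = all(vapply(bi, `[[`, TRUE, "converged")),
             tri = isTRUE(tri$converged))
  structure(list(seed = as.integer(seed), uni = uni, bi = bi, tri = tri,
                 pattern = pattern, pi_u = pi_u, pi_b = pi_b,
                 pi123 = tri$pi123,
                 selected_variants = length(sel_panel),
                 logliks = c(uni = sum(vapply(uni, `[[`, 0, "loglik")),
                             bi = sum(vapply(bi, `[[`, 0, "loglik")),
                             tri = tri$loglik),
                 flags = flags),
            class = "run_result")
}

#' Aggregate independent runs: median pattern and representative run
#'
#' Computes the per-component median of the seven-component vector across
#' runs and selects the run minimizing the union-normalized squared
#' deviation from that median.  The median pattern itself need not be
#' feasible; the representative run always is.
#'
#' @param results list of >= 2 `run_result`s.
#' @return list with `median_pi7` (per-component medians, possibly
#'   infeasible as a pattern), `representative` (index of the run closest
#'   to the median), `deviation` (per run), `median_margins` (medians of
#'   the estimated univariate/bivariate/trivariate polygenicities with
#'   `pi123` clipped into its feasible interval, plus the resulting
#'   feasible `pattern`), and `runs`.
#' @export
aggregate_runs <- function(results) {
  stopifnot(length(results) >= 2)
  mat <- t(vapply(results, function(r) r$pattern$pi7, numeric(7)))
  med <- apply(mat, 2, median)
  union_med <- sum(med)
  dev <- rowSums(((mat - rep(med, each = nrow(mat))) / union_med)^2)
  pu <- apply(vapply(results, `[[`, numeric(3), "pi_u"), 1, median)
  pb <- apply(vapply(results, `[[`, numeric(3), "pi_b"), 1, median)
  p123 <- median(vapply(results, `[[`, 0, "pi123"))
  margins <- tryCatch({
    b <- pi123_bounds(pu, pb)
    p123c <- min(max(p123, b$lo), b$hi)
    list(pi_u = pu, pi_b = pb, pi123 = p123c,
         pattern = decompose_overlap(pu, pb, p123c))
  }, error = function(e) NULL)   # median margins can be jointly infeasible
  list(median_pi7 = setNames(med, PI7_NAMES),
       representative = which.min(dev), deviation = dev,
       median_margins = margins, runs = results)
}

#' One-row-per-run parameter table for an ensemble of runs
#'
#' @param results list of `run_result`s.
#' @return data.frame with the 19 model parameters, stage log-likelihoods
#'   and bookkeeping columns, one row per run.
#' @export
ensemble_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    out <- data.frame(seed = r$seed, t(r$pattern$pi7),
                      pi1_u = r$pi_u[1], pi2_u = r$pi_u[2],
                      pi3_u = r$pi_u[3],
                      pi12_b = r$pi_b[1], pi13_b = r$pi_b[2],
                      pi23_b = r$pi_b[3])
    for (i in 1:3) {
      out[[paste0("sigma", i)]] <- r$uni[[i]]$sigma
      out[[paste0("sigma0", i)]] <- r$uni[[i]]$sigma0
    }
    nm <- c("12", "13", "23")
    for (k in 1:3) {
      out[[paste0("rho", nm[k])]] <- r$bi[[k]]$rho
      out[[paste0("rho0", nm[k])]] <- r$bi[[k]]$rho0
    }
    out$ll_uni <- r$logliks[["uni"]]; out$ll_bi <- r$logliks[["bi"]]
    out$ll_tri <- r$logliks[["tri"]]
    out$selected_variants <- r$selected_variants
    out$converged <- all(r$flags)
    out
  }))
}
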