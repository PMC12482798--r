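## Characteristic function, density by trapezoidal inversion, exact
## small-neighborhood oracle, and the dataset log-likelihood.

#' Inversion grid specification
#'
#' The density is recovered as
#' `p(z) = (2 pi)^-d * sum_t phi(t) cos(t'z) dt^d`
#' on a symmetric grid over `[-T, T]^d`.  Two accuracy rules set the
#' defaults: the step must satisfy `dt <= pi / (zmax + margin)` so that the
#' periodization alias of the trapezoidal rule falls well outside the
#' observed z range, and the half-width `T = tail / sigma0_hint` is chosen
#' so the residual Gaussian envelope `exp(-sigma0^2 t^2 / 2)` is negligible
#' at `|t| = T` (`tail = 6` leaves < 2e-8).  For `d >= 2` the corners of
#' the cube carry negligible mass and are skipped (`ball = TRUE`).
#'
#' @param zmax largest absolute z the grid must support.
#' @param d dimension (number of active traits).
#' @param sigma0_hint per-axis residual SD scale (scalar or length d).
#' @param margin aliasing safety margin added to `zmax` (z-score units).
#' @param tail envelope half-width in residual-SD units.
#' @param dt optional explicit step; defaults to `pi / (zmax + margin)`.
#' @param ball restrict integration to the inscribed ellipsoid.
#' @return a `cf_grid` list with `dt`, `m` (per-axis index bound), `margin`,
#'   `ball`.
#' @export
cf_grid <- function(zmax, d = 1, sigma0_hint = 1, margin = 4, tail = 6,
                    dt = NULL, ball = TRUE) {
  stopifnot(zmax >= 0, d %in% 1:3)
  if (is.null(dt)) dt <- pi / (zmax + margin)
  hint <- rep_len(sigma0_hint, d)
  m <- as.integer(ceiling(tail / (hint * dt)))
  structure(list(dt = dt, m = m, d = d, margin = margin, tail = tail,
                 ball = ball), class = "cf_grid")
}

#' Widest marginal component SD implied by parameters
#'
#' The trapezoidal inversion periodizes the density with period
#' `2 pi / dt`; the aliasing images of a mixture component with marginal SD
#' `s` are negligible only when the grid period exceeds `zmax` by a few
#' times `s`.  This returns the largest per-trait component SD
#' `sqrt(sigma0_i^2 + N_i * wmax * Sigma_S[i,i])` over components, which
#' the grid margin is scaled by.
#'
#' @param params a [mixture_params].
#' @param active trait subset.
#' @param nvec per-trait sample sizes.
#' @param wmax largest neighborhood weight in play.
#' @return scalar SD in z-score units.
#' @export
max_component_sd <- function(params, active, nvec, wmax = 0.5) {
  cc <- collapse_components(params, active)
  nvec <- rep_len(nvec, length(cc$active))
  s2 <- max(vapply(cc$covs, function(S) max(nvec * wmax * diag(S)), 0))
  sqrt(max(diag(cc$sigma0)) + s2)
}

## Aliasing margin for one stratum.  With step dt = pi/(zmax + margin) the
## trapezoidal sum periodizes the density with period L = 2(zmax + margin);
## the nearest image of a component with SD `sigw` must carry no more than
## ~`eps` of the density it aliases onto:
## (L - z)^2 - z^2 >= 2 log(1/eps) sigw^2 at z = zmax, i.e.
## margin >= (sqrt(zmax^2 + 2 log(1/eps) sigw^2) - zmax) / 2.
## Quantized to multiples of 2 so grid caches reuse.
stratum_margin <- function(zmax, sigw, base = 4, eps = 0.02) {
  need <- (sqrt(zmax^2 + 2 * log(1 / eps) * sigw^2) - zmax) / 2
  max(base, 2 * ceiling(need / 2))
}

check_grid <- function(grid, z) {
  zmax <- max(abs(z))
  if (grid$dt > pi / (zmax + grid$margin) + 1e-12)
    stop(sprintf(paste0("inversion grid too coarse for the requested z: ",
                        "dt = %.4g exceeds pi/(zmax + margin) = %.4g; ",
                        "aliasing would corrupt the density"),
                 grid$dt, pi / (zmax + grid$margin)))
  invisible(grid)
}

## Flatten a collapse_components() result for the C++ kernels.
comp_args <- function(cc) {
  d <- length(cc$active)
  list(pi0 = cc$pi0, pis = as.numeric(cc$pis),
       covs = as.numeric(unlist(cc$covs)),
       sigma0 = as.numeric(cc$sigma0), d = d)
}

ctx_n <- function(ctx, active) {
  n <- ctx$n
  if (length(n) == 3) n[active] else rep_len(n, length(active))
}

#' Model characteristic function
#'
#' Evaluates `phi(t)` for one tag variant: the product of the residual
#' Gaussian CF and, per LD neighbor, a convex combination of component
#' Gaussian CFs.  Always real, with `phi(0) = 1` and `0 < phi <= 1`.
#'
#' @param t numeric vector of length `length(subset)`, or a matrix with one
#'   row per evaluation point.
#' @param params a [mixture_params].
#' @param ctx a [variant_ctx].
#' @param subset active traits (subset of `1:3`).
#' @return numeric vector of CF values.
#' @export
char_fn <- function(t, params, ctx, subset = 1:3) {
  cc <- collapse_components(params, subset)
  d <- length(cc$active)
  tm <- if (is.matrix(t)) t else matrix(t, ncol = d)
  stopifnot(ncol(tm) == d)
  ca <- comp_args(cc)
  cpp_cf_phi(tm, ctx$w, ctx_n(ctx, cc$active), ca$pi0, ca$pis, ca$covs,
             ca$sigma0)
}

#' Density of the observed z-scores by characteristic-function inversion
#'
#' @param z numeric vector (one point) or matrix (rows are points) of
#'   z-scores over the active traits.
#' @inheritParams char_fn
#' @param grid a [cf_grid]; defaults to one sized for the supplied z.
#' @return numeric vector of densities (non-negative; tiny negative
#'   trapezoid results are clipped to zero).
#' @export
pdf_cf <- function(z, params, ctx, subset = 1:3, grid = NULL) {
  cc <- collapse_components(params, subset)
  d <- length(cc$active)
  zm <- if (is.matrix(z)) z else matrix(z, ncol = d)
  stopifnot(ncol(zm) == d)
  if (is.null(grid)) {
    zx <- max(abs(zm))
    sw <- max_component_sd(params, cc$active, ctx_n(ctx, cc$active),
                           max(ctx$w))
    grid <- cf_grid(zx, d = d, sigma0_hint = min(params$sigma0),
                    margin = stratum_margin(zx, sw))
  }
  check_grid(grid, zm)
  ca <- comp_args(cc)
  out <- cpp_cf_pdf(zm, ctx$w, ctx_n(ctx, cc$active), ca$pi0, ca$pis,
                    ca$covs, ca$sigma0, grid$dt,
                    rep_len(grid$m, d), isTRUE(grid$ball))
  pmax(out, 0)
}

#' Exact finite-mixture density (enumeration oracle)
#'
#' Sums over all component assignments of the `M` neighbors: each term is a
#' multinormal density at `z` with covariance
#' `Sigma0 + sum_k w_k D_N Sigma_{c_k} D_N`.  Feasible for small
#' neighborhoods only (`(nc+1)^M` terms); it is the reference the inversion
#' path is validated against.
#'
#' @inheritParams pdf_cf
#' @param max_terms feasibility cap on the number of enumerated terms.
#' @return numeric vector of densities.
#' @export
pdf_exact <- function(z, params, ctx, subset = 1:3, max_terms = 3e6) {
  cc <- collapse_components(params, subset)
  d <- length(cc$active)
  zm <- if (is.matrix(z)) z else matrix(z, ncol = d)
  M <- length(ctx$w)
  nc <- length(cc$pis)
  if ((nc + 1)^M > max_terms)
    stop("neighborhood too large for exact enumeration: (", nc + 1, ")^",
         M, " terms")
  nvec <- ctx_n(ctx, cc$active)
  dsc <- diag(sqrt(nvec), d)
  covflat <- do.call(rbind, lapply(c(list(matrix(0, d, d)), cc$covs),
                                   function(S) as.numeric(dsc %*% S %*% dsc)))
  pivec <- c(cc$pi0, cc$pis)
  A <- as.matrix(expand.grid(rep(list(seq_len(nc + 1)), M)))
  wts <- exp(rowSums(matrix(log(pivec[A]), nrow(A), M)))
  total <- matrix(rep(as.numeric(cc$sigma0), each = nrow(A)), nrow(A))
  for (k in seq_len(M))
    total <- total + ctx$w[k] * covflat[A[, k], , drop = FALSE]
  dens_rows <- dmvn_rows(zm, total, d)   # nA x nz
  as.numeric(crossprod(dens_rows, wts))
}

## Multinormal density of each z row under each covariance row (flattened
## d x d, column-major).  Closed-form 1/2/3-d inverses, vectorized over rows.
dmvn_rows <- function(zm, covs, d) {
  nz <- nrow(zm)
  if (d == 1) {
    v <- covs[, 1]
    return(outer(v, zm[, 1]^2, function(vv, z2) exp(-0.5 * z2 / vv) /
                   sqrt(2 * pi * vv)))
  }
  if (d == 2) {
    a <- covs[, 1]; b <- covs[, 2]; cdd <- covs[, 4]
    det <- a * cdd - b * b
    q <- outer(cdd / det, zm[, 1]^2) - 2 * outer(b / det, zm[, 1] * zm[, 2]) +
      outer(a / det, zm[, 2]^2)
    return(exp(-0.5 * q) / (2 * pi * sqrt(det)))
  }
  a <- covs[, 1]; b <- covs[, 2]; cc <- covs[, 3]
  dd <- covs[, 5]; e <- covs[, 6]; f <- covs[, 9]
  det <- a * (dd * f - e * e) - b * (b * f - e * cc) + cc * (b * e - dd * cc)
  i11 <- (dd * f - e * e) / det; i12 <- (cc * e - b * f) / det
  i13 <- (b * e - cc * dd) / det; i22 <- (a * f - cc * cc) / det
  i23 <- (b * cc - a * e) / det; i33 <- (a * dd - b * b) / det
  q <- outer(i11, zm[, 1]^2) + outer(i22, zm[, 2]^2) + outer(i33, zm[, 3]^2) +
    2 * (outer(i12, zm[, 1] * zm[, 2]) + outer(i13, zm[, 1] * zm[, 3]) +
           outer(i23, zm[, 2] * zm[, 3]))
  exp(-0.5 * q) / ((2 * pi)^1.5 * sqrt(det))
}

#' Assemble the per-variant likelihood inputs for a set of tag variants
#'
#' For each selected tag variant the LD neighborhood weights
#' `w_k = h_k * r2_jk` are collected from the panel (neighbors need not be
#' selected themselves) and additionally binned onto a shared geometric
#' grid for the batched likelihood path.
#'
#' @param z matrix of harmonized z-scores (rows follow `aligned$idx`).
#' @param n matrix of per-variant sample sizes, same shape as `z`.
#' @param panel the `ld_panel`.
#' @param panel_idx panel index of each row of `z`.
#' @param sel row indices (into `z`) of the selected tag variants.
#' @param n_bins number of geometric weight bins for the batched path.
#' @return a `joint_dataset` list: `z`, `n` (selected rows), `w` (exact CSR:
#'   `ptr`, `val`), `wb` (binned CSR: `ptr`, `bin`, `cnt`), `wmid`,
#'   `panel_idx`.
#' @export
build_joint_dataset <- function(z, n, panel, panel_idx, sel = seq_len(nrow(z)),
                                n_bins = 128) {
  stopifnot(nrow(z) == length(panel_idx))
  tags <- panel_idx[sel]
  ptr_all <- panel$nbr_ptr
  counts <- ptr_all[tags + 1L] - ptr_all[tags]
  ptr <- cumsum(c(0L, counts))
  pos <- sequence(counts) + rep(ptr_all[tags], counts)
  nbr <- panel$nbr_idx[pos]
  wval <- panel$het[nbr] * panel$nbr_r2[pos]
  wval <- pmax(wval, 1e-12)
  ## geometric bins over the observed weight range
  wlo <- min(wval); whi <- max(wval) * (1 + 1e-9)
  edges <- exp(seq(log(wlo), log(whi), length.out = n_bins + 1))
  bin <- pmin(findInterval(wval, edges), n_bins)
  wmid <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  row <- rep.int(seq_along(sel), counts)
  key <- (row - 1) * n_bins + bin
  agg <- rowsum(rep(1, length(key)), key)
  ukey <- as.integer(rownames(agg))
  brow <- (ukey - 1L) %/% n_bins + 1L
  bptr <- cumsum(c(0L, tabulate(brow, nbins = length(sel))))
  structure(list(z = z[sel, , drop = FALSE], n = n[sel, , drop = FALSE],
                 w = list(ptr = ptr, val = wval),
                 wb = list(ptr = as.integer(bptr),
                           bin = as.integer((ukey - 1L) %% n_bins),
                           cnt = as.numeric(agg[, 1])),
                 wmid = wmid, panel_idx = tags, cache = new.env()),
            class = "joint_dataset")
}

#' Dataset log-likelihood under the mixture model
#'
#' Sums `log max(pdf, floor)` over tag variants with uniform weights.
#' Variants are stratified by their largest absolute z-score and each
#' stratum is integrated on a grid satisfying its own aliasing bound, so
#' the bulk of near-null variants uses a small grid while rare
#' strong-signal variants get the fine step they need.  The batched path
#' bins neighborhood weights and uses per-trait median sample sizes; the
#' exact path keeps per-variant weights and sample sizes.
#'
#' @param data a `joint_dataset`.
#' @param params a [mixture_params].
#' @param subset active traits.
#' @param method `"binned"` (fast, default) or `"exact"` (reference).
#' @param strata stratum boundaries on `max |z|` (upper edges).
#' @param margin,tail,ball grid construction knobs, see [cf_grid].
#' @param floor density floor applied before the log.
#' @param per_variant also return per-variant log-densities.
#' @return scalar log-likelihood, or a list when `per_variant = TRUE`.
#' @export
loglik <- function(data, params, subset = 1:3,
                   method = c("binned", "exact"),
                   strata = c(4, 8, 16, 32, Inf), margin = 4, tail = 6,
                   ball = TRUE, floor = 1e-300, per_variant = FALSE) {
  method <- match.arg(method)
  cc <- collapse_components(params, subset)
  d <- length(cc$active)
  ca <- comp_args(cc)
  nv0 <- apply(data$n[, cc$active, drop = FALSE], 2, median)
  sigw <- ceiling(max_component_sd(params, cc$active, nv0, max(data$wmid)))
  prep <- prepare_strata(data, cc$active, strata, margin, tail, ball, sigw)
  nvec <- prep$nvec
  lp <- numeric(nrow(data$z))
  for (st in prep$strata) {
    if (method == "binned") {
      pdf <- cpp_cf_pdf_batch(st$z, st$wb$ptr, st$wb$bin, st$wb$cnt,
                              data$wmid, nvec, ca$pi0, ca$pis,
                              ca$covs, ca$sigma0, st$grid$dt,
                              rep_len(st$grid$m, d), isTRUE(st$grid$ball),
                              st$trig)
    } else {
      pdf <- vapply(seq_along(st$jj), function(i) {
        j <- st$jj[i]
        sel <- (data$w$ptr[j] + 1L):data$w$ptr[j + 1L]
        cpp_cf_pdf(st$z[i, , drop = FALSE], data$w$val[sel],
                   data$n[j, cc$active],
                   ca$pi0, ca$pis, ca$covs, ca$sigma0, st$grid$dt,
                   rep_len(st$grid$m, d), isTRUE(st$grid$ball))
      }, 0)
    }
    lp[st$jj] <- log(pmax(pdf, floor))
  }
  if (per_variant) list(loglik = sum(lp), lp = lp) else sum(lp)
}

## Stratify a dataset by max |z| over the active traits and precompute,
## per stratum, the z block, binned-weight CSR, inversion grid and trig
## tables.  Memoized on the dataset's cache environment: the fitters
## evaluate the same stage objective hundreds of times on identical
## structures.
prepare_strata <- function(data, active, strata, margin, tail, ball, sigw) {
  key <- paste(c("S", active, strata, margin, tail, ball, sigw),
               collapse = "_")
  if (!is.null(data$cache) && !is.null(data$cache[[key]]))
    return(data$cache[[key]])
  d <- length(active)
  zm <- data$z[, active, drop = FALSE]
  zmax_j <- apply(abs(zm), 1, max)
  stratum <- findInterval(zmax_j, strata[-length(strata)]) + 1L
  out <- list()
  for (s in sort(unique(stratum))) {
    jj <- which(stratum == s)
    zs <- max(zmax_j[jj])
    grid <- cf_grid(zs, d = d, margin = stratum_margin(zs, sigw, margin),
                    tail = tail, ball = ball)
    zsub <- zm[jj, , drop = FALSE]
    wb <- csr_subset(data$wb$ptr, jj, data$wb$bin, data$wb$cnt)
    out[[length(out) + 1L]] <-
      list(jj = jj, z = zsub,
           wb = list(ptr = wb$ptr, bin = wb$i1, cnt = wb$i2),
           grid = grid,
           trig = cpp_make_trig(zsub, grid$dt, rep_len(grid$m, d)))
  }
  res <- list(strata = out,
              nvec = apply(data$n[, active, drop = FALSE], 2, median))
  if (!is.null(data$cache)) data$cache[[key]] <- res
  res
}

## Subset rows of a CSR triplet structure.
csr_subset <- function(ptr, rows, v1, v2) {
  counts <- ptr[rows + 1L] - ptr[rows]
  pos <- sequence(counts) + rep(ptr[rows], counts)
  list(ptr = as.integer(cumsum(c(0L, counts))), i1 = v1[pos], i2 = v2[pos])
}
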