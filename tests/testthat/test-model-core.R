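test_that("characteristic function has CF properties and Gaussian limits", {
  set.seed(101)
  ## phi(0) = 1 and 0 < phi <= 1 across random draws
  for (i in 1:20) {
    p <- random_params(); ctx <- random_ctx()
    d <- sample(1:3, 1); sub <- sort(sample(1:3, d))
    tm <- matrix(rnorm(40 * d, 0, 2), ncol = d)
    phi <- char_fn(tm, p, ctx, sub)
    expect_true(all(phi > 0 & phi <= 1 + 1e-12))
    expect_equal(char_fn(rep(0, d), p, ctx, sub), 1)
    ## evenness: phi(t) = phi(-t)
    expect_equal(char_fn(-tm, p, ctx, sub), phi, tolerance = 1e-12)
  }
  ## pure residual: standard Gaussian CF
  p0 <- mixture_params()
  ctx <- variant_ctx(0.3, 1e5)
  tt <- seq(-4, 4, by = 0.5)
  expect_equal(char_fn(tt, p0, ctx, subset = 1), exp(-tt^2 / 2),
               tolerance = 1e-12)
  ## single neighbor, all mass causal: Gaussian convolution variance
  p1 <- mixture_params(pi = c(0.25, 0, 0, 0.25, 0.25, 0, 0.25),
                       sigma = c(0.05, 0.05, 0.05))
  ctxw <- variant_ctx(0.4, c(1000, 1000, 1000))
  v <- 1 + 0.4 * 1000 * 0.05^2
  expect_equal(char_fn(tt, p1, ctxw, subset = 1), exp(-tt^2 * v / 2),
               tolerance = 1e-10)
})

test_that("inversion density matches the standard normal and is symmetric", {
  p0 <- mixture_params()
  ctx <- variant_ctx(0.3, 1e5)
  expect_equal(pdf_cf(0, p0, ctx, subset = 1), dnorm(0), tolerance = 1e-6)
  z <- seq(-3, 3, by = 0.75)
  got <- pdf_cf(matrix(z, ncol = 1), p0, ctx, subset = 1)
  expect_equal(got, dnorm(z), tolerance = 1e-6)
  expect_equal(got, rev(got), tolerance = 1e-8)
})

test_that("inversion agrees with exact enumeration across random draws", {
  set.seed(202)
  for (i in 1:40) {
    d <- sample(1:3, 1); sub <- sort(sample(1:3, d))
    p <- random_params(); ctx <- random_ctx()
    z <- matrix(rnorm(4 * d, 0, 1.5), 4, d)
    g <- oracle_grid(z, p, ctx, d)
    a <- pdf_cf(z, p, ctx, sub, grid = g)
    b <- pdf_exact(z, p, ctx, sub)
    expect_lt(max(abs(a - b)), 1e-6)
    dense <- b > 1e-12
    if (any(dense))
      expect_lt(max(abs(a[dense] / b[dense] - 1)), 1e-4)
  }
})

test_that("grid aliasing check rejects too-coarse steps", {
  p <- mixture_params(); ctx <- variant_ctx(0.3, 1000)
  g <- cf_grid(2, d = 1)
  expect_error(pdf_cf(20, p, ctx, subset = 1, grid = g), "too coarse")
})

test_that("univariate density integrates to one", {
  set.seed(303)
  for (i in 1:5) {
    p <- random_params(); ctx <- random_ctx()
    ## integration range covering the widest component
    sw <- max_component_sd(p, 1, ctx$n[1], max(ctx$w))
    zs <- seq(-8 * sw, 8 * sw, length.out = 4001)
    g <- oracle_grid(zs, p, ctx, 1)
    dens <- pdf_cf(matrix(zs, ncol = 1), p, ctx, subset = 1, grid = g)
    expect_equal(sum(dens) * diff(zs[1:2]), 1, tolerance = 1e-3)
  }
})

test_that("integrating the bivariate density recovers the univariate", {
  set.seed(404)
  p <- random_params(); ctx <- random_ctx(M = 3)
  sw <- max_component_sd(p, 1:2, ctx$n[1:2], max(ctx$w))
  z2 <- seq(-8 * sw, 8 * sw, length.out = 801)
  for (z1 in c(-1.2, 0.4, 2)) {
    zm <- cbind(z1, z2)
    g2 <- oracle_grid(zm, p, ctx, 2)
    marg <- sum(pdf_cf(zm, p, ctx, subset = 1:2, grid = g2)) * diff(z2[1:2])
    g1 <- oracle_grid(z1, p, ctx, 1)
    uni <- pdf_cf(z1, p, ctx, subset = 1, grid = g1)
    expect_equal(marg, uni, tolerance = 1e-4)
  }
})

test_that("exact density matches Monte-Carlo simulation of the model", {
  set.seed(505)
  p <- random_params(allow_rho = FALSE)
  ctx <- random_ctx(M = 2)
  zs <- sample_z_oracle(2e5, p, ctx, subset = 1)
  breaks <- quantile(zs, seq(0, 1, length.out = 21))
  breaks[1] <- -Inf; breaks[21] <- Inf
  counts <- table(cut(zs[, 1], breaks))
  ## expected bin mass by fine quadrature of the exact density
  fine <- seq(min(zs) - 1, max(zs) + 1, length.out = 6001)
  dens <- pdf_exact(matrix(fine, ncol = 1), p, ctx, subset = 1)
  cdf <- cumsum(dens) * diff(fine[1:2])
  pmass <- diff(c(0, approx(fine, cdf, breaks[2:20])$y, 1))
  expected <- 2e5 * pmass
  resid <- (as.numeric(counts) - expected) /
    sqrt(expected * pmax(1 - pmass, 0.5))
  expect_lt(max(abs(resid)), 5)
})

test_that("batched likelihood agrees with the per-variant reference path", {
  spec <- scenario_spec("equilibrium", n_variants = 4000, pi_total = 0.01,
                        n = rep(2000, 3))
  sim <- simulate_scenario(spec, seed = 6)
  nmat <- matrix(2000, nrow(sim$z), 3)
  set.seed(61)
  data <- build_joint_dataset(sim$z, nmat, sim$panel, seq_len(nrow(sim$z)),
                              sel = sample(4000, 1200))
  sig <- sapply(1:3, function(i) sqrt(mean(sim$beta[sim$beta[, i] != 0,
                                                    i]^2)))
  p <- mixture_params(pi = spec$pi7_true, sigma = sig)
  for (sub in list(2, c(1, 3), 1:3)) {
    a <- loglik(data, p, subset = sub, per_variant = TRUE)
    b <- loglik(data, p, subset = sub, method = "exact",
                per_variant = TRUE)
    ## binned weights and single precision: small per-variant slack where
    ## the density is within quadrature resolution
    ok <- b$lp > -60
    expect_gt(mean(ok), 0.99)
    expect_lt(max(abs(a$lp[ok] - b$lp[ok])), 0.25)
    expect_lt(abs(sum(a$lp[ok]) - sum(b$lp[ok])) / abs(sum(b$lp[ok])),
              5e-4)
  }
})

test_that("independent third trait factorizes the likelihood", {
  ## membership of trait 3 independent of the (1,2) structure makes the
  ## trivariate density the product of the bivariate and univariate ones
  q12 <- c(s1 = 0.01, s2 = 0.015, b = 0.02)   # trait-1, trait-2, shared
  q3 <- 0.03
  pi0_12 <- 1 - sum(q12)
  pi7 <- c(q12[["s1"]] * (1 - q3), q12[["s2"]] * (1 - q3), pi0_12 * q3,
           q12[["b"]] * (1 - q3), q12[["s1"]] * q3, q12[["s2"]] * q3,
           q12[["b"]] * q3)
  p <- mixture_params(pi = pi7, sigma = c(0.06, 0.05, 0.07),
                      sigma0 = c(1, 1.05, 0.95))
  ## weak heritability keeps all densities well inside quadrature
  ## resolution, so the factorization identity is testable tightly
  spec <- scenario_spec("custom", n_variants = 600, pi7 = pi7, h2 = 0.02,
                        n = rep(1500, 3))
  sim <- simulate_scenario(spec, seed = 9)
  nmat <- matrix(1500, nrow(sim$z), 3)
  data <- build_joint_dataset(sim$z, nmat, sim$panel,
                              seq_len(nrow(sim$z)),
                              sel = sample(nrow(sim$z), 100))
  ll3 <- loglik(data, p, subset = 1:3, method = "exact")
  ll12 <- loglik(data, p, subset = c(1, 2), method = "exact")
  ll1 <- loglik(data, p, subset = 3, method = "exact")
  expect_equal(ll3, ll12 + ll1, tolerance = 1e-5)
})

test_that("log-likelihood is additive over variants", {
  spec <- scenario_spec("equilibrium", n_variants = 500, pi_total = 0.01,
                        n = rep(1000, 3))
  sim <- simulate_scenario(spec, seed = 2,
                           panel = make_ld_panel(500, block_size = c(1, 3),
                                                 seed = 2))
  nmat <- matrix(1000, nrow(sim$z), 3)
  one <- build_joint_dataset(sim$z, nmat, sim$panel, seq_len(nrow(sim$z)),
                             sel = 7L)
  p <- random_params()
  lp <- loglik(one, p, subset = 1:3, per_variant = TRUE)
  expect_equal(lp$loglik, lp$lp[1])
  sel <- (one$w$ptr[1] + 1):one$w$ptr[2]
  ctx <- variant_ctx(one$w$val[sel], one$n[1, ])
  direct <- log(pdf_exact(one$z[1, ], p, ctx, 1:3))
  expect_equal(lp$loglik, direct, tolerance = 0.05)
})

test_that("the likelihood prefers the generating triple overlap", {
  ## equilibrium-style truth vs the same model with the triple overlap
  ## doubled: the data should back the truth in nearly all replicates
  wins <- 0
  for (k in 1:10) {
    spec <- scenario_spec("equilibrium", n_variants = 1e4, pi_total = 0.01,
                          n = rep(6000, 3))
    sim <- simulate_scenario(spec, seed = 700 + k)
    nmat <- matrix(6000, nrow(sim$z), 3)
    data <- build_joint_dataset(sim$z, nmat, sim$panel,
                                seq_len(nrow(sim$z)))
    sig <- sapply(1:3, function(i)
      sqrt(mean(sim$beta[sim$beta[, i] != 0, i]^2)))
    p_true <- mixture_params(pi = spec$pi7_true, sigma = sig)
    pi_alt <- spec$pi7_true
    pi_alt["pi123"] <- 2 * pi_alt["pi123"]
    p_alt <- mixture_params(pi = pi_alt, sigma = sig)
    if (loglik(data, p_true) >= loglik(data, p_alt)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
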