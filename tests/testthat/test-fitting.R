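# Stage-level estimation checks on small synthetic datasets.  The heavier
# end-to-end scenario recoveries live in test-acceptance.R and share the
# cached runs from helper-scenarios.R.

dataset_from_sim <- function(sim, sel = seq_len(nrow(sim$z))) {
  nmat <- matrix(rep(sim$spec$n, each = nrow(sim$z)), nrow(sim$z))
  build_joint_dataset(sim$z, nmat, sim$panel, seq_len(nrow(sim$z)),
                      sel = sel)
}

test_that("univariate fit recovers polygenicity within a factor of two", {
  spec <- scenario_spec("equilibrium", n_variants = 2e4, pi_total = 0.002,
                        n = rep(1e5, 3))
  sim <- simulate_scenario(spec, seed = 41)
  keep <- which(apply(abs(sim$z), 1, max) <= 32)   # standard |z| filter
  data <- dataset_from_sim(sim, sel = keep)
  fit <- fit_univariate(data, 1)
  expect_true(fit$converged)
  expect_lt(abs(log10(fit$pi_u) - log10(0.002)), 0.3)
  expect_lt(abs(fit$sigma0 - 1), 0.05)
})

test_that("null data drive polygenicity to the floor and sigma0 to 1", {
  spec <- scenario_spec("custom", n_variants = 2e4, pi7 = rep(0, 7),
                        h2 = 0, n = rep(1e4, 3))
  sim <- simulate_scenario(spec, seed = 42)
  data <- dataset_from_sim(sim)
  fit <- fit_univariate(data, 2)
  expect_lt(fit$pi_u, 1e-4 * 5)
  expect_lt(abs(fit$sigma0 - 1), 0.05)
})

test_that("residual inflation sigma0 = 1.1 is recovered", {
  spec <- scenario_spec("custom", n_variants = 2e4, pi7 = rep(0, 7),
                        h2 = 0, n = rep(1e4, 3), sigma0 = rep(1.1, 3))
  sim <- simulate_scenario(spec, seed = 43)
  data <- dataset_from_sim(sim)
  fit <- fit_univariate(data, 3)
  expect_gte(fit$sigma0, 1.05)
  expect_lte(fit$sigma0, 1.15)
})

test_that("bivariate overlap is near zero for independent traits and hits
          its upper bound for fully shared ones", {
  ## independent: custom scenario with only trait-specific components
  spec0 <- scenario_spec("custom", n_variants = 2e4,
                         pi7 = c(2e-3, 2e-3, 2e-3, 0, 0, 0, 0),
                         n = rep(1e4, 3))
  sim0 <- simulate_scenario(spec0, seed = 44)
  set.seed(44)
  d0 <- dataset_from_sim(sim0, sel = sample(2e4, 1.2e4))
  u1 <- fit_univariate(d0, 1); u2 <- fit_univariate(d0, 2)
  b0 <- fit_bivariate(d0, c(1, 2), u1, u2)
  expect_lt(b0$pi_b, 0.1 * min(u1$pi_u, u2$pi_u))

  ## fully shared with correlated effects (third trait idle)
  spec1 <- scenario_spec("custom", n_variants = 2e4,
                         pi7 = c(0, 0, 0, 2e-3, 0, 0, 0),
                         h2 = c(0.4, 0.4, 0),
                         rho = c(0.5, 0, 0), n = rep(1e4, 3))
  sim1 <- simulate_scenario(spec1, seed = 45)
  set.seed(45)
  d1 <- dataset_from_sim(sim1, sel = sample(2e4, 1.2e4))
  v1 <- fit_univariate(d1, 1); v2 <- fit_univariate(d1, 2)
  b1 <- fit_bivariate(d1, c(1, 2), v1, v2)
  expect_lt(abs(b1$rho - 0.5), 0.15)
  ## simulated overlap equals min(pi_u): estimate near the box bound
  expect_gt(b1$pi_b, 0.6 * min(v1$pi_u, v2$pi_u))
})

test_that("each stage improves on its own starting point", {
  spec <- scenario_spec("equilibrium", n_variants = 2e4, pi_total = 0.005,
                        n = rep(5e3, 3))
  sim <- simulate_scenario(spec, seed = 46)
  set.seed(46)
  data <- dataset_from_sim(sim, sel = sample(2e4, 5e3))
  u <- lapply(1:2, function(i) fit_univariate(data, i))
  for (f in u) expect_gte(f$loglik, f$loglik0 - 1e-6)
  b <- fit_bivariate(data, c(1, 2), u[[1]], u[[2]])
  expect_gte(b$loglik, b$loglik0 - 1e-6)
})

test_that("trivariate stage respects degenerate and collapsed bounds", {
  unis <- lapply(1:3, function(i)
    list(pi_u = 2e-3, sigma = 0.05, sigma0 = 1, trait = i))
  bis <- list(list(pi_b = 1e-3, rho = 0, rho0 = 0, pair = c(1, 2)),
              list(pi_b = 0, rho = 0, rho0 = 0, pair = c(1, 3)),
              list(pi_b = 5e-4, rho = 0, rho0 = 0, pair = c(2, 3)))
  ## hi = min(pi_b) = 0 collapses the interval to a point: no data needed
  fit <- fit_trivariate(structure(list(), class = "joint_dataset"),
                        unis, bis)
  expect_equal(fit$pi123, 0)
})

test_that("aggregation takes medians and picks the closest run", {
  mk <- function(pi123, off = 0) {
    pi_u <- rep(8e-3, 3); pi_b <- rep(3e-3, 3)
    pat <- decompose_overlap(pi_u + off, pi_b, pi123)
    structure(list(pattern = pat, pi_u = pi_u + off, pi_b = pi_b,
                   pi123 = pi123, seed = 1L), class = "run_result")
  }
  runs <- list(mk(1e-3), mk(2e-3), mk(3e-3))
  agg <- aggregate_runs(runs)
  expect_equal(unname(agg$median_pi7[["pi123"]]), 2e-3)
  expect_equal(agg$representative, 2L)
  ## identical runs: zero deviation, any representative
  agg2 <- aggregate_runs(list(mk(2e-3), mk(2e-3)))
  expect_equal(max(agg2$deviation), 0)
  ## a run off the median on one component is not selected
  agg3 <- aggregate_runs(list(mk(2e-3), mk(2e-3), mk(2e-3, off = 5e-4)))
  expect_true(agg3$representative %in% 1:2)
})

test_that("ensemble table has one row per run with the full parameter set", {
  spec <- scenario_spec("equilibrium", n_variants = 3000, pi_total = 0.005,
                        h2 = 0.1, n = rep(5e3, 3))
  sim <- simulate_scenario(spec, seed = 47)
  tabs <- lapply(sim$tables, function(t)
    data.frame(id = t$SNP, chrom = t$CHR, pos = t$BP, a1 = t$A1,
               a2 = t$A2, z = t$Z, n = t$N))
  aligned <- harmonize_sumstats(tabs, sim$panel$variants)
  r1 <- run_pipeline(aligned, sim$panel, filter_config(), seed = 1,
                     n_random = 1200)
  r2 <- run_pipeline(aligned, sim$panel, filter_config(), seed = 1,
                     n_random = 1200)
  ## determinism: identical seed, identical result
  expect_identical(r1$pattern$pi7, r2$pattern$pi7)
  r3 <- run_pipeline(aligned, sim$panel, filter_config(), seed = 2,
                     n_random = 1200)
  et <- ensemble_table(list(r1, r3))
  expect_equal(nrow(et), 2)
  expect_true(all(c("pi123", "sigma1", "rho12", "rho023", "ll_tri")
                  %in% names(et)))
  ## different seeds select different subsets
  expect_false(identical(r1$pattern$pi7, r3$pattern$pi7))
  ## pruning can be disabled
  r4 <- run_pipeline(aligned, sim$panel, filter_config(), seed = 1,
                     n_random = 1200, do_pruning = FALSE)
  expect_s3_class(r4$pattern, "overlap_pattern")
})
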