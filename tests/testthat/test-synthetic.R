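test_that("scenario presets satisfy their defining constraints", {
  core <- scenario_spec("core", pi_total = 0.002)
  expect_equal(unname(core$pi7_true),
               c(0.001, 0.001, 0.001, 0, 0, 0, 0.001))
  ring <- scenario_spec("ring", pi_total = 0.002)
  expect_equal(unname(ring$pi7_true), c(0, 0, 0, 0.001, 0.001, 0.001, 0))
  eq <- scenario_spec("equilibrium", pi_total = 0.002)
  expect_equal(unname(eq$pi7_true), rep(5e-4, 7))
  ## per-trait polygenicity equals pi_total in all presets
  for (s in list(core, ring, eq))
    expect_equal(pattern_margins(s$truth)$pi_u, rep(0.002, 3))
  expect_error(scenario_spec("custom", pi7 = rep(0.2, 7)), "exceed")
})

test_that("component assignment hits per-trait causal totals exactly", {
  panel10k <- make_ld_panel(10000, seed = 1)
  a <- assign_components(scenario_spec("core", n_variants = 1e4), panel10k)
  expect_equal(unname(attr(a, "counts")), c(10, 10, 10, 0, 0, 0, 10))
  a <- assign_components(scenario_spec("equilibrium", n_variants = 1e4),
                         panel10k)
  expect_equal(unname(attr(a, "counts")), rep(5, 7))
  ## full-scale worked example: polygenicity 0.002 on the 12,926,691-variant
  ## panel selects 25,853 causal variants per phenotype
  spec <- scenario_spec("core", n_variants = 12926691)
  marg <- pattern_margins(spec$truth)
  n123 <- round(spec$pi7_true[["pi123"]] * spec$n_variants)
  per_trait <- round(marg$pi_u[1] * spec$n_variants)
  expect_equal(per_trait, 25853)
  expect_equal(n123 + (per_trait - n123), 25853)
})

test_that("effects respect component membership and correlations", {
  panel <- make_ld_panel(20000, seed = 2)
  spec <- scenario_spec("custom", n_variants = 2e4,
                        pi7 = c(0, 0, 0.05, 0.3, 0, 0, 0.2),
                        rho = c(0.9, 0, 0))
  a <- assign_components(spec, panel, seed = 4)
  b <- sample_effects(a, spec$rho, seed = 4)
  ## trait-3-specific variants have exact zeros on traits 1, 2
  i3 <- which(a == 3)
  expect_true(all(b[i3, 1] == 0) && all(b[i3, 2] == 0))
  ## correlation within the 12 component approximates rho12
  i12 <- which(a == 4)
  expect_gt(length(i12), 2000)
  expect_lt(abs(cor(b[i12, 1], b[i12, 2]) - 0.9), 0.05)
  ## uncorrelated component: near-zero correlation
  i123 <- which(a == 7)
  expect_lt(abs(cor(b[i123, 2], b[i123, 3])), 0.05)
})

test_that("heritability scaling is exact and scales as expected", {
  panel <- make_ld_panel(5000, seed = 3)
  spec <- scenario_spec("equilibrium", n_variants = 5000, pi_total = 0.01)
  a <- assign_components(spec, panel, seed = 1)
  b0 <- sample_effects(a, seed = 1)
  b <- scale_to_h2(b0, panel$het, 0.4)
  for (i in 1:3)
    expect_equal(sum(panel$het * b[, i]^2), 0.4, tolerance = 1e-12)
  b2 <- scale_to_h2(b0, panel$het, 0.8)
  expect_equal(b2[, 1], sqrt(2) * b[, 1], tolerance = 1e-12)
  ## single causal variant algebra: h * beta^2 = h2
  one <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(scale_to_h2(one, 0.5, c(0.4, 0, 0))[1, 1]^2, 0.8)
})

test_that("null z-scores are calibrated and reproducible", {
  spec <- scenario_spec("custom", n_variants = 3e4, pi7 = rep(0, 7),
                        h2 = 0, n = rep(5000, 3), rho0 = c(0.5, 0, 0))
  sim <- simulate_scenario(spec, seed = 8)
  expect_lt(abs(var(sim$z[, 1]) - 1), 0.02)
  expect_lt(abs(var(sim$z[, 2]) - 1), 0.02)
  expect_lt(abs(cor(sim$z[, 1], sim$z[, 2]) - 0.5), 0.02)
  expect_lt(abs(mean(sim$z[, 3])), 3 / sqrt(3e4))
  sim2 <- simulate_scenario(spec, seed = 8)
  expect_identical(sim$z, sim2$z)
})

test_that("causal signal inflates z variance and grows with N", {
  spec1 <- scenario_spec("equilibrium", n_variants = 2e4, n = rep(2000, 3))
  spec2 <- scenario_spec("equilibrium", n_variants = 2e4, n = rep(8000, 3))
  s1 <- simulate_scenario(spec1, seed = 5)
  s2 <- simulate_scenario(spec2, seed = 5)
  causal_blocks <- which(s1$beta[, 1] != 0)
  v_causal <- var(s1$z[causal_blocks, 1])
  expect_gt(v_causal, 1.5)
  expect_gt(var(s2$z[, 1]), var(s1$z[, 1]))
})

test_that("panel block r2 decays on average like the requested profile", {
  panel <- make_ld_panel(1e5, block_size = c(2, 8), r2_decay = 0.6,
                         seed = 11)
  blocks <- attr(panel, "blocks")
  expect_lt(abs(mean(blocks$c[blocks$size > 1]^2) - 0.6), 0.6 * 0.05)
  ## neighbor lists symmetric with unit self-pairs
  j <- 17
  nb <- ld_neighbors(panel, j)
  expect_true(j %in% nb$idx)
  expect_equal(nb$r2[nb$idx == j], 1)
  for (k in nb$idx[nb$idx != j]) {
    back <- ld_neighbors(panel, k)
    expect_equal(back$r2[back$idx == j], nb$r2[nb$idx == k])
  }
  ## block size 1 panels have singleton neighborhoods
  p1 <- make_ld_panel(100, block_size = c(1, 1), seed = 1)
  expect_equal(diff(p1$nbr_ptr), rep(1L, 100))
  ## determinism
  p2 <- make_ld_panel(100, block_size = c(1, 1), seed = 1)
  expect_identical(p1$variants, p2$variants)
})

test_that("toy genotype r2 matches direct correlation and round-trips", {
  set.seed(33)
  G <- matrix(rbinom(50 * 20, 2, 0.4), 50, 20)
  G[, 2] <- G[, 1]                      # identical columns -> r2 = 1
  out <- toy_genotype_r2(G, window = 20, r2_floor = 0)
  pick <- function(a, b) out$R2[out$SNP_A == sprintf("snp%07d", a) &
                                  out$SNP_B == sprintf("snp%07d", b)]
  expect_equal(pick(1, 2), 1)
  for (k in 1:20) {
    ab <- sort(sample.int(20, 2))
    expect_equal(pick(ab[1], ab[2]), cor(G[, ab[1]], G[, ab[2]])^2,
                 tolerance = 1e-12)
  }
  ## emitted table loads as an LD panel
  meta <- data.frame(ID = sprintf("snp%07d", 1:20), CHR = 1L,
                     BP = 1:20 * 1000L, A1 = "A", A2 = "G",
                     FRQ = colMeans(G) / 2)
  f <- tempfile()
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- load_ld_text(f, meta)
  expect_equal(nrow(p$variants), 20)
})
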