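## Generative simulator: block LD panels, scenario assignment of causal
## variants, effect sampling, heritability scaling, and GWAS z-score
## synthesis directly from the model the estimator assumes.

#' Scenario specification for simulated triads
#'
#' Three named presets reproduce the canonical overlap geometries at equal
#' per-trait polygenicity `pi_total` and SNP-heritability `h2`:
#' * `core` — only triple overlap: `pi1 = pi2 = pi3 = pi123 = pi_total/2`,
#'   pairs zero (half of each trait's variants shared by all three);
#' * `ring` — no triple overlap: `pi12 = pi13 = pi23 = pi_total/2`,
#'   others zero;
#' * `equilibrium` — all seven components equal (`pi_total/4` each).
#'
#' @param name `"core"`, `"ring"`, `"equilibrium"` or `"custom"`.
#' @param pi_total per-trait polygenicity (proportion of panel variants).
#' @param h2 per-trait SNP heritability target.
#' @param n_variants panel size.
#' @param n GWAS sample sizes, length 3.
#' @param rho effect correlations within shared components.
#' @param sigma0,rho0 residual structure of the three GWAS.
#' @param pi7 seven component proportions, required for `"custom"`.
#' @return a `scenario_spec` list including the ground-truth
#'   `overlap_pattern`.
#' @export
scenario_spec <- function(name = c("core", "ring", "equilibrium", "custom"),
                          pi_total = 0.002, h2 = 0.4, n_variants = 1e5,
                          n = rep(2000, 3), rho = c(0, 0, 0),
                          sigma0 = rep(1, 3), rho0 = c(0, 0, 0),
                          pi7 = NULL) {
  name <- match.arg(name)
  h <- pi_total / 2
  pi7 <- switch(name,
    core = c(h, h, h, 0, 0, 0, h),
    ring = c(0, 0, 0, h, h, h, 0),
    equilibrium = rep(pi_total / 4, 7),
    custom = {
      if (is.null(pi7) || length(pi7) != 7) stop("custom scenario needs pi7")
      if (sum(pi7) > 1) stop("sum(pi7) must not exceed 1")
      as.numeric(pi7)
    })
  pi7 <- setNames(pi7, PI7_NAMES)
  truth <- structure(list(pi7 = pi7, union = sum(pi7), source = "truth"),
                     class = "overlap_pattern")
  structure(list(name = name, pi7_true = pi7, pi_total = pi_total, h2 = h2,
                 n_variants = as.integer(n_variants), n = rep_len(n, 3),
                 rho = rep_len(rho, 3), sigma0 = rep_len(sigma0, 3),
                 rho0 = rep_len(rho0, 3), truth = truth),
            class = "scenario_spec")
}

#' Simulate a block-structured LD reference panel
#'
#' Variants are partitioned into LD blocks; within a block genotype
#' correlations follow an AR(1) profile, `r_jk = c^|j-k|`, with the
#' squared adjacent correlation `c^2` drawn per block around `r2_decay`
#' (Beta distributed, concentration `decay_conc`).  This guarantees a
#' positive-definite within-block correlation matrix.  Cross-block r2 is
#' zero; pairs below `r2_floor` are absent from the neighbor lists, as in
#' a PLINK-derived panel.  Allele frequencies are uniform on `freq_range`.
#'
#' @param n_variants panel size (>= 1).
#' @param block_size integer range `c(min, max)` of block sizes (uniform).
#' @param r2_decay mean squared correlation between adjacent variants.
#' @param freq_range allele-frequency range (kept clear of downstream MAF
#'   filters by default).
#' @param r2_floor construction floor below which pairs are dropped.
#' @param decay_conc Beta concentration of the per-block decay draw.
#' @param seed integer seed; the panel is deterministic given all inputs.
#' @return an `ld_panel` with attributes `blocks` (data.frame: start, size,
#'   c = signed adjacent correlation) and `r2_floor`.
#' @export
make_ld_panel <- function(n_variants, block_size = c(1, 10), r2_decay = 0.6,
                          freq_range = c(0.05, 0.5), r2_floor = 0.01,
                          decay_conc = 30, seed = 1L) {
  stopifnot(n_variants >= 1, block_size[1] >= 1,
            block_size[2] >= block_size[1])
  with_seed_local(seed, {
    sizes <- integer(0)
    while (sum(sizes) < n_variants)
      sizes <- c(sizes, sample(block_size[1]:block_size[2],
                               max(64, ceiling(n_variants / mean(block_size))),
                               replace = TRUE))
    sizes <- sizes[cumsum(sizes) <= n_variants]
    if (sum(sizes) < n_variants) sizes <- c(sizes, n_variants - sum(sizes))
    nb <- length(sizes)
    cdec <- sqrt(rbeta(nb, r2_decay * decay_conc, (1 - r2_decay) * decay_conc))
    cdec[sizes == 1] <- 0
    freq <- runif(n_variants, freq_range[1], freq_range[2])
    variants <- data.frame(
      id = sprintf("snp%07d", seq_len(n_variants)),
      chrom = 1L, pos = seq_len(n_variants) * 1000L,
      a1 = "A", a2 = "G", freq = freq, stringsAsFactors = FALSE)
    start <- cumsum(c(1L, sizes[-nb]))
    ## within-block pairs above the floor, vectorized by lag distance
    acc <- vector("list", 3 * max(sizes))
    na <- 0L
    dmax_b <- ifelse(cdec > 0 & sizes > 1,
                     pmin(sizes - 1, floor(log(r2_floor) /
                                             (2 * log(pmax(cdec, 1e-12))))),
                     0L)
    for (dd in seq_len(max(c(0L, dmax_b)))) {
      bsel <- which(dmax_b >= dd)
      if (!length(bsel)) break
      a <- unlist(lapply(bsel, function(b)
        start[b]:(start[b] + sizes[b] - 1L - dd)), use.names = FALSE)
      r2v <- rep.int(cdec[bsel]^(2 * dd), sizes[bsel] - dd)
      na <- na + 1L
      acc[[na]] <- list(i = a, j = a + dd, r2 = r2v)
    }
    acc <- acc[seq_len(na)]
    ii <- unlist(lapply(acc, `[[`, "i"), use.names = FALSE)
    jj <- unlist(lapply(acc, `[[`, "j"), use.names = FALSE)
    rr <- unlist(lapply(acc, `[[`, "r2"), use.names = FALSE)
    if (is.null(ii)) { ii <- integer(0); jj <- integer(0); rr <- numeric(0) }
    panel <- ld_panel(variants, list(i = ii, j = jj, r2 = rr))
    attr(panel, "blocks") <- data.frame(start = start, size = sizes, c = cdec)
    attr(panel, "r2_floor") <- r2_floor
    panel
  })
}

#' Assign causal variants to the seven overlap components
#'
#' Component counts are derived so that every per-trait causal total equals
#' `round(pi_i^u * n_variants)` exactly (the triple component is rounded
#' first, then pairs, then trait-specific remainders).  Variants are drawn
#' uniformly without replacement.
#'
#' @param spec a [scenario_spec].
#' @param panel the `ld_panel` the assignment refers to; `NULL` uses
#'   `spec$n_variants` (assignment only needs the panel size).
#' @param seed integer seed.
#' @return integer vector over panel variants with values in
#'   `0:7` coding (null, 1, 2, 3, 12, 13, 23, 123); attribute `counts`
#'   holds the per-component sizes.
#' @export
assign_components <- function(spec, panel = NULL, seed = 1L) {
  n <- if (is.null(panel)) spec$n_variants else nrow(panel$variants)
  marg <- pattern_margins(spec$truth)
  n123 <- round(spec$pi7_true[["pi123"]] * n)
  npair <- round(marg$pi_b * n) - n123
  nuni <- round(marg$pi_u * n)
  nspec <- c(nuni[1] - npair[1] - npair[2] - n123,
             nuni[2] - npair[1] - npair[3] - n123,
             nuni[3] - npair[2] - npair[3] - n123)
  counts <- c(nspec, npair, n123)
  if (any(counts < 0)) stop("component counts came out negative; ",
                            "check pi7_true against the panel size")
  if (sum(counts) > n) stop("more causal variants than panel variants")
  lab <- integer(n)
  with_seed_local(seed, {
    chosen <- sample.int(n, sum(counts))
    lab[chosen] <- rep.int(1:7, counts)
  })
  attr(lab, "counts") <- setNames(counts, PI7_NAMES)
  lab
}

## trait membership of the seven components, in PI7_NAMES order
COMP_TRAITS <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)

#' Sample direct allelic effects for an assignment
#'
#' Within each component, active-trait effects are zero-mean multinormal
#' with unit variances and the component's effect correlations; traits
#' outside the component get exact zeros.  (Scale is applied afterwards by
#' [scale_to_h2].)
#'
#' @param assignment integer labels from [assign_components].
#' @param rho effect correlations `(rho12, rho13, rho23)`.
#' @param seed integer seed.
#' @return n x 3 matrix of effects.
#' @export
sample_effects <- function(assignment, rho = c(0, 0, 0), seed = 1L) {
  n <- length(assignment)
  beta <- matrix(0, n, 3)
  rho_full <- matrix(c(1, rho[1], rho[2], rho[1], 1, rho[3], rho[2], rho[3],
                       1), 3, 3)
  with_seed_local(seed + 1000, {
    for (comp in 1:7) {
      rows <- which(assignment == comp)
      if (!length(rows)) next
      tr <- COMP_TRAITS[[comp]]
      cv <- rho_full[tr, tr, drop = FALSE]
      beta[rows, tr] <- matrix(rnorm(length(rows) * length(tr)),
                               length(rows)) %*% chol(cv)
    }
  })
  beta
}

#' Scale effects to a target SNP heritability
#'
#' Per trait, effects are multiplied by
#' `sqrt(h2_target / sum_k h_k beta_k^2)` so that the heterozygosity-
#' weighted effect variance equals the target exactly.
#'
#' @param beta n x 3 effect matrix.
#' @param het per-variant heterozygosity.
#' @param h2_target scalar or length-3 heritability target.
#' @return scaled effect matrix with attribute `h2` (realized, = target).
#' @export
scale_to_h2 <- function(beta, het, h2_target) {
  h2 <- rep_len(h2_target, 3)
  for (i in 1:3) {
    tot <- sum(het * beta[, i]^2)
    if (tot == 0) {
      if (h2[i] > 0) stop("trait ", i, " has no causal variants to scale")
      next
    }
    beta[, i] <- beta[, i] * sqrt(h2[i] / tot)
  }
  attr(beta, "h2") <- h2
  beta
}

#' Synthesize GWAS z-scores from effects and the LD panel
#'
#' Implements the model's z-score equation directly:
#' `z_ij = sum_k sqrt(h_k) r_jk sqrt(N_i) beta_ik + eps_j` with
#' `eps ~ N(0, Sigma0)`.  Signed within-block correlations come from the
#' panel's AR(1) block structure.  Residuals are drawn independently per
#' tag variant by default (the per-variant marginal the likelihood models);
#' `ld_noise = TRUE` instead draws them as an AR(1) field over each block,
#' matching how correlated sampling noise behaves in real GWAS.
#'
#' @param beta scaled n x 3 effect matrix.
#' @param panel an `ld_panel` from [make_ld_panel].
#' @param spec a [scenario_spec] (supplies N, sigma0, rho0).
#' @param seed integer seed.
#' @param ld_noise draw residuals LD-correlated within blocks.
#' @return list with `z` (n x 3 matrix) and `tables` (three `sumstats`
#'   data.frames ready for [harmonize_sumstats] or text export).
#' @export
sample_z <- function(beta, panel, spec, seed = 1L, ld_noise = FALSE) {
  blocks <- attr(panel, "blocks")
  if (is.null(blocks)) stop("panel lacks block structure (not simulated?)")
  n <- nrow(panel$variants)
  sh <- sqrt(panel$het)
  ## genetic signal: for each causal variant k spread sqrt(h_k) beta_k over
  ## its block with the signed AR(1) correlation profile
  sig <- matrix(0, n, 3)
  x <- sh * beta          # n x 3, nonzero only at causal rows
  causal <- which(rowSums(x != 0) > 0)
  if (length(causal)) {
    bl_of <- rep.int(seq_len(nrow(blocks)), blocks$size)
    for (k in causal) {
      b <- bl_of[k]
      s0 <- blocks$start[b]; s1 <- s0 + blocks$size[b] - 1L
      r <- blocks$c[b]^abs(seq(s0, s1) - k)
      sig[s0:s1, ] <- sig[s0:s1, ] + outer(r, x[k, ])
    }
  }
  sig <- sweep(sig, 2, sqrt(spec$n), "*")
  sig0 <- mixture_params(sigma0 = spec$sigma0, rho0 = spec$rho0)
  S0 <- sigma0_cov(sig0)
  eps <- with_seed_local(seed + 2000, {
    e <- matrix(rnorm(n * 3), n, 3)
    if (ld_noise) {
      bl_of <- rep.int(seq_len(nrow(blocks)), blocks$size)
      for (b in seq_len(nrow(blocks))) {
        if (blocks$size[b] < 2 || blocks$c[b] == 0) next
        rows <- blocks$start[b]:(blocks$start[b] + blocks$size[b] - 1L)
        cc <- blocks$c[b]
        for (i in 2:length(rows))
          e[rows[i], ] <- cc * e[rows[i - 1], ] +
            sqrt(1 - cc^2) * e[rows[i], ]
      }
    }
    e %*% chol(S0)
  })
  z <- sig + eps
  v <- panel$variants
  tables <- lapply(1:3, function(i)
    data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$a1, A2 = v$a2,
               Z = z[, i], N = spec$n[i], stringsAsFactors = FALSE))
  list(z = z, tables = tables)
}

#' Simulate a full scenario: panel, assignment, effects, z-scores
#'
#' Convenience wrapper running [make_ld_panel], [assign_components],
#' [sample_effects], [scale_to_h2] and [sample_z] with seeds derived from
#' one master seed.
#'
#' @param spec a [scenario_spec].
#' @param seed master seed.
#' @param panel optionally reuse an existing simulated panel.
#' @param ... passed to [make_ld_panel].
#' @return list with `panel`, `assignment`, `beta`, `z`, `tables`, `spec`.
#' @export
simulate_scenario <- function(spec, seed = 1L, panel = NULL, ...) {
  if (is.null(panel)) panel <- make_ld_panel(spec$n_variants, seed = seed, ...)
  assignment <- assign_components(spec, panel, seed = seed)
  beta <- sample_effects(assignment, spec$rho, seed = seed)
  beta <- scale_to_h2(beta, panel$het, spec$h2)
  zs <- sample_z(beta, panel, spec, seed = seed)
  list(panel = panel, assignment = assignment, beta = beta, z = zs$z,
       tables = zs$tables, spec = spec, seed = seed)
}

#' Pairwise r2 from a toy genotype matrix, in PLINK text form
#'
#' Squared Pearson correlation between genotype columns within a positional
#' window, emitted in the PLINK `--r2` dialect so the output round-trips
#' through [load_ld_text].
#'
#' @param G individuals x variants genotype (dosage) matrix.
#' @param window maximum index distance between paired variants.
#' @param r2_floor pairs below this are omitted.
#' @param meta optional variant metadata (id, chrom, pos); defaults are
#'   generated.
#' @return data.frame with columns CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2.
#' @export
toy_genotype_r2 <- function(G, window = ncol(G), r2_floor = 0.01,
                            meta = NULL) {
  if (nrow(G) < 2) stop("need at least two individuals")
  p <- ncol(G)
  if (is.null(meta))
    meta <- data.frame(id = sprintf("snp%07d", seq_len(p)), chrom = 1L,
                       pos = seq_len(p) * 1000L)
  ii <- integer(0); jj <- integer(0); rr <- numeric(0)
  for (a in seq_len(p - 1)) {
    bmax <- min(p, a + window)
    for (b in (a + 1):bmax) {
      sa <- sd(G[, a]); sb <- sd(G[, b])
      r2 <- if (sa == 0 || sb == 0) 0 else cor(G[, a], G[, b])^2
      if (is.finite(r2) && r2 >= r2_floor) {
        ii <- c(ii, a); jj <- c(jj, b); rr <- c(rr, r2)
      }
    }
  }
  data.frame(CHR_A = meta$chrom[ii], BP_A = meta$pos[ii], SNP_A = meta$id[ii],
             CHR_B = meta$chrom[jj], BP_B = meta$pos[jj], SNP_B = meta$id[jj],
             R2 = rr, stringsAsFactors = FALSE)
}
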