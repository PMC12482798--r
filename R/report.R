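## Result rendering and the two pipeline entry points used by the
## command-line wrapper: fit a triad from files, or write a simulated
## scenario to files.

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

pattern_json <- function(pattern, union_ref = NULL) {
  pct <- euler_percentages(pattern, union = union_ref)
  list(pi7 = as.list(pattern$pi7), union = pattern$union,
       percent = as.list(setNames(pct$percent, PI7_NAMES)),
       percent_rounded = as.list(setNames(pct$rounded, PI7_NAMES)),
       source = pattern$source)
}

#' Fit a triad of GWAS from a configuration and write all artifacts
#'
#' Runs the full pipeline for every `rand_prune_seed`, aggregates runs,
#' computes the maximum-entropy baseline from the representative run's
#' univariate/bivariate estimates, and writes per-run JSON, an ensemble
#' TSV (one row per run), the fitted and naive pattern JSON, and a
#' best-effort area-proportional Euler diagram (PDF).  Every file carries
#' the configuration hash and seed(s) for provenance.
#'
#' @param cfg a `trimix_config` (see [load_config]).  In-memory inputs are
#'   accepted: `sumstats` may be a list of data.frames and `panel_meta` /
#'   `ld_files` may be replaced by an `ld_panel` in `cfg$panel`.
#' @param verbose print per-stage progress.
#' @return list with `runs`, `agg`, `fitted`, `naive`, `files`.
#' @export
cmd_fit <- function(cfg, verbose = TRUE) {
  if (!inherits(cfg, "trimix_config")) cfg <- load_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- if (!is.null(cfg[["panel"]])) cfg[["panel"]]
    else load_ld_text(cfg$ld_files, data.table::fread(cfg$panel_meta,
                                                      data.table = FALSE))
  tabs <- lapply(cfg$sumstats, function(s)
    if (is.character(s)) read_sumstats(s, cfg$column_map, cfg$n_const)
    else s)
  aligned <- harmonize_sumstats(tabs, panel$variants)
  fcfg <- config_filters(cfg)
  seeds <- as.integer(cfg$rand_prune_seed)
  opt <- list()
  if (!is.null(cfg$grid$margin)) opt$margin <- cfg$grid$margin
  if (!is.null(cfg$grid$tail)) opt$tail <- rep_len(cfg$grid$tail, 3)
  runs <- lapply(seeds, function(s)
    run_pipeline(aligned, panel, fcfg, seed = s, n_random = cfg$n_random,
                 do_pruning = isTRUE(cfg$do_pruning),
                 r2_prune_thresh = cfg$r2_prune_thresh, n_bins = cfg$n_bins,
                 opt = opt, verbose = verbose))
  hash <- config_hash(cfg[!vapply(cfg, is.environment, TRUE)])
  files <- character(0)
  for (r in runs) {
    f <- file.path(cfg$out_dir, sprintf("run_seed%d.json", r$seed))
    jsonlite::write_json(
      list(config_hash = hash, seed = r$seed,
           pattern = pattern_json(r$pattern),
           pi_u = r$pi_u, pi_b = r$pi_b, pi123 = r$pi123,
           sigma = vapply(r$uni, `[[`, 0, "sigma"),
           sigma0 = vapply(r$uni, `[[`, 0, "sigma0"),
           rho = vapply(r$bi, `[[`, 0, "rho"),
           rho0 = vapply(r$bi, `[[`, 0, "rho0"),
           logliks = as.list(r$logliks),
           selected_variants = r$selected_variants),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  if (length(runs) >= 2) {
    agg <- aggregate_runs(runs)
    rep_run <- runs[[agg$representative]]
  } else {
    agg <- list(median_pi7 = runs[[1]]$pattern$pi7, representative = 1L,
                deviation = 0, runs = runs)
    rep_run <- runs[[1]]
  }
  fitted <- rep_run$pattern
  naive <- naive_max_entropy(rep_run$pi_u, rep_run$pi_b)
  tsv <- file.path(cfg$out_dir, "ensemble.tsv")
  et <- ensemble_table(runs)
  et$config_hash <- hash
  data.table::fwrite(et, tsv, sep = "\t")
  pj <- file.path(cfg$out_dir, "pattern.json")
  jsonlite::write_json(
    list(config_hash = hash, seeds = seeds,
         representative_seed = rep_run$seed,
         fitted = pattern_json(fitted),
         naive = pattern_json(naive, union_ref = fitted$union),
         median_pi7 = as.list(agg$median_pi7)),
    pj, auto_unbox = TRUE, digits = NA)
  fig <- file.path(cfg$out_dir, "euler.pdf")
  try(euler_plot(fitted, path = fig), silent = TRUE)
  list(runs = runs, agg = agg, fitted = fitted, naive = naive,
       files = c(files, tsv, pj, fig))
}

#' Simulate a scenario and write sumstats, LD files and ground truth
#'
#' @param spec a [scenario_spec] (or scenario name).
#' @param out_dir output directory.
#' @param seed master simulation seed.
#' @param ... passed to [simulate_scenario].
#' @return list with `files` and the simulation object (invisibly large
#'   pieces dropped).
#' @export
cmd_simulate <- function(spec, out_dir = "trimix_sim", seed = 1L, ...) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scenario(spec, seed = seed, ...)
  files <- character(0)
  for (i in 1:3) {
    f <- file.path(out_dir, sprintf("trait%d.sumstats.tsv", i))
    data.table::fwrite(sim$tables[[i]], f, sep = "\t")
    files <- c(files, f)
  }
  ldf <- file.path(out_dir, "panel.r2.tsv")
  write_ld_text(sim$panel, ldf)
  metaf <- file.path(out_dir, "panel.variants.tsv")
  data.table::fwrite(sim$panel$variants, metaf, sep = "\t")
  truthf <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(scenario = spec$name, seed = seed,
         pi7_true = as.list(spec$pi7_true),
         pi_total = spec$pi_total, h2 = spec$h2, n = spec$n,
         n_variants = spec$n_variants,
         causal_counts = as.list(attr(sim$assignment, "counts")),
         truth = pattern_json(sim$spec$truth)),
    truthf, auto_unbox = TRUE, digits = NA)
  files <- c(files, ldf, metaf, truthf)
  invisible(list(files = files, spec = spec, seed = seed))
}

## ---- Euler rendering -------------------------------------------------

circle_lens <- function(d, r1, r2) {
  ## area of intersection of two circles at centre distance d
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                          (d + r1 + r2)))
  a1 + a2 - a3
}

#' Draw a best-effort area-proportional three-circle Euler diagram
#'
#' Circle areas are proportional to the univariate polygenicities and
#' centre positions are optimized so pairwise intersection areas match the
#' bivariate overlaps.  Exact three-set area-proportional diagrams are not
#' always realizable with circles; the numerical pattern is the source of
#' truth and each region is annotated with its rounded percentage of the
#' union.
#'
#' @param pattern an `overlap_pattern`.
#' @param labels trait labels.
#' @param path output PDF path; `NULL` draws on the active device.
#' @return invisibly, the optimized centres and radii.
#' @export
euler_plot <- function(pattern, labels = paste("Trait", 1:3), path = NULL) {
  marg <- pattern_margins(pattern)
  r <- sqrt(marg$pi_u / pi)
  target <- marg$pi_b
  loss <- function(x) {
    cx <- c(0, x[1], x[3]); cy <- c(0, x[2], x[4])
    dd <- c(sqrt((cx[1] - cx[2])^2 + (cy[1] - cy[2])^2),
            sqrt((cx[1] - cx[3])^2 + (cy[1] - cy[3])^2),
            sqrt((cx[2] - cx[3])^2 + (cy[2] - cy[3])^2))
    got <- c(circle_lens(dd[1], r[1], r[2]), circle_lens(dd[2], r[1], r[3]),
             circle_lens(dd[3], r[2], r[3]))
    sum((got - target)^2) / sum(target^2 + 1e-12)
  }
  d0 <- mean(r)
  o <- optim(c(d0, 0, d0 / 2, d0), loss, method = "Nelder-Mead",
             control = list(maxit = 500))
  cx <- c(0, o$par[1], o$par[3]); cy <- c(0, o$par[2], o$par[4])
  pct <- euler_percentages(pattern)$rounded
  draw <- function() {
    graphics::par(mar = c(1, 1, 2, 1))
    lim <- range(c(cx - r, cx + r, cy - r, cy + r))
    graphics::plot(NA, xlim = lim, ylim = lim, asp = 1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = sprintf("Polygenic overlap (%s)", pattern$source))
    th <- seq(0, 2 * pi, length.out = 200)
    cols <- grDevices::adjustcolor(c("#1b9e77", "#d95f02", "#7570b3"), 0.35)
    for (i in 1:3) {
      graphics::polygon(cx[i] + r[i] * cos(th), cy[i] + r[i] * sin(th),
                        col = cols[i], border = "grey30")
      graphics::text(cx[i], cy[i] + 1.05 * r[i], labels[i], cex = 0.9)
    }
    legend_txt <- sprintf("%s: %d%%", PI7_NAMES, pct)
    graphics::legend("topleft", legend = legend_txt, bty = "n", cex = 0.7)
  }
  if (!is.null(path)) {
    grDevices::pdf(path, width = 5, height = 5)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(list(cx = cx, cy = cy, r = r, loss = o$value))
}
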