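write_sumstats_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

toy_panel <- function() {
  ld_panel(data.frame(
    id = paste0("rs", 1:6), chrom = c(1L, 1L, 2L, 6L, 6L, 9L),
    pos = c(100L, 200L, 300L, 26e6, 40e6, 500L),
    a1 = c("A", "G", "C", "A", "G", "T"),
    a2 = c("G", "A", "T", "C", "T", "A"),
    freq = c(0.3, 0.2, 0.01, 0.4, 0.25, 0.45),
    stringsAsFactors = FALSE))
}

test_that("read_sumstats parses z directly or derives it from beta/se", {
  f <- write_sumstats_file(data.frame(
    SNP = paste0("rs", 1:5), CHR = 1, BP = 1:5 * 100,
    A1 = "A", A2 = "G", Z = c(1, -2, 0.5, 3, -1), N = 1000))
  t1 <- read_sumstats(f)
  expect_equal(nrow(t1), 5)
  expect_equal(t1$z, c(1, -2, 0.5, 3, -1))

  f2 <- write_sumstats_file(data.frame(
    SNP = "rs1", CHR = 1, BP = 100, A1 = "A", A2 = "G",
    BETA = 0.2, SE = 0.1, N = 1000))
  expect_equal(read_sumstats(f2)$z, 2)

  f3 <- write_sumstats_file(data.frame(SNP = "rs1", CHR = 1, BP = 1,
                                       A1 = "A", A2 = "G", N = 10))
  expect_error(read_sumstats(f3), "Z, or both BETA and SE")
  f4 <- write_sumstats_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G"))
  expect_error(read_sumstats(f4), "Z, or both BETA and SE")
})

test_that("read_sumstats drops incomplete rows and duplicates with a log", {
  f <- write_sumstats_file(data.frame(
    SNP = c("rs1", "rs2", "rs2", "rs3"), CHR = 1, BP = c(1, 2, 2, 3) * 100,
    A1 = "A", A2 = "G", Z = c(1, 2, 2, NA), N = 1000))
  t1 <- read_sumstats(f)
  expect_equal(t1$id, c("rs1", "rs2"))
  log <- attr(t1, "log")
  expect_equal(log$rows_in,
               log$rows_out + log$dropped_incomplete +
                 log$dropped_duplicate_id)
})

test_that("harmonization aligns alleles, flips swapped z, drops ambiguous", {
  panel <- toy_panel()
  base <- data.frame(id = paste0("rs", 1:6), chrom = panel$variants$chrom,
                     pos = panel$variants$pos, a1 = panel$variants$a1,
                     a2 = panel$variants$a2, z = c(1.5, 1, 2, -1, 0.5, 2),
                     n = 1000, stringsAsFactors = FALSE)
  t2 <- base
  ## swap alleles for rs2: z must flip
  t2$a1[2] <- panel$variants$a2[2]; t2$a2[2] <- panel$variants$a1[2]
  ## mismatched alleles for rs3: dropped
  t3 <- base; t3$a1[3] <- "G"; t3$a2[3] <- "C"
  al <- harmonize_sumstats(list(base, t2, t3), panel$variants)
  ids <- panel$variants$id[al$idx]
  ## rs3 mismatch in table 3; rs6 is palindromic (T/A) everywhere
  expect_false(any(c("rs3", "rs6") %in% ids))
  i2 <- which(ids == "rs2")
  expect_equal(al$z[i2, 2], -base$z[2])
  expect_equal(al$z[i2, 1], base$z[2])
  ## harmonizing an already-aligned table is the identity
  al2 <- harmonize_sumstats(list(base, base, base), panel$variants)
  j <- match(al$idx, al2$idx)
  expect_equal(al2$z[j, 1], al$z[, 1])
})

test_that("filters retain exactly the variants passing every rule", {
  panel <- toy_panel()
  base <- data.frame(id = paste0("rs", 1:6), chrom = panel$variants$chrom,
                     pos = panel$variants$pos, a1 = panel$variants$a1,
                     a2 = panel$variants$a2,
                     z = c(1, 1, 1, 1, 33, 1), n = 1000,
                     info = c(1, 0.5, 1, 1, 1, 1),
                     stringsAsFactors = FALSE)
  al <- harmonize_sumstats(list(base, base, base), panel$variants)
  ## rs6 (palindromic) already gone; of the rest: rs2 fails INFO, rs3 fails
  ## MAF (freq 0.01), rs4 in the MHC, rs5 fails |z| <= 32
  res <- apply_filters(al, filter_config(), panel)
  expect_equal(panel$variants$id[res$idx], "rs1")
  expect_equal(res$log$n_in,
               res$log$n_out + res$log$dropped_maf + res$log$dropped_info +
                 res$log$dropped_z + res$log$dropped_region)
  ## boundary: |z| exactly at the threshold is retained
  base$z[5] <- 32; base$info[2] <- 0.8
  al <- harmonize_sumstats(list(base, base, base), panel$variants)
  res <- apply_filters(al, filter_config(), panel)
  expect_true(all(c("rs2", "rs5") %in% panel$variants$id[res$idx]))
  ## filtering is idempotent
  al_sub <- list(idx = res$idx, z = al$z[res$keep, , drop = FALSE],
                 n = al$n[res$keep, , drop = FALSE],
                 info = al$info[res$keep, , drop = FALSE])
  res2 <- apply_filters(al_sub, filter_config(), panel)
  expect_equal(res2$idx, res$idx)
  ## no exclude regions + passing thresholds = identity
  res3 <- apply_filters(al_sub, filter_config(exclude_regions = list()),
                        panel)
  expect_equal(res3$idx, res$idx)
})
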