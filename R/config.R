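## JSON configuration: defaults, validation, region parsing.

CONFIG_DEFAULTS <- list(
  sumstats = NULL,            # three file paths
  ld_files = NULL,            # PLINK-dialect r2 text file(s)
  panel_meta = NULL,          # variant table with frequencies
  panel = NULL,               # in-memory ld_panel (alternative to files)
  n_const = NULL,             # constant N when sumstats lack an N column
  column_map = NULL,
  maf_thresh = 0.05,
  info_thresh = 0.8,
  z_thresh = 32,
  exclude_regions = list("6:25000000-34000000"),
  do_pruning = TRUE,
  r2_prune_thresh = 0.8,
  n_random = 300000,
  rand_prune_seed = 1,
  n_bins = 128,
  grid = list(margin = 4, tail = c(6, 6, 5)),
  out_dir = "trimix_out")

#' Parse a genomic region string
#'
#' `"6:25000000-34000000"` (hyphen or en-dash, optional thousands commas)
#' to a numeric `c(chrom, start, end)`, 1-based inclusive.
#'
#' @param x region string, or an already-numeric length-3 vector.
#' @return numeric(3).
#' @export
parse_region <- function(x) {
  if (is.numeric(x) && length(x) == 3) return(as.numeric(x))
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([0-9XY]+):([0-9]+)[-–]([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region '", x,
                           "'; expected CHR:START-END")
  out <- as.numeric(m[2:4])
  if (out[2] > out[3]) stop("region start exceeds end in '", x, "'")
  out
}

#' Load and validate a JSON configuration
#'
#' Missing keys take the built-in defaults (the thresholds every analysis
#' in the accompanying work used: MAF 0.05, INFO 0.8, |z| 32, MHC exclusion
#' on chr6, random pruning at r2 0.8, 300,000 optimization variants,
#' seed 1).  Unknown keys are rejected with a list.
#'
#' @param path JSON file, or a named list already in memory.
#' @return validated `trimix_config` list.
#' @export
load_config <- function(path) {
  user <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else as.list(path)
  unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(CONFIG_DEFAULTS, user)
  chk <- function(cond, msg) if (!cond) stop("invalid configuration: ", msg)
  chk(cfg$maf_thresh >= 0 && cfg$maf_thresh <= 0.5,
      "maf_thresh must be in [0, 0.5]")
  chk(cfg$info_thresh >= 0 && cfg$info_thresh <= 1,
      "info_thresh must be in [0, 1]")
  chk(is.numeric(cfg$z_thresh) && cfg$z_thresh > 0,
      "z_thresh must be positive")
  chk(cfg$r2_prune_thresh > 0 && cfg$r2_prune_thresh <= 1,
      "r2_prune_thresh must be in (0, 1]")
  chk(cfg$n_random >= 1, "n_random must be at least 1")
  chk(all(cfg$rand_prune_seed == floor(cfg$rand_prune_seed)),
      "rand_prune_seed must be integer(s)")
  cfg$exclude_regions <- lapply(cfg$exclude_regions, parse_region)
  class(cfg) <- "trimix_config"
  cfg
}

#' Filter settings carried by a configuration
#' @param cfg a `trimix_config`.
#' @return a [filter_config].
#' @export
config_filters <- function(cfg) {
  filter_config(cfg$maf_thresh, cfg$info_thresh, cfg$z_thresh,
                cfg$exclude_regions)
}
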