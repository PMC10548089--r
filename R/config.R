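#' Target-scan scoring parameters
#'
#' The expectation-penalty parameterization used for high-complementarity
#' (plant-style) miRNA target scanning. Defaults reproduce the published
#' configuration: maximum expectation 2, G:U penalty 0.5, other mismatches 1,
#' seed weighting 1.5 over miRNA positions 2-13, at most 2 seed mismatches,
#' gap open 2, gap extension 0.5, minimum complementary span (HSP) 19 nt.
#'
#' @param max_expectation Maximum expectation score of an emitted hit
#'   (inclusive boundary: a site scoring exactly this value is kept).
#' @param gu_penalty Penalty for a G:U wobble pair.
#' @param mismatch_penalty Penalty for a non-G:U mismatch.
#' @param seed_weight Multiplier applied to every penalty falling in the seed
#'   region.
#' @param max_seed_mismatches Hard cap on non-Watson-Crick columns (mismatch,
#'   G:U, or gap) at seed positions.
#' @param gap_open,gap_extend Penalty for the first / each subsequent column
#'   of a gap run.
#' @param hsp_size Minimum number of paired (non-gap) columns in a hit.
#' @param seed_start,seed_end Seed region bounds, 1-based miRNA positions
#'   counted 5' to 3', inclusive.
#' @param max_gaps Maximum total gap columns per duplex.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(max_expectation = 2, gu_penalty = 0.5,
                        mismatch_penalty = 1, seed_weight = 1.5,
                        max_seed_mismatches = 2, gap_open = 2,
                        gap_extend = 0.5, hsp_size = 19,
                        seed_start = 2, seed_end = 13, max_gaps = 2) {
  p <- list(
    max_expectation = max_expectation, gu_penalty = gu_penalty,
    mismatch_penalty = mismatch_penalty, seed_weight = seed_weight,
    max_seed_mismatches = max_seed_mismatches, gap_open = gap_open,
    gap_extend = gap_extend, hsp_size = hsp_size,
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    max_gaps = as.integer(max_gaps)
  )
  for (nm in c("gu_penalty", "mismatch_penalty", "gap_open", "gap_extend")) {
    check_positive_scalar(p[[nm]], nm, strict = FALSE)
  }
  check_positive_scalar(p$max_expectation, "max_expectation", strict = FALSE)
  check_positive_scalar(p$seed_weight, "seed_weight")
  if (p$seed_start < 1L || p$seed_end < p$seed_start) {
    abort("Need 1 <= seed_start <= seed_end.")
  }
  if (p$hsp_size < 1L) abort("`hsp_size` must be >= 1.")
  if (p$max_gaps < 0L) abort("`max_gaps` must be >= 0.")
  structure(p, class = "scan_params")
}

run_config_defaults <- function() {
  list(
    seed = 0L,
    permutations = 10000L,
    fdr_threshold = 0.05,
    fold_change_threshold = 2,
    cpm_threshold = 1,
    cpm_min_libraries = 2L,
    scan = scan_params()
  )
}

#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' 10,000 permutations, FDR < 0.05, fold change >= 2, CPM < 1 in at least 2
#' libraries for background removal, and the default [scan_params()].
#'
#' @param ... Named overrides of the defaults (`seed`, `permutations`,
#'   `fdr_threshold`, `fold_change_threshold`, `cpm_threshold`,
#'   `cpm_min_libraries`, `scan`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(!nzchar(names(over))))) {
    abort("All arguments to run_config() must be named.")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s. Valid keys are: %s.",
                  paste(unknown, collapse = ", "),
                  paste(names(cfg), collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (!is.numeric(cfg$seed) || cfg$seed < 0) {
    abort("`seed` must be a non-negative integer.")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!is.numeric(cfg$permutations) || cfg$permutations < 1) {
    abort("`permutations` must be >= 1.")
  }
  cfg$permutations <- as.integer(cfg$permutations)
  for (nm in c("fdr_threshold", "fold_change_threshold", "cpm_threshold")) {
    check_positive_scalar(cfg[[nm]], nm)
  }
  if (!is.numeric(cfg$cpm_min_libraries) || cfg$cpm_min_libraries < 1) {
    abort("`cpm_min_libraries` must be a positive integer.")
  }
  cfg$cpm_min_libraries <- as.integer(cfg$cpm_min_libraries)
  if (!inherits(cfg$scan, "scan_params")) {
    cfg$scan <- do.call(scan_params, as.list(cfg$scan))
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take the package defaults; unknown keys raise an error
#' listing the valid keys; scan parameters may be given as a nested `scan:`
#' mapping.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read config: no such file '%s'.", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (nm in setdiff(names(raw), c("seed", "permutations", "cpm_min_libraries", "scan"))) {
    if (!is.numeric(raw[[nm]])) {
      abort(sprintf("Config key `%s` must be numeric, got '%s'.",
                    nm, paste(raw[[nm]], collapse = ", ")))
    }
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  seed: %d  permutations: %d\n", x$seed, x$permutations))
  cat(sprintf("  DEG thresholds: FDR < %g, fold change >= %g\n",
              x$fdr_threshold, x$fold_change_threshold))
  cat(sprintf("  background: remove genes with CPM < %g in >= %d libraries\n",
              x$cpm_threshold, x$cpm_min_libraries))
  cat(sprintf("  scan: E <= %g, seed %d-%d (weight %g), GU %g, mismatch %g, gap %g/%g, HSP %d\n",
              x$scan$max_expectation, x$scan$seed_start, x$scan$seed_end,
              x$scan$seed_weight, x$scan$gu_penalty, x$scan$mismatch_penalty,
              x$scan$gap_open, x$scan$gap_extend, x$scan$hsp_size))
  invisible(x)
}
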