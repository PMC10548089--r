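# Internal helpers shared across modules.

# Coerce a gene collection (character vector, or data frame with a `gene`
# column) to a trimmed, deduplicated character vector.
as_gene_vector <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) {
      abort(sprintf("`%s` is a data frame but has no `gene` column.", arg))
    }
    x <- x$gene
  }
  x <- trimws(as.character(x))
  x <- x[nzchar(x) & !is.na(x)]
  unique(x)
}

# Evaluate `expr` under `seed` when non-NULL, otherwise in the current RNG
# stream. Keeps every simulating function reproducible on demand without
# touching the caller's RNG state when a seed is supplied.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Deterministically derive `k` child seeds from one parent seed, so pipeline
# stages get independent streams without cross-stage coupling.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

check_positive_scalar <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort(sprintf("`%s` must be a single %s number.", name,
                  if (strict) "strictly positive" else "non-negative"))
  }
  invisible(x)
}
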