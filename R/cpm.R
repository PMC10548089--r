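# Background construction from a raw count matrix.

# Validate a counts tibble (gene column + numeric library columns) and
# return its pieces.
check_counts <- function(counts) {
  if (!is.data.frame(counts) || !"gene" %in% names(counts)) {
    abort("`counts` must be a data frame with a `gene` column plus one numeric column per library.")
  }
  libs <- setdiff(names(counts), "gene")
  if (length(libs) == 0L) abort("`counts` has no library columns.")
  mat <- as.matrix(counts[libs])
  if (!is.numeric(mat)) abort("Library columns must be numeric.")
  if (anyNA(mat) || any(mat < 0)) abort("Counts must be non-negative and non-missing.")
  if (anyDuplicated(counts$gene)) abort("Duplicate gene ids in `counts`.")
  rownames(mat) <- counts$gene
  list(genes = counts$gene, mat = mat, libs = libs)
}

#' Counts per million
#'
#' Library-size normalization: `cpm[g, l] = counts[g, l] * 1e6 /
#' library_total[l]`. No compositional normalization factors (TMM,
#' median-of-ratios) are applied; this is the plain CPM used for background
#' filtering, not for differential expression.
#'
#' @param counts A tibble with a `gene` column and one numeric column of raw
#'   counts per library.
#' @return A tibble of the same shape holding CPM values.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), libA = c(1, 9), libB = c(5, 5))
#' cpm(counts)
#' @export
cpm <- function(counts) {
  cc <- check_counts(counts)
  totals <- colSums(cc$mat)
  if (any(totals == 0)) {
    abort(sprintf("Library with zero total counts: %s.",
                  paste(cc$libs[totals == 0], collapse = ", ")))
  }
  out <- sweep(cc$mat, 2L, totals, "/") * 1e6
  dplyr::bind_cols(tibble(gene = cc$genes), as_tibble(out))
}

#' Filter genes into an expression background
#'
#' A gene is removed from the background when it has CPM below `threshold`
#' in at least `min_libraries` libraries (pooled across conditions); all
#' remaining genes form the background universe used as the sampling frame
#' for permutation enrichment tests.
#'
#' @param counts A tibble with a `gene` column and one raw-count column per
#'   library.
#' @param threshold CPM threshold (default 1).
#' @param min_libraries Number of below-threshold libraries that triggers
#'   removal (default 2).
#' @return A tibble with columns `gene`, `n_low_libraries` (libraries with
#'   CPM below the threshold) and `retained`. Genes with `retained == TRUE`
#'   form the background.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"),
#'                          a = c(100, 0), b = c(100, 0), c = c(100, 0))
#' cpm_filter(counts)
#' @export
cpm_filter <- function(counts, threshold = 1, min_libraries = 2) {
  check_positive_scalar(threshold, "threshold", strict = FALSE)
  cc <- check_counts(counts)
  if (min_libraries > length(cc$libs)) {
    abort(sprintf("`min_libraries` (%d) exceeds the number of libraries (%d).",
                  as.integer(min_libraries), length(cc$libs)))
  }
  cpm_tab <- cpm(counts)
  cpm_mat <- as.matrix(cpm_tab[cc$libs])
  n_low <- rowSums(cpm_mat < threshold)
  tibble(
    gene = cc$genes,
    n_low_libraries = as.integer(n_low),
    retained = n_low < min_libraries
  )
}

#' Extract the background gene set from a filter report
#'
#' @param filter_report Output of [cpm_filter()].
#' @return Character vector of retained gene ids.
#' @export
background_genes <- function(filter_report) {
  filter_report$gene[filter_report$retained]
}
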