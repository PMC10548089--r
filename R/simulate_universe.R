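#' Simulate a count matrix with a planted expression background
#'
#' Generates a genes-by-libraries integer count matrix emulating a bulk
#' RNA-seq experiment (by default 6 libraries: 3 control, 3 treatment).
#' Expressed genes draw negative-binomial counts with the given mean and
#' dispersion, identical across libraries (the pipeline never re-estimates
#' differential expression, so no per-condition signal is simulated).
#' A `zero_gene_fraction` share of genes is constructed to fail the CPM
#' background rule (CPM below `cpm_threshold` in at least
#' `cpm_min_libraries` libraries): these genes are zero in all but at most
#' one library. Expressed genes are nudged upward where sampling noise
#' would otherwise drop them below the rule, so the truth table is exact by
#' construction and is verified against [cpm_filter()] before returning.
#'
#' @param n_genes Number of background genes.
#' @param n_libraries Number of libraries (default 6).
#' @param nb_mean Negative-binomial mean of expressed genes.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param zero_gene_fraction Fraction of genes planted below the CPM rule,
#'   in `[0, 1)`.
#' @param cpm_threshold,cpm_min_libraries The CPM rule the truth table is
#'   constructed against (defaults 1 and 2).
#' @param seed Optional integer seed.
#' @return A list with `counts` (tibble: `gene` plus one column per
#'   library, named `<condition>_<i>`) and `truth` (tibble: `gene`,
#'   `expressed` -- `TRUE` iff the gene must survive the CPM filter).
#' @examples
#' u <- simulate_universe(200, zero_gene_fraction = 0.1, seed = 1)
#' sum(cpm_filter(u$counts)$retained) == sum(u$truth$expressed)
#' @export
simulate_universe <- function(n_genes, n_libraries = 6, nb_mean = 100,
                              nb_dispersion = 0.3, zero_gene_fraction = 0.1,
                              cpm_threshold = 1, cpm_min_libraries = 2,
                              seed = NULL) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (n_libraries < cpm_min_libraries + 1) {
    abort("Need more libraries than `cpm_min_libraries` to plant both classes.")
  }
  check_positive_scalar(nb_mean, "nb_mean")
  check_positive_scalar(nb_dispersion, "nb_dispersion")
  if (zero_gene_fraction < 0 || zero_gene_fraction >= 1) {
    abort("`zero_gene_fraction` must be in [0, 1).")
  }
  if (as.double(n_genes) * n_libraries > 1e8) {
    abort("Refusing to simulate more than 1e8 matrix cells.")
  }

  with_seed_opt(seed, {
    n_low <- round(zero_gene_fraction * n_genes)
    n_high <- n_genes - n_low
    if (n_high < 1L) abort("zero_gene_fraction leaves no expressed genes.")
    is_low <- rep(FALSE, n_genes)
    if (n_low > 0L) is_low[sample.int(n_genes, n_low)] <- TRUE

    mat <- matrix(0L, nrow = n_genes, ncol = n_libraries)
    mat[!is_low, ] <- rnbinom(n_high * n_libraries, mu = nb_mean,
                              size = 1 / nb_dispersion)
    # Low genes: zero everywhere except (possibly) one library with a tiny
    # count, so they always have CPM < threshold in >= n_libraries - 1
    # libraries.
    if (n_low > 0L) {
      lib_pick <- sample.int(n_libraries, n_low, replace = TRUE)
      mat[cbind(which(is_low), lib_pick)] <- rpois(n_low, 0.5)
    }

    # Nudge expressed genes that sampling left below the rule.
    for (iter in 1:100) {
      totals <- colSums(mat)
      if (any(totals == 0)) {  # degenerate tiny simulations
        mat[which(!is_low)[1], totals == 0] <- max(1L, round(nb_mean))
        next
      }
      lib_floor <- ceiling(totals * cpm_threshold / 1e6) + 1L
      low_cell <- sweep(mat, 2L, totals / 1e6 * cpm_threshold, "<")
      bad <- which(!is_low & rowSums(low_cell) >= cpm_min_libraries)
      if (length(bad) == 0L) break
      for (g in bad) {
        libs <- which(low_cell[g, ])
        mat[g, libs] <- pmax(mat[g, libs], lib_floor[libs])
      }
    }

    conds <- rep(c("control", "treatment"), length.out = 2)
    half <- ceiling(n_libraries / 2)
    lib_names <- paste0(rep(conds, c(half, n_libraries - half)), "_",
                        c(seq_len(half), seq_len(n_libraries - half)))
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    counts <- dplyr::bind_cols(
      tibble(gene = genes),
      as_tibble(matrix(as.integer(mat), nrow = n_genes,
                       dimnames = list(NULL, lib_names)))
    )
    truth <- tibble(gene = genes, expressed = !is_low)

    check <- cpm_filter(counts, threshold = cpm_threshold,
                        min_libraries = cpm_min_libraries)
    if (!identical(check$retained, truth$expressed)) {
      abort("Internal error: planted background truth failed verification.")
    }
    list(counts = counts, truth = truth)
  })
}
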