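#' Plant a gene-set enrichment configuration with exact overlap
#'
#' Draws a target set of size `k` and a query (DEG-like) list of size `n`
#' from a background so that their intersection is *exactly* `x_target`
#' genes; membership is otherwise uniform at random. This reproduces the
#' combinatorial structure of an enrichment analysis with known truth.
#'
#' @param background Background gene collection.
#' @param k Target-set size.
#' @param n Query-list size.
#' @param x_target Planted overlap; must satisfy
#'   `max(0, n + k - B) <= x_target <= min(n, k)`.
#' @param seed Optional integer seed.
#' @return A list with `target` and `degs` (character vectors) and `truth`
#'   (one-row tibble: `b`, `k`, `n`, `x_target`).
#' @examples
#' bg <- paste0("g", 1:20)
#' pe <- plant_enrichment(bg, k = 5, n = 4, x_target = 1, seed = 1)
#' length(intersect(pe$target, pe$degs))  # 1
#' @export
plant_enrichment <- function(background, k, n, x_target, seed = NULL) {
  background <- as_gene_vector(background, "background")
  b <- length(background)
  if (k > b || n > b) abort("`k` and `n` cannot exceed the background size.")
  lo <- max(0, n + k - b)
  hi <- min(n, k)
  if (x_target < lo || x_target > hi) {
    abort(sprintf("Infeasible x_target = %d: feasible range is [%d, %d] for B=%d, K=%d, n=%d.",
                  as.integer(x_target), as.integer(lo), as.integer(hi),
                  b, as.integer(k), as.integer(n)))
  }
  with_seed_opt(seed, {
    target <- sample(background, k)
    shared <- if (x_target > 0) sample(target, x_target) else character(0)
    rest_pool <- setdiff(background, target)
    rest <- if (n - x_target > 0) sample(rest_pool, n - x_target) else character(0)
    degs <- sample(c(shared, rest))  # shuffle so order carries no signal
    list(target = target, degs = degs,
         truth = tibble(b = b, k = as.integer(k), n = as.integer(n),
                        x_target = as.integer(x_target)))
  })
}

#' Simulate a single-cell cluster marker catalogue
#'
#' Draws marker genes from the background and assigns each to exactly one
#' cluster (the generator never repeats a gene across clusters, so
#' per-cluster DEG counts always sum to the distinct-gene total; real
#' marker tables may repeat genes, which the consumer handles).
#'
#' @param background Background gene collection.
#' @param cluster_sizes Named integer vector of markers per cluster (names
#'   are the cluster labels; unnamed vectors get labels `"1"`, `"2"`, ...).
#' @param seed Optional integer seed.
#' @return A list with `markers` (tibble: `gene`, `cluster`) and `truth`
#'   (tibble: `cluster`, `size`).
#' @examples
#' bg <- paste0("g", 1:100)
#' sim <- simulate_marker_table(bg, c(a = 5, b = 3), seed = 1)
#' nrow(sim$markers)  # 8
#' @export
simulate_marker_table <- function(background, cluster_sizes, seed = NULL) {
  background <- as_gene_vector(background, "background")
  if (any(cluster_sizes < 0)) abort("Cluster sizes must be non-negative.")
  if (is.null(names(cluster_sizes))) {
    names(cluster_sizes) <- as.character(seq_along(cluster_sizes))
  }
  total <- sum(cluster_sizes)
  if (total > length(background)) {
    abort(sprintf("Requested %d markers but the background has only %d genes.",
                  total, length(background)))
  }
  with_seed_opt(seed, {
    genes <- if (total > 0) sample(background, total) else character(0)
    markers <- tibble(
      gene = genes,
      cluster = rep(names(cluster_sizes), times = cluster_sizes)
    )
    list(markers = markers,
         truth = tibble(cluster = names(cluster_sizes),
                        size = as.integer(cluster_sizes)))
  })
}

#' Simulate per-method DE result tables with planted DEG truth
#'
#' Builds one DE result table per method over the background such that
#' exactly the genes in `deg_genes` satisfy the DEG definition (adjusted
#' p below `fdr` and `|log2FC| >= log2(fc)` with concordant signs) in every
#' method. Non-DEGs fail for one randomly chosen reason: a non-significant
#' adjusted p in every table, a sub-threshold fold change, or significance
#' in only one method (the intersection rule must reject these).
#'
#' @param background Background gene collection.
#' @param deg_genes Genes to plant as DEGs (subset of the background).
#' @param prop_down Fraction of planted DEGs that are downregulated
#'   (default 0.85, matching a knockdown dominated by downregulation).
#' @param methods Method labels (default `c("deseq2", "edger")`).
#' @param fdr,fc Thresholds the truth is constructed against.
#' @param seed Optional integer seed.
#' @return A list with `tables` (named list of tibbles: `gene`, `log2fc`,
#'   `pvalue`, `padj`) and `truth` (tibble: `gene`, `is_deg`, `direction`).
#' @export
simulate_de_tables <- function(background, deg_genes, prop_down = 0.85,
                               methods = c("deseq2", "edger"),
                               fdr = 0.05, fc = 2, seed = NULL) {
  background <- as_gene_vector(background, "background")
  deg_genes <- as_gene_vector(deg_genes, "deg_genes")
  if (!all(deg_genes %in% background)) {
    abort("All `deg_genes` must belong to the background.")
  }
  if (length(methods) < 1L) abort("Need at least one method label.")
  b <- length(background)
  is_deg <- background %in% deg_genes
  lfc_min <- log2(fc)

  with_seed_opt(seed, {
    direction <- rep(NA_character_, b)
    direction[is_deg] <- ifelse(stats::runif(sum(is_deg)) < prop_down,
                                "down", "up")
    sgn <- ifelse(direction == "down", -1, 1)
    # Failure mode for non-DEGs: 1 = high padj, 2 = small fc, 3 = one
    # method only (when several methods exist).
    n_modes <- if (length(methods) > 1L) 3L else 2L
    mode <- sample.int(n_modes, b, replace = TRUE)
    lucky_method <- sample(seq_along(methods), b, replace = TRUE)

    tables <- lapply(seq_along(methods), function(mi) {
      lfc <- numeric(b)
      padj <- numeric(b)
      # planted DEGs: comfortably inside both thresholds, concordant sign
      lfc[is_deg] <- sgn[is_deg] * stats::runif(sum(is_deg), lfc_min + 0.1, 4)
      padj[is_deg] <- stats::runif(sum(is_deg), 1e-8, fdr * 0.8)
      nd <- !is_deg
      m1 <- nd & mode == 1L
      lfc[m1] <- stats::runif(sum(m1), -3, 3)
      padj[m1] <- stats::runif(sum(m1), fdr * 1.2, 1)
      m2 <- nd & mode == 2L
      lfc[m2] <- stats::runif(sum(m2), -0.9 * lfc_min, 0.9 * lfc_min)
      padj[m2] <- stats::runif(sum(m2), 1e-8, 1)
      m3 <- nd & mode == 3L
      if (any(m3)) {
        sig_here <- lucky_method[m3] == mi
        lfc[m3] <- stats::runif(sum(m3), lfc_min + 0.1, 3) *
          sample(c(-1, 1), sum(m3), replace = TRUE)
        padj[m3] <- ifelse(sig_here,
                           stats::runif(sum(m3), 1e-8, fdr * 0.8),
                           stats::runif(sum(m3), fdr * 1.2, 1))
      }
      tibble(gene = background, log2fc = lfc,
             pvalue = padj * stats::runif(b, 0.1, 1), padj = padj)
    })
    names(tables) <- methods
    list(tables = tables,
         truth = tibble(gene = background, is_deg = is_deg,
                        direction = direction))
  })
}
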