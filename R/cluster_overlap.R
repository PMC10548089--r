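# Distribution of DEGs across single-cell cluster marker sets.

# Normalize a marker table: columns gene, cluster; duplicate rows collapsed.
check_marker_table <- function(markers) {
  if (!is.data.frame(markers) || !all(c("gene", "cluster") %in% names(markers))) {
    abort("`markers` must be a data frame with columns `gene` and `cluster`.")
  }
  out <- tibble(gene = trimws(as.character(markers$gene)),
                cluster = trimws(as.character(markers$cluster)))
  if (any(!nzchar(out$cluster))) abort("Cluster ids must be non-empty.")
  if (any(!nzchar(out$gene))) abort("Marker gene ids must be non-empty.")
  dplyr::distinct(out)
}

#' Distribute DEGs across single-cell cluster markers
#'
#' Counts, for each cluster in a marker catalogue, how many of the query
#' DEGs are markers of that cluster, and computes the share of
#' marker-overlapping DEGs that fall in a designated focal cluster set
#' (e.g. the cnidocyte clusters). A DEG that is a marker of several clusters
#' contributes to each cluster's count but only once to the distinct-gene
#' totals, so the focal fraction is always a well-defined proportion of
#' distinct genes. Cluster ids are opaque labels; which clusters are
#' "focal" is configuration, not code.
#'
#' @param markers Marker table: data frame with columns `gene` and
#'   `cluster` (duplicate rows are collapsed).
#' @param degs DEG collection (character vector or data frame with a `gene`
#'   column).
#' @param focal_clusters Character vector of cluster labels making up the
#'   focal set; must all be present in the marker table.
#' @return An object of class `cluster_distribution`: a list with
#'   `per_cluster` (tibble of `cluster`, `n_markers`, `n_degs`),
#'   `total_overlapping` (distinct DEGs with at least one marker row),
#'   `n_focal` (distinct DEGs whose marker clusters intersect the focal
#'   set), `focal_fraction` (NA with `focal_defined = FALSE` when no DEG
#'   overlaps the catalogue), and `focal_clusters`.
#' @examples
#' markers <- tibble::tibble(gene = c("a", "b", "c"), cluster = c("1", "3", "3"))
#' assign_degs_to_clusters(markers, c("a", "b", "c"), focal_clusters = "1")
#' @export
assign_degs_to_clusters <- function(markers, degs, focal_clusters) {
  markers <- check_marker_table(markers)
  degs <- as_gene_vector(degs, "degs")
  focal_clusters <- as.character(focal_clusters)
  missing_cl <- setdiff(focal_clusters, unique(markers$cluster))
  if (length(missing_cl) > 0L) {
    abort(sprintf("Focal cluster(s) not in the marker table: %s.",
                  paste(missing_cl, collapse = ", ")))
  }

  hits <- dplyr::filter(markers, .data$gene %in% degs)
  per_cluster <- markers |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     n_degs = sum(.data$gene %in% degs),
                     .groups = "drop") |>
    dplyr::arrange(.data$cluster)

  total_overlapping <- dplyr::n_distinct(hits$gene)
  n_focal <- dplyr::n_distinct(hits$gene[hits$cluster %in% focal_clusters])
  focal_defined <- total_overlapping > 0L
  structure(list(
    per_cluster = per_cluster,
    total_overlapping = total_overlapping,
    n_focal = n_focal,
    focal_fraction = if (focal_defined) n_focal / total_overlapping else NA_real_,
    focal_defined = focal_defined,
    focal_clusters = focal_clusters,
    n_degs = length(degs)
  ), class = "cluster_distribution")
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat("DEG distribution across cluster markers\n")
  cat(sprintf("  %d of %d DEGs overlap the marker catalogue\n",
              x$total_overlapping, x$n_degs))
  if (x$focal_defined) {
    cat(sprintf("  focal clusters {%s}: %d/%d = %.1f%%\n",
                paste(x$focal_clusters, collapse = ","),
                x$n_focal, x$total_overlapping, 100 * x$focal_fraction))
  } else {
    cat("  focal fraction undefined: no DEG overlaps the marker catalogue\n")
  }
  print(x$per_cluster)
  invisible(x)
}

#' @rdname assign_degs_to_clusters
#' @param x A `cluster_distribution`.
#' @param ... Unused.
#' @export
tidy.cluster_distribution <- function(x, ...) x$per_cluster

#' @rdname assign_degs_to_clusters
#' @export
glance.cluster_distribution <- function(x, ...) {
  tibble(
    n_degs = x$n_degs,
    total_overlapping = x$total_overlapping,
    n_focal = x$n_focal,
    focal_fraction = x$focal_fraction,
    focal_defined = x$focal_defined,
    focal_clusters = paste(x$focal_clusters, collapse = ",")
  )
}

#' @rdname assign_degs_to_clusters
#' @param object A `cluster_distribution`.
#' @export
autoplot.cluster_distribution <- function(object, ...) {
  dat <- dplyr::mutate(object$per_cluster,
                       focal = .data$cluster %in% object$focal_clusters)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cluster, y = .data$n_degs,
                                    fill = .data$focal)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                               name = "focal") +
    ggplot2::labs(x = "cluster", y = "overlapping DEGs") +
    ggplot2::theme_minimal()
}

#' Permutation enrichment of DEGs in focal cluster markers
#'
#' Tests whether the DEG list overlaps the union of the focal clusters'
#' marker genes more than random gene lists of the same size drawn from the
#' background. Delegates to [permutation_overlap_test()] with the focal
#' marker union as the target.
#'
#' @inheritParams assign_degs_to_clusters
#' @inheritParams permutation_overlap_test
#' @return A `perm_overlap_test` object.
#' @export
cluster_enrichment_test <- function(markers, degs, focal_clusters, background,
                                    r = 10000, seed = NULL,
                                    alternative = "greater") {
  markers <- check_marker_table(markers)
  focal_clusters <- as.character(focal_clusters)
  missing_cl <- setdiff(focal_clusters, unique(markers$cluster))
  if (length(missing_cl) > 0L) {
    abort(sprintf("Focal cluster(s) not in the marker table: %s.",
                  paste(missing_cl, collapse = ", ")))
  }
  target <- unique(markers$gene[markers$cluster %in% focal_clusters])
  permutation_overlap_test(degs, target, background, r = r, seed = seed,
                           alternative = alternative)
}
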