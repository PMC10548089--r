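#' Read a gene set from a text file
#'
#' Reads a gene collection either as one identifier per line or as a
#' two-column tab-separated file of `(set name, gene id)` pairs. Identifiers
#' are whitespace-trimmed and deduplicated; duplicate lines are reported with
#' a warning, never an error. Identifiers are treated as opaque,
#' case-sensitive strings: no attempt is made to reconcile different gene-id
#' catalogues (supply a mapping table upstream if two namespaces must be
#' joined).
#'
#' @param path Path to the file.
#' @param name Set label used when the file has a single column. Defaults to
#'   the file name without extension.
#' @return A tibble with columns `set` and `gene`, one row per distinct gene.
#' @examples
#' f <- tempfile()
#' writeLines(c("g1", "g2", "g2"), f)
#' read_gene_set(f)
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read gene set: no such file '%s'.", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("empty gene set: '%s' contains no identifiers.", path))
  }
  has_tab <- grepl("\t", lines, fixed = TRUE)
  if (all(has_tab)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble(
      set  = trimws(vapply(parts, `[[`, character(1), 1L)),
      gene = trimws(vapply(parts, function(p) p[[2L]], character(1)))
    )
  } else if (any(has_tab)) {
    abort(sprintf("Mixed one- and two-column lines in gene set '%s'.", path))
  } else {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    out <- tibble(set = name, gene = lines)
  }
  out <- dplyr::filter(out, nzchar(.data$gene))
  if (nrow(out) == 0L) {
    abort(sprintf("empty gene set: '%s' contains no identifiers.", path))
  }
  n_before <- nrow(out)
  out <- dplyr::distinct(out, .data$set, .data$gene)
  if (nrow(out) < n_before) {
    warn(sprintf("Dropped %d duplicate gene-set line(s) in '%s'.",
                 n_before - nrow(out), path))
  }
  out
}

#' Write a gene set to a text file
#'
#' Inverse of [read_gene_set()]: a single set is written one identifier per
#' line; multiple sets are written as a two-column tab-separated file.
#'
#' @param genes Character vector of gene ids, or a tibble with columns
#'   `set` and `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  if (is.data.frame(genes) && all(c("set", "gene") %in% names(genes))) {
    sets <- unique(genes$set)
    if (length(sets) > 1L) {
      writeLines(paste(genes$set, genes$gene, sep = "\t"), path)
      return(invisible(path))
    }
    genes <- genes$gene
  }
  writeLines(as_gene_vector(genes, "genes"), path)
  invisible(path)
}
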