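# Differential-expression calling from per-method result tables.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (a validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`). Used when building synthetic
#' DE tables; real DE tables normally arrive with their method's own
#' adjusted p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

# Normalize one DE result table: requires gene + padj + either log2fc or a
# linear fc column (auto-detected, recorded in attr "fc_scale").
normalize_de_table <- function(tab, method) {
  if (!is.data.frame(tab)) abort("Each DE table must be a data frame.")
  nms <- names(tab)
  if (!"gene" %in% nms) abort("DE tables need a `gene` column.")
  if ("log2fc" %in% nms) {
    lfc <- tab$log2fc
    scale <- "log2"
  } else if ("fc" %in% nms) {
    if (any(tab$fc <= 0, na.rm = TRUE)) {
      abort("Linear `fc` values must be strictly positive.")
    }
    lfc <- log2(tab$fc)
    scale <- "linear"
  } else {
    abort("DE tables need a `log2fc` (log2 scale) or `fc` (linear) column.")
  }
  if (!"padj" %in% nms) abort("DE tables need a `padj` column.")
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    abort("`padj` values must lie in [0, 1].")
  }
  padj <- tab$padj
  if (anyNA(padj)) {
    warn(sprintf("%d NA adjusted p-value(s) in table '%s' treated as 1.",
                 sum(is.na(padj)), method))
    padj[is.na(padj)] <- 1
  }
  out <- tibble(gene = as.character(tab$gene), log2fc = lfc, padj = padj,
                method = method)
  attr(out, "fc_scale") <- scale
  out
}

#' Call differentially expressed genes from several DE method tables
#'
#' Implements the intersection rule: a gene is a DEG iff in *every* supplied
#' table its adjusted p-value is strictly below `fdr` and its absolute fold
#' change is at least `fc` (i.e. `|log2FC| >= log2(fc)`, two-sided), with the
#' fold-change sign agreeing across tables. Genes passing both thresholds in
#' every table but with discordant signs are excluded and reported via the
#' `discordant` attribute. Genes missing from any table are never DEGs; NA
#' adjusted p-values are treated as 1 with a warning.
#'
#' @param tables A named list of DE result tables (one per method), each a
#'   data frame with columns `gene`, `padj`, and either `log2fc` or linear
#'   `fc`; or a single long data frame with an additional `method` column.
#' @param fdr FDR threshold, strict comparison (default 0.05).
#' @param fc Linear fold-change threshold, inclusive comparison (default 2).
#' @return A tibble of class `deg_calls` with columns `gene`, `direction`
#'   (`"up"`/`"down"`), `mean_log2fc`, and `passed_methods`. Attributes:
#'   `n_up`, `n_down`, `discordant` (excluded gene ids).
#' @examples
#' t1 <- tibble::tibble(gene = c("a", "b"), log2fc = c(1.2, 0.4),
#'                      padj = c(0.01, 0.01))
#' t2 <- tibble::tibble(gene = c("a", "b"), log2fc = c(1.5, 1.4),
#'                      padj = c(0.04, 0.2))
#' call_degs(list(deseq2 = t1, edger = t2))
#' @export
call_degs <- function(tables, fdr = 0.05, fc = 2) {
  check_positive_scalar(fdr, "fdr")
  check_positive_scalar(fc, "fc")
  if (is.data.frame(tables)) {
    if (!"method" %in% names(tables)) {
      abort("A single data frame input needs a `method` column.")
    }
    tables <- split(tables[setdiff(names(tables), "method")], tables$method)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("method", seq_along(tables))
  }
  if (length(tables) < 1L) abort("Need at least one DE table.")
  long <- dplyr::bind_rows(purrr::imap(tables, normalize_de_table))
  if (anyDuplicated(long[c("gene", "method")])) {
    abort("Each DE table must have one row per gene.")
  }
  n_methods <- length(tables)
  lfc_min <- log2(fc)

  per_gene <- long |>
    dplyr::mutate(pass = .data$padj < fdr & abs(.data$log2fc) >= lfc_min) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_tables = dplyr::n(),
      n_pass = sum(.data$pass),
      signs_agree = length(unique(sign(.data$log2fc[.data$pass]))) <= 1L,
      mean_log2fc = mean(.data$log2fc),
      passed_methods = paste(sort(.data$method[.data$pass]), collapse = ","),
      .groups = "drop"
    )

  candidate <- per_gene$n_tables == n_methods & per_gene$n_pass == n_methods
  discordant <- per_gene$gene[candidate & !per_gene$signs_agree]
  if (length(discordant) > 0L) {
    inform(sprintf(
      "Excluded %d gene(s) passing both thresholds with discordant fold-change signs: %s",
      length(discordant), paste(head(discordant, 5L), collapse = ", ")))
  }
  degs <- per_gene |>
    dplyr::filter(candidate & .data$signs_agree) |>
    dplyr::mutate(direction = ifelse(.data$mean_log2fc > 0, "up", "down")) |>
    dplyr::select("gene", "direction", "mean_log2fc", "passed_methods") |>
    dplyr::arrange(.data$gene)

  structure(degs,
            class = c("deg_calls", class(degs)),
            n_up = sum(degs$direction == "up"),
            n_down = sum(degs$direction == "down"),
            discordant = discordant,
            fdr = fdr, fc = fc)
}

#' @describeIn call_degs One-row summary: number of DEGs, up, down,
#'   discordant exclusions, thresholds.
#' @param x A `deg_calls` tibble.
#' @param ... Unused.
#' @export
glance.deg_calls <- function(x, ...) {
  tibble(
    n_deg = nrow(x),
    n_up = attr(x, "n_up"),
    n_down = attr(x, "n_down"),
    n_discordant = length(attr(x, "discordant")),
    fdr = attr(x, "fdr"),
    fc = attr(x, "fc")
  )
}
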