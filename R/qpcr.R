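# Stem-loop qPCR relative quantification and two-group comparisons.

#' Relative quantification by the 2^-ddCt method
#'
#' Livak relative quantification: technical replicates are averaged first;
#' per biological replicate, `dCt = Ct(target) - Ct(reference)`; `ddCt` is
#' anchored to the *mean* control `dCt`; the relative quantity is
#' `2^-ddCt`, so the control group averages 1 by construction.
#' Amplification efficiency is fixed at 2 (no standard-curve correction).
#'
#' @param ct A Ct table: data frame with columns `condition`, `gene`,
#'   `bio_rep`, `ct`, and optionally `tech_rep` (technical replicates are
#'   averaged within `(condition, gene, bio_rep)`) and `sample`.
#' @param reference_gene Internal-control gene (e.g. `"5sRNA"`); must be
#'   present in every (condition, biological replicate).
#' @param control_condition Label of the control condition (default
#'   `"control"`).
#' @return An object of class `rq_result`: a list with `per_replicate`
#'   (tibble: `gene`, `condition`, `bio_rep`, `delta_ct`, `delta_delta_ct`,
#'   `rq`) and `summary` (per gene and condition: mean and SD of `rq` and
#'   `delta_delta_ct`, n). See [tidy()] / [glance()] methods.
#' @examples
#' ct <- simulate_qpcr(effect = 0.25, noise_sd = 0, replicates = 3, seed = 1)
#' res <- ddct(ct$ct_table, reference_gene = "reference")
#' glance(res)
#' @export
ddct <- function(ct, reference_gene, control_condition = "control") {
  need <- c("condition", "gene", "bio_rep", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    abort(sprintf("`ct` must be a data frame with columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(ct$ct <= 0, na.rm = TRUE) || anyNA(ct$ct)) {
    abort("Ct values must be positive and non-missing.")
  }
  if (!reference_gene %in% ct$gene) {
    abort(sprintf("Reference gene '%s' is absent from the Ct table.",
                  reference_gene))
  }
  if (!control_condition %in% ct$condition) {
    abort(sprintf("Control condition '%s' is absent from the Ct table.",
                  control_condition))
  }

  # Average technical replicates first.
  mean_ct <- ct |>
    dplyr::group_by(.data$condition, .data$gene, .data$bio_rep) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  n_reps <- mean_ct |>
    dplyr::distinct(.data$condition, .data$bio_rep) |>
    dplyr::count(.data$condition)
  if (any(n_reps$n < 2L)) {
    abort(sprintf(
      "Need >= 2 biological replicates per condition; condition '%s' has %d.",
      n_reps$condition[n_reps$n < 2L][1], min(n_reps$n)))
  }

  ref <- mean_ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("condition", "bio_rep", ref_ct = "ct")
  per_rep <- mean_ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(ref, by = c("condition", "bio_rep"))
  if (anyNA(per_rep$ref_ct)) {
    miss <- per_rep[is.na(per_rep$ref_ct), ]
    abort(sprintf(
      "Missing reference gene '%s' measurement for condition '%s', replicate %s.",
      reference_gene, miss$condition[1], miss$bio_rep[1]))
  }

  per_rep <- per_rep |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(delta_delta_ct =
                    .data$delta_ct -
                    mean(.data$delta_ct[.data$condition == control_condition])) |>
    dplyr::ungroup() |>
    dplyr::mutate(rq = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("gene", "condition", "bio_rep",
                  "delta_ct", "delta_delta_ct", "rq")

  summary <- per_rep |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rq = mean(.data$rq), sd_rq = sd(.data$rq),
      mean_ddct = mean(.data$delta_delta_ct), sd_ddct = sd(.data$delta_delta_ct),
      .groups = "drop")

  structure(list(per_replicate = per_rep, summary = summary,
                 reference_gene = reference_gene,
                 control_condition = control_condition),
            class = "rq_result")
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("2^-ddCt relative quantification (reference %s, control '%s')\n",
              x$reference_gene, x$control_condition))
  print(x$summary)
  invisible(x)
}

#' @rdname ddct
#' @param x An `rq_result`.
#' @param ... Unused.
#' @export
tidy.rq_result <- function(x, ...) x$per_replicate

#' @rdname ddct
#' @export
glance.rq_result <- function(x, ...) x$summary

#' Two-group t test
#'
#' Classical two-sided two-sample comparison, Student (equal variance,
#' the default) or Welch. Degenerate inputs with zero variance in both
#' groups are handled explicitly: equal means give `p = 1`; different means
#' give `p = 0` with `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `estimate`
#'   (mean difference a - b), `variant`, `degenerate`.
#' @examples
#' two_group_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
two_group_ttest <- function(values_a, values_b,
                            variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  if (anyNA(values_a) || anyNA(values_b) ||
      any(!is.finite(c(values_a, values_b)))) {
    abort("Group values must be finite and non-missing.")
  }
  diff_means <- mean(values_a) - mean(values_b)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (diff_means == 0) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    estimate = 0, variant = variant, degenerate = TRUE))
    }
    return(tibble(statistic = sign(diff_means) * Inf, df = NA_real_,
                  p_value = 0, estimate = diff_means,
                  variant = variant, degenerate = TRUE))
  }
  res <- t.test(values_a, values_b, var.equal = (variant == "student"))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, estimate = diff_means,
         variant = variant, degenerate = FALSE)
}
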