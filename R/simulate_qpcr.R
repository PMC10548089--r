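#' Simulate a stem-loop qPCR Ct table with a planted fold change
#'
#' Generates cycle-threshold measurements for one target gene and one
#' reference gene in a control and a treatment condition, with Gaussian
#' measurement noise added per technical replicate. The treatment target
#' Ct is shifted by `-log2(effect)` so that, at zero noise, [ddct()]
#' recovers exactly `effect` as the relative quantity.
#'
#' @param effect Planted linear fold change (treatment vs control) of the
#'   target gene; must be positive.
#' @param noise_sd Standard deviation of the per-measurement Ct noise, in
#'   cycles.
#' @param replicates Biological replicates per condition (>= 2).
#' @param tech_replicates Technical replicates per measurement (default 2).
#' @param target_gene,reference_gene Gene labels.
#' @param base_ct_target,base_ct_reference Baseline Ct values, cycles.
#' @param seed Optional integer seed.
#' @return A list with `ct_table` (tibble: `sample`, `condition`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`) and `truth` (one-row tibble: `gene`,
#'   `effect`).
#' @examples
#' sim <- simulate_qpcr(effect = 0.25, noise_sd = 0, replicates = 3)
#' glance(ddct(sim$ct_table, reference_gene = "reference"))
#' @export
simulate_qpcr <- function(effect, noise_sd = 0, replicates = 3,
                          tech_replicates = 2,
                          target_gene = "target",
                          reference_gene = "reference",
                          base_ct_target = 20, base_ct_reference = 15,
                          seed = NULL) {
  check_positive_scalar(effect, "effect")
  if (replicates < 2) abort("Need >= 2 biological replicates to estimate variance.")
  if (tech_replicates < 1) abort("Need >= 1 technical replicate.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  with_seed_opt(seed, {
    grid <- tidyr::expand_grid(
      condition = c("control", "treatment"),
      gene = c(target_gene, reference_gene),
      bio_rep = seq_len(replicates),
      tech_rep = seq_len(tech_replicates)
    )
    base_ct <- ifelse(grid$gene == reference_gene, base_ct_reference,
                      base_ct_target)
    shift <- ifelse(grid$gene == target_gene & grid$condition == "treatment",
                    -log2(effect), 0)
    ct_table <- grid |>
      dplyr::mutate(
        sample = paste0(.data$condition, "_", .data$bio_rep),
        ct = base_ct + shift + rnorm(dplyr::n(), sd = noise_sd)
      ) |>
      dplyr::select("sample", "condition", "gene", "bio_rep", "tech_rep", "ct")
    list(ct_table = ct_table,
         truth = tibble(gene = target_gene, effect = effect))
  })
}
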