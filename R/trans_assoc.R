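#' Correlate trans-factor expression changes with directional shift summaries
#'
#' For each factor (splicing factor or transcription factor) and event
#' type, computes Spearman's rank correlation between the factor's
#' log-fold expression change and the percent positive events (PPE)
#' across environments. BH correction is applied across all factors
#' within one event type — never across event types.
#'
#' @param expr Factor expression table: `factor_id`, `cell_type`,
#'   `treatment`, `log_fc`.
#' @param ppe_by_env PPE per environment: `event_type`, `cell_type`,
#'   `treatment`, `ppe` (as from [summarise_directions()]).
#' @param min_environments Minimum environments with both values
#'   (default 10); factors below it are reported with
#'   `skipped_reason`.
#' @return Tibble with `factor_id`, `event_type`, `n_env`,
#'   `spearman_rho`, `p_value`, `q_value`, `skipped_reason`.
#' @export
factor_ppe_correlation <- function(expr, ppe_by_env, min_environments = 10) {
  assert_columns(expr, c("factor_id", "cell_type", "treatment", "log_fc"),
                 "`expr`")
  assert_columns(ppe_by_env, c("event_type", "cell_type", "treatment", "ppe"),
                 "`ppe_by_env`")
  joined <- expr %>%
    inner_join(ppe_by_env, by = c("cell_type", "treatment"),
               relationship = "many-to-many") %>%
    filter(is.finite(log_fc), is.finite(ppe))
  res <- joined %>%
    group_by(factor_id, event_type) %>%
    summarise(
      n_env = n(),
      spearman_rho = if (n_env >= min_environments && sd(ppe) > 0 &&
                         sd(log_fc) > 0) {
        unname(suppressWarnings(
          cor.test(log_fc, ppe, method = "spearman"))$estimate)
      } else NA_real_,
      p_value = if (n_env >= min_environments && sd(ppe) > 0 &&
                    sd(log_fc) > 0) {
        suppressWarnings(cor.test(log_fc, ppe, method = "spearman"))$p.value
      } else NA_real_,
      skipped_reason = dplyr::case_when(
        n_env < min_environments ~
          sprintf("fewer than %d environments", min_environments),
        sd(ppe) == 0 ~ "constant PPE",
        sd(log_fc) == 0 ~ "constant log_fc",
        TRUE ~ NA_character_
      ),
      .groups = "drop"
    ) %>%
    group_by(event_type) %>%
    mutate(q_value = {
      q <- rep(NA_real_, n())
      ok <- !is.na(p_value)
      q[ok] <- p.adjust(p_value[ok], method = "BH")
      q
    }) %>%
    ungroup()
  res
}

#' Correlate per-gene expression change with mean delta-PSI
#'
#' Within each treatment x event type group with at least `min_shifts`
#' significant shifts whose gene expression could be assessed, computes
#' Spearman's correlation between gene-level log-fold expression change
#' and the event's mean oriented delta-PSI across individuals.
#'
#' @param shifts Tibble of significant shifts with `gene_id`,
#'   `treatment`, `event_type`, `mean_delta_psi`.
#' @param gene_lfc Tibble with `gene_id`, `treatment`, `log_fc`.
#' @param min_shifts Minimum group size (default 30); smaller groups are
#'   skipped with a reason.
#' @return Tibble with `treatment`, `event_type`, `n`, `spearman_rho`,
#'   `p_value`, `skipped_reason`.
#' @export
expression_deltapsi_correlation <- function(shifts, gene_lfc,
                                            min_shifts = 30) {
  assert_columns(shifts, c("gene_id", "treatment", "event_type",
                           "mean_delta_psi"), "`shifts`")
  assert_columns(gene_lfc, c("gene_id", "treatment", "log_fc"), "`gene_lfc`")
  joined <- shifts %>%
    inner_join(gene_lfc, by = c("gene_id", "treatment")) %>%
    filter(is.finite(log_fc), is.finite(mean_delta_psi))
  joined %>%
    group_by(treatment, event_type) %>%
    summarise(
      n = n(),
      spearman_rho = if (n >= min_shifts) {
        unname(suppressWarnings(
          cor.test(log_fc, mean_delta_psi, method = "spearman"))$estimate)
      } else NA_real_,
      p_value = if (n >= min_shifts) {
        suppressWarnings(
          cor.test(log_fc, mean_delta_psi, method = "spearman"))$p.value
      } else NA_real_,
      skipped_reason = if_else(n < min_shifts,
                               sprintf("fewer than %d shifts", min_shifts),
                               NA_character_),
      .groups = "drop"
    )
}
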