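#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline facet_wrap labs theme_minimal stat_ecdf
#'   scale_color_manual
#' @export
ggplot2::autoplot

#' Volcano-style overview of called shifts
#'
#' Combined Z against -log10 q-value, one panel per event type,
#' significant shifts highlighted.
#'
#' @param object A `shift_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shift_calls
#' @export
autoplot.shift_calls <- function(object, ...) {
  df <- as_tibble(unclass(object)) %>% filter(is.finite(z_combined))
  ggplot(df, aes(x = z_combined, y = -log10(pmax(q_value, 1e-300)),
                 color = significant)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    facet_wrap(~ event_type) +
    labs(x = "combined Z", y = expression(-log[10]~q),
         color = "significant") +
    theme_minimal()
}

#' Cross-validated AUC path of a direction classifier
#'
#' AUC along the regularization path with the positions of the
#' AUC-maximal lambda and lambda.1se.
#'
#' @param object A `direction_classifier` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot direction_classifier
#' @export
autoplot.direction_classifier <- function(object, ...) {
  cv <- object$fit
  df <- tibble(log_lambda = log(cv$lambda), auc = cv$cvm,
               auc_lo = cv$cvlo, auc_hi = cv$cvup)
  ggplot(df, aes(log_lambda, auc)) +
    geom_line() +
    geom_point(size = 0.7) +
    geom_vline(xintercept = log(object$lambda_1se), linetype = 2) +
    geom_vline(xintercept = log(object$lambda_max_auc), linetype = 3) +
    labs(x = expression(log~lambda), y = "CV AUC",
         title = sprintf("AUC %.3f at lambda.1se", object$cv_auc)) +
    theme_minimal()
}

#' Event-type proportions among significant shifts per treatment
#'
#' @param object An `enrichment_model` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_model
#' @export
autoplot.enrichment_model <- function(object, ...) {
  ggplot(object$proportions,
         aes(x = treatment, y = proportion, fill = event_type)) +
    geom_col() +
    labs(x = "treatment", y = "share of significant events",
         fill = "event type") +
    theme_minimal()
}

#' ECDF comparison of environment vs null delta-PSI distributions
#'
#' @param deltas_env Oriented delta-PSI values in the environment.
#' @param deltas_null Control-vs-control delta-PSI values.
#' @return A ggplot object.
#' @export
plot_delta_ecdf <- function(deltas_env, deltas_null) {
  df <- bind_rows(
    tibble(delta_psi = deltas_env[is.finite(deltas_env)], set = "environment"),
    tibble(delta_psi = deltas_null[is.finite(deltas_null)], set = "null")
  )
  ggplot(df, aes(delta_psi, color = set)) +
    stat_ecdf() +
    labs(x = expression(Delta*Psi), y = "ECDF", color = NULL) +
    theme_minimal()
}

#' TSS accessibility profile plot
#'
#' Normalized per-bp coverage around preferred and non-preferred TSSs
#' for each condition.
#'
#' @param profile Output of [tss_accessibility_profile()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  ggplot(profile, aes(rel_pos, norm_coverage,
                      color = tss_class, linetype = condition)) +
    geom_line() +
    labs(x = "position relative to TSS (bp)", y = "normalized coverage",
         color = "TSS class", linetype = NULL) +
    theme_minimal()
}

#' QQ plot of QTL p-values by binding class
#'
#' @param enrichment Output of [binding_enrichment()].
#' @return A ggplot object.
#' @export
plot_qtl_qq <- function(enrichment) {
  ggplot(enrichment$qq,
         aes(-log10(expected), -log10(pmax(p_value, 1e-300)),
             color = binding_effect)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = 0, color = "grey80") +
    labs(x = expression(-log[10]~expected~p),
         y = expression(-log[10]~observed~p),
         color = "binding-affecting") +
    theme_minimal()
}
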