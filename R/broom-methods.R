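#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-event results of a shift-calling run
#'
#' @param x A `shift_calls` object.
#' @param ... Unused.
#' @return A plain tibble, one row per combined event, excluded records
#'   included with their `exclusion_reason`.
#' @method tidy shift_calls
#' @export
tidy.shift_calls <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a shift-calling run
#'
#' @param x A `shift_calls` object.
#' @param ... Unused.
#' @return Tibble with `n_events`, `n_tested`, `n_significant`,
#'   `nominal_fdr`.
#' @method glance shift_calls
#' @export
glance.shift_calls <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_tested = sum(is.finite(x$z_combined)),
    n_significant = sum(x$significant, na.rm = TRUE),
    nominal_fdr = attr(x, "nominal_fdr")
  )
}

#' Tidy the nonzero coefficients of a direction classifier
#'
#' @param x A `direction_classifier` object.
#' @param ... Unused.
#' @return Tibble with `feature` and `coefficient` at lambda.1se.
#' @method tidy direction_classifier
#' @export
tidy.direction_classifier <- function(x, ...) {
  x$nonzero
}

#' One-row summary of a direction classifier
#'
#' @param x A `direction_classifier` object.
#' @param ... Unused.
#' @return Tibble with `n_events`, `cv_auc`, `cv_auc_max`,
#'   `lambda_1se`, `lambda_max_auc`, `n_nonzero`, `alpha`.
#' @method glance direction_classifier
#' @export
glance.direction_classifier <- function(x, ...) {
  tibble(
    n_events = x$n_events,
    cv_auc = x$cv_auc,
    cv_auc_max = x$cv_auc_max,
    lambda_1se = x$lambda_1se,
    lambda_max_auc = x$lambda_max_auc,
    n_nonzero = nrow(x$nonzero),
    alpha = x$alpha
  )
}

#' Tidy an event-type enrichment model
#'
#' @param x An `enrichment_model` object.
#' @param interactions_only Return only treatment:event_type terms
#'   (default FALSE).
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std_error`,
#'   `p_value`).
#' @method tidy enrichment_model
#' @export
tidy.enrichment_model <- function(x, interactions_only = FALSE, ...) {
  if (interactions_only) x$interactions else x$coefficients
}

#' One-row summary of an event-type enrichment model
#'
#' @param x An `enrichment_model` object.
#' @param ... Unused.
#' @return Tibble with term counts and the number of significant
#'   interactions at Wald p < 0.05.
#' @method glance enrichment_model
#' @export
glance.enrichment_model <- function(x, ...) {
  tibble(
    n_terms = nrow(x$coefficients),
    n_interactions = nrow(x$interactions),
    n_sig_interactions = sum(x$interactions$p_value < 0.05, na.rm = TRUE),
    ridge_fallback = is.null(x$fit)
  )
}
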