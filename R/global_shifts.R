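#' Directional enrichment of significant shifts in an environment
#'
#' Exact two-sided binomial test of the number of positive significant
#' shifts against the 50:50 expectation. Environments are labelled
#' `positive-enriched` or `negative-enriched` when p < 0.05 in the
#' corresponding direction, `none` otherwise.
#'
#' Takes a per-environment summary table so it can be chained directly
#' after [summarise_directions()].
#'
#' @param summary Data frame with columns `n_pos` and `n_sig` (one row
#'   per environment x event type). Rows with `n_sig` = 0 get `NA`
#'   p-values and label `none`.
#' @param alpha Significance threshold for labelling (default 0.05).
#' @return Input with `binom_p` and `label` appended.
#' @export
directional_binomial <- function(summary, alpha = 0.05) {
  assert_columns(summary, c("n_pos", "n_sig"), "`summary`")
  summary %>%
    as_tibble() %>%
    mutate(
      binom_p = map2(n_pos, n_sig, function(k, n) {
        if (n < 1) return(NA_real_)
        binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
      }) %>% unlist(),
      label = case_when(
        is.na(binom_p) ~ "none",
        binom_p < alpha & n_pos > n_sig / 2 ~ "positive-enriched",
        binom_p < alpha & n_pos < n_sig / 2 ~ "negative-enriched",
        TRUE ~ "none"
      )
    )
}

#' Summarise shift direction per environment and event type
#'
#' Counts significant shifts and their positive fraction (PPE, percent
#' positive events) for each environment x directional event type.
#'
#' @param calls A [call_shifts()] result (columns `event_type`,
#'   `cell_type`, `treatment`, `significant`, `direction`).
#' @param min_sig Report only combinations with at least this many
#'   significant shifts (default 10).
#' @return Tibble with `n_sig`, `n_pos`, `ppe`.
#' @export
summarise_directions <- function(calls, min_sig = 10) {
  assert_columns(calls, c("event_type", "cell_type", "treatment",
                          "significant", "direction"), "`calls`")
  calls %>%
    as_tibble() %>%
    filter(event_type %in% DIRECTIONAL_TYPES, significant) %>%
    group_by(event_type, cell_type, treatment) %>%
    summarise(
      n_sig = n(),
      n_pos = sum(direction > 0),
      .groups = "drop"
    ) %>%
    mutate(ppe = ppe(n_pos, n_sig)) %>%
    filter(n_sig >= min_sig)
}

#' Percent positive events
#'
#' Fraction of significant shifts of an event type that are positive in
#' the oriented convention. Undefined (NA) when there are no
#' significant shifts.
#'
#' @param n_pos,n_sig Counts of positive significant and all significant
#'   shifts (vectorized).
#' @return Numeric vector in [0, 1] (NA where `n_sig` = 0).
#' @export
ppe <- function(n_pos, n_sig) {
  if (any(n_pos > n_sig, na.rm = TRUE)) abort("`n_pos` cannot exceed `n_sig`.")
  if_else(n_sig > 0, n_pos / n_sig, NA_real_)
}

#' Compare an environment's delta-PSI distribution to the null ECDF
#'
#' Two-sample Kolmogorov-Smirnov test of all oriented delta-PSI values
#' in an environment (significant or not) against the delta-PSI values
#' from control-vs-control comparisons. A global regulatory shift moves
#' the whole ECDF, not only the significant tail.
#'
#' @param deltas_env Numeric vector of oriented delta-PSI values.
#' @param deltas_null Numeric vector of control-vs-control delta-PSI.
#' @param min_n Minimum size of each sample (default 30); smaller
#'   samples return `NA` with a `skipped_reason`.
#' @return Tibble with `ks_d`, `ks_p`, `n_env`, `n_null`,
#'   `skipped_reason`.
#' @export
ecdf_ks <- function(deltas_env, deltas_null, min_n = 30) {
  deltas_env <- deltas_env[is.finite(deltas_env)]
  deltas_null <- deltas_null[is.finite(deltas_null)]
  if (length(deltas_env) < min_n || length(deltas_null) < min_n) {
    return(tibble(ks_d = NA_real_, ks_p = NA_real_,
                  n_env = length(deltas_env), n_null = length(deltas_null),
                  skipped_reason = sprintf("fewer than %d values", min_n)))
  }
  kt <- suppressWarnings(ks.test(deltas_env, deltas_null))
  tibble(ks_d = unname(kt$statistic), ks_p = kt$p.value,
         n_env = length(deltas_env), n_null = length(deltas_null),
         skipped_reason = NA_character_)
}

#' Event-type enrichment among significant shifts (logistic model)
#'
#' Fits `significant ~ treatment * event_type + cell_type` by logistic
#' regression. The treatment-by-event-type interaction Wald p-values
#' identify event types over- or under-represented among significant
#' shifts of a given treatment beyond the marginal rates. Per-treatment
#' event-type proportions among significant events are computed by
#' reweighting fitted significance probabilities by the number of
#' events tested: `p_hat[t,e] * n[t,e] / sum_e' p_hat[t,e'] * n[t,e']`.
#'
#' When only one cell type is present the cell-type term is dropped.
#' If the fit fails to converge (e.g. complete separation), a
#' ridge-stabilized fit (glmnet, small L2 penalty) supplies the
#' coefficients with a warning; Wald p-values are then unavailable.
#'
#' @param rows Data frame with one row per tested event: logical
#'   `significant`, and factors/characters `treatment`, `event_type`,
#'   `cell_type`.
#' @return Object of class `enrichment_model`: list with `fit` (glm or
#'   NULL), `coefficients` tibble (term, estimate, std_error, p_value),
#'   `interactions` (the treatment:event_type subset), and
#'   `proportions` (per-treatment event-type shares among significant
#'   events, summing to 1 within treatment).
#' @export
event_type_enrichment <- function(rows) {
  assert_columns(rows, c("significant", "treatment", "event_type",
                         "cell_type"), "`rows`")
  rows <- rows %>%
    mutate(across(c(treatment, event_type, cell_type), as.factor),
           significant = as.logical(significant))
  empty_cells <- rows %>% count(treatment, event_type, .drop = FALSE) %>%
    filter(n == 0)
  if (nrow(empty_cells) > 0) {
    abort("Every treatment x event_type cell needs at least one tested event.")
  }
  drop_cell <- nlevels(rows$cell_type) < 2
  form <- if (drop_cell) significant ~ treatment * event_type
          else significant ~ treatment * event_type + cell_type
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = rows),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  separated <- !fit$converged ||
    any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (separated) {
    warn("Logistic fit unstable (possible separation); using ridge-stabilized coefficients.")
    mm <- model.matrix(form, rows)[, -1, drop = FALSE]
    rf <- glmnet::glmnet(mm, as.numeric(rows$significant), family = "binomial",
                         alpha = 0, lambda = 1e-3)
    est <- as.numeric(coef(rf))
    coefs <- tibble(term = c("(Intercept)", colnames(mm)), estimate = est,
                    std_error = NA_real_, p_value = NA_real_)
    fit_obj <- NULL
  } else {
    sm <- summary(fit)$coefficients
    coefs <- tibble(term = rownames(sm), estimate = sm[, 1],
                    std_error = sm[, 2], p_value = sm[, 4])
    fit_obj <- fit
  }
  interactions <- coefs %>% filter(grepl(":", term))
  # Per-treatment event-type shares among significant events.
  cells <- rows %>%
    count(treatment, event_type, cell_type, name = "n_tested")
  pred_fit <- if (!is.null(fit_obj)) fit_obj else fit
  cells$p_hat <- predict(pred_fit, newdata = cells, type = "response")
  proportions <- cells %>%
    group_by(treatment, event_type) %>%
    summarise(expected_sig = sum(p_hat * n_tested),
              n_tested = sum(n_tested), .groups = "drop_last") %>%
    group_by(treatment) %>%
    mutate(proportion = expected_sig / sum(expected_sig)) %>%
    ungroup() %>%
    select(treatment, event_type, n_tested, proportion)
  structure(list(fit = fit_obj, coefficients = coefs,
                 interactions = interactions, proportions = proportions),
            class = "enrichment_model")
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat(sprintf("<enrichment_model> %d coefficients, %d treatment:event_type interactions\n",
              nrow(x$coefficients), nrow(x$interactions)))
  sig <- x$interactions %>% filter(!is.na(p_value), p_value < 0.05)
  cat(sprintf("  interactions with Wald p < 0.05: %d\n", nrow(sig)))
  invisible(x)
}
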