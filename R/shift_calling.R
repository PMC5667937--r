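#' Empirical null distribution of Bayes factors from control-vs-control
#'
#' Bayes factors from comparisons of two control conditions (CO2 vs CO1)
#' measured in the same individual and batch carry no treatment signal,
#' so their distribution is an empirical null against which
#' treatment-vs-control Bayes factors can be calibrated. One null is
#' built per event type, since the null Bayes-factor distribution
#' depends on the event type's coverage characteristics.
#'
#' @param cc_comparisons Filter-passing control-vs-control comparisons
#'   (output of [compare_conditions()]): must contain `event_type` and
#'   `log_bf`.
#' @param event_type The single event type the null is for. May be
#'   omitted when `cc_comparisons` contains exactly one type; mixing
#'   types without saying which to use is an error.
#' @param min_n Minimum number of null comparisons (default 500); fewer
#'   is an error suggesting more null data or pooling.
#' @return Object of class `null_distribution`: list with `event_type`,
#'   sorted `log_bfs`, and `n`.
#' @export
build_null <- function(cc_comparisons, event_type = NULL, min_n = 500) {
  assert_columns(cc_comparisons, c("event_type", "log_bf"),
                 "`cc_comparisons`")
  types <- unique(cc_comparisons$event_type)
  if (is.null(event_type)) {
    if (length(types) != 1) {
      abort("`cc_comparisons` mixes event types; pass `event_type` and filter.")
    }
    event_type <- types
  } else if (!all(types == event_type)) {
    abort("`cc_comparisons` contains rows of a different event type.")
  }
  lb <- cc_comparisons$log_bf
  lb <- lb[is.finite(lb)]
  if (length(lb) < min_n) {
    abort(sprintf(
      "Only %d null comparisons for %s (minimum %d); generate more control-vs-control comparisons or pool.",
      length(lb), event_type, min_n))
  }
  structure(
    list(event_type = event_type, log_bfs = sort(lb), n = length(lb)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d control-vs-control log-BFs, median %.3f\n",
              x$event_type, x$n, stats::median(x$log_bfs)))
  invisible(x)
}

#' Empirical p-value of a Bayes factor against a control-vs-control null
#'
#' The p-value is the add-one upper-tail quantile
#' `p = (1 + #\{null >= observed\}) / (1 + n)`, with ties counted as
#' exceedances. The add-one rule keeps p strictly positive so the
#' normal-quantile transform stays finite.
#'
#' @param log_bf Numeric vector of observed log Bayes factors.
#' @param null A [build_null()] object of the matching event type.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(log_bf, null) {
  if (!inherits(null, "null_distribution")) abort("`null` must be a null_distribution.")
  if (any(is.na(log_bf))) abort("`log_bf` contains NA/NaN.")
  n_ge <- null$n - findInterval(log_bf, null$log_bfs, left.open = TRUE)
  (1 + n_ge) / (1 + null$n)
}

#' Signed Z-score from an empirical p-value and delta-PSI direction
#'
#' Converts each comparison's empirical p-value to a standard-normal
#' score whose sign carries the direction of the PSI change:
#' `Z = sign(delta_psi) * |qnorm(p / 2)|`. A p-value of 1 maps to Z = 0;
#' `delta_psi = 0` also yields Z = 0.
#'
#' @param p Empirical p-values in (0, 1].
#' @param delta_psi Oriented delta-PSI values (same length).
#' @return Numeric vector of signed Z-scores.
#' @export
signed_z <- function(p, delta_psi) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  sign(delta_psi) * abs(qnorm(p / 2))
}

#' Combine per-individual signed Z-scores within an environment
#'
#' Stouffer combination: for each event in each environment the
#' per-individual Z-scores are summed and divided by the square root of
#' the number of contributing individuals. Events measurable in fewer
#' than `min_individuals` individuals are not errors but exclusions:
#' they are returned with `z_combined = NA` and an `exclusion_reason`.
#'
#' Also reports, per S2-table convention, `n_tested` (individuals with
#' enough coverage), `n_p05` (individuals with individual empirical
#' p < 0.05) and `n_positive` (individuals with positive delta-PSI and
#' p < 0.05).
#'
#' @param per_individual Tibble with one row per (event, individual)
#'   containing `z`, `p_emp`, `delta_psi` and the grouping keys.
#' @param by Character vector of grouping keys defining one combined
#'   record (default event within environment).
#' @param min_individuals Minimum individuals required (default 2).
#' @return Tibble with `z_combined`, `k`, `n_p05`, `n_positive`,
#'   `mean_delta_psi`, and `exclusion_reason` (`NA` when combined).
#' @export
combine_individuals <- function(per_individual,
                                by = c("event_id", "event_type",
                                       "cell_type", "treatment"),
                                min_individuals = 2) {
  assert_columns(per_individual, c(by, "z", "p_emp", "delta_psi"),
                 "`per_individual`")
  out <- per_individual %>%
    group_by(across(all_of(by))) %>%
    summarise(
      k = sum(is.finite(z)),
      z_combined = sum(z[is.finite(z)]) / sqrt(pmax(k, 1)),
      n_p05 = sum(p_emp < 0.05, na.rm = TRUE),
      n_positive = sum(p_emp < 0.05 & delta_psi > 0, na.rm = TRUE),
      mean_delta_psi = mean(delta_psi[is.finite(delta_psi)]),
      .groups = "drop"
    ) %>%
    mutate(
      exclusion_reason = if_else(k < min_individuals,
                                 sprintf("fewer than %d individuals", min_individuals),
                                 NA_character_),
      z_combined = if_else(is.na(exclusion_reason), z_combined, NA_real_)
    )
  out
}

#' Call significant RNA-processing shifts by BH FDR on combined Z-scores
#'
#' Converts each combined Z to a two-sided normal p-value
#' `p = 2 * (1 - pnorm(|Z|))`, applies Benjamini-Hochberg correction
#' within each event type across all environments jointly, and flags
#' events with `q_value < fdr` (default 15%) as significant shifts.
#' Direction is the sign of the combined Z.
#'
#' @param combined Output of [combine_individuals()] (excluded rows are
#'   dropped from testing but retained in the output).
#' @param fdr Nominal BH false-discovery rate, default 0.15.
#' @param by_type Apply BH within each event type (default TRUE) rather
#'   than over the pooled set.
#' @return A `shift_calls` tibble with `p_two_sided`, `q_value`,
#'   `significant` and `direction` appended.
#' @export
call_shifts <- function(combined, fdr = 0.15, by_type = TRUE) {
  assert_columns(combined, c("z_combined", "event_type"), "`combined`")
  combined <- as_tibble(combined)
  if (nrow(combined) == 0) {
    out <- combined %>%
      mutate(p_two_sided = numeric(0), q_value = numeric(0),
             significant = logical(0), direction = numeric(0))
    return(new_shift_calls(out, fdr))
  }
  tested <- is.finite(combined$z_combined)
  out <- combined %>%
    mutate(p_two_sided = if_else(tested, 2 * pnorm(-abs(z_combined)), NA_real_))
  grouping <- if (by_type) "event_type" else character(0)
  out <- out %>%
    group_by(across(all_of(grouping))) %>%
    mutate(q_value = {
      q <- rep(NA_real_, n())
      ok <- is.finite(p_two_sided)
      q[ok] <- p.adjust(p_two_sided[ok], method = "BH")
      q
    }) %>%
    ungroup() %>%
    mutate(
      significant = !is.na(q_value) & q_value < fdr,
      direction = sign(z_combined)
    )
  new_shift_calls(out, fdr)
}

new_shift_calls <- function(df, fdr) {
  structure(df, class = c("shift_calls", class(tibble())),
            nominal_fdr = fdr)
}
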