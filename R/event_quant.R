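#' Posterior PSI estimates from inclusion/exclusion read counts
#'
#' Computes the conjugate Beta posterior of the percent-spliced-in (PSI)
#' value of each event from reads unique to the inclusion isoform
#' (`n_inc`) and reads unique to the exclusion isoform (`n_exc`). With a
#' Beta(a, b) prior the posterior is Beta(a + n_inc, b + n_exc); the
#' reported interval is the central 95% credible interval.
#'
#' For tandem-UTR events, where one isoform fully contains the other,
#' `n_inc` is the count of reads specific to the longer isoform and
#' `n_exc` the remaining reads covering either isoform, so that
#' `n_inc + n_exc` is the total informative coverage.
#'
#' @param counts Data frame with columns `n_inc` and `n_exc`
#'   (non-negative integers). Additional columns are preserved.
#' @param prior Length-2 numeric vector of Beta prior shape parameters
#'   `c(a, b)`; default uniform `c(1, 1)`.
#' @return The input as a tibble with columns `psi_mean`, `psi_low`,
#'   `psi_high` appended.
#' @examples
#' estimate_psi(data.frame(n_inc = 9, n_exc = 1))
#' @export
estimate_psi <- function(counts, prior = c(1, 1)) {
  assert_columns(counts, c("n_inc", "n_exc"), "`counts`")
  check_prior(prior)
  if (any(counts$n_inc < 0 | counts$n_exc < 0)) {
    abort("Read counts must be non-negative.")
  }
  a <- prior[1] + counts$n_inc
  b <- prior[2] + counts$n_exc
  counts %>%
    as_tibble() %>%
    mutate(
      psi_mean = a / (a + b),
      psi_low  = qbeta(0.025, a, b),
      psi_high = qbeta(0.975, a, b)
    )
}

check_prior <- function(prior) {
  if (length(prior) != 2 || any(!is.finite(prior)) || any(prior <= 0)) {
    abort("`prior` must be two positive Beta shape parameters c(a, b).")
  }
  invisible(prior)
}

#' Bayes factor for a PSI difference between two samples
#'
#' Evidence ratio BF10 comparing the model in which treatment and control
#' have independent PSI values (each with a Beta(a, b) prior) against the
#' model in which they share a single PSI. With inclusion counts k and
#' totals n the marginal likelihoods are Beta functions and the binomial
#' coefficients cancel:
#'
#' \deqn{BF_{10} = \frac{B(a+k_t, b+n_t-k_t)\, B(a+k_c, b+n_c-k_c)}
#'   {B(a,b)\, B(a+k_t+k_c,\; b+n_t+n_c-k_t-k_c)}}
#'
#' All arguments are vectorized. The computation is carried out on the
#' log scale; `exp(psi_log_bf(...))` can overflow to `Inf` for extreme
#' counts, so downstream calibration works with the log Bayes factor.
#'
#' @param k_t,n_t Inclusion count and total informative count in treatment.
#' @param k_c,n_c Inclusion count and total informative count in control.
#' @param prior Beta prior shape parameters `c(a, b)`.
#' @return Numeric vector of log Bayes factors (natural log).
#' @export
psi_log_bf <- function(k_t, n_t, k_c, n_c, prior = c(1, 1)) {
  check_prior(prior)
  if (any(k_t < 0 | k_c < 0 | k_t > n_t | k_c > n_c)) {
    abort("Counts must satisfy 0 <= k <= n in both samples.")
  }
  a <- prior[1]; b <- prior[2]
  lbeta(a + k_t, b + n_t - k_t) + lbeta(a + k_c, b + n_c - k_c) -
    lbeta(a, b) - lbeta(a + k_t + k_c, b + n_t + n_c - k_t - k_c)
}

#' Per-event read-coverage filter
#'
#' Applies the minimum-coverage rule under which a treatment/control
#' comparison is considered measurable. For all event types except
#' tandem UTRs both samples must have at least 2 reads unique to each
#' isoform and at least 10 reads unique to either. For tandem UTRs, where
#' only the longer isoform has specific reads, both samples must have at
#' least 5 reads specific to the longer isoform (`n_inc`) and at least 10
#' informative reads in total.
#'
#' @param comparisons Data frame with columns `event_type`,
#'   `n_inc_treat`, `n_exc_treat`, `n_inc_ctrl`, `n_exc_ctrl`.
#' @return Tibble with logical `filter_pass` and character
#'   `filter_reason` (`NA` when passing) appended.
#' @export
apply_coverage_filter <- function(comparisons) {
  assert_columns(comparisons,
                 c("event_type", "n_inc_treat", "n_exc_treat",
                   "n_inc_ctrl", "n_exc_ctrl"), "`comparisons`")
  bad <- setdiff(unique(comparisons$event_type), EVENT_TYPES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown event type(s): %s", paste(bad, collapse = ", ")))
  }
  comparisons %>%
    as_tibble() %>%
    mutate(
      filter_reason = case_when(
        event_type == "TandemUTR" & n_inc_treat < 5 ~ "treat n_long < 5",
        event_type == "TandemUTR" & n_inc_ctrl < 5 ~ "ctrl n_long < 5",
        event_type == "TandemUTR" &
          (n_inc_treat + n_exc_treat) < 10 ~ "treat n_total < 10",
        event_type == "TandemUTR" &
          (n_inc_ctrl + n_exc_ctrl) < 10 ~ "ctrl n_total < 10",
        event_type != "TandemUTR" & n_inc_treat < 2 ~ "treat n_inc < 2",
        event_type != "TandemUTR" & n_exc_treat < 2 ~ "treat n_exc < 2",
        event_type != "TandemUTR" & n_inc_ctrl < 2 ~ "ctrl n_inc < 2",
        event_type != "TandemUTR" & n_exc_ctrl < 2 ~ "ctrl n_exc < 2",
        event_type != "TandemUTR" &
          (n_inc_treat + n_exc_treat) < 10 ~ "treat total < 10",
        event_type != "TandemUTR" &
          (n_inc_ctrl + n_exc_ctrl) < 10 ~ "ctrl total < 10",
        TRUE ~ NA_character_
      ),
      filter_pass = is.na(filter_reason)
    )
}

#' Compare treatment and control counts for each event
#'
#' Builds one comparison record per row: posterior PSI means in both
#' samples, their difference (`delta_psi`, treatment minus control, in
#' the raw isoform-1 orientation), and the Bayes factor for a PSI
#' difference. Rows failing the coverage filter are retained with
#' `filter_pass = FALSE` and `NA` statistics, never silently dropped.
#'
#' @param comparisons Data frame with one row per (event, comparison) and
#'   columns `event_id`, `event_type`, `n_inc_treat`, `n_exc_treat`,
#'   `n_inc_ctrl`, `n_exc_ctrl`. Any key columns (individual,
#'   environment, ...) are carried through.
#' @param prior Beta prior shape parameters, default uniform.
#' @return Tibble with `psi_treat`, `psi_ctrl`, `delta_psi`, `log_bf`,
#'   `bayes_factor`, `filter_pass`, `filter_reason` appended and
#'   `oriented = FALSE` (see [orient_delta()]).
#' @export
compare_conditions <- function(comparisons, prior = c(1, 1)) {
  assert_columns(comparisons, c("event_id", "event_type"), "`comparisons`")
  out <- apply_coverage_filter(comparisons)
  a <- prior[1]; b <- prior[2]
  out <- out %>%
    mutate(
      psi_treat = (a + n_inc_treat) / (a + b + n_inc_treat + n_exc_treat),
      psi_ctrl  = (a + n_inc_ctrl) / (a + b + n_inc_ctrl + n_exc_ctrl),
      delta_psi = psi_treat - psi_ctrl,
      log_bf = psi_log_bf(n_inc_treat, n_inc_treat + n_exc_treat,
                          n_inc_ctrl, n_inc_ctrl + n_exc_ctrl, prior),
      bayes_factor = exp(log_bf),
      oriented = FALSE
    )
  out <- out %>%
    mutate(across(c(psi_treat, psi_ctrl, delta_psi, log_bf, bayes_factor),
                  ~ if_else(filter_pass, .x, NA_real_)))
  out
}

# Per-event orientation sign and directionality from the annotation.
# Isoform 1 is the isoform whose PSI the raw delta refers to.
orientation_signs <- function(annotation) {
  assert_columns(annotation, c("event_id", "event_type", "strand"),
                 "`annotation`")
  ann <- as_tibble(annotation)
  needs_tss <- ann$event_type %in% c("AFE", "ALE")
  if (any(needs_tss)) {
    assert_columns(ann, c("iso1_start", "iso1_end", "iso2_start", "iso2_end"),
                   "`annotation` (AFE/ALE rows)")
  }
  ann %>%
    mutate(
      # Transcribed-orientation anchor of each alternative terminal exon:
      # AFE -> first transcribed base (TSS); ALE -> last transcribed base.
      anchor1 = case_when(
        event_type == "AFE" & strand == "+" ~ iso1_start,
        event_type == "AFE" & strand == "-" ~ iso1_end - 1,
        event_type == "ALE" & strand == "+" ~ iso1_end - 1,
        event_type == "ALE" & strand == "-" ~ iso1_start,
        TRUE ~ NA_real_
      ),
      anchor2 = case_when(
        event_type == "AFE" & strand == "+" ~ iso2_start,
        event_type == "AFE" & strand == "-" ~ iso2_end - 1,
        event_type == "ALE" & strand == "+" ~ iso2_end - 1,
        event_type == "ALE" & strand == "-" ~ iso2_start,
        TRUE ~ NA_real_
      ),
      # Positive oriented delta must mean: upstream AFE up, downstream
      # ALE up.  "Upstream" on the minus strand is the larger genomic
      # coordinate.
      orient_sign = case_when(
        event_type == "AFE" & strand == "+" ~ if_else(anchor1 < anchor2, 1, -1),
        event_type == "AFE" & strand == "-" ~ if_else(anchor1 > anchor2, 1, -1),
        event_type == "ALE" & strand == "+" ~ if_else(anchor1 > anchor2, 1, -1),
        event_type == "ALE" & strand == "-" ~ if_else(anchor1 < anchor2, 1, -1),
        TRUE ~ 1
      ),
      directional = event_type %in% DIRECTIONAL_TYPES
    ) %>%
    select(event_id, orient_sign, directional)
}

#' Orient delta-PSI so its sign is biologically comparable across events
#'
#' Positive oriented delta-PSI means: more skipped-exon inclusion (SE),
#' more intron retention (RI), the longer tandem UTR, the upstream
#' alternative first exon, or the downstream alternative last exon —
#' always on the transcribed strand. SE, RI and TandemUTR counts already
#' follow this convention and pass through; AFE and ALE are flipped when
#' isoform 1 of the annotation is not the upstream-first-exon /
#' downstream-last-exon isoform. A3SS, A5SS and MXE have no global
#' direction: their values pass through with `directional = FALSE`.
#'
#' The operation is idempotent: rows with `oriented = TRUE` are returned
#' unchanged, so applying it twice equals applying it once.
#'
#' @param comparisons Output of [compare_conditions()] (column
#'   `delta_psi`, `event_id`, `event_type`).
#' @param annotation Event annotation with `event_id`, `event_type`,
#'   `strand` and, for AFE/ALE, the two terminal-exon blocks
#'   `iso1_start`, `iso1_end`, `iso2_start`, `iso2_end` (0-based
#'   half-open).
#' @return `comparisons` with `delta_psi` oriented, plus logical columns
#'   `directional` and `oriented`.
#' @export
orient_delta <- function(comparisons, annotation) {
  assert_columns(comparisons, c("event_id", "event_type", "delta_psi"),
                 "`comparisons`")
  comparisons <- as_tibble(comparisons)
  if (!"oriented" %in% names(comparisons)) comparisons$oriented <- FALSE
  comparisons$.orig_order <- seq_len(nrow(comparisons))
  todo <- !comparisons$oriented
  if (!any(todo)) return(select(comparisons, -".orig_order"))
  signs <- orientation_signs(annotation)
  missing_ann <- setdiff(unique(comparisons$event_id[todo]), signs$event_id)
  if (length(missing_ann) > 0) {
    abort(sprintf("No annotation for %d event(s), e.g. %s",
                  length(missing_ann), missing_ann[1]))
  }
  upd <- comparisons[todo, ] %>%
    select(-dplyr::any_of(c("directional"))) %>%
    left_join(signs, by = "event_id") %>%
    mutate(delta_psi = delta_psi * orient_sign,
           oriented = TRUE) %>%
    select(-orient_sign)
  done <- comparisons[!todo, ]
  if (!"directional" %in% names(done)) {
    done <- done %>% left_join(signs, by = "event_id") %>% select(-orient_sign)
  }
  bind_rows(done, upd) %>% arrange(.data$.orig_order) %>% select(-".orig_order")
}
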