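#' Configuration for a synthetic RNA-processing cohort
#'
#' Describes a synthetic study of the same shape as the real design the
#' package targets: cell types crossed with treatments, two or more
#' vehicle controls per environment each applied in technical
#' replicates, and three individuals per environment. All downstream
#' stages can be exercised against the planted truth the generator
#' records.
#'
#' @param n_cell_types Number of cell types (default 1).
#' @param n_treatments Number of treatment compounds (default 1).
#' @param n_controls Number of vehicle controls; at least 2 so that a
#'   control-vs-control empirical null can be formed (default 2).
#' @param n_individuals Individuals per environment (default 3).
#' @param replicates_per_control Technical replicates per control
#'   compound, pooled before comparison (default 3).
#' @param event_types Event types to simulate (default all 8).
#' @param n_events_per_type Events per type (default 200).
#' @param read_depth Expected informative reads per event in a treatment
#'   library; each control replicate gets `read_depth /
#'   replicates_per_control` so the pooled control matches the treatment
#'   depth (default 300).
#' @param effect_fraction Fraction of (event, environment) pairs with a
#'   true shift (default 0.3).
#' @param effect_size_range Range of |delta-PSI| for true shifts
#'   (default c(0.15, 0.4)).
#' @param pi_pos Per-environment probability that a true shift is
#'   positive in the oriented convention (default 0.5).
#' @param rho Beta-binomial intra-class correlation of library-level PSI
#'   around the individual baseline (default 0.01); biological
#'   replicates overdisperse, which is what makes empirical-null
#'   calibration a real test.
#' @param rho_individual Overdispersion of individual baselines around
#'   the event baseline (default 0.01).
#' @param baseline_shape Beta shape parameters of event baseline PSI,
#'   mapped onto [0.05, 0.95] (default c(2, 2)).
#' @param seed Global integer seed; all generator streams derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cell_types = 1,
                          n_treatments = 1,
                          n_controls = 2,
                          n_individuals = 3,
                          replicates_per_control = 3,
                          event_types = EVENT_TYPES,
                          n_events_per_type = 200,
                          read_depth = 300,
                          effect_fraction = 0.3,
                          effect_size_range = c(0.15, 0.4),
                          pi_pos = 0.5,
                          rho = 0.01,
                          rho_individual = 0.01,
                          baseline_shape = c(2, 2),
                          seed = 1L) {
  if (n_controls < 2) abort("`n_controls` must be >= 2 for a control-vs-control null.")
  for (frac in list(effect_fraction = effect_fraction, pi_pos = pi_pos)) {
    if (any(frac < 0 | frac > 1)) abort("Fractions must lie in [0, 1].")
  }
  if (any(rho < 0 | rho >= 1)) abort("`rho` must be in [0, 1).")
  if (!all(event_types %in% EVENT_TYPES)) abort("Unknown event type in `event_types`.")
  structure(list(
    n_cell_types = n_cell_types, n_treatments = n_treatments,
    n_controls = n_controls, n_individuals = n_individuals,
    replicates_per_control = replicates_per_control,
    event_types = event_types, n_events_per_type = n_events_per_type,
    read_depth = read_depth, effect_fraction = effect_fraction,
    effect_size_range = effect_size_range, pi_pos = pi_pos,
    rho = rho, rho_individual = rho_individual,
    baseline_shape = baseline_shape, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate event annotations for a synthetic cohort
#'
#' Lays out one annotation record per event with internally consistent
#' 0-based half-open coordinates: alternative-unit blocks, flanking
#' exons for SE/RI, and two terminal-exon blocks with random
#' upstream/downstream isoform labelling for AFE/ALE (so orientation
#' logic is genuinely exercised).
#'
#' @param config A [cohort_config()].
#' @return Annotation tibble (one row per event).
#' @export
simulate_event_annotation <- function(config) {
  with_stream_seed(config$seed, "annotation", {
    per_type <- purrr::map(config$event_types, function(ty) {
      ty_i <- match(ty, config$event_types)
      n <- config$n_events_per_type
      # Globally unique, non-overlapping 20 kb slots: windows around one
      # event can never touch another event's, whatever the chromosome.
      base <- 1e5 + ((ty_i - 1) * n + seq_len(n) - 1) * 2e4
      strand <- sample(c("+", "-"), n, replace = TRUE)
      gap <- round(runif(n, 1500, 5000))
      swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
      # Two candidate terminal exons at base and base+gap (AFE/ALE);
      # `swap` decides which one is isoform 1.
      a_start <- base; a_end <- base + 200
      b_start <- base + gap; b_end <- base + gap + 200
      tibble(
        event_id = sprintf("%s_%05d", ty, seq_len(n)),
        gene_id = sprintf("G_%s_%05d", ty, seq_len(n)),
        event_type = ty,
        chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
        strand = strand,
        iso1_start = dplyr::case_when(
          ty %in% c("AFE", "ALE") & swap ~ b_start,
          ty %in% c("AFE", "ALE") ~ a_start,
          ty == "RI" ~ base + 200,       # the retained intron
          TRUE ~ base + 1200             # alternative unit (e.g. skipped exon)
        ),
        iso1_end = dplyr::case_when(
          ty %in% c("AFE", "ALE") & swap ~ b_end,
          ty %in% c("AFE", "ALE") ~ a_end,
          ty == "RI" ~ base + 1200,
          TRUE ~ base + 1400
        ),
        iso2_start = dplyr::case_when(
          ty %in% c("AFE", "ALE") & swap ~ a_start,
          ty %in% c("AFE", "ALE") ~ b_start,
          TRUE ~ NA_real_
        ),
        iso2_end = dplyr::case_when(
          ty %in% c("AFE", "ALE") & swap ~ a_end,
          ty %in% c("AFE", "ALE") ~ b_end,
          TRUE ~ NA_real_
        ),
        flank_up_start = if (ty %in% c("SE", "RI")) base else NA_real_,
        flank_up_end = if (ty %in% c("SE", "RI")) base + 200 else NA_real_,
        flank_down_start = if (ty == "SE") base + 2400
                           else if (ty == "RI") base + 1200 else NA_real_,
        flank_down_end = if (ty == "SE") base + 2600
                         else if (ty == "RI") base + 1400 else NA_real_
      )
    })
    list_rbind(per_type)
  })
}

#' Simulate a cohort of inclusion/exclusion counts with planted truth
#'
#' Generates, for every event, individual and environment: a treatment
#' library, and `n_controls` control compounds each applied in
#' `replicates_per_control` technical replicates that are pooled before
#' comparison. Library-level PSI is beta-binomially overdispersed around
#' the individual baseline; technical replicates of the same condition
#' share one PSI realization. True shifts move the treatment PSI by the
#' planted oriented delta (converted to the raw isoform-1 convention by
#' the annotation's orientation sign).
#'
#' The output comparison table contains both the treatment-vs-CO1
#' comparisons (`comparison_class = "treatment"`) and the CO2-vs-CO1
#' null comparisons (`comparison_class = "control"`) that downstream
#' calibration consumes, with identical filtering semantics.
#'
#' @param config A [cohort_config()].
#' @return List with `annotation`, `comparisons` (input of
#'   [compare_conditions()]), `truth` (one row per event, cell type and
#'   treatment: `true_shift`, `true_delta` oriented, `true_direction`),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ann <- simulate_event_annotation(config)
  signs <- orientation_signs(ann)
  n_ev <- nrow(ann)
  cell_types <- paste0("CT", seq_len(config$n_cell_types))
  treatments <- paste0("T", seq_len(config$n_treatments))
  individuals <- paste0("I", seq_len(config$n_individuals))
  controls <- paste0("CO", seq_len(config$n_controls))

  events <- with_stream_seed(config$seed, "baseline", {
    ann %>%
      select(event_id, event_type) %>%
      mutate(psi_base = 0.05 + 0.9 * rbeta(n_ev, config$baseline_shape[1],
                                           config$baseline_shape[2])) %>%
      left_join(signs, by = "event_id")
  })

  truth <- with_stream_seed(config$seed, "truth", {
    tidyr::expand_grid(events, cell_type = cell_types,
                       treatment = treatments) %>%
      mutate(
        true_shift = runif(n()) < config$effect_fraction,
        magnitude = runif(n(), config$effect_size_range[1],
                          config$effect_size_range[2]),
        pos = runif(n()) < config$pi_pos,
        true_delta = if_else(true_shift, magnitude * if_else(pos, 1, -1), 0),
        true_direction = sign(true_delta)
      ) %>%
      select(event_id, event_type, cell_type, treatment,
             true_shift, true_delta, true_direction)
  })

  # Individual baseline PSI per event x individual x cell type.
  indiv <- with_stream_seed(config$seed, "individual", {
    tidyr::expand_grid(events, cell_type = cell_types,
                       individual_id = individuals) %>%
      mutate(psi_ind = if (config$rho_individual > 0) {
        sh <- beta_shapes(psi_base, config$rho_individual)
        rbeta(n(), sh$a, sh$b)
      } else psi_base)
  })

  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)

  # One PSI realization per biological condition (treatment compound or
  # control compound); technical replicates share it.
  cond_grid <- tidyr::expand_grid(
    indiv, condition = c(treatments, controls)
  ) %>%
    left_join(truth %>% rename(condition = treatment),
              by = c("event_id", "event_type", "cell_type", "condition")) %>%
    mutate(
      # Oriented planted delta -> raw isoform-1 scale via the
      # orientation sign (its own inverse).
      mu = clamp(psi_ind + dplyr::coalesce(true_delta, 0) * orient_sign)
    )

  cond_grid <- with_stream_seed(config$seed, "condition_psi", {
    cond_grid %>%
      mutate(psi_cond = if (config$rho > 0) {
        sh <- beta_shapes(mu, config$rho)
        rbeta(n(), sh$a, sh$b)
      } else mu)
  })

  counts <- with_stream_seed(config$seed, "counts", {
    is_control <- cond_grid$condition %in% controls
    reps <- config$replicates_per_control
    n_rows <- nrow(cond_grid)
    depth_treat <- rpois(n_rows, config$read_depth)
    rep_depth <- matrix(rpois(n_rows * reps, config$read_depth / reps),
                        nrow = n_rows)
    rep_k <- matrix(rbinom(n_rows * reps, as.vector(rep_depth),
                           rep(cond_grid$psi_cond, times = reps)),
                    nrow = n_rows)
    k_treat <- rbinom(n_rows, depth_treat, cond_grid$psi_cond)
    cond_grid %>%
      mutate(
        n_total = if_else(is_control, as.integer(rowSums(rep_depth)),
                          as.integer(depth_treat)),
        n_inc = if_else(is_control, as.integer(rowSums(rep_k)),
                        as.integer(k_treat)),
        n_exc = n_total - n_inc
      ) %>%
      select(event_id, event_type, cell_type, individual_id,
             condition, n_inc, n_exc)
  })

  ctrl1 <- counts %>%
    filter(condition == "CO1") %>%
    rename(n_inc_ctrl = n_inc, n_exc_ctrl = n_exc) %>%
    select(-condition)

  treat_cmp <- counts %>%
    filter(condition %in% treatments) %>%
    rename(treatment = condition, n_inc_treat = n_inc, n_exc_treat = n_exc) %>%
    inner_join(ctrl1, by = c("event_id", "event_type", "cell_type",
                             "individual_id")) %>%
    mutate(comparison_class = "treatment", control_id = "CO1")

  null_cmp <- counts %>%
    filter(condition %in% setdiff(controls, "CO1")) %>%
    rename(treatment = condition, n_inc_treat = n_inc, n_exc_treat = n_exc) %>%
    inner_join(ctrl1, by = c("event_id", "event_type", "cell_type",
                             "individual_id")) %>%
    mutate(comparison_class = "control", control_id = "CO1")

  comparisons <- bind_rows(treat_cmp, null_cmp) %>%
    arrange(event_type, event_id, cell_type, individual_id, treatment)

  list(annotation = ann, comparisons = comparisons, truth = truth,
       config = config)
}
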