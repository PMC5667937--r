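# End-to-end orchestration of the synthetic-mode pipeline with a
# reproducibility manifest.

#' Quantify all comparisons of a synthetic cohort
#'
#' Runs the comparison stage on a cohort's count table: coverage
#' filters, PSI posteriors, delta-PSI and Bayes factors, then orients
#' delta-PSI using the cohort annotation. Both treatment-vs-control and
#' control-vs-control comparisons are quantified identically.
#'
#' @param cohort Result of [simulate_cohort()] (or a list with
#'   `comparisons` and `annotation` of the same shape).
#' @param prior Beta prior shape parameters (default uniform).
#' @return Comparison tibble with statistics and orientation applied.
#' @export
quantify_cohort <- function(cohort, prior = c(1, 1)) {
  cohort$comparisons %>%
    compare_conditions(prior = prior) %>%
    orient_delta(cohort$annotation)
}

#' Call shifts from quantified comparisons via the empirical null
#'
#' The calibration-and-combination stage: builds one empirical null per
#' event type from the control-vs-control comparisons, converts each
#' treatment comparison's Bayes factor to an empirical p-value and a
#' signed Z, combines individuals by Stouffer's method, and applies BH
#' FDR control per event type.
#'
#' @param comparisons Output of [quantify_cohort()] with a
#'   `comparison_class` column distinguishing `"treatment"` rows from
#'   `"control"` (CO2-vs-CO1) rows.
#' @param fdr Nominal BH threshold (default 0.15).
#' @param min_null Minimum null comparisons per event type (default 500).
#' @param min_individuals Minimum individuals per combined record
#'   (default 2).
#' @return List with `calls` (a [call_shifts()] tibble),
#'   `per_individual` (per-comparison p and Z), and `nulls` (one
#'   [build_null()] object per event type).
#' @export
call_shifts_pipeline <- function(comparisons, fdr = 0.15, min_null = 500,
                                 min_individuals = 2) {
  assert_columns(comparisons, c("comparison_class", "filter_pass", "log_bf",
                                "delta_psi", "event_type"), "`comparisons`")
  null_rows <- comparisons %>% filter(comparison_class == "control", filter_pass)
  nulls <- null_rows %>%
    split(.$event_type) %>%
    purrr::map(~ build_null(.x, min_n = min_null))
  per_individual <- comparisons %>%
    filter(comparison_class == "treatment", filter_pass) %>%
    group_by(event_type) %>%
    mutate(p_emp = empirical_pvalue(log_bf, nulls[[unique(event_type)]]),
           z = signed_z(p_emp, delta_psi)) %>%
    ungroup()
  combined <- combine_individuals(per_individual,
                                  min_individuals = min_individuals)
  calls <- call_shifts(combined, fdr = fdr)
  list(calls = calls, per_individual = per_individual, nulls = nulls)
}

#' Run the synthetic-mode pipeline end to end
#'
#' Wires the stages together: cohort simulation, comparison
#' quantification, empirical-null shift calling, directional global
#' statistics, and (optionally) the direction-prediction, ATAC and QTL
#' validation arms on the same synthetic truth. Every stage's output is
#' digested into a run manifest; re-running with an identical config
#' and seed reproduces identical digests.
#'
#' @param config A [cohort_config()]; its `seed` drives every stage.
#' @param fdr Nominal BH threshold for shift calling (default 0.15).
#' @param stages Character vector of stages to run after the mandatory
#'   cohort/quant/call: any of `"global"`, `"predict"`, `"atac"`,
#'   `"qtl"` (default `"global"`).
#' @param min_null Minimum null comparisons per event type.
#' @return Object of class `shift_pipeline`: list with `manifest`
#'   (tibble: stage, rows, digest), `config`, and one element per
#'   executed stage.
#' @export
run_shift_pipeline <- function(config, fdr = 0.15,
                               stages = "global", min_null = 500) {
  extra <- setdiff(stages, c("global", "predict", "atac", "qtl"))
  if (length(extra) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(extra, collapse = ", ")))
  }
  manifest <- list()
  note <- function(stage, obj, rows) {
    manifest[[stage]] <<- tibble(stage = stage, rows = rows,
                                 digest = rlang::hash(obj))
  }
  cohort <- simulate_cohort(config)
  note("cohort", cohort$comparisons, nrow(cohort$comparisons))
  comparisons <- quantify_cohort(cohort)
  note("quant", comparisons, nrow(comparisons))
  called <- call_shifts_pipeline(comparisons, fdr = fdr, min_null = min_null)
  note("call", as_tibble(called$calls), nrow(called$calls))
  out <- list(cohort = cohort, comparisons = comparisons,
              calls = called$calls, nulls = called$nulls,
              per_individual = called$per_individual)

  if ("global" %in% stages) {
    directions <- summarise_directions(called$calls, min_sig = 10) %>%
      directional_binomial()
    note("global", directions, nrow(directions))
    out$directions <- directions
  }
  afe_dir <- called$calls %>%
    filter(event_type == "AFE", significant, direction != 0) %>%
    select(event_id, direction)
  if ("predict" %in% stages) {
    landscape <- simulate_footprint_landscape(
      cohort$annotation, afe_dir, seed = derive_seed(config$seed, "landscape"))
    feats <- build_afe_features(
      cohort$annotation %>% filter(event_id %in% afe_dir$event_id),
      landscape$footprints)
    fm <- pivot_feature_matrix(feats, value = "diff") %>%
      inner_join(afe_dir, by = "event_id")
    clf <- tryCatch(
      fit_direction_classifier(fm %>% select(-direction),
                               fm$direction,
                               seed = derive_seed(config$seed, "classifier")),
      error = function(e) e$message)
    note("predict", if (is.character(clf)) clf else clf$nonzero,
         if (is.character(clf)) 0L else clf$n_events)
    out$classifier <- clf
    out$landscape <- landscape
  }
  if ("atac" %in% stages) {
    relaxed <- called$calls %>%
      filter(event_type == "AFE", !is.na(q_value), q_value < 0.25,
             direction != 0) %>%
      select(event_id, direction)
    landscape <- out$landscape %||% simulate_footprint_landscape(
      cohort$annotation, relaxed, seed = derive_seed(config$seed, "landscape"))
    fragments <- simulate_atac_fragments(
      cohort$annotation, relaxed, footprints = landscape$footprints,
      causal_motifs = landscape$truth$motif_id[landscape$truth$causal],
      seed = derive_seed(config$seed, "atac"))
    atac <- footprint_accessibility_test(
      fragments, landscape$footprints, cohort$annotation, relaxed)
    note("atac", atac, nrow(atac))
    out$atac <- atac
    out$fragments <- fragments
  }
  if ("qtl" %in% stages) {
    afe_ann <- cohort$annotation %>% filter(event_type == "AFE")
    panel <- simulate_qtl_panel(afe_ann,
                                seed = derive_seed(config$seed, "qtl"))
    norm <- normalize_afe_psi(panel$psi, panel$covariates,
                              min_individuals = min(200, ncol(panel$psi)))
    scan <- afe_qtl_scan(norm$normalized, panel$genotypes, panel$snps, afe_ann)
    enr <- binding_enrichment(scan)
    note("qtl", scan, nrow(scan))
    out$qtl <- list(panel = panel, scan = scan, enrichment = enr)
  }
  out$manifest <- list_rbind(manifest[order(names(manifest))])
  out$config <- config
  structure(out, class = "shift_pipeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shift_pipeline <- function(x, ...) {
  n_sig <- sum(x$calls$significant, na.rm = TRUE)
  cat(sprintf("<shift_pipeline> %d comparisons, %d combined events, %d significant shifts (FDR %.2f)\n",
              nrow(x$comparisons), nrow(x$calls), n_sig,
              attr(x$calls, "nominal_fdr")))
  print(x$manifest)
  invisible(x)
}
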