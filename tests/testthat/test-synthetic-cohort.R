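test_that("config validation enforces the study-design invariants", {
  expect_error(cohort_config(n_controls = 1), "n_controls")
  expect_error(cohort_config(pi_pos = 1.2), "Fractions")
  expect_error(cohort_config(effect_fraction = -0.1), "Fractions")
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(event_types = "XX"), "Unknown event type")
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- cohort_config(n_events_per_type = 30, event_types = c("SE", "AFE"),
                       seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$comparisons, b$comparisons)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation, b$annotation)
})

test_that("zero effect fraction plants no shifts", {
  cfg <- cohort_config(n_events_per_type = 40, event_types = "SE",
                       effect_fraction = 0, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_false(any(coh$truth$true_shift))
  expect_true(all(coh$truth$true_delta == 0))
})

test_that("directional bias of planted shifts matches pi_pos", {
  cfg <- cohort_config(n_events_per_type = 400, event_types = c("SE", "RI"),
                       effect_fraction = 0.3, pi_pos = 0.9, seed = 21)
  coh <- simulate_cohort(cfg)
  shifts <- dplyr::filter(coh$truth, true_shift)
  k <- sum(shifts$true_direction > 0)
  n <- nrow(shifts)
  bounds <- qbinom(c(0.005, 0.995), n, 0.9)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("baseline PSI moments match the configured Beta law", {
  cfg <- cohort_config(n_events_per_type = 5000, event_types = "SE",
                       effect_fraction = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  # recover the per-event baseline from pooled CO1 control counts
  psi_hat <- coh$comparisons %>%
    dplyr::group_by(event_id) %>%
    dplyr::summarise(psi = sum(n_inc_ctrl) / sum(n_inc_ctrl + n_exc_ctrl))
  # Beta(2,2) mapped to [0.05, 0.95]: mean 0.5, var 0.9^2/20
  expect_equal(mean(psi_hat$psi), 0.5, tolerance = 0.01)
  expect_equal(sd(psi_hat$psi), sqrt(0.81 / 20), tolerance = 0.05)
})

test_that("comparison tables carry both treatment and null comparisons", {
  cfg <- cohort_config(n_events_per_type = 20, event_types = "SE", seed = 2)
  coh <- simulate_cohort(cfg)
  counts <- dplyr::count(coh$comparisons, comparison_class)
  expect_setequal(counts$comparison_class, c("treatment", "control"))
  # 20 events x 3 individuals for each class (1 treatment, CO2-vs-CO1)
  expect_equal(counts$n, c(60, 60))
})

test_that("planted footprint coupling links count differences to direction", {
  cfg <- cohort_config(n_events_per_type = 150, event_types = "AFE", seed = 31)
  coh <- simulate_cohort(cfg)
  dir <- coh$truth %>%
    dplyr::filter(true_direction != 0) %>%
    dplyr::transmute(event_id, direction = true_direction)
  # maximal coupling: the causal difference sign matches direction
  land <- simulate_footprint_landscape(coh$annotation, dir, n_motifs = 10,
                                       n_causal = 1, coupling = 1, seed = 7)
  feats <- build_afe_features(coh$annotation, land$footprints) %>%
    dplyr::filter(motif_id == "M001") %>%
    dplyr::inner_join(dir, by = "event_id")
  agree <- mean(sign(feats$diff) == feats$direction)
  expect_gte(agree, 0.95)
  # zero coupling: no association between difference sign and direction
  land0 <- simulate_footprint_landscape(coh$annotation, dir, n_motifs = 10,
                                        n_causal = 1, coupling = 0, seed = 7)
  feats0 <- build_afe_features(coh$annotation, land0$footprints) %>%
    dplyr::filter(motif_id == "M001") %>%
    dplyr::inner_join(dir, by = "event_id") %>%
    dplyr::filter(diff != 0)
  tab <- table(feats0$diff > 0, feats0$direction > 0)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
  # no AFE events -> empty landscape
  empty <- simulate_footprint_landscape(
    coh$annotation[0, ], dir, n_motifs = 5, seed = 1)
  expect_equal(nrow(empty$footprints), 0)
})

test_that("ATAC fragments are seeded, well-formed and span the length bins", {
  cfg <- cohort_config(n_events_per_type = 30, event_types = "AFE", seed = 41)
  coh <- simulate_cohort(cfg)
  dir <- coh$truth %>% dplyr::filter(true_direction != 0) %>%
    dplyr::transmute(event_id, direction = true_direction)
  fr1 <- simulate_atac_fragments(coh$annotation, dir, seed = 11)
  fr2 <- simulate_atac_fragments(coh$annotation, dir, seed = 11)
  expect_identical(fr1, fr2)
  expect_true(all(fr1$start < fr1$end))
  expect_true(all(fr1$length >= 39 & fr1$length <= 250))
  expect_setequal(unique(fr1$condition), c("treatment", "control"))
})

test_that("a null QTL panel yields uniform scan p-values", {
  cfg <- cohort_config(n_events_per_type = 40, event_types = "AFE", seed = 51)
  coh <- simulate_cohort(cfg)
  afe_ann <- dplyr::filter(coh$annotation, event_type == "AFE")
  panel <- simulate_qtl_panel(afe_ann, n_individuals = 250,
                              p_qtl_nonbinding = 0, binding_odds = 1,
                              seed = 3)
  expect_true(all(panel$snps$true_beta == 0))
  expect_true(all(panel$genotypes %in% 0:2))
  norm <- normalize_afe_psi(panel$psi, panel$covariates,
                            min_individuals = 150)
  scan <- afe_qtl_scan(norm$normalized, panel$genotypes, panel$snps, afe_ann)
  expect_gt(stats::ks.test(scan$p_value, "punif")$p.value, 0.01)
})

test_that("dosage and PSI matrices are consistent with planted effects", {
  cfg <- cohort_config(n_events_per_type = 25, event_types = "AFE", seed = 61)
  coh <- simulate_cohort(cfg)
  afe_ann <- dplyr::filter(coh$annotation, event_type == "AFE")
  panel <- simulate_qtl_panel(afe_ann, n_individuals = 300,
                              p_qtl_nonbinding = 0.5, binding_odds = 1,
                              noise_sd = 0.4, seed = 9)
  norm <- normalize_afe_psi(panel$psi, panel$covariates,
                            min_individuals = 150)
  scan <- afe_qtl_scan(norm$normalized, panel$genotypes, panel$snps, afe_ann)
  j <- dplyr::inner_join(scan, panel$snps, by = c("snp_id", "event_id"))
  strong <- dplyr::filter(j, abs(true_beta) > 0.4)
  null_snps <- dplyr::filter(j, true_beta == 0)
  # effect carriers score far lower p than null SNPs on average
  expect_gt(mean(-log10(strong$p_value)), mean(-log10(null_snps$p_value)))
  # planted effect signs are recovered for clearly significant SNPs
  hits <- dplyr::filter(strong, p_value < 1e-4)
  expect_true(nrow(hits) > 0)
  expect_true(all(sign(hits$beta) == sign(hits$true_beta)))
})
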