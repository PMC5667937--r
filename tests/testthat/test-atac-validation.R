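test_that("Tn5 insertion arithmetic and fragment-length bins", {
  fr <- tibble::tibble(chrom = "chr1", start = c(1000, 500, 2000, 100),
                       end = c(1100, 538, 2007, 350))
  out <- insertion_sites(fr)
  expect_equal(attr(out, "n_skipped"), 1)  # the 7 bp fragment
  f1 <- dplyr::filter(out, start == 1000)
  expect_equal(f1$site_left, 1004)
  expect_equal(f1$site_right, 1095)
  expect_equal(f1$length_bin, "100-139")
  expect_true(is.na(dplyr::filter(out, start == 500)$length_bin))  # 38 bp
  expect_equal(dplyr::filter(out, start == 100)$length_bin, "180-250")
  expect_error(insertion_sites(tibble::tibble(chrom = "c", start = 5, end = 5)),
               "start < end")
})

test_that("insertion sites are invariant under mate-label swap", {
  # swapping mates reverses which end is 'left', but the site pair is
  # a function of the fragment interval only
  fr <- tibble::tibble(chrom = "chr1", start = 3000, end = 3120)
  out <- insertion_sites(fr)
  expect_equal(sort(c(out$site_left, out$site_right)),
               sort(c(3000 + 4, 3120 - 1 - 4)))
})

atac_fixture <- function(seed = 1, tss_depletion = c(preferred = 0,
                                                     nonpreferred = 0),
                         n_events = 40, ...) {
  cfg <- cohort_config(n_events_per_type = n_events, event_types = "AFE",
                       seed = seed)
  coh <- simulate_cohort(cfg)
  dir <- coh$truth %>% dplyr::filter(true_direction != 0) %>%
    dplyr::transmute(event_id, direction = true_direction)
  frag <- simulate_atac_fragments(coh$annotation, dir,
                                  tss_depletion = tss_depletion,
                                  seed = seed + 1, ...)
  list(coh = coh, dir = dir, frag = frag)
}

test_that("TSS profiles are normalized and additive", {
  fx <- atac_fixture(seed = 71)
  prof <- tss_accessibility_profile(fx$frag, fx$coh$annotation, fx$dir)
  expect_setequal(unique(prof$tss_class), c("preferred", "nonpreferred"))
  expect_equal(nrow(prof), 2 * 2 * 1001)

  # normalization invariance: duplicating every fragment changes nothing
  prof2 <- tss_accessibility_profile(dplyr::bind_rows(fx$frag, fx$frag),
                                     fx$coh$annotation, fx$dir)
  expect_equal(prof$norm_coverage, prof2$norm_coverage, tolerance = 1e-12)

  # additivity of raw coverage over disjoint fragment subsets
  idx <- seq_len(nrow(fx$frag)) %% 2 == 0
  pa <- tss_accessibility_profile(fx$frag[idx, ], fx$coh$annotation, fx$dir)
  pb <- tss_accessibility_profile(fx$frag[!idx, ], fx$coh$annotation, fx$dir)
  joined <- prof %>%
    dplyr::left_join(pa, by = c("tss_class", "condition", "rel_pos"),
                     suffix = c("", "_a")) %>%
    dplyr::left_join(pb, by = c("tss_class", "condition", "rel_pos"),
                     suffix = c("", "_b"))
  expect_equal(joined$coverage,
               dplyr::coalesce(joined$coverage_a, 0) +
                 dplyr::coalesce(joined$coverage_b, 0))

  # no planted depletion: treatment/control ratio ~ 1 in the window core
  core <- prof %>%
    dplyr::filter(abs(rel_pos) < 300) %>%
    dplyr::group_by(tss_class, condition) %>%
    dplyr::summarise(m = mean(norm_coverage), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = condition, values_from = m)
  expect_equal(core$treatment / core$control, rep(1, 2), tolerance = 0.1)
})

test_that("a planted 40% depletion shows up as a 0.5-0.7 center ratio", {
  fx <- atac_fixture(seed = 73, n_events = 100, frag_rate_tss = 400,
                     tss_depletion = c(preferred = 0.4, nonpreferred = 0))
  # totals are dominated by the TSS background, so normalization does
  # not cancel the planted effect here
  prof <- tss_accessibility_profile(fx$frag, fx$coh$annotation, fx$dir)
  center <- prof %>%
    dplyr::filter(abs(rel_pos) <= 100, tss_class == "preferred") %>%
    dplyr::group_by(condition) %>%
    dplyr::summarise(m = mean(coverage), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = condition, values_from = m)
  ratio <- center$treatment / center$control
  expect_gte(ratio, 0.5)
  expect_lte(ratio, 0.7)
})

test_that("no qualifying AFE events yields empty profiles with a warning", {
  fx <- atac_fixture(seed = 75)
  expect_warning(
    prof <- tss_accessibility_profile(
      fx$frag, fx$coh$annotation,
      tibble::tibble(event_id = character(), direction = numeric())),
    "No qualifying")
  expect_equal(nrow(prof), 0)
})

test_that("footprint accessibility t-test edge cases", {
  fx <- atac_fixture(seed = 77)
  land <- simulate_footprint_landscape(fx$coh$annotation, fx$dir,
                                       n_motifs = 4, n_causal = 0, seed = 3)
  res <- footprint_accessibility_test(fx$frag, land$footprints,
                                      fx$coh$annotation, fx$dir)
  expect_true(all(c("t_stat", "p_value", "q_value") %in% names(res)))
  # motif with one footprint in a class is skipped with a note
  tss1 <- afe_tss(fx$coh$annotation) %>%
    dplyr::semi_join(fx$dir, by = "event_id") %>% dplyr::slice(1)
  one_fp <- tibble::tibble(chrom = tss1$chrom,
                           start = tss1$tss_upstream - 6,
                           end = tss1$tss_upstream + 6,
                           motif_id = "RARE", posterior = 1, strand = ".")
  res2 <- footprint_accessibility_test(
    fx$frag, dplyr::bind_rows(land$footprints, one_fp),
    fx$coh$annotation, fx$dir)
  expect_match(res2$note[res2$motif_id == "RARE"], "fewer than 2")
})

test_that("the ratio t statistic is scale-invariant", {
  # multiplying all ratios by a positive constant rescales means and
  # SDs together, leaving t unchanged; verified through the library
  # totals: scaling one library's total scales every ratio by the same
  # constant
  fx <- atac_fixture(seed = 79)
  land <- simulate_footprint_landscape(fx$coh$annotation, fx$dir,
                                       n_motifs = 3, n_causal = 0, seed = 5)
  r1 <- footprint_accessibility_test(fx$frag, land$footprints,
                                     fx$coh$annotation, fx$dir)
  # duplicate only control fragments: control totals double, halving
  # every treatment/control ratio by the same factor
  ctrl <- dplyr::filter(fx$frag, condition == "control")
  shifted <- dplyr::bind_rows(
    fx$frag,
    dplyr::mutate(ctrl, chrom = "chrUnmapped")  # contribute to totals only
  )
  r2 <- footprint_accessibility_test(shifted, land$footprints,
                                     fx$coh$annotation, fx$dir)
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})
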