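# ATAC-seq validation of the chromatin-accessibility mechanism behind
# AFE shifts: Tn5 insertion arithmetic, TSS accessibility profiles, and
# per-motif footprint accessibility ratio tests.

#' Tn5 insertion sites and fragment-length bins
#'
#' Each ATAC fragment carries two transposase insertion sites, one per
#' mate, located 4 bp inside the fragment from each 5' end (in that
#' mate's 5'-to-3' direction): left site `start + 4`, right site
#' `end - 1 - 4` (0-based). Fragments shorter than 9 bp would have
#' crossing sites and are skipped (counted in attribute `n_skipped`).
#' Fragment lengths are binned into the four accessibility bins
#' 39-99, 100-139, 140-179, 180-250; lengths outside fall in no bin.
#'
#' @param fragments Tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Input tibble with `length`, `site_left`, `site_right` and
#'   `length_bin` appended; attribute `n_skipped` gives the number of
#'   dropped short fragments.
#' @export
insertion_sites <- function(fragments) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  fragments <- fragments %>% as_tibble() %>%
    mutate(length = end - start)
  if (any(fragments$length <= 0)) abort("Fragments must satisfy start < end.")
  short <- fragments$length < 9
  out <- fragments[!short, ] %>%
    mutate(
      site_left = start + 4,
      site_right = end - 1 - 4,
      length_bin = case_when(
        length >= 39 & length <= 99 ~ "39-99",
        length >= 100 & length <= 139 ~ "100-139",
        length >= 140 & length <= 179 ~ "140-179",
        length >= 180 & length <= 250 ~ "180-250",
        TRUE ~ NA_character_
      )
    )
  attr(out, "n_skipped") <- sum(short)
  out
}

#' Classify AFE TSSs as treatment-preferred or not
#'
#' Expands each directed AFE event into its two TSSs, labelled
#' `preferred` (the TSS the shift moves toward under treatment, +1 =
#' upstream) and `nonpreferred`.
#'
#' @param annotation AFE annotation.
#' @param direction Tibble with `event_id`, `direction` in \{-1, 1\}
#'   (0 rows are dropped).
#' @return Tibble with `event_id`, `chrom`, `tss_class`, `center`.
#' @export
tss_classes <- function(annotation, direction) {
  afe_tss(annotation) %>%
    inner_join(direction, by = "event_id") %>%
    filter(direction != 0) %>%
    mutate(
      preferred = if_else(direction > 0, tss_upstream, tss_downstream),
      nonpreferred = if_else(direction > 0, tss_downstream, tss_upstream)
    ) %>%
    tidyr::pivot_longer(c(preferred, nonpreferred),
                        names_to = "tss_class", values_to = "center") %>%
    select(event_id, chrom, tss_class, center)
}

#' Chromatin-accessibility profiles around preferred and other TSSs
#'
#' Per-bp fragment coverage within +/-`window` bp of each AFE TSS,
#' summed over events separately for the treatment-preferred TSS class
#' and the non-preferred class, per condition, and normalized to the
#' total number of fragments in each library (so doubling every count
#' and the library total leaves the profile unchanged). Only fragments
#' in the open-chromatin length range (default 30-140 bp) contribute
#' coverage; the library total counts all fragments.
#'
#' @param fragments Fragment tibble with `chrom`, `start`, `end`,
#'   `condition`, `library_id`.
#' @param annotation AFE annotation.
#' @param direction Tibble `event_id`, `direction` (+1 = upstream TSS
#'   preferred; the qualifying call set, e.g. shifts at a relaxed
#'   q < 0.25).
#' @param window Half-window around each TSS (default 500).
#' @param length_range Fragment lengths contributing coverage
#'   (default c(30, 140)).
#' @return Tibble with `tss_class`, `condition`, `rel_pos`
#'   (-window..window), `coverage`, `norm_coverage`. Empty (with a
#'   warning) when no qualifying events exist.
#' @export
tss_accessibility_profile <- function(fragments, annotation, direction,
                                      window = 500,
                                      length_range = c(30, 140)) {
  assert_columns(fragments, c("chrom", "start", "end", "condition",
                              "library_id"), "`fragments`")
  centers <- tss_classes(annotation, direction)
  empty <- tibble(tss_class = character(), condition = character(),
                  rel_pos = integer(), coverage = numeric(),
                  norm_coverage = numeric())
  if (nrow(centers) == 0) {
    warn("No qualifying AFE events; returning empty profiles.")
    return(empty)
  }
  lib_totals <- fragments %>% count(condition, name = "lib_total")
  frag <- fragments %>%
    mutate(flen = end - start) %>%
    filter(flen >= length_range[1], flen <= length_range[2])
  pairs <- frag %>%
    inner_join(centers, by = "chrom", relationship = "many-to-many") %>%
    filter(start < center + window + 1, end > center - window)
  if (nrow(pairs) == 0) {
    warn("No fragments overlap any TSS window; returning empty profiles.")
    return(empty)
  }
  # Per-bp coverage via difference arrays over the relative window.
  width <- 2 * window + 1
  pairs <- pairs %>%
    mutate(
      lo = pmax(start - (center - window), 0),
      hi = pmin(end - (center - window), width)
    )
  prof <- pairs %>%
    group_by(tss_class, condition) %>%
    dplyr::reframe({
      d <- numeric(width + 1)
      for (j in seq_along(lo)) {
        d[lo[j] + 1] <- d[lo[j] + 1] + 1
        d[hi[j] + 1] <- d[hi[j] + 1] - 1
      }
      tibble(rel_pos = seq(-window, window), coverage = cumsum(d)[seq_len(width)])
    })
  prof %>%
    left_join(lib_totals, by = "condition") %>%
    mutate(norm_coverage = coverage / lib_total) %>%
    select(tss_class, condition, rel_pos, coverage, norm_coverage)
}

#' Per-motif footprint accessibility ratio test
#'
#' For each footprint within `tss_window` bp of a preferred or
#' non-preferred TSS, counts fragments overlapping the footprint's
#' +/-`count_window` bp window in each condition (any overlap), adds a
#' pseudocount to both conditions, normalizes by library totals, and
#' forms the treatment/control accessibility ratio. Per motif, a
#' two-tailed two-sample t-test (Welch by default; pooled-variance via
#' `var_equal = TRUE`) compares ratios at preferred-TSS footprints
#' against non-preferred-TSS footprints, with BH correction across
#' motifs.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`,
#'   `condition`).
#' @param footprints Footprint tibble (`chrom`, `start`, `end`,
#'   `motif_id`).
#' @param annotation AFE annotation.
#' @param direction Tibble `event_id`, `direction`.
#' @param tss_window Footprint-to-TSS assignment window (default 500).
#' @param count_window Fragment counting half-window around the
#'   footprint (default 100).
#' @param pseudocount Added to both condition counts (default 1).
#' @param var_equal Use pooled-variance Student's t (default FALSE =
#'   Welch).
#' @param fdr BH significance threshold (default 0.05).
#' @return Tibble with one row per testable motif: footprint counts per
#'   class, mean ratios, `t_stat`, `p_value`, `q_value`, `significant`,
#'   `note`; motifs with fewer than 2 footprints in either class are
#'   reported with a `note` and no test.
#' @export
footprint_accessibility_test <- function(fragments, footprints, annotation,
                                         direction, tss_window = 500,
                                         count_window = 100,
                                         pseudocount = 1,
                                         var_equal = FALSE, fdr = 0.05) {
  assert_columns(footprints, c("chrom", "start", "end", "motif_id"),
                 "`footprints`")
  centers <- tss_classes(annotation, direction)
  fp <- footprints %>%
    mutate(fp_mid = floor((start + end) / 2),
           fp_id = row_number()) %>%
    inner_join(centers, by = "chrom", relationship = "many-to-many") %>%
    filter(abs(fp_mid - center) <= tss_window) %>%
    distinct(fp_id, motif_id, chrom, start, end, tss_class)
  lib_totals <- fragments %>% count(condition, name = "lib_total")
  if (nrow(lib_totals) < 2) abort("Need fragments for both conditions.")
  counts <- fp %>%
    mutate(w_start = start - count_window, w_end = end + count_window) %>%
    inner_join(fragments, by = join_by(chrom, w_start < end, w_end > start),
               relationship = "many-to-many", suffix = c("_fp", "")) %>%
    count(fp_id, motif_id, tss_class, condition)
  ratios <- fp %>%
    select(fp_id, motif_id, tss_class) %>%
    tidyr::expand_grid(condition = lib_totals$condition) %>%
    left_join(counts, by = c("fp_id", "motif_id", "tss_class", "condition")) %>%
    mutate(n = dplyr::coalesce(n, 0L)) %>%
    left_join(lib_totals, by = "condition") %>%
    mutate(norm = (n + pseudocount) / lib_total) %>%
    select(fp_id, motif_id, tss_class, condition, norm) %>%
    tidyr::pivot_wider(names_from = condition, values_from = norm) %>%
    mutate(ratio = treatment / control)
  res <- ratios %>%
    group_by(motif_id) %>%
    summarise(
      n_preferred = sum(tss_class == "preferred"),
      n_nonpreferred = sum(tss_class == "nonpreferred"),
      mean_ratio_preferred = mean(ratio[tss_class == "preferred"]),
      mean_ratio_nonpreferred = mean(ratio[tss_class == "nonpreferred"]),
      t_stat = NA_real_, p_value = NA_real_, note = NA_character_,
      .groups = "drop"
    )
  for (i in seq_len(nrow(res))) {
    m <- res$motif_id[i]
    rp <- ratios$ratio[ratios$motif_id == m & ratios$tss_class == "preferred"]
    rn <- ratios$ratio[ratios$motif_id == m & ratios$tss_class == "nonpreferred"]
    if (length(rp) < 2 || length(rn) < 2) {
      res$note[i] <- "fewer than 2 footprints in a class"
      next
    }
    if (sd(rp) == 0 && sd(rn) == 0) {
      res$t_stat[i] <- 0
      res$p_value[i] <- 1
      res$note[i] <- "degenerate variance"
      next
    }
    tt <- t.test(rp, rn, var.equal = var_equal)
    res$t_stat[i] <- unname(tt$statistic)
    res$p_value[i] <- tt$p.value
  }
  res %>%
    mutate(q_value = {
      q <- rep(NA_real_, n())
      ok <- !is.na(p_value)
      q[ok] <- p.adjust(p_value[ok], method = "BH")
      q
    },
    significant = !is.na(q_value) & q_value < fdr)
}
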