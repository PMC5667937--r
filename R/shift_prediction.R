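#' Motif-region indicator features for SE and RI events
#'
#' Splits each event into five regions defined on the transcribed
#' strand and records, per motif, whether at least one same-strand
#' motif hit overlaps each region. For skipped exons the regions are:
#' the upstream intron, the skipped exon, the downstream intron, and
#' the 100 bp windows upstream and downstream of the 3' splice site.
#' For retained introns: the upstream exon, the intron, the downstream
#' exon, and the 100 bp windows upstream and downstream of the 5'
#' splice site. All windows are half-open; a hit straddling a region
#' boundary sets both adjacent indicators.
#'
#' @param events Annotation rows of the given type with flanking exon
#'   blocks (`flank_up_start/end`, `flank_down_start/end`) and the
#'   alternative unit in `iso1_start/end`; events missing flanking
#'   annotation are excluded with a reason.
#' @param motif_hits Tibble of strand-annotated intervals: `chrom`,
#'   `start`, `end`, `motif_id`, `strand`.
#' @param event_type `"SE"` or `"RI"`.
#' @return List with `features` (tibble: `event_id`, `motif_id`,
#'   `region`, `value` = 0/1 in long form) and `excluded` (tibble of
#'   `event_id`, `reason`).
#' @export
build_se_ri_features <- function(events, motif_hits, event_type = c("SE", "RI")) {
  event_type <- match.arg(event_type)
  assert_columns(events, c("event_id", "chrom", "strand",
                           "iso1_start", "iso1_end",
                           "flank_up_start", "flank_up_end",
                           "flank_down_start", "flank_down_end"), "`events`")
  assert_columns(motif_hits, c("chrom", "start", "end", "motif_id", "strand"),
                 "`motif_hits`")
  ok <- complete.cases(events[, c("flank_up_start", "flank_up_end",
                                  "flank_down_start", "flank_down_end")])
  excluded <- tibble(event_id = events$event_id[!ok],
                     reason = "missing flanking-exon annotation")
  ev <- events[ok, ]
  regions <- purrr::map(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    plus <- e$strand == "+"
    # genomic blocks; "upstream"/"downstream" are transcribed-strand
    up_flank <- c(e$flank_up_start, e$flank_up_end)
    down_flank <- c(e$flank_down_start, e$flank_down_end)
    if (!plus) { tmp <- up_flank; up_flank <- down_flank; down_flank <- tmp }
    unit <- c(e$iso1_start, e$iso1_end)
    if (event_type == "SE") {
      # introns flank the skipped exon
      up_intron <- if (plus) c(up_flank[2], unit[1]) else c(unit[2], up_flank[1])
      down_intron <- if (plus) c(unit[2], down_flank[1]) else c(down_flank[2], unit[1])
      # 3' splice site = acceptor of the skipped exon (transcribed)
      ss3 <- if (plus) unit[1] else unit[2]
      w_up <- if (plus) c(ss3 - 100, ss3) else c(ss3, ss3 + 100)
      w_down <- if (plus) c(ss3, ss3 + 100) else c(ss3 - 100, ss3)
      tibble(
        event_id = e$event_id, chrom = e$chrom, strand = e$strand,
        region = c("upstream_intron", "alt_unit", "downstream_intron",
                   "ss_upstream_100", "ss_downstream_100"),
        r_start = c(up_intron[1], unit[1], down_intron[1], w_up[1], w_down[1]),
        r_end = c(up_intron[2], unit[2], down_intron[2], w_up[2], w_down[2])
      )
    } else {
      # RI: regions are the flanking exons and the intron itself;
      # 5' splice site = donor at the intron's transcribed start
      ss5 <- if (plus) unit[1] else unit[2]
      w_up <- if (plus) c(ss5 - 100, ss5) else c(ss5, ss5 + 100)
      w_down <- if (plus) c(ss5, ss5 + 100) else c(ss5 - 100, ss5)
      tibble(
        event_id = e$event_id, chrom = e$chrom, strand = e$strand,
        region = c("upstream_exon", "alt_unit", "downstream_exon",
                   "ss_upstream_100", "ss_downstream_100"),
        r_start = c(up_flank[1], unit[1], down_flank[1], w_up[1], w_down[1]),
        r_end = c(up_flank[2], unit[2], down_flank[2], w_up[2], w_down[2])
      )
    }
  }) %>% list_rbind()
  motifs <- unique(motif_hits$motif_id)
  hits <- regions %>%
    inner_join(motif_hits, by = join_by(chrom, strand,
                                        r_start < end, r_end > start),
               relationship = "many-to-many") %>%
    distinct(event_id, motif_id, region) %>%
    mutate(value = 1)
  features <- tidyr::expand_grid(
    event_id = ev$event_id,
    motif_id = motifs,
    region = unique(regions$region)
  ) %>%
    left_join(hits, by = c("event_id", "motif_id", "region")) %>%
    mutate(value = dplyr::coalesce(value, 0))
  list(features = features, excluded = excluded)
}

#' Footprint-imbalance features for AFE events
#'
#' For each AFE event and motif, counts footprints whose midpoint lies
#' within 1000 bp (closed interval, either direction) of each TSS and
#' returns the signed difference: footprints near the upstream TSS
#' minus footprints near the downstream TSS, upstream defined on the
#' transcribed strand. Overlapping TSS windows double-count by design.
#'
#' @param afe_events Annotation rows of type AFE.
#' @param footprints Footprint tibble (`chrom`, `start`, `end`,
#'   `motif_id`).
#' @param window Half-width of the TSS window in bp (default 1000).
#' @return Tibble with `event_id`, `motif_id`, `n_upstream`,
#'   `n_downstream`, `diff`.
#' @export
build_afe_features <- function(afe_events, footprints, window = 1000) {
  tss <- afe_tss(afe_events)
  assert_columns(footprints, c("chrom", "start", "end", "motif_id"),
                 "`footprints`")
  motifs <- unique(footprints$motif_id)
  fp <- footprints %>% mutate(mid = floor((start + end) / 2))
  count_near <- function(pos_col) {
    tss %>%
      select(event_id, chrom, center = all_of(pos_col)) %>%
      inner_join(fp, by = "chrom", relationship = "many-to-many") %>%
      filter(abs(mid - center) <= window) %>%
      count(event_id, motif_id)
  }
  n_up <- count_near("tss_upstream") %>% rename(n_upstream = n)
  n_down <- count_near("tss_downstream") %>% rename(n_downstream = n)
  tidyr::expand_grid(event_id = tss$event_id, motif_id = motifs) %>%
    left_join(n_up, by = c("event_id", "motif_id")) %>%
    left_join(n_down, by = c("event_id", "motif_id")) %>%
    mutate(n_upstream = dplyr::coalesce(n_upstream, 0L),
           n_downstream = dplyr::coalesce(n_downstream, 0L),
           diff = n_upstream - n_downstream)
}

#' Elastic-net classifier of shift direction
#'
#' Fits a logistic elastic-net regularization path to predict the sign
#' of the oriented delta-PSI of significant shifts from feature
#' columns, with stratified seeded cross-validation measuring AUC along
#' the path. The reported model uses `lambda.1se`, the largest penalty
#' whose cross-validated AUC is within one standard error of the
#' maximum, favouring sparser models.
#'
#' Mirrors the inclusion rule of the analysis it implements: at least
#' `min_events` labelled events (default 100) are required, and both
#' direction classes must be present.
#'
#' @param features Wide tibble or matrix: one row per event, one column
#'   per feature (an `event_id` column, if present, is dropped).
#' @param labels Direction labels (+1/-1, TRUE/FALSE, or a factor with
#'   two levels); zero labels are not allowed.
#' @param cv_folds Number of CV folds (default 10).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Integer seed controlling fold assignment.
#' @param min_events Minimum number of events (default 100).
#' @return Object of class `direction_classifier`: list with `fit`
#'   (the cv.glmnet object), `cv_auc` (AUC at lambda.1se),
#'   `cv_auc_max` (AUC at lambda of maximal AUC), `lambda_1se`,
#'   `lambda_max_auc`, `nonzero` (tibble of nonzero coefficients at
#'   lambda.1se), `n_events`.
#' @export
fit_direction_classifier <- function(features, labels, cv_folds = 10,
                                     alpha = 0.5, seed = 1L,
                                     min_events = 100) {
  x <- features
  if (is.data.frame(x)) {
    x <- x %>% select(-dplyr::any_of("event_id"))
    x <- as.matrix(x)
  }
  y <- labels
  if (is.numeric(y)) {
    if (any(y == 0)) abort("Zero-direction labels are not allowed.")
    y <- factor(if_else(y > 0, "pos", "neg"), levels = c("neg", "pos"))
  } else {
    y <- as.factor(y)
  }
  if (nrow(x) != length(y)) abort("`features` and `labels` differ in length.")
  if (nrow(x) < min_events) {
    abort(sprintf("Only %d events; at least %d required for direction prediction.",
                  nrow(x), min_events))
  }
  if (nlevels(droplevels(y)) < 2) abort("Both direction classes must be present.")
  foldid <- with_stream_seed(seed, "cv_folds", {
    id <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      id[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    id
  })
  cv <- with_stream_seed(seed, "glmnet", {
    glmnet::cv.glmnet(x, y, family = "binomial", type.measure = "auc",
                      alpha = alpha, foldid = foldid)
  })
  i1se <- which(cv$lambda == cv$lambda.1se)
  imax <- which.max(cv$cvm)
  cf <- coef(cv, s = "lambda.1se")
  nz <- which(as.numeric(cf) != 0 & rownames(cf) != "(Intercept)")
  nonzero <- tibble(feature = rownames(cf)[nz], coefficient = as.numeric(cf)[nz])
  structure(list(
    fit = cv,
    cv_auc = cv$cvm[i1se],
    cv_auc_max = cv$cvm[imax],
    lambda_1se = cv$lambda.1se,
    lambda_max_auc = cv$lambda[imax],
    nonzero = nonzero,
    n_events = nrow(x),
    alpha = alpha
  ), class = "direction_classifier")
}

#' @export
print.direction_classifier <- function(x, ...) {
  cat(sprintf("<direction_classifier> n = %d, CV AUC at lambda.1se = %.3f (max %.3f), %d nonzero coefficients\n",
              x$n_events, x$cv_auc, x$cv_auc_max, nrow(x$nonzero)))
  invisible(x)
}

#' Pivot long feature tables to a model matrix
#'
#' Helper turning the long outputs of [build_se_ri_features()] and
#' [build_afe_features()] into one-row-per-event wide matrices for
#' [fit_direction_classifier()].
#'
#' @param features Long tibble with `event_id`, feature key columns,
#'   and a value column.
#' @param value Name of the value column (`"value"` for region
#'   indicators, `"diff"` for footprint differences).
#' @return Wide tibble with `event_id` first.
#' @export
pivot_feature_matrix <- function(features, value = c("value", "diff")) {
  value <- match.arg(value)
  keys <- setdiff(names(features),
                  c("event_id", value, "n_upstream", "n_downstream"))
  features %>%
    tidyr::unite("feature", all_of(keys), sep = ":") %>%
    select(event_id, feature, !!rlang::sym(value)) %>%
    tidyr::pivot_wider(names_from = feature,
                       values_from = !!rlang::sym(value),
                       values_fill = 0)
}
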