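# Genetic validation arm: AFE PSI normalization across individuals,
# cis linear-model QTL scan over footprint SNPs, and Fisher enrichment
# of binding-disrupting SNPs among QTLs.

#' Normalize an AFE PSI matrix across individuals
#'
#' Per event (rows), removes the effect of the lab and population
#' covariates and of the first `n_pcs` principal components of the
#' covariate-residualized, mean-imputed PSI matrix, then applies
#' rank-based inverse-normal quantile normalization across the
#' individuals in which the event was observed (offset
#' `(rank - 0.5)/n`). Imputation is used only to extract PCs, never for
#' association. Events observed in fewer than `min_individuals`
#' individuals are dropped.
#'
#' @param psi Numeric matrix, events x individuals, `NA` where an
#'   event could not be measured; PSI values in [0, 1].
#' @param covariates Tibble with `individual_id` (matching `colnames(psi)`),
#'   `lab`, `population`.
#' @param n_pcs Number of phenotype principal components to remove
#'   (default 5).
#' @param min_individuals Minimum observed individuals per event
#'   (default 200).
#' @return List with `normalized` (matrix, same shape, `NA` preserved),
#'   `kept_events`, `dropped_events`, and `pcs` (individuals x
#'   `n_pcs` scores).
#' @export
normalize_afe_psi <- function(psi, covariates, n_pcs = 5,
                              min_individuals = 200) {
  if (!is.matrix(psi)) abort("`psi` must be an events x individuals matrix.")
  assert_columns(covariates, c("individual_id", "lab", "population"),
                 "`covariates`")
  if (!setequal(colnames(psi), covariates$individual_id)) {
    abort("`covariates$individual_id` must match `colnames(psi)`.")
  }
  covariates <- covariates[match(colnames(psi), covariates$individual_id), ]
  n_obs <- rowSums(!is.na(psi))
  keep <- n_obs >= min_individuals
  dropped <- rownames(psi)[!keep]
  psi <- psi[keep, , drop = FALSE]
  if (nrow(psi) == 0) abort("No events pass the minimum-individuals rule.")

  cov_df <- data.frame(lab = factor(covariates$lab),
                       population = factor(covariates$population))
  keep_terms <- vapply(cov_df, function(v) nlevels(v) > 1, logical(1))
  if (!all(keep_terms)) {
    warn(sprintf("Covariate(s) constant and dropped: %s",
                 paste(names(cov_df)[!keep_terms], collapse = ", ")))
  }
  mm <- if (any(keep_terms)) {
    model.matrix(~ ., cov_df[, keep_terms, drop = FALSE])
  } else {
    matrix(1, nrow(cov_df), 1)
  }

  # Per-event residual on covariates over observed individuals.
  resid_mat <- psi
  for (i in seq_len(nrow(psi))) {
    obs <- !is.na(psi[i, ])
    f <- stats::lm.fit(mm[obs, , drop = FALSE], psi[i, obs])
    resid_mat[i, obs] <- f$residuals
  }
  # PCs of the mean-imputed residual matrix (individuals as samples).
  imp <- resid_mat
  imp[is.na(imp)] <- 0  # residuals are centered; mean-impute = 0
  n_pcs_eff <- min(n_pcs, nrow(imp) - 1, ncol(imp) - 1)
  pcs <- if (n_pcs_eff > 0) {
    prcomp(t(imp), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs_eff),
                                                    drop = FALSE]
  } else {
    matrix(0, ncol(imp), 0)
  }
  out <- resid_mat
  for (i in seq_len(nrow(out))) {
    obs <- !is.na(out[i, ])
    if (ncol(pcs) > 0) {
      f <- stats::lm.fit(cbind(1, pcs[obs, , drop = FALSE]), out[i, obs])
      out[i, obs] <- f$residuals
    }
    # rank-based inverse-normal transform across observed individuals
    r <- rank(out[i, obs], ties.method = "average")
    out[i, obs] <- qnorm((r - 0.5) / sum(obs))
  }
  list(normalized = out, kept_events = rownames(out),
       dropped_events = dropped, pcs = pcs)
}

#' Cis QTL scan of normalized AFE phenotypes
#'
#' Ordinary least squares of each event's normalized PSI on the dosage
#' of each candidate SNP within `cis_window` bp of either TSS of the
#' event, over the individuals with both phenotype and genotype.
#' Monomorphic SNPs and SNPs below the minor-allele-count threshold are
#' skipped.
#'
#' @param normalized Events x individuals matrix from
#'   [normalize_afe_psi()].
#' @param genotypes SNPs x individuals dosage matrix (0/1/2).
#' @param snps Tibble with `snp_id`, `event_id`, `pos` and optional
#'   `binding_effect`.
#' @param annotation AFE annotation (for the TSS positions).
#' @param cis_window Maximum SNP distance from either TSS (default
#'   10000 bp).
#' @param min_mac Minimum minor-allele count among phenotyped
#'   individuals (default 10).
#' @return Tibble with `event_id`, `snp_id`, `n`, `beta`, `se`,
#'   `p_value` and `binding_effect` when provided.
#' @export
afe_qtl_scan <- function(normalized, genotypes, snps, annotation,
                         cis_window = 1e4, min_mac = 10) {
  assert_columns(snps, c("snp_id", "event_id", "pos"), "`snps`")
  tss <- afe_tss(annotation)
  cand <- snps %>%
    inner_join(tss, by = "event_id") %>%
    filter(pmin(abs(pos - tss_upstream), abs(pos - tss_downstream)) <=
             cis_window,
           event_id %in% rownames(normalized),
           snp_id %in% rownames(genotypes))
  common <- intersect(colnames(normalized), colnames(genotypes))
  res <- purrr::map(seq_len(nrow(cand)), function(i) {
    ev <- cand$event_id[i]; sn <- cand$snp_id[i]
    y <- normalized[ev, common]
    g <- genotypes[sn, common]
    obs <- !is.na(y) & !is.na(g)
    y <- y[obs]; g <- g[obs]
    mac <- min(sum(g), 2 * length(g) - sum(g))
    if (length(unique(g)) < 2 || mac < min_mac) return(NULL)
    n <- length(y)
    gc <- g - mean(g); yc <- y - mean(y)
    beta <- sum(gc * yc) / sum(gc^2)
    rss <- sum((yc - beta * gc)^2)
    se <- sqrt(rss / (n - 2) / sum(gc^2))
    tstat <- beta / se
    tibble(event_id = ev, snp_id = sn, n = n, beta = beta, se = se,
           p_value = 2 * pt(-abs(tstat), df = n - 2))
  }) %>% list_rbind()
  if (!is.null(res) && nrow(res) > 0 && "binding_effect" %in% names(snps)) {
    res <- res %>%
      left_join(snps %>% select(snp_id, binding_effect), by = "snp_id")
  }
  res
}

#' Enrichment of binding-disrupting SNPs among QTLs
#'
#' Builds the 2x2 table of QTL-significant vs not against
#' binding-affecting vs not and applies Fisher's exact test. Also
#' returns per-class sorted p-values for QQ plotting.
#'
#' @param qtl Result of [afe_qtl_scan()] with a logical
#'   `binding_effect` column.
#' @param sig_rule Function mapping the result tibble to a logical
#'   significance vector; default nominal `p_value < 0.05`.
#' @return List with `table` (2x2 matrix), `odds_ratio` (sample
#'   cross-ratio), `fisher_p`, and `qq` (tibble `binding_effect`,
#'   `p_value`, `expected` uniform quantiles per class).
#' @export
binding_enrichment <- function(qtl,
                               sig_rule = function(d) d$p_value < 0.05) {
  assert_columns(qtl, c("p_value", "binding_effect"), "`qtl`")
  qtl <- qtl %>% filter(!is.na(p_value), !is.na(binding_effect))
  if (length(unique(qtl$binding_effect)) < 2) {
    abort(sprintf("Class '%s' is empty; both binding classes are required.",
                  if (all(qtl$binding_effect)) "non-binding" else "binding"))
  }
  sig <- sig_rule(qtl)
  tab <- table(factor(qtl$binding_effect, levels = c(TRUE, FALSE)),
               factor(sig, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(binding = c("affecting", "neutral"),
                        qtl = c("significant", "not"))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c_)
  ft <- fisher.test(tab)
  qq <- qtl %>%
    group_by(binding_effect) %>%
    arrange(p_value, .by_group = TRUE) %>%
    mutate(expected = (row_number() - 0.5) / n()) %>%
    ungroup() %>%
    select(binding_effect, p_value, expected)
  list(table = unclass(tab), odds_ratio = unname(or), fisher_p = ft$p.value,
       qq = qq)
}
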