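# Synthetic landscapes downstream of the cohort: footprints, ATAC
# fragments, and a QTL panel, all with recorded planted truth.

#' Upstream/downstream TSS positions of AFE events
#'
#' The transcription start site of each alternative first exon is its
#' first transcribed base; "upstream" is defined on the transcribed
#' strand, so on the minus strand the upstream TSS is the larger genomic
#' coordinate.
#'
#' @param annotation Annotation tibble restricted to (or containing)
#'   AFE events.
#' @return Tibble with `event_id`, `chrom`, `strand`, `tss_upstream`,
#'   `tss_downstream` (genomic positions).
#' @export
afe_tss <- function(annotation) {
  assert_columns(annotation, c("event_id", "event_type", "chrom", "strand",
                               "iso1_start", "iso1_end",
                               "iso2_start", "iso2_end"), "`annotation`")
  afe <- annotation %>% filter(event_type == "AFE")
  afe %>%
    mutate(
      tss1 = if_else(strand == "+", iso1_start, iso1_end - 1),
      tss2 = if_else(strand == "+", iso2_start, iso2_end - 1),
      tss_upstream = if_else(strand == "+", pmin(tss1, tss2), pmax(tss1, tss2)),
      tss_downstream = if_else(strand == "+", pmax(tss1, tss2), pmin(tss1, tss2))
    ) %>%
    select(event_id, chrom, strand, tss_upstream, tss_downstream)
}

#' Simulate a transcription-factor footprint landscape around AFE TSSs
#'
#' Places motif footprints in the +/-1000 bp windows around both TSSs of
#' each AFE event. Background counts per window are Poisson; for the
#' first `n_causal` ("causal") motifs, extra footprints are added on the
#' side matching the event's planted direction, so the
#' upstream-minus-downstream footprint count difference is predictive of
#' direction with strength controlled by `coupling` (0 = no
#' association; 1 = sign agreement for essentially all directed events).
#' Remaining motifs are decoys placed independently of direction.
#'
#' @param annotation Cohort annotation (AFE rows are used).
#' @param direction Tibble with `event_id` and `direction` in
#'   \{-1, 0, 1\} (+1 = shift toward the upstream TSS).
#' @param n_motifs Total motifs (default 30).
#' @param n_causal Number of direction-coupled motifs (default 3).
#' @param coupling Coupling strength in [0, 1] (default 0.8).
#' @param base_rate Poisson mean of background footprints per window
#'   (default 1).
#' @param extra_rate Poisson mean of direction-matched extra footprints
#'   at `coupling = 1` (default 8).
#' @param seed Integer seed.
#' @return List with `footprints` (BED-like tibble: `chrom`, `start`,
#'   `end`, `motif_id`, `posterior`, `strand`) and `truth` (tibble of
#'   `motif_id`, `causal`).
#' @export
simulate_footprint_landscape <- function(annotation, direction,
                                         n_motifs = 30, n_causal = 3,
                                         coupling = 0.8, base_rate = 1,
                                         extra_rate = 8, seed = 1L) {
  if (coupling < 0 || coupling > 1) abort("`coupling` must be in [0, 1].")
  tss <- afe_tss(annotation)
  if (nrow(tss) == 0) {
    return(list(
      footprints = tibble(chrom = character(), start = numeric(),
                          end = numeric(), motif_id = character(),
                          posterior = numeric(), strand = character()),
      truth = tibble(motif_id = sprintf("M%03d", seq_len(n_motifs)),
                     causal = seq_len(n_motifs) <= n_causal)
    ))
  }
  assert_columns(direction, c("event_id", "direction"), "`direction`")
  tss <- tss %>% left_join(direction, by = "event_id") %>%
    mutate(direction = dplyr::coalesce(direction, 0))
  motifs <- sprintf("M%03d", seq_len(n_motifs))
  fps <- with_stream_seed(seed, "footprints", {
    grid <- tidyr::expand_grid(tss, motif_id = motifs) %>%
      mutate(
        causal = match(motif_id, motifs) <= n_causal,
        n_up = rpois(n(), base_rate) +
          if_else(causal & direction > 0, rpois(n(), extra_rate * coupling), 0L),
        n_down = rpois(n(), base_rate) +
          if_else(causal & direction < 0, rpois(n(), extra_rate * coupling), 0L)
      )
    up <- grid %>% filter(n_up > 0) %>%
      tidyr::uncount(n_up) %>%
      mutate(center = tss_upstream + round(runif(n(), -1000, 1000)))
    down <- grid %>% filter(n_down > 0) %>%
      tidyr::uncount(n_down, .remove = FALSE) %>%
      mutate(center = tss_downstream + round(runif(n(), -1000, 1000)))
    bind_rows(up, down) %>%
      mutate(start = center - 6, end = center + 6,
             posterior = runif(n(), 0.99, 1), strand = ".") %>%
      select(chrom, start, end, motif_id, posterior, strand) %>%
      arrange(chrom, start)
  })
  list(footprints = fps,
       truth = tibble(motif_id = motifs,
                      causal = seq_len(n_motifs) <= n_causal))
}

# Fragment-length mixture spanning the four accessibility bins.
sample_fragment_lengths <- function(n) {
  bin <- sample.int(4, n, replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
  lo <- c(39, 100, 140, 180)[bin]
  hi <- c(99, 139, 179, 250)[bin]
  round(runif(n, lo, hi))
}

#' Simulate ATAC-seq fragments around AFE TSSs with planted depletion
#'
#' Generates paired-end fragment intervals for one treatment and one
#' control library. Background fragments are placed uniformly in the
#' +/-500 bp window around each TSS; the treatment library is depleted
#' by `tss_depletion` at each TSS class. When footprints are supplied,
#' additional fragments are placed in the +/-100 bp windows around each
#' footprint, with motif-specific treatment depletion: causal motifs are
#' depleted differentially between the preferred- and non-preferred-TSS
#' classes, decoys equally.
#'
#' @param annotation Cohort annotation (AFE rows used).
#' @param preferred Tibble with `event_id`, `direction` (+1 = upstream
#'   TSS preferred under treatment; 0 rows are dropped).
#' @param footprints Optional footprint tibble (BED-like, as produced by
#'   [simulate_footprint_landscape()]).
#' @param causal_motifs Character vector of motifs with differential
#'   depletion.
#' @param frag_rate_tss Expected background fragments per TSS window per
#'   library (default 200).
#' @param tss_depletion Named depletion fractions for the treatment
#'   library, `c(preferred = , nonpreferred = )`. The default (0.2 /
#'   0.4) plants an overall accessibility loss that is milder at the
#'   preferred TSS.
#' @param motif_rate Expected fragments per footprint window (default 50).
#' @param motif_depletion Named depletion for causal motifs,
#'   `c(preferred = , nonpreferred = )` (default 0.2 / 0.5: depletion
#'   twice as strong at the non-preferred TSS).
#' @param decoy_depletion Depletion applied to decoy motifs at both
#'   classes (default 0.3).
#' @param seed Integer seed.
#' @return Tibble of fragments: `chrom`, `start`, `end`, `length`,
#'   `library_id`, `condition`.
#' @export
simulate_atac_fragments <- function(annotation, preferred,
                                    footprints = NULL,
                                    causal_motifs = character(),
                                    frag_rate_tss = 200,
                                    tss_depletion = c(preferred = 0.2,
                                                      nonpreferred = 0.4),
                                    motif_rate = 50,
                                    motif_depletion = c(preferred = 0.2,
                                                        nonpreferred = 0.5),
                                    decoy_depletion = 0.3,
                                    seed = 1L) {
  tss <- afe_tss(annotation) %>%
    inner_join(preferred, by = "event_id") %>%
    filter(direction != 0) %>%
    mutate(
      tss_preferred = if_else(direction > 0, tss_upstream, tss_downstream),
      tss_nonpreferred = if_else(direction > 0, tss_downstream, tss_upstream)
    )
  centers <- bind_rows(
    tss %>% select(event_id, chrom, center = tss_preferred) %>%
      mutate(tss_class = "preferred"),
    tss %>% select(event_id, chrom, center = tss_nonpreferred) %>%
      mutate(tss_class = "nonpreferred")
  )
  with_stream_seed(seed, "atac", {
    grid <- tidyr::expand_grid(centers, condition = c("treatment", "control")) %>%
      mutate(
        rate = frag_rate_tss *
          if_else(condition == "treatment",
                  1 - tss_depletion[tss_class], 1),
        n_frag = rpois(n(), rate)
      )
    bg <- grid %>% filter(n_frag > 0) %>%
      tidyr::uncount(n_frag) %>%
      mutate(mid = center + round(runif(n(), -500, 500)))
    frag <- bg
    if (!is.null(footprints) && nrow(footprints) > 0) {
      fp <- footprints %>%
        mutate(fp_mid = floor((start + end) / 2)) %>%
        select(chrom, fp_mid, motif_id)
      # assign each footprint to the nearest TSS class window (500 bp)
      fp <- fp %>%
        inner_join(centers, by = "chrom", relationship = "many-to-many") %>%
        filter(abs(fp_mid - center) <= 500) %>%
        distinct(chrom, fp_mid, motif_id, tss_class)
      fp_grid <- tidyr::expand_grid(fp, condition = c("treatment", "control")) %>%
        mutate(
          depl = if_else(motif_id %in% causal_motifs,
                         motif_depletion[tss_class], decoy_depletion),
          rate = motif_rate * if_else(condition == "treatment", 1 - depl, 1),
          n_frag = rpois(n(), rate)
        )
      fp_frag <- fp_grid %>% filter(n_frag > 0) %>%
        tidyr::uncount(n_frag) %>%
        mutate(mid = fp_mid + round(runif(n(), -100, 100))) %>%
        select(chrom, mid, condition)
      frag <- bind_rows(bg %>% select(chrom, mid, condition), fp_frag)
    } else {
      frag <- bg %>% select(chrom, mid, condition)
    }
    frag %>%
      mutate(
        length = sample_fragment_lengths(n()),
        start = mid - floor(length / 2),
        end = start + length,
        library_id = if_else(condition == "treatment", "atac_treat_1",
                             "atac_ctrl_1")
      ) %>%
      select(chrom, start, end, length, library_id, condition) %>%
      arrange(chrom, start)
  })
}

#' Simulate a genotype/phenotype panel for AFE QTL mapping
#'
#' Generates dosage genotypes for SNPs placed inside footprint windows
#' within 10 kb of AFE TSSs, covariates (lab, population), and a PSI
#' matrix in which each event's logit-PSI responds linearly to the
#' planted SNP effects plus covariate effects and noise.
#' Binding-affecting SNPs are given nonzero effects at `binding_odds`
#' times the odds of other SNPs.
#'
#' @param annotation Cohort annotation (AFE rows used).
#' @param n_individuals Panel size (default 373).
#' @param snps_per_event SNPs in the cis window per event (default 3).
#' @param maf_range Minor-allele-frequency range (default c(0.1, 0.5)).
#' @param frac_binding Fraction of SNPs flagged binding-affecting
#'   (default 0.3).
#' @param p_qtl_nonbinding Probability a non-binding SNP has a true
#'   effect (default 0.05).
#' @param binding_odds Odds multiplier for binding-affecting SNPs
#'   having a true effect (default 4).
#' @param beta_range Magnitude range of true logit-scale effects
#'   (default c(0.3, 0.7)).
#' @param noise_sd Residual SD on the logit scale (default 0.8).
#' @param obs_rate Probability each (event, individual) PSI is observed
#'   (default 0.9).
#' @param n_labs,n_pops Numbers of lab and population levels (3 and 4).
#' @param seed Integer seed.
#' @return List: `psi` (events x individuals matrix, NAs for missing),
#'   `genotypes` (SNPs x individuals dosage matrix), `snps` (tibble with
#'   `snp_id`, `event_id`, `chrom`, `pos`, `binding_effect`,
#'   `true_beta`), `covariates` (tibble with `individual_id`, `lab`,
#'   `population`).
#' @export
simulate_qtl_panel <- function(annotation, n_individuals = 373,
                               snps_per_event = 3,
                               maf_range = c(0.1, 0.5),
                               frac_binding = 0.3,
                               p_qtl_nonbinding = 0.05,
                               binding_odds = 4,
                               beta_range = c(0.3, 0.7),
                               noise_sd = 0.8, obs_rate = 0.9,
                               n_labs = 3, n_pops = 4, seed = 1L) {
  tss <- afe_tss(annotation)
  n_ev <- nrow(tss)
  if (n_ev == 0) abort("No AFE events in `annotation`.")
  with_stream_seed(seed, "qtl_panel", {
    individuals <- sprintf("IND%04d", seq_len(n_individuals))
    covariates <- tibble(
      individual_id = individuals,
      lab = sample(paste0("lab", seq_len(n_labs)), n_individuals, TRUE),
      population = sample(paste0("pop", seq_len(n_pops)), n_individuals, TRUE)
    )
    snps <- tidyr::expand_grid(tss, snp_i = seq_len(snps_per_event)) %>%
      mutate(
        snp_id = sprintf("rs_%s_%d", event_id, snp_i),
        pos = tss_upstream + round(runif(n(), -1e4, 1e4)),
        maf = runif(n(), maf_range[1], maf_range[2]),
        binding_effect = runif(n()) < frac_binding,
        p_qtl = if_else(
          binding_effect,
          binding_odds * p_qtl_nonbinding /
            (1 - p_qtl_nonbinding + binding_odds * p_qtl_nonbinding),
          p_qtl_nonbinding),
        has_effect = runif(n()) < p_qtl,
        true_beta = if_else(
          has_effect,
          runif(n(), beta_range[1], beta_range[2]) *
            sample(c(-1, 1), n(), TRUE),
          0)
      ) %>%
      select(snp_id, event_id, chrom, pos, maf, binding_effect, true_beta)
    geno <- matrix(rbinom(nrow(snps) * n_individuals, 2,
                          rep(snps$maf, each = n_individuals)),
                   nrow = nrow(snps), byrow = TRUE,
                   dimnames = list(snps$snp_id, individuals))
    lab_eff <- setNames(rnorm(n_labs, 0, 0.3), paste0("lab", seq_len(n_labs)))
    pop_eff <- setNames(rnorm(n_pops, 0, 0.3), paste0("pop", seq_len(n_pops)))
    base_logit <- qlogis(0.05 + 0.9 * rbeta(n_ev, 2, 2))
    psi <- matrix(NA_real_, n_ev, n_individuals,
                  dimnames = list(tss$event_id, individuals))
    for (i in seq_len(n_ev)) {
      ev_snps <- which(snps$event_id == tss$event_id[i])
      gsum <- if (length(ev_snps) > 0) {
        colSums(geno[ev_snps, , drop = FALSE] * snps$true_beta[ev_snps])
      } else rep(0, n_individuals)
      logit_psi <- base_logit[i] + gsum +
        lab_eff[covariates$lab] + pop_eff[covariates$population] +
        rnorm(n_individuals, 0, noise_sd)
      psi[i, ] <- plogis(logit_psi)
    }
    miss <- matrix(runif(n_ev * n_individuals) > obs_rate, n_ev)
    psi[miss] <- NA_real_
    list(psi = psi, genotypes = geno, snps = snps, covariates = covariates)
  })
}
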