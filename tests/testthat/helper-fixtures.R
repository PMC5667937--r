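# Fixture builders shared across test files. Everything is built in
# code; no binary fixtures.

# A minimal annotation covering the orientation cases.
fixture_annotation <- function() {
  tibble::tribble(
    ~event_id, ~gene_id, ~event_type, ~chrom, ~strand,
    ~iso1_start, ~iso1_end, ~iso2_start, ~iso2_end,
    "se1",  "gSE",  "SE",  "chr1", "+", 1200, 1400, NA, NA,
    "ri1",  "gRI",  "RI",  "chr1", "+", 5200, 6200, NA, NA,
    "mxe1", "gMXE", "MXE", "chr2", "+", 1200, 1400, NA, NA,
    # plus strand, isoform 1 upstream (smaller coordinate)
    "afe_plus_up",  "gA1", "AFE", "chr3", "+", 1000, 1200, 3000, 3200,
    # plus strand, isoform 1 downstream
    "afe_plus_down", "gA2", "AFE", "chr3", "+", 43000, 43200, 41000, 41200,
    # minus strand, isoform 1 is the smaller-coordinate exon =
    # downstream on the transcribed strand
    "afe_minus_down", "gA3", "AFE", "chr4", "-", 81000, 81200, 83000, 83200,
    # minus strand, isoform 1 upstream (larger coordinate)
    "afe_minus_up", "gA4", "AFE", "chr4", "-", 123000, 123200, 121000, 121200,
    # ALE: plus strand, isoform 1 downstream (larger end)
    "ale_plus_down", "gL1", "ALE", "chr5", "+", 163000, 163200, 161000, 161200,
    # ALE: minus strand, isoform 1 downstream (smaller start)
    "ale_minus_down", "gL2", "ALE", "chr5", "-", 201000, 201200, 203000, 203200
  )
}

# SE/RI annotation with flanking exons for feature construction.
fixture_se_ri_annotation <- function() {
  tibble::tribble(
    ~event_id, ~event_type, ~chrom, ~strand,
    ~iso1_start, ~iso1_end,
    ~flank_up_start, ~flank_up_end, ~flank_down_start, ~flank_down_end,
    # exon [2000,2200); upstream flank [1000,1200); downstream [3000,3200)
    "se_plus",  "SE", "chr1", "+", 2000, 2200, 1000, 1200, 3000, 3200,
    # minus strand: transcribed upstream flank is the larger-coordinate exon
    "se_minus", "SE", "chr2", "-", 12000, 12200, 11000, 11200, 13000, 13200,
    # RI: intron [22000,23000) between exons [21800,22000) and [23000,23200)
    "ri_plus",  "RI", "chr3", "+", 22000, 23000, 21800, 22000, 23000, 23200
  )
}

# Small comparison-count table in compare_conditions() input form.
fixture_counts <- function() {
  tibble::tibble(
    event_id = c("se1", "se1", "afe_plus_up"),
    event_type = c("SE", "SE", "AFE"),
    cell_type = "CT1", treatment = "T1", individual_id = c("I1", "I2", "I1"),
    n_inc_treat = c(50, 90, 30),
    n_exc_treat = c(50, 10, 70),
    n_inc_ctrl = c(50, 10, 30),
    n_exc_ctrl = c(50, 90, 70)
  )
}

# Numeric double-integration oracle for the two-sample PSI Bayes
# factor, independent of the closed form: integrates the binomial
# kernels (without binomial coefficients, which cancel in the ratio)
# against the Beta prior, with peak scaling for numerical stability.
bf_integration_oracle <- function(k_t, n_t, k_c, n_c, a = 1, b = 1) {
  kernel <- function(k, n) {
    lmax <- if (k == 0 || k == n) 0 else
      k * log(k / n) + (n - k) * log(1 - k / n)
    list(
      f = function(p) exp(k * log(p) + (n - k) * log1p(-p) - lmax) *
        stats::dbeta(p, a, b),
      lmax = lmax
    )
  }
  kt <- kernel(k_t, n_t); kc <- kernel(k_c, n_c)
  m1 <- stats::integrate(kt$f, 0, 1, rel.tol = 1e-12)$value
  m2 <- stats::integrate(kc$f, 0, 1, rel.tol = 1e-12)$value
  joint <- stats::integrate(function(p)
    exp((k_t + k_c) * log(p) + (n_t + n_c - k_t - k_c) * log1p(-p) -
          kt$lmax - kc$lmax) * stats::dbeta(p, a, b),
    0, 1, rel.tol = 1e-12)$value
  log(m1) + log(m2) - log(joint)
}

# Brute-force Benjamini-Hochberg from the definition: the q-value of
# p_i is the smallest value of m * p_(j) / j over all order statistics
# p_(j) >= p_i, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / vapply(cand, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}
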