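qtl_fixture_psi <- function(n_ev = 6, n_ind = 250, seed = 1) {
  set.seed(seed)
  psi <- matrix(runif(n_ev * n_ind), n_ev, n_ind,
                dimnames = list(paste0("AFE_", seq_len(n_ev)),
                                sprintf("IND%04d", seq_len(n_ind))))
  cov <- tibble::tibble(
    individual_id = colnames(psi),
    lab = sample(c("lab1", "lab2"), n_ind, TRUE),
    population = sample(c("pop1", "pop2", "pop3"), n_ind, TRUE)
  )
  list(psi = psi, cov = cov)
}

test_that("normalized phenotypes are exact inverse-normal order statistics", {
  fx <- qtl_fixture_psi(seed = 5)
  out <- normalize_afe_psi(fx$psi, fx$cov, min_individuals = 100)
  for (i in seq_len(nrow(out$normalized))) {
    v <- out$normalized[i, ]
    obs <- !is.na(v)
    n <- sum(obs)
    expect_equal(unname(sort(v[obs])), qnorm(((1:n) - 0.5) / n),
                 tolerance = 1e-12)
  }
})

test_that("constant covariates are dropped with a warning", {
  fx <- qtl_fixture_psi(seed = 6)
  fx$cov$lab <- "lab1"
  expect_warning(out <- normalize_afe_psi(fx$psi, fx$cov,
                                          min_individuals = 100),
                 "lab")
  expect_equal(dim(out$normalized), dim(fx$psi))
})

test_that("events below the minimum-individuals rule are dropped", {
  fx <- qtl_fixture_psi(seed = 7)
  fx$psi[2, 1:120] <- NA  # leaves 130 observed
  out <- normalize_afe_psi(fx$psi, fx$cov, min_individuals = 200)
  expect_true("AFE_2" %in% out$dropped_events)
  expect_false("AFE_2" %in% rownames(out$normalized))
})

test_that("the cis window and allele-count rules gate the scan", {
  ann <- tibble::tibble(
    event_id = "AFE_1", gene_id = "g", event_type = "AFE", chrom = "chr1",
    strand = "+", iso1_start = 100000, iso1_end = 100200,
    iso2_start = 103000, iso2_end = 103200
  )
  n_ind <- 300
  norm <- matrix(rnorm(n_ind), 1,
                 dimnames = list("AFE_1", sprintf("I%03d", seq_len(n_ind))))
  set.seed(8)
  geno <- rbind(
    in_cis = rbinom(n_ind, 2, 0.3),
    at_edge = rbinom(n_ind, 2, 0.3),
    too_far = rbinom(n_ind, 2, 0.3),
    mono = rep(0L, n_ind),
    rare = c(rep(1L, 5), rep(0L, n_ind - 5))
  )
  colnames(geno) <- colnames(norm)
  snps <- tibble::tibble(
    snp_id = rownames(geno), event_id = "AFE_1",
    pos = c(100500, 110000, 113001 + 200, 100600, 100700)
  )
  # upstream TSS = 100000, downstream = 103000; 113201 is > 10 kb from both
  out <- afe_qtl_scan(norm, geno, snps, ann)
  expect_setequal(out$snp_id, c("in_cis", "at_edge"))
})

test_that("a planted effect on the normalized scale is recovered", {
  set.seed(9)
  n_ind <- 300
  g <- rbinom(n_ind, 2, 0.3)
  y <- 0.5 * g + rnorm(n_ind)
  norm <- matrix(y, 1, dimnames = list("AFE_1", sprintf("I%03d", 1:n_ind)))
  geno <- matrix(g, 1, dimnames = list("snp1", colnames(norm)))
  ann <- tibble::tibble(
    event_id = "AFE_1", gene_id = "g", event_type = "AFE", chrom = "chr1",
    strand = "+", iso1_start = 100000, iso1_end = 100200,
    iso2_start = 103000, iso2_end = 103200
  )
  snps <- tibble::tibble(snp_id = "snp1", event_id = "AFE_1", pos = 100500)
  out <- afe_qtl_scan(norm, geno, snps, ann)
  expect_equal(out$beta, 0.5, tolerance = 3 * out$se / 0.5)
  # cross-check beta/se against lm()
  ref <- summary(lm(y ~ g))$coefficients
  expect_equal(out$beta, ref[2, 1], tolerance = 1e-10)
  expect_equal(out$se, ref[2, 2], tolerance = 1e-10)
  expect_equal(out$p_value, ref[2, 4], tolerance = 1e-10)
})

test_that("binding enrichment reproduces the cross-ratio and flags classes", {
  qtl <- tibble::tibble(
    p_value = c(rep(0.01, 10), rep(0.5, 90), rep(0.01, 5), rep(0.5, 195)),
    binding_effect = c(rep(TRUE, 100), rep(FALSE, 200))
  )
  out <- binding_enrichment(qtl)
  expect_equal(out$odds_ratio, (10 * 195) / (90 * 5))
  expect_lt(out$fisher_p, 0.05)
  expect_equal(sum(out$table), 300)
  expect_error(
    binding_enrichment(dplyr::mutate(qtl, binding_effect = TRUE)),
    "non-binding")
})

test_that("permuted binding flags center the odds ratio at 1", {
  set.seed(10)
  ors <- replicate(40, {
    qtl <- tibble::tibble(
      p_value = runif(400),
      binding_effect = sample(rep(c(TRUE, FALSE), each = 200))
    )
    binding_enrichment(qtl)$odds_ratio
  })
  lor <- log(ors[is.finite(ors) & ors > 0])
  expect_lt(abs(mean(lor)), 0.25)
})

test_that("downstream t-statistics are invariant to monotone PSI distortion", {
  fx <- qtl_fixture_psi(n_ev = 3, seed = 11)
  ann <- tibble::tibble(
    event_id = rownames(fx$psi), gene_id = "g", event_type = "AFE",
    chrom = "chr1", strand = "+",
    iso1_start = 100000, iso1_end = 100200,
    iso2_start = 103000, iso2_end = 103200
  )
  set.seed(12)
  geno <- matrix(rbinom(3 * 250, 2, 0.4), 3,
                 dimnames = list(paste0("s", 1:3), colnames(fx$psi)))
  snps <- tibble::tibble(snp_id = paste0("s", 1:3),
                         event_id = rownames(fx$psi), pos = 100500)
  # rank-preserving residualization (constant covariates, no PCs) makes
  # the rank-based inverse-normal step the only transformation
  cov0 <- dplyr::mutate(fx$cov, lab = "lab1", population = "pop1")
  run <- function(psi) {
    norm <- suppressWarnings(
      normalize_afe_psi(psi, cov0, n_pcs = 0, min_individuals = 100))
    afe_qtl_scan(norm$normalized, geno, snps, ann)
  }
  a <- run(fx$psi)
  b <- run(fx$psi^3)  # strictly monotone distortion
  expect_equal(a$beta / a$se, b$beta / b$se, tolerance = 1e-10)
})
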