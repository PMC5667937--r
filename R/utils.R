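# Internal helpers shared across modules.

# Derive a reproducible child seed from a global seed and a stream label.
# Keeps derived seeds in the 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- substr(rlang::hash(list(as.integer(seed), as.character(stream))), 1, 7)
  as.integer(strtoi(h, base = 16L) %% .Machine$integer.max)
}

# Run code under a temporary RNG state seeded from (seed, stream).
with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, stream))
  force(code)
}

# Beta shape parameters for a beta-binomial with mean `mu` and intra-class
# correlation `rho` (rho -> 0 degenerates to a binomial).
beta_shapes <- function(mu, rho) {
  stopifnot(all(mu > 0 & mu < 1))
  if (any(rho < 0 | rho >= 1)) abort("`rho` must be in [0, 1).")
  prec <- (1 - rho) / pmax(rho, 1e-12)
  list(a = mu * prec, b = (1 - mu) * prec)
}

# Vectorized beta-binomial sampler: size n trials, mean mu, overdispersion rho.
rbetabinom <- function(n_draws, size, mu, rho) {
  if (all(rho == 0)) return(rbinom(n_draws, size, mu))
  sh <- beta_shapes(mu, rho)
  p <- rbeta(n_draws, sh$a, sh$b)
  rbinom(n_draws, size, p)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
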