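# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# Minimal dataset wrapper: one metadata column so validation passes.
mkds <- function(wavelengths, values, mode = "absorbance", samples = NULL) {
  values <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  if (is.null(samples)) samples <- data.frame(replicate = seq_len(nrow(values)))
  spectral_dataset(wavelengths, values, mode, samples)
}

# Random absorbance dataset with full storage metadata.
random_ds <- function(n = 8, p = 20, seed = 42) {
  withr::with_seed(seed, {
    samples <- data.frame(
      treatment = rep(c("A", "B"), length.out = n),
      day = rep(c(0L, 13L), each = ceiling(n / 2))[seq_len(n)],
      bag = paste0("b", seq_len(n)),
      side = rep(c("front", "back"), length.out = n),
      replicate = seq_len(n))
    mkds(seq(1300, 1600, length.out = p),
         matrix(rnorm(n * p, mean = 0.5, sd = 0.1), n, p),
         samples = samples)
  })
}

# Direct permutation null for the one-way ANOVA F statistic: p-value is the
# fraction of label permutations with F >= observed. Computes F from sums
# of squares without touching the package's ANOVA path.
perm_anova_p <- function(group_list, n_perm = 2000, seed = 1) {
  y <- unlist(group_list, use.names = FALSE)
  sizes <- lengths(group_list)
  idx <- rep(seq_along(group_list), sizes)
  f_stat <- function(y, idx) {
    gm <- tapply(y, idx, mean)
    n <- tapply(y, idx, length)
    ssb <- sum(n * (gm - mean(y))^2)
    ssw <- sum((y - gm[idx])^2)
    dfb <- length(gm) - 1
    dfw <- length(y) - length(gm)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- f_stat(y, idx)
  withr::with_seed(seed, {
    hits <- vapply(seq_len(n_perm), function(i) {
      f_stat(sample(y), idx) >= f_obs
    }, logical(1))
  })
  mean(hits)
}

# Brute-force one-way ANOVA from explicit sums of squares (oracle).
ss_anova <- function(group_list) {
  y <- unlist(group_list, use.names = FALSE)
  idx <- rep(seq_along(group_list), lengths(group_list))
  gm <- tapply(y, idx, mean)
  n <- tapply(y, idx, length)
  ssb <- sum(n * (gm - mean(y))^2)
  ssw <- sum((y - gm[idx])^2)
  dfb <- length(gm) - 1
  dfw <- length(y) - length(gm)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE), mse = ssw / dfw,
       df_within = dfw)
}

# Default-scenario pipeline products used by several test files; computed
# once per test run.
scenario_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- spectral_scenario(seed = 1)
      gen <- generate_spectra(sc)
      absb <- reflectance_to_absorbance(gen$ds)
      cache <<- list(sc = sc, gen = gen, absb = absb)
    }
    cache
  }
})
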