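test_that("moving average preserves constants and linear trends, trims edges", {
  wl <- seq(900, 1600, length.out = 125)
  const <- mkds(wl, matrix(0.7, 1, 125))
  out <- moving_average(const, 15)
  expect_equal(length(out$wavelengths), 111)   # 125 - 2 * 7
  expect_equal(as.vector(out$values), rep(0.7, 111), tolerance = 1e-14)

  lin <- mkds(wl, matrix(0.001 * wl - 0.5, 1))
  sm <- moving_average(lin, 15)
  expect_equal(as.vector(sm$values), 0.001 * sm$wavelengths - 0.5,
               tolerance = 1e-12)

  expect_error(moving_average(const, 14), "odd")
  expect_error(moving_average(mkds(1:9, matrix(1.0, 1, 9)), 11), "larger")
})

test_that("SG filter is exact on polynomials up to the fit order", {
  wl <- 1:60
  quad <- mkds(wl, matrix(as.numeric(wl)^2, 1))
  d2 <- sg_derivative(quad, window = 21, polyorder = 2, deriv = 2)
  expect_equal(as.vector(d2$values), rep(2, length(d2$wavelengths)),
               tolerance = 1e-10)

  const <- mkds(wl, matrix(0.4, 1, 60))
  d1 <- sg_derivative(const, window = 11, polyorder = 2, deriv = 1)
  expect_equal(as.vector(d1$values), rep(0, length(d1$wavelengths)),
               tolerance = 1e-12)

  # deriv = 0 smoothing reproduces polynomial inputs of the fit degree
  cub <- mkds(wl, matrix(0.1 * wl^3 - wl, 1))
  s0 <- sg_derivative(cub, window = 9, polyorder = 3, deriv = 0)
  expect_equal(as.vector(s0$values), 0.1 * s0$wavelengths^3 - s0$wavelengths,
               tolerance = 1e-8)

  # derivative scaling follows the nm spacing: doubling the spacing halves
  # the first derivative of the same sample sequence
  y <- sin(seq(0, 3, length.out = 40))
  a <- sg_derivative(mkds(seq(0, 39), matrix(y, 1)), 7, 2, 1)
  b <- sg_derivative(mkds(seq(0, 78, by = 2), matrix(y, 1)), 7, 2, 1)
  expect_equal(b$values, a$values / 2, tolerance = 1e-12)
})

test_that("SG second derivative tracks the analytic derivative of a sine", {
  wl <- 1:300
  ds <- mkds(wl, matrix(sin(wl / 50), 1))
  out <- sg_derivative(ds, window = 11, polyorder = 2, deriv = 2)
  truth <- -sin(out$wavelengths / 50) / 2500
  # relative to the derivative's amplitude scale 1/2500
  expect_lt(max(abs(out$values - truth)) * 2500, 1e-3)
})

test_that("SG rejects invalid parameter combinations and nonuniform grids", {
  ds <- mkds(1:30, matrix(rnorm(30), 1))
  expect_error(sg_derivative(ds, 10, 2, 2), "odd")
  expect_error(sg_derivative(ds, 11, 2, 3), "deriv <= polyorder")
  nonuni <- mkds(c(1:10, 12:20), matrix(0.5, 1, 19))
  expect_error(sg_derivative(nonuni, 5, 2, 1), "uniform")
})

test_that("Norris gap derivative is the symmetric difference over the gap", {
  wl <- 1:80
  lin <- mkds(wl, matrix(3 * wl + 1, 1))
  out <- norris_gap(lin, gap = 21)
  expect_equal(as.vector(out$values), rep(3, length(out$wavelengths)),
               tolerance = 1e-12)
  expect_equal(length(out$wavelengths), 80 - 2 * 10)

  const <- mkds(wl, matrix(1.5, 1, 80))
  expect_equal(max(abs(norris_gap(const, 21)$values)), 0)

  # symmetric difference of a quadratic equals the exact derivative at the
  # centre; brute-force check of the definition
  quad <- mkds(wl, matrix(as.numeric(wl)^2, 1))
  g <- 10
  ng <- norris_gap(quad, gap = 21)
  brute <- vapply((g + 1):(80 - g), function(i) {
    (wl[i + g]^2 - wl[i - g]^2) / (wl[i + g] - wl[i - g])
  }, numeric(1))
  expect_equal(as.vector(ng$values), brute, tolerance = 1e-12)
  expect_equal(as.vector(ng$values), 2 * ng$wavelengths, tolerance = 1e-12)

  expect_error(norris_gap(mkds(1:5, matrix(1:5 / 10, 1)), 21), "too large")
  expect_error(norris_gap(quad, 20), "odd")
})

test_that("Norris gap and SG agree on smooth band-limited spectra", {
  wl <- seq(900, 1600, length.out = 125)
  y <- 0.5 * exp(-((wl - 1430) / 60)^2) + 0.2 * exp(-((wl - 1160) / 40)^2)
  ds <- mkds(wl, matrix(y, 1))
  a <- norris_gap(ds, gap = 9)
  b <- sg_derivative(ds, window = 9, polyorder = 2, deriv = 1)
  shared <- intersect(round(a$wavelengths, 6), round(b$wavelengths, 6))
  av <- a$values[, round(a$wavelengths, 6) %in% shared]
  bv <- b$values[, round(b$wavelengths, 6) %in% shared]
  expect_lt(max(abs(av - bv)) / max(abs(av)), 0.15)
  expect_gt(stats::cor(as.vector(av), as.vector(bv)), 0.99)
})

test_that("SNV standardises each spectrum and is affine invariant", {
  ds <- random_ds(6, 25)
  out <- snv(ds)
  expect_equal(rowMeans(out$values), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(out$values, 1, sd), rep(1, 6), tolerance = 1e-12)

  scaled <- ds
  scaled$values <- 2.5 * ds$values + 0.3
  expect_equal(snv(scaled)$values, out$values, tolerance = 1e-12)

  flat <- ds
  flat$values[3, ] <- 1
  expect_error(snv(flat), "sample 3")
})

test_that("MSC recovers a common reference from noiseless affine distortions", {
  wl <- seq_len(50)
  ref <- sin(seq(0, 3, length.out = 50)) + 2
  slopes <- c(0.5, 2); offsets <- c(-0.1, 0.3)
  X <- rbind(slopes[1] * ref + offsets[1], slopes[2] * ref + offsets[2])
  ds <- mkds(wl, X)
  fit <- msc(ds, reference = ref)
  expect_equal(fit$ds$values, rbind(ref, ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  # independent least-squares oracle for the fitted coefficients
  for (i in 1:2) {
    ols <- coef(lm(X[i, ] ~ ref))
    expect_equal(fit$slope[i], unname(ols[2]), tolerance = 1e-10)
    expect_equal(fit$offset[i], unname(ols[1]), tolerance = 1e-10)
  }
  expect_equal(fit$slope, slopes, tolerance = 1e-10)
  expect_equal(fit$offset, offsets, tolerance = 1e-10)
})

test_that("MSC is the identity on the reference and idempotent", {
  wl <- seq_len(30)
  ref <- cos(seq(0, 2, length.out = 30)) + 1.5
  ds <- mkds(wl, matrix(ref, 1))
  fit <- msc(ds, reference = ref)
  expect_equal(as.vector(fit$ds$values), ref, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$offset, 0, tolerance = 1e-12)

  ds2 <- random_ds(4, 30)
  ds2$values <- withr::with_seed(8,
    outer(runif(4, 0.5, 2), ref) + runif(4) + matrix(rnorm(120, 0, 0.05), 4))
  once <- msc(ds2, reference = ref)
  twice <- msc(once$ds, reference = ref)
  expect_equal(twice$ds$values, once$ds$values, tolerance = 1e-10)

  expect_error(msc(ds2, reference = rep(1, 30)), "zero variance")
  neg <- ds2
  neg$values[1, ] <- -2 * ref + 5
  expect_warning(msc(neg, reference = ref), "slope")
})

test_that("the aquaphotomics standardisation centres and scales columns", {
  ds <- random_ds(9, 14)
  nm <- aqua_normalize(ds)
  expect_lt(max(abs(colMeans(nm$ds$values))), 1e-10)
  expect_lt(max(abs(apply(nm$ds$values, 2, sd) - 1)), 1e-10)
  expect_equal(nm$stats$n, 9)

  # two spectra x and -x: zero-mean columns, rows map to +/- x / sd
  x <- withr::with_seed(4, rnorm(14))
  pm <- mkds(1:14, rbind(x, -x))
  npm <- aqua_normalize(pm)$ds
  expect_equal(npm$values[1, ], -npm$values[2, ], tolerance = 1e-12)
  expect_equal(npm$values[1, ], x / (abs(x) * sqrt(2)), tolerance = 1e-12)

  dup <- mkds(1:5, rbind(1:5, 1:5) / 10)
  expect_error(aqua_normalize(dup), "zero spread")
})

test_that("the standardisation inverts to machine precision", {
  ds <- random_ds(7, 11)
  nm <- aqua_normalize(ds)
  back <- aqua_denormalize(nm$ds, nm$stats)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  proj <- aqua_project(ds, nm$stats)
  expect_equal(proj$values, nm$ds$values, tolerance = 1e-14)
})

test_that("all pretreatment operators preserve metadata and row order", {
  ds <- random_ds(6, 40)
  ops <- list(
    function(d) moving_average(d, 5),
    function(d) sg_derivative(d, 7, 2, 1),
    function(d) norris_gap(d, 5),
    snv,
    function(d) msc(d)$ds,
    function(d) aqua_normalize(d)$ds,
    function(d) truncate_spectra(d, 1350, 1550)
  )
  for (op in ops) {
    out <- op(ds)
    expect_identical(out$samples, ds$samples)
  }
})

test_that("preset chains compose and report their side outputs", {
  fx <- scenario_fixture()
  res <- apply_steps(fx$absb, "aqua_prep")
  expect_s3_class(res$aqua_stats, "aqua_stats")
  expect_length(res$msc_fit$slope, n_spectra(fx$absb))
  expect_true(all(res$ds$wavelengths >= 1300 & res$ds$wavelengths <= 1600))
  expect_lt(max(abs(colMeans(res$ds$values))), 1e-10)

  pca_prep <- apply_steps(fx$absb, "pca_prep")$ds
  # MA(15) trims 7, Norris(21) trims 10 per side before truncation
  expect_equal(length(pca_prep$wavelengths),
               sum(instrument_grid()[18:108] >= 1300))

  # custom chain from a YAML config
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste(
    "steps:",
    "- kind: snv",
    "- kind: sg_derivative",
    "  params: {window: 11, polyorder: 2, deriv: 2}",
    sep = "\n"), cfgfile)
  via_yaml <- apply_steps(fx$absb, cfgfile)$ds
  direct <- apply_steps(fx$absb, "pls_prep")$ds
  expect_equal(via_yaml$values, direct$values, tolerance = 1e-14)
  expect_error(apply_steps(fx$absb, list(list(kind = "wavelets"))), "unknown")
})
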