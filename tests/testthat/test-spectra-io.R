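test_that("wide and long CSV round trips preserve the dataset", {
  ds <- random_ds(n = 6, p = 15)
  for (dialect in c("wide_csv", "long_csv")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectra(ds, path, dialect)
    back <- read_spectra(path, dialect)
    expect_identical(back$wavelengths, ds$wavelengths)
    expect_equal(back$values, ds$values, tolerance = 1e-14)
    expect_equal(back$samples$treatment, ds$samples$treatment)
    expect_equal(back$samples$day, ds$samples$day)
    expect_equal(back$samples$side, ds$samples$side)
  }
})

test_that("read_spectra rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("treatment,day,1300,1310", empty)
  expect_error(read_spectra(empty), "no spectra")

  badtr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("treatment,1300,1310", "Z,0.1,0.2"), badtr)
  expect_error(read_spectra(badtr), "treatment")

  nonmono <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("treatment,1310,1300", "A,0.1,0.2"), nonmono)
  expect_error(read_spectra(nonmono), "non-monotone")

  expect_error(read_spectra(tempfile()), "not found")
})

test_that("a 60-spectrum wide CSV loads with the full checkpoint structure", {
  # 3 bags x 2 sides x 10 replicates: one treatment's acquisition at one
  # checkpoint
  meta <- expand.grid(replicate = 1:10, side = c("front", "back"),
                      bag = paste0("b", 1:3), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  meta$treatment <- "A"; meta$day <- 0L
  ds <- withr::with_seed(7, mkds(instrument_grid(),
                                 matrix(runif(60 * 125, 0.2, 0.8), 60),
                                 mode = "reflectance", samples = meta))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path, "wide_csv")
  back <- read_spectra(path, "wide_csv", mode = "reflectance")
  expect_equal(n_spectra(back), 60)
  expect_equal(length(back$wavelengths), 125)
})

test_that("write_spectra refuses an empty dataset", {
  ds <- random_ds(4, 6)
  ds$values <- ds$values[0, , drop = FALSE]
  ds$samples <- ds$samples[0, , drop = FALSE]
  expect_error(write_spectra(ds, tempfile(), "wide_csv"), "no spectra")
})

test_that("absorbance transform matches log10(1/R) and inverts exactly", {
  ds <- mkds(c(1, 2, 3), matrix(c(1, 0.1, 0.01), 1), mode = "reflectance")
  ab <- reflectance_to_absorbance(ds)
  expect_equal(as.vector(ab$values), c(0, 1, 2))
  expect_identical(ab$mode, "absorbance")

  r <- random_ds(5, 12)
  r$mode <- "reflectance"
  r$values <- withr::with_seed(3, matrix(runif(60, 0.05, 0.95), 5, 12))
  round_trip <- absorbance_to_reflectance(reflectance_to_absorbance(r))
  expect_equal(round_trip$values, r$values, tolerance = 1e-12)
  expect_error(reflectance_to_absorbance(reflectance_to_absorbance(r)),
               "already")
})

test_that("nonpositive reflectance is rejected with sample coordinates", {
  ds <- random_ds(3, 5)
  ds$mode <- "reflectance"
  ds$values <- matrix(0.5, 3, 5)
  ds$values[2, 4] <- -0.1
  expect_error(reflectance_to_absorbance(ds), "sample 2")
})

test_that("reference subtraction removes the mean reference spectrum", {
  ds <- random_ds(6, 10)
  # self-subtraction of a one-spectrum dataset replicated as reference
  self <- subtract_reference(ds, ds)
  expect_equal(self$values,
               sweep(ds$values, 2, colMeans(ds$values)), tolerance = 1e-14)

  ref_row <- withr::with_seed(11, rnorm(10))
  ref <- mkds(ds$wavelengths, matrix(rep(ref_row, each = 10), 10,
                                     byrow = FALSE))
  # 10 identical reference spectra: subtract exactly that spectrum
  ref$values <- matrix(ref_row, 10, 10, byrow = TRUE)
  out <- subtract_reference(ds, ref)
  expect_equal(out$values, sweep(ds$values, 2, ref_row), tolerance = 1e-14)
  expect_identical(out$samples, ds$samples)

  shifted <- ds; shifted$wavelengths <- ds$wavelengths + 1
  expect_error(subtract_reference(ds, shifted), "grid mismatch")
})

test_that("reference subtraction is linear in the reference means", {
  ds <- random_ds(4, 8)
  ref1 <- random_ds(3, 8, seed = 5)
  ref2 <- random_ds(2, 8, seed = 6)
  ref1$wavelengths <- ds$wavelengths
  ref2$wavelengths <- ds$wavelengths
  combined <- ref1
  combined$values <- matrix(colMeans(ref1$values) + colMeans(ref2$values),
                            1, 8, byrow = TRUE)
  combined$samples <- combined$samples[1, , drop = FALSE]
  two_step <- subtract_reference(subtract_reference(ds, ref1), ref2)
  one_step <- subtract_reference(ds, combined)
  expect_equal(two_step$values, one_step$values, tolerance = 1e-12)
})

test_that("truncation keeps exactly the first-overtone window", {
  ds <- mkds(instrument_grid(), matrix(0.5, 2, 125),
             samples = data.frame(replicate = 1:2))
  tr <- truncate_spectra(ds, 1300, 1600)
  expect_true(all(tr$wavelengths >= 1300 & tr$wavelengths <= 1600))
  expect_equal(length(tr$wavelengths), sum(instrument_grid() >= 1300))

  full <- truncate_spectra(ds, 900, 1600)
  expect_equal(full$values, ds$values)
  expect_error(truncate_spectra(ds, 2000, 2100), "empty range")
  expect_error(truncate_spectra(ds, 1500, 1400), "lo must be")
})

test_that("average_by collapses groups to arithmetic means", {
  fx <- scenario_fixture()
  one <- truncate_spectra(fx$absb, 1300, 1360)
  sub <- one
  keep <- sub$samples$treatment == "A" & sub$samples$day == 0
  sub$values <- sub$values[keep, , drop = FALSE]
  sub$samples <- sub$samples[keep, , drop = FALSE]
  expect_equal(n_spectra(sub), 60)   # 3 bags x 2 sides x 10 replicates
  avg <- average_by(sub, c("treatment", "day"))
  expect_equal(n_spectra(avg), 1)
  expect_equal(as.vector(avg$values), colMeans(sub$values), tolerance = 1e-14)
  expect_equal(avg$samples$replicate, 60)

  # singleton groups: identity on values
  ds <- random_ds(5, 7)
  ident <- average_by(ds, "bag")
  o <- order(ds$samples$bag)
  expect_equal(ident$values, ds$values[o, ], tolerance = 1e-15)

  # mean of x and -x is zero
  x <- withr::with_seed(9, rnorm(7))
  pm <- mkds(1:7, rbind(x, -x),
             samples = data.frame(treatment = c("A", "A"), day = c(0, 0)))
  z <- average_by(pm, c("treatment", "day"))
  expect_equal(as.vector(z$values), rep(0, 7), tolerance = 1e-15)
})

test_that("average_by validates its keys", {
  ds <- random_ds(4, 5)
  expect_error(average_by(ds, character()), "non-empty")
  expect_error(average_by(ds, "flavour"), "unknown key")
})
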