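test_that("the reference WAB set carries the twelve coordinates", {
  wabs <- default_wabs()
  expect_equal(nrow(wabs), 12)
  expect_equal(wabs$wamac, paste0("C", 1:12))
  expect_true(all(diff(wabs$wavelength) > 0))
  expect_equal(wabs$wavelength[1], 1342)
  expect_equal(wabs$assignment[1], "v3")
  expect_equal(wabs$wavelength[5], 1416)
  expect_match(wabs$assignment[5], "free water")
  expect_equal(wabs$wavelength[8], 1453)
  expect_match(wabs$assignment[8], "solvation shell")
  expect_equal(wabs$wavelength[12], 1509)
  expect_no_error(validate_wab_set(wabs))
})

test_that("WAB selection finds an isolated spike inside its coordinate", {
  wl <- seq(1300, 1600, by = 1)
  base <- matrix(0.01, 2, length(wl))
  base[, wl == 1373] <- c(5, 5)      # spike inside C3's range, flat elsewhere
  ds <- mkds(wl, rbind(base, -base) / 2,
             samples = data.frame(treatment = rep(c("A", "B"), each = 2),
                                  day = 0L, replicate = 1:4))
  set <- select_wabs(ds)
  expect_equal(set$wavelength[set$wamac == "C3"], 1373)
  # brute-force scan oracle over the C3 range
  rng <- wamac_ranges()
  cand <- wl[wl >= rng$lo[3] & wl <= rng$hi[3]]
  gm <- apply(abs((rbind(base, -base) / 2)), 2, max)
  expect_equal(set$wavelength[set$wamac == "C3"],
               cand[which.max(gm[wl %in% cand])])
})

test_that("flat spectra with zero loadings fall back to the lowest wavelength", {
  wl <- seq(1300, 1600, by = 1)
  ds <- mkds(wl, matrix(0, 3, length(wl)),
             samples = data.frame(treatment = "A", day = 0L, replicate = 1:3))
  set <- select_wabs(ds, pca_loadings = rep(0, length(wl)),
                     pls_loadings = rep(0, length(wl)))
  rng <- wamac_ranges()
  for (i in 1:12) {
    lowest <- min(wl[wl >= rng$lo[i] & wl <= rng$hi[i]])
    expect_equal(set$wavelength[i], lowest)
  }
})

test_that("extrema engineered at the reference wavelengths reproduce the set", {
  ref <- default_wabs()
  wl <- seq(1300, 1600, by = 1)
  spec <- rep(0.05, length(wl))
  spec[wl %in% ref$wavelength] <- 3     # extremum exactly at each reference WAB
  ds <- mkds(wl, rbind(spec, spec * 1.1),
             samples = data.frame(treatment = c("A", "A"), day = c(0L, 13L),
                                  replicate = 1:2))
  set <- select_wabs(ds)
  expect_equal(set$wavelength, ref$wavelength)
  expect_equal(set$wamac, ref$wamac)
})

test_that("WAB selection is deterministic and stable under sample duplication", {
  fx <- scenario_fixture()
  norm_ds <- apply_steps(fx$absb, "aqua_prep")$ds
  s1 <- select_wabs(norm_ds)
  s2 <- select_wabs(norm_ds)
  expect_identical(s1$wavelength, s2$wavelength)
  dup <- norm_ds
  dup$values <- rbind(norm_ds$values, norm_ds$values)
  dup$samples <- rbind(norm_ds$samples, norm_ds$samples)
  expect_identical(select_wabs(dup)$wavelength, s1$wavelength)
})

test_that("aquagram of a single-sample group is its interpolated spectrum", {
  wl <- seq(1300, 1600, by = 2)
  x <- withr::with_seed(44, rnorm(length(wl)))
  ds <- mkds(wl, rbind(x, -x),
             samples = data.frame(treatment = c("A", "B"), day = 0L))
  aq <- compute_aquagram(ds, group_keys = "treatment", flip_sign = FALSE)
  wabs <- default_wabs()
  expected <- approx(wl, x, xout = wabs$wavelength)$y
  expect_equal(unname(aq$values[1, ]), expected, tolerance = 1e-12)
  # mirror groups give mirror-image rows
  expect_equal(aq$values[1, ], -aq$values[2, ], tolerance = 1e-12)
  # sign flip negates the pattern
  flipped <- compute_aquagram(ds, group_keys = "treatment", flip_sign = TRUE)
  expect_equal(flipped$values, -aq$values, tolerance = 1e-15)
})

test_that("interpolated WAB values are exact at grid points", {
  wabs <- default_wabs()
  wl <- sort(c(seq(1300, 1600, by = 7), wabs$wavelength))
  wl <- unique(wl)
  x <- withr::with_seed(45, rnorm(length(wl)))
  ds <- mkds(wl, matrix(x, 1), samples = data.frame(treatment = "A", day = 0L))
  aq <- compute_aquagram(ds, flip_sign = FALSE)
  expect_equal(unname(aq$values[1, ]), x[match(wabs$wavelength, wl)],
               tolerance = 1e-15)
})

test_that("the grand-mean aquagram is zero on the standardised scale", {
  fx <- scenario_fixture()
  prep <- apply_steps(fx$absb, "aqua_prep")$ds
  all_one_group <- prep
  all_one_group$samples$treatment <- "A"
  all_one_group$samples$day <- 0L
  aq <- compute_aquagram(all_one_group)
  expect_lt(max(abs(aq$values)), 1e-10)
})

test_that("aquagram computation commutes with group-preserving permutation", {
  fx <- scenario_fixture()
  prep <- apply_steps(fx$absb, "aqua_prep")$ds
  aq1 <- compute_aquagram(prep)
  perm <- withr::with_seed(46, sample(n_spectra(prep)))
  shuffled <- prep
  shuffled$values <- prep$values[perm, ]
  shuffled$samples <- prep$samples[perm, ]
  aq2 <- compute_aquagram(shuffled)
  expect_equal(aq1$values, aq2$values, tolerance = 1e-12)
  expect_equal(aq1$groups, aq2$groups)
})

test_that("storage drift shows as rising free-water and falling bound-water axes", {
  fx <- scenario_fixture()
  prep <- apply_steps(fx$absb, "aqua_prep")$ds
  aq <- compute_aquagram(prep)
  df <- as.data.frame(aq)
  for (tr in c("A", "B", "C")) {
    for (w in c(1416, 1428)) {
      sub <- df[df$treatment == tr & df$wavelength == w, ]
      v <- sub$value[order(sub$day)]
      expect_true(all(diff(v) > 0),
                  label = sprintf("rising trajectory at %d nm, treatment %s", w, tr))
    }
    for (w in c(1490, 1509)) {
      sub <- df[df$treatment == tr & df$wavelength == w, ]
      v <- sub$value[order(sub$day)]
      expect_true(all(diff(v) < 0),
                  label = sprintf("falling trajectory at %d nm, treatment %s", w, tr))
    }
  }
})

test_that("aquagram serialisation and rendering produce files", {
  fx <- scenario_fixture()
  prep <- apply_steps(fx$absb, "aqua_prep")$ds
  aq <- compute_aquagram(prep)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_aquagram(aq, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 18)
  expect_true(all(paste0("C", 1:12) %in% names(back)))

  png_path <- withr::local_tempfile(fileext = ".png")
  render_aquagram(aq, png_path, panel_by = "treatment")
  expect_true(file.exists(png_path) && file.size(png_path) > 0)

  empty <- aq
  empty$values <- aq$values[0, , drop = FALSE]
  empty$groups <- aq$groups[0, , drop = FALSE]
  expect_error(render_aquagram(empty, tempfile()), "empty")
})
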