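# Synthetic storage-series generator.
#
# Emulates the statistical structure the monitoring analysis assumes:
# water-band-dominated absorbance spectra on the 125-point instrument grid,
# multiplicative/additive scatter between bags and sides, a storage-day-
# dependent redistribution of absorbance from strongly hydrogen-bonded
# water bands (1490/1509 nm) towards free/weakly bonded bands
# (1416/1428 nm), leaf-damage trajectories that stay flat early and rise
# after about a week, and an electronic nose whose three broad-range
# sensors drift upward fastest under the CO2-enriched atmosphere. Every
# generated dataset ships with its ground truth so recovery claims can be
# verified without re-running the pipeline.

# Logistic storage-damage curve: 0 at day 0, rising mainly after `midpoint`.
damage_curve <- function(day, dmax, midpoint, tau) {
  dmax / (1 + exp(-(day - midpoint) / tau)) -
    dmax / (1 + exp(midpoint / tau))
}

#' Define a synthetic storage scenario
#'
#' The default scenario mirrors the rocket-salad storage study design:
#' 3 treatments (A air, B oxygen-enriched, C CO2-enriched) x 6 checkpoints
#' (days 0, 1, 4, 7, 11, 13) x 3 bags x 2 sides x 10 replicate spectra,
#' 125-point 900-1600 nm grid. Absorbance is a sum of Gaussian water
#' bands: three broad bands (second overtone ~975 nm, combination band
#' ~1160 nm, first overtone ~1435 nm) plus twelve narrow bands at the
#' reference water absorbance bands. Each narrow band's amplitude drifts
#' linearly in a latent damage score `damage = rate_treatment *
#' damage_curve(day)`; the drift is a conserved redistribution (amplitude
#' lost at 1490/1509 equals amplitude gained at 1416/1428). Treatment
#' rates order the deterioration speed C > A > B, the ranking the
#' leakage and E-nose analyses are expected to recover.
#'
#' @param preset `"trial1"` (default) or `"trial2"`. The second preset has
#'   doubled scatter variance (a more heterogeneous raw material) and the
#'   water-species drift reversed in sign, giving aquagrams of opposite
#'   orientation.
#' @param days sampling schedule in storage days.
#' @param n_bags,n_sides,n_reps replication structure per checkpoint.
#' @param noise_sd additive spectral noise (AU).
#' @param scatter_slope_sd,scatter_offset_sd per-spectrum multiplicative /
#'   additive scatter spread (half of each variance is shared at bag
#'   level).
#' @param seed integer RNG seed; every generator call is reproducible
#'   given the scenario.
#' @return object of class `spectral_scenario`.
#' @export
spectral_scenario <- function(preset = c("trial1", "trial2"),
                              days = c(0, 1, 4, 7, 11, 13),
                              n_bags = 3, n_sides = 2, n_reps = 10,
                              noise_sd = 0.0015,
                              scatter_slope_sd = 0.015,
                              scatter_offset_sd = 0.004,
                              seed = 1) {
  preset <- match.arg(preset)
  wabs <- default_wabs()
  # signed amplitude drift (AU per damage unit): weakly bonded species
  # (low-wavelength side) gain, strongly bonded species lose; the main
  # free-water pair mirrors the strongly-bound pair exactly.
  delta <- c(0.0008, 0.0008, 0.0010, 0.0008, 0.0025, 0.0025,
             0.0008, -0.0008, -0.0010, -0.0012, -0.0025, -0.0025)
  scatter_mult <- 1
  if (preset == "trial2") {
    delta <- -delta
    scatter_mult <- 2
  }
  bands <- rbind(
    data.frame(center = c(975, 1160, 1435),
               width = c(30, 25, 38),
               amplitude = c(0.25, 0.30, 0.65),
               delta = 0),
    data.frame(center = wabs$wavelength,
               width = 7,
               amplitude = 0.10,
               delta = delta)
  )
  structure(list(
    preset = preset,
    grid = list(lo = 900, hi = 1600, n = 125),
    baseline = 0.15,
    bands = bands,
    day_curve = list(dmax = 18, midpoint = 8, tau = 2),
    treatments = c(A = 1.0, B = 0.7, C = 1.4),
    days = days,
    n_bags = n_bags, n_sides = n_sides, n_reps = n_reps,
    noise_sd = noise_sd,
    scatter_slope_sd = scatter_slope_sd * scatter_mult,
    scatter_offset_sd = scatter_offset_sd * scatter_mult,
    bag_damage_cv = 0.05,
    seed = as.integer(seed)
  ), class = "spectral_scenario")
}

#' @export
print.spectral_scenario <- function(x, ...) {
  cat(sprintf(
    "<spectral_scenario> preset %s: %d treatments x %d days x %d bags x %d sides x %d reps, seed %d\n",
    x$preset, length(x$treatments), length(x$days), x$n_bags, x$n_sides,
    x$n_reps, x$seed))
  invisible(x)
}

# Per-bag design table with latent damage scores.
scenario_bags <- function(sc) {
  design <- expand.grid(bag = seq_len(sc$n_bags),
                        day = sc$days,
                        treatment = names(sc$treatments),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("treatment", "day", "bag")]
  base <- damage_curve(design$day, sc$day_curve$dmax, sc$day_curve$midpoint,
                       sc$day_curve$tau) *
    sc$treatments[design$treatment]
  design$bag_dev <- rnorm(nrow(design), 0, sc$bag_damage_cv)
  design$damage <- base * (1 + design$bag_dev)
  design$bag <- paste0(design$treatment, design$day, "_b", design$bag)
  design
}

#' Generate a synthetic storage spectra set
#'
#' Draws the full scenario design reproducibly from the scenario seed.
#' Per spectrum: band amplitudes are shifted by the bag's latent damage
#' score, the Gaussian bands plus baseline are summed into absorbance, a
#' per-spectrum affine scatter `a * x + b` (with a bag-level shared
#' component) is applied, Gaussian noise is added, and the result is
#' emitted in reflectance mode as `R = 10^(-A)`.
#'
#' @param sc a `spectral_scenario`.
#' @return list with `ds` (reflectance-mode `spectral_dataset`) and
#'   `truth` (list: `bags` with latent damage per bag, `samples` with
#'   per-spectrum damage and scatter coefficients, `amplitudes` with
#'   realized band amplitudes, `bands`, `delta_sign` per reference WAB).
#' @export
generate_spectra <- function(sc) {
  stopifnot(inherits(sc, "spectral_scenario"))
  withr::with_seed(sc$seed, {
    wl <- instrument_grid(sc$grid$lo, sc$grid$hi, sc$grid$n)
    bags <- scenario_bags(sc)
    per_bag <- sc$n_sides * sc$n_reps
    n <- nrow(bags) * per_bag

    samples <- bags[rep(seq_len(nrow(bags)), each = per_bag),
                    c("treatment", "day", "bag", "damage")]
    samples$side <- rep(rep(c("front", "back"), each = sc$n_reps),
                        times = nrow(bags))
    samples$replicate <- rep(seq_len(sc$n_reps), times = nrow(bags) * sc$n_sides)
    rownames(samples) <- NULL

    # amplitudes: base + delta * damage, per sample x band
    amp <- outer(samples$damage, sc$bands$delta) +
      matrix(sc$bands$amplitude, n, nrow(sc$bands), byrow = TRUE)
    if (any(amp <= 0))
      stop("generate_spectra: drift drove a band amplitude non-positive; ",
           "reduce the day effect or raise the base amplitude")

    shapes <- exp(-outer(sc$bands$center, wl, function(c0, x)
      ((x - c0)^2)) / (2 * sc$bands$width^2))    # n_bands x n_wl
    A <- amp %*% shapes + sc$baseline

    # affine scatter: half the variance shared within bag
    bag_id <- match(samples$bag, bags$bag)
    a_bag <- rnorm(nrow(bags), 0, sc$scatter_slope_sd / sqrt(2))
    b_bag <- rnorm(nrow(bags), 0, sc$scatter_offset_sd / sqrt(2))
    a <- 1 + a_bag[bag_id] + rnorm(n, 0, sc$scatter_slope_sd / sqrt(2))
    b <- b_bag[bag_id] + rnorm(n, 0, sc$scatter_offset_sd / sqrt(2))
    A <- A * a + b + matrix(rnorm(n * length(wl), 0, sc$noise_sd),
                            n, length(wl))
    if (any(A <= 0))
      stop("generate_spectra: absorbance driven non-positive; ",
           "raise the baseline or reduce scatter/noise")

    meta <- samples[, c("treatment", "day", "bag", "side", "replicate")]
    ds <- spectral_dataset(wl, 10^(-A), "reflectance", meta)
    truth <- list(
      bags = bags,
      samples = cbind(meta, damage = samples$damage, slope = a, offset = b),
      amplitudes = amp,
      bands = sc$bands,
      delta_sign = sign(sc$bands$delta[sc$bands$width == 7])
    )
    list(ds = ds, truth = truth)
  })
}

#' Generate synthetic electrolyte-leakage records
#'
#' The leaf-damage index is linked linearly to the latent damage score:
#' `ild = intercept + slope * damage + noise`, clipped to (0, 100]. Each
#' bag yields `n_meas` records; conductivity pairs are back-solved from a
#' fixed final-conductivity scale so `compute_ild(ic, fc)` reproduces the
#' emitted index exactly.
#'
#' @param sc a `spectral_scenario`.
#' @param link list with `intercept` (percent at zero damage), `slope` (percent per
#'   damage unit) and `noise_sd` (percent).
#' @param truth optional truth from [generate_spectra()]: reuses its
#'   per-bag latent damage so leakage and spectra describe the same bags.
#' @param n_meas measurements per bag.
#' @param fc_scale final conductivity scale (uS/cm).
#' @return data frame of leakage records: `treatment`, `day`, `bag`,
#'   `replicate`, `ic`, `fc`, `ild`, `damage`.
#' @export
generate_leakage <- function(sc, link = list(intercept = 4, slope = 1,
                                             noise_sd = 0.6),
                             truth = NULL, n_meas = 3, fc_scale = 1500) {
  stopifnot(inherits(sc, "spectral_scenario"))
  if (link$noise_sd < 0) stop("generate_leakage: noise_sd must be >= 0")
  withr::with_seed(sc$seed + 1L, {
    bags <- if (!is.null(truth)) truth$bags else {
      withr::with_seed(sc$seed, scenario_bags(sc))
    }
    n <- nrow(bags) * n_meas
    rec <- bags[rep(seq_len(nrow(bags)), each = n_meas),
                c("treatment", "day", "bag", "damage")]
    rec$replicate <- rep(seq_len(n_meas), times = nrow(bags))
    ild <- link$intercept + link$slope * rec$damage +
      rnorm(n, 0, link$noise_sd)
    if (any(ild <= 0 | ild > 100))
      stop("generate_leakage: link parameters yield an index outside (0, 100]")
    rec$fc <- fc_scale
    rec$ic <- ild / 100 * fc_scale
    rec$ild <- compute_ild(rec$ic, rec$fc)
    rownames(rec) <- NULL
    rec[, c("treatment", "day", "bag", "replicate", "ic", "fc", "ild",
            "damage")]
  })
}

# Default E-nose sensor model: baselines for the ten MOS channels and the
# damage sensitivity of the three broad-range channels.
enose_defaults <- function() {
  list(
    baseline = c(W1C = 0.4, W5S = 2.0, W3C = 0.5, W6S = 1.0, W5C = 0.6,
                 W1S = 1.8, W1W = 1.2, W2S = 1.5, W2W = 1.1, W3S = 0.9),
    drift = c(W1C = 0, W5S = 0.15, W3C = 0, W6S = 0, W5C = 0,
              W1S = 0.08, W1W = 0, W2S = 0.08, W2W = 0, W3S = 0),
    sdlog = 0.05
  )
}

#' Generate a synthetic E-nose table
#'
#' The three broad-range sensors (W5S, W1S, W2S) rise with the latent
#' damage score — fastest under the CO2-enriched treatment — while the
#' remaining seven stay stationary around their baselines; all channels
#' carry multiplicative lognormal noise.
#'
#' @param sc a `spectral_scenario`.
#' @param sensor_params list as from `enose_defaults()`; `drift` entries
#'   are relative increase per damage unit.
#' @param n_meas measurements per bag.
#' @return data frame: `treatment`, `day`, `bag`, `replicate` and the ten
#'   sensor columns (conductivity ratios G/G0).
#' @export
generate_enose <- function(sc, sensor_params = enose_defaults(), n_meas = 3) {
  stopifnot(inherits(sc, "spectral_scenario"))
  withr::with_seed(sc$seed + 2L, {
    bags <- withr::with_seed(sc$seed, scenario_bags(sc))
    n <- nrow(bags) * n_meas
    rec <- bags[rep(seq_len(nrow(bags)), each = n_meas),
                c("treatment", "day", "bag", "damage")]
    rec$replicate <- rep(seq_len(n_meas), times = nrow(bags))
    for (s in enose_sensors()) {
      mu <- sensor_params$baseline[[s]] *
        (1 + sensor_params$drift[[s]] * rec$damage)
      rec[[s]] <- mu * rlnorm(n, -sensor_params$sdlog^2 / 2,
                              sensor_params$sdlog)
    }
    rec$damage <- NULL
    rownames(rec) <- NULL
    rec
  })
}
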