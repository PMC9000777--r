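# Spectral pretreatment operators. All windowed operators trim edges rather
# than pad: padding would invent data next to the 1300/1600 nm boundaries
# where the water absorbance bands sit. All operators preserve the sample
# metadata and never reorder rows.

check_uniform_grid <- function(wl, what, tol = 1e-6) {
  d <- diff(wl)
  if (length(d) && (max(d) - min(d)) > tol * mean(d))
    stop(what, ": wavelength grid must be uniformly spaced")
  mean(d)
}

#' Moving-average (boxcar) smoothing
#'
#' Centered boxcar mean of each spectrum over an odd window. The output
#' grid keeps only the interior wavelengths: `(window - 1) / 2` points are
#' trimmed from each edge, so a 15-point window on the 125-point instrument
#' grid yields 111 points.
#'
#' @param ds a `spectral_dataset`.
#' @param window odd window length in points, >= 3 (default 15, the
#'   smoothing used ahead of the exploratory PCA).
#' @return smoothed dataset on the trimmed grid.
#' @export
moving_average <- function(ds, window = 15) {
  validate_spectral_dataset(ds)
  p <- length(ds$wavelengths)
  if (window %% 2 == 0 || window < 3) stop("moving_average: window must be odd and >= 3")
  if (window > p) stop("moving_average: window larger than grid")
  h <- (window - 1) / 2
  keep <- (h + 1):(p - h)
  sm <- t(apply(ds$values, 1L, function(x) {
    cs <- cumsum(c(0, x))
    (cs[keep + h + 1] - cs[keep - h]) / window
  }))
  if (length(keep) == 1L) sm <- matrix(sm, ncol = 1L)
  out <- ds
  out$wavelengths <- ds$wavelengths[keep]
  out$values <- sm
  out
}

# Central Savitzky-Golay coefficient row for (window, polyorder, deriv) on a
# unit-spaced abscissa; signal::sgolay provides the least-squares filters and
# already folds in the deriv! factorial and the ts^-deriv spacing scale.
sg_coefficients <- function(window, polyorder, deriv, spacing) {
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = spacing)
  F[(window + 1) / 2, ]
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Least-squares polynomial filter applied per spectrum. Derivatives are
#' scaled by the actual nm spacing, so outputs are in AU * nm^-deriv and
#' comparable across grids. Edges are trimmed by `(window - 1) / 2` points.
#'
#' @param ds a `spectral_dataset` on a uniform grid.
#' @param window odd window length in points ("gap size N points" in common
#'   chemometrics parlance means the full window length N).
#' @param polyorder polynomial order of the local fit, `deriv <= polyorder
#'   < window`.
#' @param deriv derivative order (0 = smoothing only).
#' @return filtered dataset on the trimmed grid.
#' @export
sg_derivative <- function(ds, window = 21, polyorder = 2, deriv = 2) {
  validate_spectral_dataset(ds)
  p <- length(ds$wavelengths)
  if (window %% 2 == 0 || window < 3) stop("sg_derivative: window must be odd and >= 3")
  if (!(deriv <= polyorder && polyorder < window))
    stop("sg_derivative: need deriv <= polyorder < window")
  if (window > p) stop("sg_derivative: window larger than grid")
  spacing <- check_uniform_grid(ds$wavelengths, "sg_derivative")
  cf <- sg_coefficients(window, polyorder, deriv, spacing)
  h <- (window - 1) / 2
  keep <- (h + 1):(p - h)
  filt <- t(apply(ds$values, 1L, function(x) {
    as.vector(stats::filter(x, rev(cf), sides = 2))[keep]
  }))
  if (length(keep) == 1L) filt <- matrix(filt, ncol = 1L)
  out <- ds
  out$wavelengths <- ds$wavelengths[keep]
  out$values <- filt
  out
}

#' Norris gap derivative
#'
#' First-derivative estimate over a wavelength gap,
#' `d(l_i) = (A(l_{i+g}) - A(l_{i-g})) / (l_{i+g} - l_{i-g})`, used to
#' resolve broad overlapped water bands. "Gap size N points" is read as the
#' total span N (odd), i.e. `g = (N - 1) / 2` points on each side; pass
#' `gap_is_half = TRUE` to supply g directly, since the Norris convention
#' varies between software packages. Edges are trimmed by g points.
#'
#' @param ds a `spectral_dataset`.
#' @param gap total span in points (odd) or, with `gap_is_half`, the
#'   one-sided gap g.
#' @param deriv derivative order; only 1 is supported.
#' @param gap_is_half interpret `gap` as the one-sided g.
#' @return derivative dataset (AU/nm) on the trimmed grid.
#' @export
norris_gap <- function(ds, gap = 21, deriv = 1, gap_is_half = FALSE) {
  validate_spectral_dataset(ds)
  if (deriv != 1) stop("norris_gap: only the first derivative is supported")
  g <- if (gap_is_half) as.integer(gap) else {
    if (gap %% 2 == 0) stop("norris_gap: total span must be odd")
    (as.integer(gap) - 1L) %/% 2L
  }
  if (g < 1) stop("norris_gap: gap too small")
  p <- length(ds$wavelengths)
  if (2 * g + 1 > p) stop("norris_gap: gap too large for grid")
  keep <- (g + 1):(p - g)
  denom <- ds$wavelengths[keep + g] - ds$wavelengths[keep - g]
  der <- (ds$values[, keep + g, drop = FALSE] -
            ds$values[, keep - g, drop = FALSE]) /
    matrix(denom, nrow(ds$values), length(keep), byrow = TRUE)
  out <- ds
  out$wavelengths <- ds$wavelengths[keep]
  out$values <- der
  out
}

#' Standard normal variate
#'
#' Row-wise standardisation: each spectrum is centred to mean 0 and scaled
#' to standard deviation 1 across wavelengths, removing additive offsets
#' and multiplicative scatter per spectrum.
#'
#' @param ds a `spectral_dataset`; every spectrum must be non-constant.
#' @return standardised dataset on the same grid.
#' @export
snv <- function(ds) {
  validate_spectral_dataset(ds)
  mu <- rowMeans(ds$values)
  s <- apply(ds$values, 1L, sd)
  zero <- which(s == 0)
  if (length(zero))
    stop("snv: constant spectrum (zero variance) at sample ", zero[1])
  out <- ds
  out$values <- (ds$values - mu) / s
  out
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, `x ~ a * ref + b`, and corrected as `(x - b) / a`. The default
#' reference is the dataset mean spectrum.
#'
#' @param ds a `spectral_dataset` with >= 2 spectra when `reference` is
#'   omitted.
#' @param reference optional numeric reference spectrum on the same grid.
#' @return list with `ds` (corrected dataset), `slope` and `offset`
#'   (per-sample fitted a and b). Fitted slopes `a <= 0` are reported with
#'   a warning: they indicate a physically anomalous spectrum.
#' @export
msc <- function(ds, reference = NULL) {
  validate_spectral_dataset(ds)
  if (is.null(reference)) {
    if (n_spectra(ds) < 2)
      stop("msc: need >= 2 spectra to form a mean reference")
    reference <- colMeans(ds$values)
  }
  reference <- as.numeric(reference)
  if (length(reference) != length(ds$wavelengths))
    stop("msc: reference length does not match the grid")
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) stop("msc: reference has zero variance")
  a <- as.vector(ds$values %*% rc) / den
  b <- rowMeans(ds$values) - a * mean(reference)
  if (any(a <= 0))
    warning("msc: non-positive fitted slope for sample(s) ",
            paste(which(a <= 0), collapse = ", "))
  out <- ds
  out$values <- (ds$values - b) / a
  list(ds = out, slope = a, offset = b)
}

#' Aquaphotomics column standardisation
#'
#' Standardises the spectra set wavelength by wavelength:
#' `z = (A_lambda - mu_lambda) / sigma_lambda`, where `mu_lambda` and
#' `sigma_lambda` are the mean and standard deviation of the (pretreated)
#' absorbance over all spectra at wavelength lambda. This places every
#' wavelength on a comparable scale so that the water absorbance band
#' pattern of a sample group can be read off directly; it is the scale on
#' which aquagrams are drawn.
#'
#' @param ds a `spectral_dataset` with >= 2 spectra and positive column
#'   standard deviation everywhere.
#' @return list with `ds` (normalised dataset) and `stats` (an
#'   `aqua_stats` object with fields `mu`, `sigma`, `n`) so further spectra
#'   can be projected into the same normalised space via
#'   [aqua_project()] and the map inverted via [aqua_denormalize()].
#' @export
aqua_normalize <- function(ds) {
  validate_spectral_dataset(ds)
  if (n_spectra(ds) < 2) stop("aqua_normalize: need >= 2 spectra")
  mu <- colMeans(ds$values)
  sigma <- apply(ds$values, 2L, sd)
  zero <- which(sigma == 0)
  if (length(zero))
    stop(sprintf("aqua_normalize: zero spread at wavelength %.2f nm",
                 ds$wavelengths[zero[1]]))
  out <- ds
  out$values <- sweep(sweep(ds$values, 2L, mu, "-"), 2L, sigma, "/")
  stats <- structure(list(mu = mu, sigma = sigma, n = n_spectra(ds),
                          wavelengths = ds$wavelengths),
                     class = "aqua_stats")
  list(ds = out, stats = stats)
}

#' Project spectra into an existing normalised space
#' @param ds dataset on the same grid as `stats`.
#' @param stats an `aqua_stats` object from [aqua_normalize()].
#' @return normalised dataset.
#' @export
aqua_project <- function(ds, stats) {
  validate_spectral_dataset(ds)
  stopifnot(inherits(stats, "aqua_stats"))
  if (length(stats$mu) != length(ds$wavelengths))
    stop("aqua_project: grid mismatch with stored stats")
  out <- ds
  out$values <- sweep(sweep(ds$values, 2L, stats$mu, "-"), 2L, stats$sigma, "/")
  out
}

#' Invert the aquaphotomics standardisation
#' @param ds normalised dataset.
#' @param stats the `aqua_stats` used to normalise it.
#' @return dataset on the original scale.
#' @export
aqua_denormalize <- function(ds, stats) {
  validate_spectral_dataset(ds)
  stopifnot(inherits(stats, "aqua_stats"))
  out <- ds
  out$values <- sweep(sweep(ds$values, 2L, stats$sigma, "*"), 2L, stats$mu, "+")
  out
}

# ---- pretreatment chains -------------------------------------------------

#' Named pretreatment presets
#'
#' The three chains used by the monitoring analysis:
#' \describe{
#'   \item{pca_prep}{moving_average(15) -> norris_gap(21) ->
#'     truncate(1300, 1600): smoothing plus gap derivative ahead of the
#'     exploratory PCA on the first overtone of water.}
#'   \item{pls_prep}{snv -> sg_derivative(11, 2, 2): scatter removal plus
#'     second derivative ahead of the PLS regression on the leaf-damage
#'     index.}
#'   \item{aqua_prep}{sg_derivative(21, 2, 2) -> msc ->
#'     truncate(1300, 1600) -> aqua_normalize: the aquagram chain;
#'     truncation precedes the column statistics so the standardisation is
#'     computed on the water first-overtone range only.}
#' }
#'
#' @param preset preset name.
#' @return list of step descriptors `{kind, params}` consumable by
#'   [apply_steps()].
#' @export
preset_steps <- function(preset = c("pca_prep", "pls_prep", "aqua_prep")) {
  preset <- match.arg(preset)
  switch(preset,
    pca_prep = list(
      list(kind = "moving_average", params = list(window = 15)),
      list(kind = "norris_gap", params = list(gap = 21, deriv = 1)),
      list(kind = "truncate", params = list(lo = 1300, hi = 1600))
    ),
    pls_prep = list(
      list(kind = "snv", params = list()),
      list(kind = "sg_derivative",
           params = list(window = 11, polyorder = 2, deriv = 2))
    ),
    aqua_prep = list(
      list(kind = "sg_derivative",
           params = list(window = 21, polyorder = 2, deriv = 2)),
      list(kind = "msc", params = list()),
      list(kind = "truncate", params = list(lo = 1300, hi = 1600)),
      list(kind = "aqua_normalize", params = list())
    )
  )
}

#' Apply an ordered chain of pretreatment steps
#'
#' Steps may be a preset name, a list of `{kind, params}` descriptors, or a
#' YAML file containing such a list (`steps:` top-level key or a bare
#' list). Supported kinds: `moving_average`, `sg_derivative`, `norris_gap`,
#' `snv`, `msc`, `aqua_normalize`, `truncate`.
#'
#' @param ds a `spectral_dataset`.
#' @param steps preset name, step list, or YAML path.
#' @return list with `ds` (pretreated dataset), `aqua_stats` (if the chain
#'   normalised; else NULL) and `msc_fit` (slopes/offsets if the chain ran
#'   MSC; else NULL).
#' @export
apply_steps <- function(ds, steps) {
  if (is.character(steps) && length(steps) == 1L) {
    if (file.exists(steps)) {
      cfg <- yaml::read_yaml(steps)
      steps <- if (!is.null(cfg$steps)) cfg$steps else cfg
    } else {
      steps <- preset_steps(steps)
    }
  }
  aqua_stats <- NULL
  msc_fit <- NULL
  for (st in steps) {
    kind <- st$kind
    par <- if (is.null(st$params)) list() else st$params
    ds <- switch(kind,
      moving_average = do.call(moving_average, c(list(ds), par)),
      sg_derivative  = do.call(sg_derivative, c(list(ds), par)),
      norris_gap     = do.call(norris_gap, c(list(ds), par)),
      snv            = snv(ds),
      truncate       = do.call(truncate_spectra, c(list(ds), par)),
      msc            = {
        fit <- do.call(msc, c(list(ds), par))
        msc_fit <- fit[c("slope", "offset")]
        fit$ds
      },
      aqua_normalize = {
        nm <- aqua_normalize(ds)
        aqua_stats <- nm$stats
        nm$ds
      },
      stop("apply_steps: unknown step kind: ", kind)
    )
  }
  list(ds = ds, aqua_stats = aqua_stats, msc_fit = msc_fit)
}
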