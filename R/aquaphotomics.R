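# Water absorbance band (WAB) selection and aquagram construction.
#
# Within the first overtone of water (1300-1600 nm) twelve characteristic
# absorbance ranges — the water matrix coordinates C1..C12, each 6-20 nm
# wide — reflect distinct water molecular species (free water S0, water
# with 1-4 hydrogen bonds S1-S4, solvation shells, strongly bound water).
# A WAB is the specific wavelength inside a coordinate that a perturbation
# (here: storage time under modified atmosphere) consistently activates.
# The aquagram is a radar chart of the group-mean standardised absorbance
# at the twelve WABs: the water absorbance spectral pattern (WASP).

#' The twelve reference water absorbance bands
#'
#' Canonical WAB set used for the rocket-salad storage aquagrams: one
#' wavelength per water matrix coordinate C1-C12 with its water-species
#' assignment.
#'
#' @return data frame of class `wab_set` with columns `wavelength` (nm),
#'   `wamac` ("C1".."C12") and `assignment`.
#' @export
default_wabs <- function() {
  wabs <- data.frame(
    wavelength = c(1342, 1366, 1373, 1385, 1416, 1428,
                   1441, 1453, 1466, 1478, 1490, 1509),
    wamac = paste0("C", 1:12),
    assignment = c(
      "v3",
      "water solvation shell, OH-(H2O) n, n = 1, 2, 4",
      "v1 + v3",
      "water solvation shell, OH-(H2O)1,4 and superoxide, O2-(H2O)4",
      "free water molecules (S0)",
      "water hydration, H-OH bend and O...O",
      "water molecules with 1 hydrogen bond (S1)",
      "v2 + v3, Water solvation shell, OH-(H2O)4,5",
      "water molecules with 2 hydrogen bonds (S2)",
      "water molecules with 3 hydrogen bonds (S3)",
      "water molecules with 4 hydrogen bonds (S4)",
      "v1, v2, strongly bound water"),
    stringsAsFactors = FALSE
  )
  class(wabs) <- c("wab_set", "data.frame")
  validate_wab_set(wabs)
}

#' Validate a WAB set
#' @param wabs candidate `wab_set`.
#' @return `wabs` invisibly, or an error.
#' @export
validate_wab_set <- function(wabs) {
  stopifnot(is.data.frame(wabs),
            all(c("wavelength", "wamac") %in% names(wabs)))
  if (nrow(wabs) != 12) stop("wab_set: exactly 12 entries required")
  if (any(diff(wabs$wavelength) <= 0))
    stop("wab_set: wavelengths must be strictly increasing")
  if (any(wabs$wavelength < 1300 | wabs$wavelength > 1600))
    stop("wab_set: wavelengths must lie in the 1300-1600 nm first overtone")
  if (anyDuplicated(wabs$wamac)) stop("wab_set: duplicated coordinate label")
  invisible(wabs)
}

#' Candidate wavelength ranges per water matrix coordinate
#'
#' Default search window: +/- `halfwidth` nm around each reference WAB,
#' consistent with the 6-20 nm width of the coordinates.
#'
#' @param halfwidth half-width in nm.
#' @return data frame with `wamac`, `lo`, `hi`.
#' @export
wamac_ranges <- function(halfwidth = 6) {
  ref <- default_wabs()
  data.frame(wamac = ref$wamac,
             lo = ref$wavelength - halfwidth,
             hi = ref$wavelength + halfwidth,
             stringsAsFactors = FALSE)
}

#' Select water absorbance bands from data
#'
#' Inside each coordinate range the candidate wavelengths are scored by the
#' magnitude of the group-mean standardised spectrum extremum and, where
#' supplied, the magnitude of the PCA and/or PLS loadings. The criteria are
#' combined by rank sum (each criterion ranks candidates descending by
#' magnitude; lowest total rank wins) because no canonical weighting of
#' spectrum extrema against loading impact exists. Ties break to the lower
#' wavelength, making the selection deterministic.
#'
#' @param norm_ds standardised `spectral_dataset` on the 1300-1600 nm
#'   range (output of the aquagram pretreatment chain).
#' @param pca_loadings optional numeric vector, one loading magnitude
#'   source per wavelength of `norm_ds` (e.g. PC1 loadings).
#' @param pls_loadings optional numeric vector, same length.
#' @param ranges coordinate ranges as from [wamac_ranges()].
#' @param group_keys metadata keys defining the groups whose mean spectra
#'   are scanned for extrema.
#' @return `wab_set` with the winning wavelength per coordinate.
#' @export
select_wabs <- function(norm_ds, pca_loadings = NULL, pls_loadings = NULL,
                        ranges = wamac_ranges(),
                        group_keys = c("treatment", "day")) {
  validate_spectral_dataset(norm_ds)
  wl <- norm_ds$wavelengths
  group_keys <- intersect(group_keys, names(norm_ds$samples))
  gmeans <- if (length(group_keys)) {
    average_by(norm_ds, group_keys)$values
  } else {
    matrix(colMeans(norm_ds$values), nrow = 1)
  }
  extremum <- apply(abs(gmeans), 2L, max)
  crit <- list(extremum = extremum)
  for (nm in c("pca", "pls")) {
    v <- if (nm == "pca") pca_loadings else pls_loadings
    if (!is.null(v)) {
      if (length(v) != length(wl))
        stop("select_wabs: ", nm, " loadings length does not match the grid")
      crit[[nm]] <- abs(v)
    }
  }
  ref <- default_wabs()
  picked <- vapply(seq_len(nrow(ranges)), function(i) {
    cand <- which(wl >= ranges$lo[i] & wl <= ranges$hi[i])
    if (!length(cand))
      stop("select_wabs: no grid wavelength inside coordinate ",
           ranges$wamac[i], " [", ranges$lo[i], ", ", ranges$hi[i], "] nm")
    # rank sum over available criteria; rank 1 = largest magnitude;
    # ties within a criterion share the minimum rank so that flat inputs
    # leave the final lower-wavelength tie-break in charge
    total <- rowSums(vapply(crit, function(v) {
      rank(-v[cand], ties.method = "min")
    }, numeric(length(cand))))
    cand[which.min(total)]          # which.min takes the first = lowest nm
  }, integer(1))
  out <- data.frame(wavelength = wl[picked],
                    wamac = ranges$wamac,
                    assignment = ref$assignment[match(ranges$wamac, ref$wamac)],
                    stringsAsFactors = FALSE)
  if (any(diff(out$wavelength) <= 0))
    stop("select_wabs: selected wavelengths are not strictly increasing; ",
         "coordinate ranges overlap on this grid")
  class(out) <- c("wab_set", "data.frame")
  validate_wab_set(out)
}

# Linear interpolation of each row of a dataset at arbitrary wavelengths;
# exact at grid points.
interp_at <- function(ds, at) {
  wl <- ds$wavelengths
  if (any(at < wl[1] | at > wl[length(wl)]))
    stop("wavelength outside the grid span")
  t(apply(ds$values, 1L, function(x) {
    stats::approx(wl, x, xout = at, method = "linear")$y
  }))
}

#' Compute an aquagram
#'
#' Group-mean standardised absorbance at the twelve WABs. Because the
#' instrument grid (~5.6 nm spacing) does not contain the reference
#' wavelengths exactly, values are linearly interpolated between the two
#' flanking grid points; at a grid point the interpolation is exact.
#'
#' With `flip_sign = TRUE` (default) the axis value is the negated
#' standardised second-derivative value. A growing absorbance band makes
#' the second derivative at its centre more negative, so negation renders
#' "more of this water species" as a larger radius — the orientation in
#' which a prevalence of free water late in storage reads as a rise at
#' 1416/1428 nm. Set `flip_sign = FALSE` for the raw standardised scale.
#'
#' @param norm_ds standardised `spectral_dataset` (aquagram chain output).
#' @param wabs a `wab_set`; default [default_wabs()].
#' @param group_keys subset of `c("treatment", "day")` defining the curves.
#' @param flip_sign negate values (see Details).
#' @return object of class `aquagram_result`: `groups` (data frame of key
#'   values), `values` (n_groups x 12), `wabs`, `flip_sign`.
#' @export
compute_aquagram <- function(norm_ds, wabs = default_wabs(),
                             group_keys = c("treatment", "day"),
                             flip_sign = TRUE) {
  validate_spectral_dataset(norm_ds)
  validate_wab_set(wabs)
  group_keys <- as.character(group_keys)
  if (!length(group_keys)) stop("compute_aquagram: empty group keys")
  missing <- setdiff(group_keys, names(norm_ds$samples))
  if (length(missing))
    stop("compute_aquagram: metadata lacks ", paste(missing, collapse = ", "))
  gm <- average_by(norm_ds, group_keys)
  vals <- interp_at(gm, wabs$wavelength)
  if (flip_sign) vals <- -vals
  colnames(vals) <- wabs$wamac
  structure(list(
    groups = gm$samples[, group_keys, drop = FALSE],
    values = vals,
    wabs = wabs,
    flip_sign = flip_sign
  ), class = "aquagram_result")
}

#' @export
print.aquagram_result <- function(x, ...) {
  cat("<aquagram_result>", nrow(x$values), "group(s) x 12 WABs",
      if (x$flip_sign) "(sign-flipped scale)" else "(raw scale)", "\n")
  invisible(x)
}

#' Aquagram as a long data frame
#' @param x an `aquagram_result`.
#' @param ... unused.
#' @return data frame with group keys, `wamac`, `wavelength`, `value`.
#' @export
as.data.frame.aquagram_result <- function(x, ...) {
  k <- nrow(x$values)
  out <- x$groups[rep(seq_len(k), each = 12), , drop = FALSE]
  out$wamac <- rep(x$wabs$wamac, times = k)
  out$wavelength <- rep(x$wabs$wavelength, times = k)
  out$value <- as.vector(t(x$values))
  rownames(out) <- NULL
  out
}

#' Render an aquagram radar chart
#'
#' Twelve axes ordered C1 (top) clockwise to C12, one closed polyline per
#' group, optionally one panel per value of `panel_by` (e.g. treatment)
#' with a radial scale shared across panels so patterns stay comparable.
#'
#' @param aq an `aquagram_result`.
#' @param path output image path (.png).
#' @param panel_by optional group column to facet by.
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
render_aquagram <- function(aq, path, panel_by = NULL,
                            width = 9, height = 4, dpi = 150) {
  stopifnot(inherits(aq, "aquagram_result"))
  if (nrow(aq$values) == 0) stop("render_aquagram: empty group list")
  df <- as.data.frame(aq)
  # clockwise from top: C1 at angle 0, subsequent axes increasing
  df$axis <- match(df$wamac, aq$wabs$wamac)
  keys <- setdiff(names(aq$groups), panel_by)
  df$curve <- if (length(keys)) {
    interaction(df[, keys, drop = FALSE], drop = TRUE, sep = " / ")
  } else factor("all")
  # close the polygons
  closing <- df[df$axis == 1, , drop = FALSE]
  closing$axis <- 13
  df <- rbind(df, closing)
  rng <- range(aq$values)
  pad <- 0.05 * diff(rng)
  if (pad == 0) pad <- 1
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$axis, y = .data$value,
    group = .data$curve, colour = .data$curve)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::scale_x_continuous(
      breaks = 1:12,
      labels = paste0(aq$wabs$wamac, "\n", aq$wabs$wavelength),
      limits = c(1, 13)) +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::ylim(rng[1] - pad, rng[2] + pad) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 8)
  if (!is.null(panel_by))
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", panel_by)))
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Serialise an aquagram to CSV
#' @param aq an `aquagram_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_aquagram <- function(aq, path) {
  stopifnot(inherits(aq, "aquagram_result"))
  wide <- cbind(aq$groups, as.data.frame(aq$values))
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(format(wide, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
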