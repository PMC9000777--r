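#' Convert reflectance spectra to absorbance
#'
#' Applies the standard transform A = log10(1/R) to every value. The
#' instrument acquires in reflectance mode; all chemometric pretreatment in
#' this package operates on absorbance.
#'
#' @param ds a `spectral_dataset` in reflectance mode, all values > 0.
#' @return the dataset in absorbance mode; metadata unchanged.
#' @export
reflectance_to_absorbance <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (ds$mode != "reflectance")
    stop("reflectance_to_absorbance: dataset is already in ", ds$mode)
  bad <- which(ds$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "nonpositive reflectance at sample %d, wavelength %.2f nm",
      bad[1, 1], ds$wavelengths[bad[1, 2]]))
  }
  validate_spectral_dataset(ds)
  out <- ds
  out$values <- log10(1 / ds$values)
  out$mode <- "absorbance"
  out
}

#' Invert the absorbance transform
#'
#' R = 10^(-A); inverse of [reflectance_to_absorbance()], mainly for
#' round-trip checks and for emitting instrument-like reflectance files.
#'
#' @param ds a `spectral_dataset` in absorbance mode.
#' @return the dataset in reflectance mode.
#' @export
absorbance_to_reflectance <- function(ds) {
  validate_spectral_dataset(ds)
  if (ds$mode != "absorbance")
    stop("absorbance_to_reflectance: dataset is in ", ds$mode)
  out <- ds
  out$values <- 10^(-ds$values)
  out$mode <- "reflectance"
  out
}

#' Subtract a reference (packaging) spectrum
#'
#' Subtracts the mean of the reference spectra from every sample spectrum,
#' e.g. to remove the PET packaging contribution when spectra are acquired
#' through a sealed bag. Both datasets must share the wavelength grid and
#' mode; the subtraction is performed in that common mode.
#'
#' @param ds sample `spectral_dataset`.
#' @param ref reference `spectral_dataset` (e.g. 10 packaging spectra).
#' @return `ds` with the mean reference spectrum subtracted; metadata kept.
#' @export
subtract_reference <- function(ds, ref) {
  validate_spectral_dataset(ds)
  validate_spectral_dataset(ref)
  if (length(ds$wavelengths) != length(ref$wavelengths) ||
      any(ds$wavelengths != ref$wavelengths))
    stop("subtract_reference: wavelength grid mismatch")
  if (ds$mode != ref$mode)
    stop("subtract_reference: mode mismatch (", ds$mode, " vs ", ref$mode, ")")
  ref_mean <- colMeans(ref$values)
  out <- ds
  out$values <- sweep(ds$values, 2L, ref_mean, "-")
  if (out$mode == "reflectance" &&
      (any(out$values <= 0) || any(out$values > 1)))
    stop("subtract_reference: result leaves the (0, 1] reflectance range; ",
         "convert to absorbance before subtracting")
  out
}

#' Truncate a dataset to a wavelength range
#'
#' Keeps the grid points with `lo <= wavelength <= hi`, e.g. the first
#' overtone of water at 1300-1600 nm where the twelve water matrix
#' coordinates live.
#'
#' @param ds a `spectral_dataset`.
#' @param lo,hi range bounds in nm, `lo < hi`.
#' @return truncated dataset; errors if no grid point falls in the range.
#' @export
truncate_spectra <- function(ds, lo, hi) {
  validate_spectral_dataset(ds)
  if (lo >= hi) stop("truncate_spectra: lo must be < hi")
  keep <- ds$wavelengths >= lo & ds$wavelengths <= hi
  if (!any(keep))
    stop(sprintf("truncate_spectra: empty range [%g, %g] on this grid", lo, hi))
  out <- ds
  out$wavelengths <- ds$wavelengths[keep]
  out$values <- ds$values[, keep, drop = FALSE]
  out
}

#' Average spectra by metadata keys
#'
#' Collapses the dataset to one mean spectrum per distinct combination of
#' the grouping keys (e.g. `c("treatment", "day")` for checkpoint means).
#' The `replicate` field of each output row records how many spectra were
#' averaged; other metadata columns are kept where constant within the
#' group and set to NA otherwise.
#'
#' @param ds a `spectral_dataset`.
#' @param keys non-empty character subset of
#'   `c("treatment", "day", "bag", "side")`.
#' @return averaged dataset, groups ordered by the keys.
#' @export
average_by <- function(ds, keys) {
  validate_spectral_dataset(ds)
  keys <- as.character(keys)
  if (!length(keys)) stop("average_by: keys must be non-empty")
  bad <- setdiff(keys, c("treatment", "day", "bag", "side"))
  if (length(bad)) stop("average_by: unknown key(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(keys, names(ds$samples))
  if (length(missing))
    stop("average_by: metadata lacks column(s): ", paste(missing, collapse = ", "))

  key_df <- ds$samples[, keys, drop = FALSE]
  gid <- interaction(key_df, drop = TRUE, lex.order = TRUE)
  groups <- levels(gid)
  idx <- split(seq_len(n_spectra(ds)), gid)

  vals <- t(vapply(idx, function(i) colMeans(ds$values[i, , drop = FALSE]),
                   numeric(length(ds$wavelengths))))
  dimnames(vals) <- NULL

  meta <- do.call(rbind, lapply(idx, function(i) {
    row <- ds$samples[i[1], , drop = FALSE]
    for (col in setdiff(names(row), keys)) {
      u <- unique(ds$samples[i, col])
      if (length(u) != 1L) row[[col]] <- NA
    }
    row$replicate <- length(i)
    row
  }))
  rownames(meta) <- NULL

  out <- ds
  out$values <- vals
  out$samples <- meta
  stopifnot(length(groups) == nrow(vals))
  out
}

#' Checkpoint means in the acquisition hierarchy
#'
#' Two-stage averaging used for per-checkpoint spectra: replicate spectra
#' are first averaged within bag side, sides within bag, then bags within
#' treatment x day. With balanced replication this equals a flat mean; the
#' staged order is kept so unbalanced data weight bags equally.
#'
#' @param ds a `spectral_dataset` with full metadata.
#' @return one spectrum per (treatment, day).
#' @export
checkpoint_means <- function(ds) {
  have <- names(ds$samples)
  stages <- list(c("treatment", "day", "bag", "side"),
                 c("treatment", "day", "bag"),
                 c("treatment", "day"))
  out <- ds
  for (st in stages) {
    st <- intersect(st, have)
    if (length(st)) out <- average_by(out, st)
  }
  out
}
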