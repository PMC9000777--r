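#' Spectral dataset container
#'
#' A `spectral_dataset` bundles a strictly increasing wavelength grid (nm),
#' a spectra matrix (one row per spectrum) and per-spectrum sample metadata.
#' Every pretreatment operator in the package maps a `spectral_dataset` to a
#' new `spectral_dataset`, so chains can be composed freely.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values numeric matrix, `n_spectra x n_wavelengths`. Reflectance is
#'   a fraction in (0, 1]; absorbance is in AU (any sign after derivative
#'   pretreatments).
#' @param mode `"reflectance"` or `"absorbance"`.
#' @param samples data frame with one row per spectrum. Recognised columns:
#'   `treatment` (factor levels "A", "B", "C" — the storage atmospheres:
#'   A = air 21% O2 / 78% N2, B = 30% O2 / 70% N2,
#'   C = 10% CO2 / 5% O2 / 85% N2), `day` (non-negative integer storage
#'   day), `bag`, `side` ("front"/"back") and `replicate`.
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavelengths, values, mode, samples) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.matrix(values)
  mode <- match.arg(mode, c("reflectance", "absorbance"))
  samples <- as.data.frame(samples)
  ds <- structure(
    list(wavelengths = wavelengths, values = values, mode = mode,
         samples = samples),
    class = "spectral_dataset"
  )
  validate_spectral_dataset(ds)
}

#' Validate a spectral dataset
#'
#' Checks the structural invariants: strictly increasing grid, matching
#' dimensions between grid, values and metadata, reflectance in (0, 1],
#' known treatment codes and non-negative days.
#'
#' @param ds object to validate.
#' @return `ds`, invisibly unchanged, or an error.
#' @export
validate_spectral_dataset <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  wl <- ds$wavelengths
  if (length(wl) < 1L) stop("spectral_dataset: empty wavelength grid")
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("spectral_dataset: wavelengths must be strictly increasing")
  if (!is.matrix(ds$values) || !is.numeric(ds$values))
    stop("spectral_dataset: values must be a numeric matrix")
  if (ncol(ds$values) != length(wl))
    stop("spectral_dataset: ncol(values) != length(wavelengths)")
  if (nrow(ds$values) != nrow(ds$samples))
    stop("spectral_dataset: nrow(values) != nrow(samples)")
  if (nrow(ds$values) == 0L) stop("spectral_dataset: no spectra")
  if (ds$mode == "reflectance") {
    if (any(!is.finite(ds$values)) ||
        any(ds$values <= 0) || any(ds$values > 1))
      stop("spectral_dataset: reflectance values must lie in (0, 1]")
  }
  sm <- ds$samples
  if ("treatment" %in% names(sm)) {
    tr <- as.character(sm$treatment)
    bad <- setdiff(unique(tr[!is.na(tr)]), c("A", "B", "C"))
    if (length(bad))
      stop("spectral_dataset: unknown treatment code(s): ",
           paste(bad, collapse = ", "))
  }
  if ("day" %in% names(sm)) {
    if (any(!is.na(sm$day) & sm$day < 0))
      stop("spectral_dataset: storage day must be non-negative")
  }
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d wavelengths [%.1f-%.1f nm], %s\n",
    nrow(x$values), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$mode))
  meta <- intersect(c("treatment", "day", "bag", "side", "replicate"),
                    names(x$samples))
  if (length(meta)) cat("  metadata:", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$values)

#' Number of spectra in a dataset
#' @param ds a `spectral_dataset`.
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(ds) nrow(ds$values)

#' The 125-point instrument wavelength grid
#'
#' The portable instrument emulated here reads 125 points over 900-1600 nm;
#' only the endpoints and the count are published, so the grid is taken as
#' evenly spaced over the closed interval (spacing ~5.645 nm).
#'
#' @param lo,hi range endpoints in nm.
#' @param n number of reading points.
#' @return numeric vector of length `n`.
#' @export
instrument_grid <- function(lo = 900, hi = 1600, n = 125) {
  seq(lo, hi, length.out = n)
}

meta_cols <- c("treatment", "day", "bag", "side", "replicate")

# Coerce raw metadata columns read from CSV into canonical types; errors on
# unparseable content rather than silently defaulting.
parse_sample_meta <- function(df) {
  out <- df
  if ("treatment" %in% names(out)) {
    tr <- as.character(out$treatment)
    bad <- setdiff(unique(tr[!is.na(tr)]), c("A", "B", "C"))
    if (length(bad))
      stop("unknown treatment code(s): ", paste(bad, collapse = ", "))
    out$treatment <- tr
  }
  for (col in c("day", "replicate")) {
    if (col %in% names(out)) {
      v <- suppressWarnings(as.numeric(out[[col]]))
      if (anyNA(v) && !all(is.na(out[[col]])))
        stop("unparseable '", col, "' metadata")
      out[[col]] <- as.integer(v)
    }
  }
  if ("side" %in% names(out)) out$side <- as.character(out$side)
  if ("bag" %in% names(out)) out$bag <- as.character(out$bag)
  out
}

#' Read a spectral dataset from CSV
#'
#' Two dialects are supported. `wide_csv`: one row per spectrum; reserved
#' metadata columns (`treatment`, `day`, `bag`, `side`, `replicate`, any
#' subset) come first, followed by one column per wavelength whose header is
#' the nm value. `long_csv`: one row per (spectrum, wavelength) with columns
#' `spectrum` (row index), the metadata columns, `wavelength` and `value`.
#'
#' @param path CSV file path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param mode mode of the stored values (the CSV itself carries no mode).
#' @return a validated [spectral_dataset()].
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "long_csv"),
                         mode = "absorbance") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no spectra in ", path)
  if (dialect == "wide_csv") {
    is_wl <- !is.na(suppressWarnings(as.numeric(names(df))))
    if (!any(is_wl)) stop("no wavelength columns found in ", path)
    wl <- as.numeric(names(df)[is_wl])
    if (any(diff(wl) <= 0))
      stop("non-monotone wavelength header in ", path)
    vals <- as.matrix(df[, is_wl, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric spectral values in ", path)
    storage.mode(vals) <- "double"
    dimnames(vals) <- NULL
    samples <- parse_sample_meta(df[, !is_wl, drop = FALSE])
    spectral_dataset(wl, vals, mode, samples)
  } else {
    need <- c("spectrum", "wavelength", "value")
    if (!all(need %in% names(df)))
      stop("long_csv requires columns: ", paste(need, collapse = ", "))
    wl <- sort(unique(df$wavelength))
    ids <- sort(unique(df$spectrum))
    key <- match(df$spectrum, ids)
    col <- match(df$wavelength, wl)
    vals <- matrix(NA_real_, length(ids), length(wl))
    vals[cbind(key, col)] <- df$value
    if (anyNA(vals)) stop("ragged long_csv: missing (spectrum, wavelength) cells")
    first <- !duplicated(df$spectrum)
    meta <- df[first, intersect(meta_cols, names(df)), drop = FALSE]
    meta <- meta[order(df$spectrum[first]), , drop = FALSE]
    rownames(meta) <- NULL
    spectral_dataset(wl, vals, mode, parse_sample_meta(meta))
  }
}

#' Write a spectral dataset to CSV
#'
#' Inverse of [read_spectra()]: values survive a write/read round trip within
#' floating-point printing precision (17 significant digits are written, enough for bit-exact doubles).
#'
#' @param ds a `spectral_dataset`.
#' @param path output file path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, dialect = c("wide_csv", "long_csv")) {
  validate_spectral_dataset(ds)
  dialect <- match.arg(dialect)
  meta <- ds$samples[, intersect(meta_cols, names(ds$samples)), drop = FALSE]
  if (dialect == "wide_csv") {
    vals <- as.data.frame(ds$values)
    names(vals) <- format(ds$wavelengths, digits = 17, trim = TRUE,
                          scientific = FALSE)
    out <- cbind(meta, vals)
  } else {
    n <- n_spectra(ds); p <- length(ds$wavelengths)
    out <- data.frame(spectrum = rep(seq_len(n), each = p))
    for (col in names(meta)) out[[col]] <- rep(meta[[col]], each = p)
    out$wavelength <- rep(ds$wavelengths, times = n)
    out$value <- as.vector(t(ds$values))
  }
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
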