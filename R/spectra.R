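#' Construct a spectrum
#'
#' A spectrum is a sampled function of wavelength: reflectance of a surface,
#' spectral sensitivity of a photoreceptor, or spectral irradiance of an
#' illuminant. Wavelengths must be strictly increasing and lie in the
#' 200--1000 nm window that covers the instruments and visual systems this
#' package deals with.
#'
#' Reflectance is stored internally as a proportion. Spectrometer exports in
#' percent (detected when the maximum value exceeds 1.5) are divided by 100
#' with a message. Small negative reflectances -- common instrument noise
#' around dark surfaces -- are clamped to 0 with a warning; values above the
#' white standard (>1 after unit handling) are kept but flagged, since
#' glossy or fluorescent samples can legitimately exceed it.
#'
#' @param wl Numeric vector of wavelengths in nm, strictly increasing,
#'   all within \[200, 1000\].
#' @param value Numeric vector of the same length: reflectance (proportion
#'   or percent), sensitivity, or relative irradiance.
#' @param kind One of `"reflectance"`, `"sensitivity"`, `"irradiance"`.
#' @return An object of class `"spectrum"`: a list with elements `wl`,
#'   `value` and `kind`.
#' @examples
#' s <- spectrum(c(300, 400, 500), c(0.1, 0.2, 0.3))
#' s
#' @export
spectrum <- function(wl, value, kind = c("reflectance", "sensitivity", "irradiance")) {
  kind <- match.arg(kind)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) != length(value))
    stop("`wl` and `value` must have the same length", call. = FALSE)
  if (length(wl) < 2L)
    stop("a spectrum needs at least 2 sampled wavelengths", call. = FALSE)
  if (anyNA(wl) || any(!is.finite(wl)))
    stop("wavelengths must be finite and non-missing", call. = FALSE)
  if (anyNA(value) || any(!is.finite(value)))
    stop("spectral values must be finite and non-missing", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wl) < 200 || max(wl) > 1000)
    stop("wavelengths must lie within [200, 1000] nm", call. = FALSE)
  if (kind == "reflectance") {
    if (max(value) > 1.5) {
      message("reflectance maximum ", format(max(value)),
              " > 1.5: interpreting values as percent and converting to proportion")
      value <- value / 100
    }
    if (any(value < 0)) {
      warning("negative reflectance values clamped to 0 (instrument noise)",
              call. = FALSE)
      value[value < 0] <- 0
    }
    if (any(value > 1))
      warning("reflectance values above the white standard (>1) retained",
              call. = FALSE)
  }
  structure(list(wl = wl, value = value, kind = kind), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm, range [%.4g, %.4g]>\n",
              x$kind, length(x$wl), min(x$wl), max(x$wl),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wl = x$wl, value = x$value)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation onto `seq(grid_lo, grid_hi, by = step)`. Resampling
#' is exact on nodes of the source grid. By default the target grid must lie
#' inside the spectrum's support; with `extrapolate = TRUE`, values outside
#' the support are held at the nearest measured endpoint.
#'
#' @param x A [spectrum()].
#' @param grid_lo,grid_hi Grid bounds in nm.
#' @param step Grid step in nm.
#' @param extrapolate Allow the grid to extend beyond the measured support?
#' @return A [spectrum()] on the requested grid, same `kind`.
#' @examples
#' s <- spectrum(c(300, 400, 500), c(0, 1, 0))
#' resample(s, 300, 500, 50)
#' @export
resample <- function(x, grid_lo, grid_hi, step = 1, extrapolate = FALSE) {
  stopifnot(is_spectrum(x))
  if (grid_hi <= grid_lo) stop("`grid_hi` must exceed `grid_lo`", call. = FALSE)
  if (!extrapolate && (grid_lo < min(x$wl) || grid_hi > max(x$wl)))
    stop(sprintf(
      "target grid [%g, %g] outside measured support [%g, %g]; set extrapolate = TRUE to hold endpoint values",
      grid_lo, grid_hi, min(x$wl), max(x$wl)), call. = FALSE)
  grid <- seq(grid_lo, grid_hi, by = step)
  v <- stats::approx(x$wl, x$value, xout = grid, method = "linear", rule = 2)$y
  spectrum(grid, v, kind = x$kind)
}

#' Construct a set of like-kind spectra
#'
#' A spectrum set collects repeated measurements of one patch class (e.g.
#' the yellow stripes of adult spiders, or the vegetation background), one
#' spectrum per specimen or measurement.
#'
#' @param spectra A non-empty list of [spectrum()] objects sharing `kind`.
#' @param label Patch identifier, e.g. `"yellow_adult"` or `"vegetation"`.
#' @return An object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(spectra, label = "unlabelled") {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("`spectra` must be a non-empty list of spectrum objects", call. = FALSE)
  if (!all(vapply(spectra, is_spectrum, logical(1))))
    stop("all elements of `spectra` must be spectrum objects", call. = FALSE)
  kinds <- unique(vapply(spectra, function(s) s$kind, character(1)))
  if (length(kinds) != 1L)
    stop("all spectra in a set must share the same kind", call. = FALSE)
  structure(list(spectra = spectra, label = label, kind = kinds),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set '%s': %d %s spectra>\n",
              x$label, length(x$spectra), x$kind))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

same_grid <- function(spectra) {
  wl0 <- spectra[[1]]$wl
  all(vapply(spectra, function(s)
    length(s$wl) == length(wl0) && all(s$wl == wl0), logical(1)))
}

#' Pointwise mean spectrum of a set
#'
#' All spectra must already sit on one common grid (use [resample()] first);
#' the mean is the pointwise arithmetic mean across specimens.
#'
#' @param x A [spectrum_set()].
#' @return A [spectrum()] of the same kind on the shared grid.
#' @export
mean_spectrum <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  if (!same_grid(x$spectra))
    stop("spectra are not on a common grid; resample() them first", call. = FALSE)
  vals <- vapply(x$spectra, function(s) s$value, numeric(length(x$spectra[[1]]$wl)))
  spectrum(x$spectra[[1]]$wl, rowMeans(as.matrix(vals)), kind = x$kind)
}

#' Read spectra from a wide CSV file
#'
#' The canonical dialect is a header row, a wavelength column (named `"wl"`,
#' or the first column otherwise) and one numeric column per measurement --
#' the layout most spectrometer software exports.
#'
#' @param path Path to a CSV file.
#' @param kind Kind to assign to the spectra (default reflectance).
#' @param label Label for the returned set; defaults to the file name.
#' @return A [spectrum_set()], one spectrum per measurement column, named
#'   after the columns.
#' @export
read_spectra <- function(path, kind = "reflectance", label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("spectra file must have a wavelength column and at least one measurement column",
         call. = FALSE)
  wl_col <- if ("wl" %in% names(tab)) "wl" else names(tab)[1]
  wl <- suppressWarnings(as.numeric(tab[[wl_col]]))
  if (anyNA(wl))
    stop("non-numeric entries in the wavelength column", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelength column must be strictly increasing (unsorted input)", call. = FALSE)
  meas <- setdiff(names(tab), wl_col)
  spectra <- lapply(meas, function(cn) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop("non-numeric entries in measurement column '", cn, "'", call. = FALSE)
    spectrum(wl, v, kind = kind)
  })
  names(spectra) <- meas
  spectrum_set(spectra, label = label %||% basename(path))
}

#' Write a spectrum set to the canonical wide CSV dialect
#'
#' @param x A [spectrum_set()] on a common grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  if (!same_grid(x$spectra))
    stop("spectra are not on a common grid", call. = FALSE)
  vals <- lapply(x$spectra, function(s) s$value)
  nm <- names(x$spectra)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- sprintf("%s_%02d", x$label, seq_along(x$spectra))
  # full double precision so read -> write -> read round-trips bit-identically
  out <- data.frame(wl = sprintf("%.17g", x$spectra[[1]]$wl),
                    lapply(vals, function(v) sprintf("%.17g", v)),
                    check.names = FALSE)
  names(out) <- c("wl", nm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The canonical working wavelength grid
#'
#' 300--700 nm at 1 nm: covers hymenopteran spectral sensitivity with room
#' on both sides of the receptor peaks.
#'
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function() seq(300, 700, by = 1)
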