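# Trichromatic hymenopteran colour-vision model: quantum catches under von
# Kries adaptation to a vegetation background, colour-hexagon coordinates,
# chromatic (hexagon distance) and achromatic (green-catch ratio) contrast.

# CIE standard illuminant D65, relative spectral power distribution in
# energy units, 300-700 nm at 10 nm (standard published tabulation,
# normalized to 100 at 560 nm).
.d65_wl <- seq(300, 700, by = 10)
.d65_energy <- c(
  0.0341, 3.2945, 20.2360, 37.0535, 39.9488, 44.9117, 46.6383, 52.0891,
  49.9755, 54.6482, 82.7549, 91.4860, 93.4318, 86.6823, 104.8650, 117.0080,
  117.8120, 114.8610, 115.9230, 108.8110, 109.3540, 107.8020, 104.7900,
  107.6890, 104.4050, 104.0460, 100.0000, 96.3342, 95.7880, 88.6856,
  90.0062, 89.5991, 87.6987, 83.2886, 83.6992, 80.0268, 80.1207, 82.2778,
  78.2842, 69.7213, 71.6091)

#' CIE D65 daylight illuminant
#'
#' Returns the standard D65 spectral power distribution interpolated onto a
#' wavelength grid. Receptor models work with photon (quantal) flux, so by
#' default the tabulated energy units are converted to relative quanta by
#' multiplying by wavelength; the result is max-normalized (the overall
#' scale of the illuminant cancels in the von Kries normalization anyway).
#'
#' @param grid Wavelength grid in nm (default [default_grid()]).
#' @param quantal Convert energy units to relative quanta (default `TRUE`)?
#' @return A [spectrum()] of kind `"irradiance"`.
#' @export
cie_d65 <- function(grid = default_grid(), quantal = TRUE) {
  if (min(grid) < min(.d65_wl) || max(grid) > max(.d65_wl))
    stop("requested grid outside the bundled D65 tabulation (300-700 nm)",
         call. = FALSE)
  v <- stats::approx(.d65_wl, .d65_energy, xout = grid, rule = 1)$y
  if (quantal) v <- v * grid
  spectrum(grid, v / max(v), kind = "irradiance")
}

#' Visual-pigment sensitivity template
#'
#' Renders a smooth, unimodal (alpha band plus short-wavelength beta band)
#' photoreceptor sensitivity curve from its wavelength of peak absorbance,
#' using the Govardovskii et al. (2000) A1 rhodopsin template. The curve is
#' max-normalized to 1 at its peak.
#'
#' @param lambda_max Peak wavelength in nm; must lie inside `grid`.
#' @param grid Wavelength grid in nm.
#' @return A [spectrum()] of kind `"sensitivity"`, values in \[0, 1\].
#' @export
receptor_template <- function(lambda_max, grid = default_grid()) {
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("`lambda_max` must lie within the wavelength grid", call. = FALSE)
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lmb) / bb)^2)
  s <- alpha + beta
  spectrum(grid, s / max(s), kind = "sensitivity")
}

#' Assemble a trichromatic visual system
#'
#' Bundles the three receptor sensitivities (UV, blue, green), the
#' illuminant, and the adapting background into one object on a common
#' wavelength grid. Backgrounds and user-supplied spectra are resampled to
#' the grid. The von Kries denominators (background quantum catches per
#' receptor) are precomputed; a receptor whose background catch is zero is
#' rejected as a degenerate background.
#'
#' @param background A [spectrum()] (reflectance) or [spectrum_set()] of
#'   vegetation measurements; a set is averaged after resampling.
#' @param lambda_max Named or ordered numeric triple of peak wavelengths
#'   (UV, blue, green) in nm. Defaults to an *Apis mellifera*-like set.
#' @param sensitivities Optional list of three [spectrum()] sensitivity
#'   curves (uv, blue, green) overriding the template.
#' @param illuminant Optional [spectrum()] irradiance; default [cie_d65()].
#' @param grid Common wavelength grid (default [default_grid()]).
#' @return An object of class `"visual_system"`.
#' @export
visual_system <- function(background,
                          lambda_max = c(uv = 344, blue = 436, green = 544),
                          sensitivities = NULL,
                          illuminant = NULL,
                          grid = default_grid()) {
  if (inherits(background, "spectrum_set")) {
    background <- spectrum_set(lapply(background$spectra, resample,
                                      grid_lo = min(grid), grid_hi = max(grid),
                                      step = grid[2] - grid[1]),
                               label = background$label)
    background <- mean_spectrum(background)
  }
  stopifnot(is_spectrum(background))
  background <- resample(background, min(grid), max(grid), grid[2] - grid[1])
  if (is.null(sensitivities)) {
    if (length(lambda_max) != 3L)
      stop("`lambda_max` must hold three peak wavelengths (uv, blue, green)",
           call. = FALSE)
    sensitivities <- lapply(lambda_max, receptor_template, grid = grid)
  } else {
    if (length(sensitivities) != 3L)
      stop("`sensitivities` must hold three sensitivity spectra", call. = FALSE)
    sensitivities <- lapply(sensitivities, resample, grid_lo = min(grid),
                            grid_hi = max(grid), step = grid[2] - grid[1])
  }
  names(sensitivities) <- c("uv", "blue", "green")
  illuminant <- if (is.null(illuminant)) cie_d65(grid) else
    resample(illuminant, min(grid), max(grid), grid[2] - grid[1])
  vs <- structure(list(sensitivities = sensitivities,
                       illuminant = illuminant,
                       background = background,
                       grid = grid), class = "visual_system")
  denom <- vapply(names(sensitivities), function(r)
    trapz_catch(background, sensitivities[[r]], illuminant), numeric(1))
  if (any(denom <= 0))
    stop("degenerate background: zero quantum catch for receptor(s) ",
         paste(names(denom)[denom <= 0], collapse = ", "), call. = FALSE)
  vs$background_catch <- denom
  vs
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system: trichromat on %g-%g nm grid (%d points)>\n",
              min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

# Unnormalized receptor signal: trapezoidal integral of
# stimulus * sensitivity * illuminant over the common grid.
trapz_catch <- function(stimulus, sensitivity, illuminant) {
  pracma::trapz(stimulus$wl, stimulus$value * sensitivity$value * illuminant$value)
}

check_on_grid <- function(stimulus, vs) {
  if (!(length(stimulus$wl) == length(vs$grid) && all(stimulus$wl == vs$grid)))
    stop("stimulus is not on the visual system's wavelength grid; resample() it first",
         call. = FALSE)
}

#' Quantum catch of a stimulus, von Kries normalized
#'
#' The receptor-weighted integral of the stimulus under the illuminant,
#' divided by the same integral for the adapting background, so the
#' background yields a catch of exactly 1 for every receptor (von Kries
#' chromatic adaptation).
#'
#' @param stimulus A reflectance [spectrum()] on the system's grid.
#' @param vs A [visual_system()].
#' @param receptor `"uv"`, `"blue"`, `"green"`, or `NULL` for all three.
#' @return Named numeric vector of catches (or a scalar for one receptor).
#' @export
quantum_catch <- function(stimulus, vs, receptor = NULL) {
  stopifnot(inherits(vs, "visual_system"), is_spectrum(stimulus))
  check_on_grid(stimulus, vs)
  rec <- receptor %||% c("uv", "blue", "green")
  rec <- match.arg(rec, c("uv", "blue", "green"), several.ok = TRUE)
  p <- vapply(rec, function(r)
    trapz_catch(stimulus, vs$sensitivities[[r]], vs$illuminant) /
      vs$background_catch[[r]], numeric(1))
  if (length(p) == 1L) unname(p) else p
}

#' Receptor excitation from quantum catch
#'
#' The hyperbolic (Michaelis--Menten) transform `E = P / (P + 1)`: half the
#' maximum excitation at the adapting background (`P = 1`), saturating
#' towards 1 for bright stimuli.
#'
#' @param P Non-negative quantum catch(es).
#' @return Excitation values in \[0, 1).
#' @export
excitation <- function(P) {
  if (any(P < 0)) stop("quantum catch must be non-negative", call. = FALSE)
  P / (P + 1)
}

#' Colour-hexagon coordinates of an excitation triple
#'
#' Chittka's hexagon for trichromats: the adapted background (all
#' excitations 0.5) maps to the origin, and the six hexagon vertices lie at
#' distance 1.
#'
#' @param E Numeric triple `(uv, blue, green)` in \[0, 1\], or a matrix with
#'   three columns of such triples.
#' @return Numeric `(x, y)` pair, or a two-column matrix.
#' @export
hexagon_coords <- function(E) {
  if (is.matrix(E)) {
    stopifnot(ncol(E) == 3L)
    cbind(x = sqrt(3) / 2 * (E[, 3] - E[, 1]),
          y = E[, 2] - 0.5 * (E[, 1] + E[, 3]))
  } else {
    stopifnot(length(E) == 3L)
    c(x = sqrt(3) / 2 * (E[[3]] - E[[1]]),
      y = E[[2]] - 0.5 * (E[[1]] + E[[3]]))
  }
}

hexagon_coords_of <- function(sample, vs) {
  E <- excitation(quantum_catch(sample, vs))
  hexagon_coords(c(E[["uv"]], E[["blue"]], E[["green"]]))
}

#' Chromatic contrast (hexagon distance to the background)
#'
#' Euclidean distance in the colour-hexagon plane between a sample and the
#' adapting background. Under von Kries adaptation the background sits at
#' the origin, so the contrast is the norm of the sample's coordinates;
#' it lies in \[0, 1\] and drives short-range (colour-based) detection.
#'
#' @param sample A reflectance [spectrum()] on the system's grid.
#' @param vs A [visual_system()].
#' @return Chromatic contrast in hexagon units.
#' @export
chromatic_contrast <- function(sample, vs) {
  xy <- hexagon_coords_of(sample, vs)
  bg <- hexagon_coords_of(vs$background, vs)
  sqrt(sum((xy - bg)^2))
}

#' Achromatic contrast (green-receptor brightness ratio)
#'
#' The ratio of green-receptor quantum catches, sample over background: 1.0
#' means equal brightness, values above 1 a sample brighter than the
#' vegetation, below 1 darker. The linear catch (not the saturating
#' excitation) is used, so the ratio is unbounded above and exactly linear
#' in flat scalings of the sample. It drives long-range detection.
#'
#' @inheritParams chromatic_contrast
#' @return Non-negative brightness ratio.
#' @export
achromatic_contrast <- function(sample, vs) {
  quantum_catch(sample, vs, receptor = "green")
}

#' Per-specimen contrast records for patch spectra
#'
#' Computes chromatic and achromatic contrast against the system's
#' background for every spectrum in each set, after resampling to the
#' system grid.
#'
#' @param sets A [spectrum_set()] or (possibly named) list of sets.
#' @param vs A [visual_system()].
#' @return A data.frame with columns `patch`, `specimen`, `chromatic`,
#'   `achromatic` -- one row per measured spectrum.
#' @export
contrast_records <- function(sets, vs) {
  if (inherits(sets, "spectrum_set")) sets <- list(sets)
  step <- vs$grid[2] - vs$grid[1]
  rows <- lapply(sets, function(set) {
    ids <- names(set$spectra) %||% as.character(seq_along(set$spectra))
    if (any(!nzchar(ids))) ids <- as.character(seq_along(set$spectra))
    recs <- lapply(seq_along(set$spectra), function(i) {
      s <- resample(set$spectra[[i]], min(vs$grid), max(vs$grid), step)
      data.frame(patch = set$label, specimen = ids[i],
                 chromatic = chromatic_contrast(s, vs),
                 achromatic = achromatic_contrast(s, vs))
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
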