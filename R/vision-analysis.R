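# Assembles the spectrophotometric analysis: per-specimen contrasts of
# every body patch against the vegetation background, one-sample t-tests
# against the detection thresholds, and Holm adjustment within the
# chromatic and achromatic test families.

#' Spectrophotometric contrast analysis against a vegetation background
#'
#' Computes per-specimen chromatic and achromatic contrasts for every
#' patch class, then tests each patch's contrasts against the detection
#' thresholds with one-sample t-tests: chromatic contrasts against the
#' *Apis mellifera* colour-discrimination threshold (default 0.05 hexagon
#' units), achromatic contrasts against equal brightness (1.0).
#' Holm--Bonferroni adjustment is applied separately within the chromatic
#' and the achromatic family.
#'
#' @param spectra Named list of [spectrum_set()]s, one of which is the
#'   vegetation background (see `background_label`); or a directory path
#'   of CSV files, one per patch, read with [read_spectra()].
#' @param background_label Name of the background set (default
#'   `"vegetation"`).
#' @param chromatic_threshold Detection threshold for chromatic contrast,
#'   hexagon units.
#' @param achromatic_null Null achromatic ratio (equal brightness).
#' @param lambda_max,illuminant,grid Passed to [visual_system()].
#' @return An object of class `"vision_report"`: the contrast records, the
#'   Table-2-shaped test summary, and the visual system used.
#' @export
run_vision_analysis <- function(spectra, background_label = "vegetation",
                                chromatic_threshold = 0.05,
                                achromatic_null = 1.0,
                                lambda_max = c(uv = 344, blue = 436, green = 544),
                                illuminant = NULL, grid = default_grid()) {
  if (is.character(spectra) && length(spectra) == 1L) {
    files <- list.files(spectra, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L)
      stop("no CSV spectra files found in ", spectra, call. = FALSE)
    spectra <- stats::setNames(lapply(files, read_spectra),
                               sub("\\.csv$", "", basename(files)))
    for (nm in names(spectra)) spectra[[nm]]$label <- nm
  }
  if (!background_label %in% names(spectra))
    stop("no '", background_label, "' spectra supplied for the background",
         call. = FALSE)
  stopifnot(chromatic_threshold > 0, achromatic_null > 0)
  vs <- visual_system(spectra[[background_label]], lambda_max = lambda_max,
                      illuminant = illuminant, grid = grid)
  patches <- spectra[setdiff(names(spectra), background_label)]
  records <- contrast_records(patches, vs)
  tests <- do.call(rbind, lapply(split(records, records$patch), function(d) {
    chro <- one_sample_t(d$chromatic, chromatic_threshold)
    achr <- one_sample_t(d$achromatic, achromatic_null)
    data.frame(patch = d$patch[1], n = nrow(d),
               family = c("chromatic", "achromatic"),
               mean = c(mean(d$chromatic), mean(d$achromatic)),
               sd = c(stats::sd(d$chromatic), stats::sd(d$achromatic)),
               t = c(chro$statistic, achr$statistic),
               df = c(chro$df, achr$df),
               p = c(chro$p, achr$p))
  }))
  rownames(tests) <- NULL
  tests$p_holm <- NA_real_
  for (fam in c("chromatic", "achromatic")) {
    i <- tests$family == fam
    tests$p_holm[i] <- holm_adjust(tests$p[i])
  }
  structure(list(records = records, tests = tests, system = vs,
                 chromatic_threshold = chromatic_threshold,
                 achromatic_null = achromatic_null),
            class = "vision_report")
}

#' @export
print.vision_report <- function(x, digits = 3, ...) {
  cat("Chromatic/achromatic contrast vs vegetation background\n")
  cat(sprintf("  thresholds: chromatic %.3g hexagon units, achromatic %.3g\n\n",
              x$chromatic_threshold, x$achromatic_null))
  tab <- x$tests
  tab$mean_sd <- sprintf("%.2f +/- %.2f", tab$mean, tab$sd)
  print(format(tab[, c("family", "patch", "n", "mean_sd", "t", "df",
                       "p", "p_holm")], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a vision report as CSV tables
#'
#' @param report A `vision_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_vision_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "contrast_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "contrast_tests.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Plot mean reflectance spectra of patch sets
#'
#' Base-graphics line plot of the mean spectrum of each supplied set.
#'
#' @param sets Named list of [spectrum_set()]s on a common grid.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of mean spectra.
#' @export
plot_mean_spectra <- function(sets, ...) {
  means <- lapply(sets, mean_spectrum)
  wl <- means[[1]]$wl
  m <- vapply(means, function(s) s$value, numeric(length(wl)))
  graphics::matplot(wl, m, type = "l", lty = 1, lwd = 2,
                    xlab = "Wavelength (nm)", ylab = "Reflectance", ...)
  graphics::legend("topleft", legend = names(sets), col = seq_along(sets),
                   lty = 1, lwd = 2, bty = "n")
  invisible(m)
}
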