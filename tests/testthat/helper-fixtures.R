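# Small fixtures built in code at test time.

write_spectra_csv <- function(text) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# a smooth random reflectance curve (positive, bounded) for oracle checks
random_smooth_spectrum <- function(grid = default_grid()) {
  centre <- stats::runif(1, 350, 650)
  width <- stats::runif(1, 25, 120)
  base <- stats::runif(1, 0.02, 0.3)
  amp <- stats::runif(1, 0, 0.5)
  slope <- stats::runif(1, -2e-4, 2e-4)
  v <- base + amp * exp(-(grid - centre)^2 / (2 * width^2)) +
    slope * (grid - 500)
  v[v < 1e-4] <- 1e-4
  spectrum(grid, v)
}

default_background <- function(seed = 42) {
  mean_spectrum(sim_reflectance("vegetation", n = 8, seed = seed))
}
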