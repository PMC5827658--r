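# Seeded generators for every input the analyses consume: reflectance
# spectra, field web observations, and choice-experiment trials. One
# global seed fans out to fixed per-generator substreams so that adding a
# generator never perturbs the draws of an existing one.

sub_seed <- function(seed, tag) {
  s <- (as.numeric(seed) %% 2147483647) * 1103 + tag
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# truncated normal by inverse-CDF (keeps draw count deterministic)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Smooth patch shape templates on the working grid. Parameters are the
# generator's emulation of the measured curves: a green-peaked vegetation
# background, a yellow long-pass step with a slight UV peak, a dark flat
# black, and a pale-red curve rising beyond 600 nm. Amplitudes are chosen
# so the patches sit where the study places them relative to the
# background: yellow about twice as bright to the green receptor, pale
# red near equal brightness, black much darker.
patch_shape <- function(patch, wl, p) {
  switch(patch,
    vegetation = p$base + p$peak * exp(-(wl - 550)^2 / (2 * 40^2)),
    yellow_adult = p$base + p$step / (1 + exp(-(wl - p$edge) / 20)) +
      p$uv * exp(-(wl - 360)^2 / (2 * 15^2)),
    red_adult = ,
    red_juvenile = p$base + p$step / (1 + exp(-(wl - 620) / 15)),
    black_adult = ,
    black_juvenile = rep(p$base, length(wl)),
    stop("unknown patch label: ", patch, call. = FALSE))
}

patch_params <- function(patch) {
  switch(patch,
    vegetation = list(base = 0.05, peak = 0.13),
    yellow_adult = list(base = 0.05, step = 0.36, edge = 515, uv = 0.08),
    red_adult = ,
    red_juvenile = list(base = 0.12, step = 0.18),
    black_adult = ,
    black_juvenile = list(base = 0.035),
    stop("unknown patch label: ", patch, call. = FALSE))
}

.patch_tags <- c(vegetation = 11, yellow_adult = 12, red_adult = 13,
                 black_adult = 14, red_juvenile = 15, black_juvenile = 16)

#' Simulate reflectance spectra for a body patch or the vegetation
#'
#' Draws `n` smooth reflectance curves on the working grid for one of the
#' six patch classes. Specimen-to-specimen variation is multiplicative
#' log-normal jitter on the shape parameters (baseline and
#' peak/step/UV-bump amplitudes), which keeps reflectance positive and
#' produces realistic between-specimen spread in both chromatic and
#' achromatic contrast.
#'
#' @param patch One of `"vegetation"`, `"yellow_adult"`, `"red_adult"`,
#'   `"black_adult"`, `"red_juvenile"`, `"black_juvenile"`.
#' @param n Number of specimens.
#' @param seed Integer seed (per-patch substream derived from it).
#' @param jitter_sd SD of the log-normal parameter jitter.
#' @param grid Wavelength grid.
#' @return A [spectrum_set()] labelled by `patch`.
#' @export
sim_reflectance <- function(patch, n = 8, seed = 1, jitter_sd = 0.15,
                            grid = default_grid()) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!patch %in% names(.patch_tags))
    stop("unknown patch label: ", patch, call. = FALSE)
  base_par <- patch_params(patch)
  with_seed(sub_seed(seed, .patch_tags[[patch]]), {
    spectra <- lapply(seq_len(n), function(i) {
      p <- lapply(base_par, function(v)
        if (is.numeric(v) && length(v) == 1 && v < 100)
          v * exp(stats::rnorm(1, 0, jitter_sd)) else v)
      p$edge <- base_par$edge  # step position kept fixed; amplitudes jitter
      spectrum(grid, patch_shape(patch, grid, p), kind = "reflectance")
    })
    names(spectra) <- sprintf("%s_%02d", patch, seq_len(n))
    spectrum_set(spectra, label = patch)
  })
}

#' Simulate a full spectral study
#'
#' All five body-patch classes plus the vegetation background, `n`
#' specimens each.
#'
#' @param n Specimens per patch class.
#' @param seed Integer seed.
#' @param ... Passed to [sim_reflectance()].
#' @return Named list of [spectrum_set()]s.
#' @export
sim_spectra_study <- function(n = 8, seed = 1, ...) {
  patches <- names(.patch_tags)
  stats::setNames(lapply(patches, sim_reflectance, n = n, seed = seed, ...),
                  patches)
}

stage_defaults <- function(stage) {
  switch(stage,
    juvenile = list(wh = c(160, 50), wi = c(15, 12), ca = c(76, 42),
                    bs = c(2.6, 0.7), target_mean = 3.4,
                    beta = c(web_height = 0.007, inclination = 0,
                             capture_area = 0, body_size = 0)),
    adult = list(wh = c(120, 45), wi = c(15, 12), ca = c(166, 78),
                 bs = c(3.3, 1.5), target_mean = 4.9,
                 beta = c(web_height = 0.01, inclination = -0.01,
                          capture_area = 0, body_size = 1.3)),
    stop("stage must be 'juvenile' or 'adult'", call. = FALSE))
}

#' Simulate field web observations for one ontogenetic stage
#'
#' Predictors are drawn from truncated normals matching the study's
#' printed summaries (capture area 76 +/- 42 cm^2 for juveniles, 166 +/-
#' 78 for adults; body sizes 2.6 +/- 0.7 vs 3.3 +/- 1.5 mm), web geometry
#' (`d_v`, `d_h`, `free_zone`) is back-solved to be exactly consistent
#' with the drawn capture area, and damage counts are Poisson with a
#' log-linear mean in the four predictors.
#'
#' @param stage `"juvenile"` or `"adult"`.
#' @param n Number of webs (default 35 juveniles / 28 adults as sampled in
#'   the field study).
#' @param beta Named coefficient vector over `(intercept, web_height,
#'   inclination, capture_area, body_size)` on the log scale. A missing or
#'   `NA` intercept is solved so the expected count at the mean predictor
#'   values matches the stage's observed mean damage count.
#' @param seed Integer seed.
#' @return data.frame of web observations (one row per web) with columns
#'   `stage, web_height, inclination, d_v, d_h, free_zone, body_size,
#'   capture_area, damaged_areas`.
#' @export
sim_field_data <- function(stage = c("juvenile", "adult"),
                           n = NULL, beta = NULL, seed = 1) {
  stage <- match.arg(stage)
  def <- stage_defaults(stage)
  if (is.null(n)) n <- if (stage == "juvenile") 35L else 28L
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  slopes <- def$beta
  intercept <- NA_real_
  if (!is.null(beta)) {
    if ("intercept" %in% names(beta)) intercept <- beta[["intercept"]]
    for (nm in names(slopes)) if (nm %in% names(beta)) slopes[nm] <- beta[[nm]]
  }
  if (is.na(intercept)) {
    mean_x <- c(web_height = def$wh[1], inclination = def$wi[1],
                capture_area = def$ca[1], body_size = def$bs[1])
    intercept <- log(def$target_mean) - sum(slopes * mean_x)
  }
  tag <- if (stage == "juvenile") 21 else 22
  with_seed(sub_seed(seed, tag), {
    wh <- rtnorm(n, def$wh[1], def$wh[2], lo = 30, hi = 350)
    wi <- pmin(abs(stats::rnorm(n, def$wi[1], def$wi[2])), 90)
    ca <- rtnorm(n, def$ca[1], def$ca[2], lo = 10)
    bs <- rtnorm(n, def$bs[1], def$bs[2], lo = 0.8)
    aspect <- stats::runif(n, 0.75, 1)         # d_h / d_v
    h <- stats::runif(n, 1, 4)                 # free-zone height, cm
    d_v <- sqrt((ca + pi * h^2 / 4) * 4 / (pi * aspect))
    d_h <- aspect * d_v
    eta <- intercept + slopes[["web_height"]] * wh +
      slopes[["inclination"]] * wi + slopes[["capture_area"]] * ca +
      slopes[["body_size"]] * bs
    data.frame(stage = stage, web_height = wh, inclination = wi,
               d_v = d_v, d_h = d_h, free_zone = h, body_size = bs,
               capture_area = ca,
               damaged_areas = stats::rpois(n, exp(eta)))
  })
}

#' Simulate the full two-stage field data set
#'
#' @param n_juvenile,n_adult Webs per stage (study design: 35 and 28).
#' @param seed Integer seed.
#' @param beta_juvenile,beta_adult Optional coefficient overrides, passed
#'   to [sim_field_data()].
#' @return Combined data.frame of both stages.
#' @export
sim_field_study <- function(n_juvenile = 35, n_adult = 28, seed = 1,
                            beta_juvenile = NULL, beta_adult = NULL) {
  rbind(sim_field_data("juvenile", n_juvenile, beta_juvenile, seed),
        sim_field_data("adult", n_adult, beta_adult, seed))
}

#' Simulate frame-web-choice trials
#'
#' Each replicate releases `n_released` bees per treatment frame; the
#' number intercepted is binomial with the cell's interception
#' probability. The default design mirrors the tunnel experiment: 12
#' replicates per age, 10 bees each, with two juvenile replicates of 9
#' bees; adults have a spider-web advantage (0.5 vs 0.15) and juveniles
#' none (0.3 vs 0.3).
#'
#' @param n_replicates Replicates per age class.
#' @param p Named interception probabilities
#'   `c(adult_spider, adult_empty, juvenile_spider, juvenile_empty)`.
#' @param n_released Bees released per replicate.
#' @param short_juvenile How many juvenile replicates ran one bee short.
#' @param seed Integer seed.
#' @return data.frame of trials: `replicate, age, treatment, n_released,
#'   n_intercepted`.
#' @export
sim_choice_trials <- function(n_replicates = 12,
                              p = c(adult_spider = 0.5, adult_empty = 0.15,
                                    juvenile_spider = 0.3, juvenile_empty = 0.3),
                              n_released = 10, short_juvenile = 2, seed = 1) {
  if (any(p < 0 | p > 1))
    stop("interception probabilities must lie in [0, 1]", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be at least 1", call. = FALSE)
  with_seed(sub_seed(seed, 31), {
    ages <- rep(c("juvenile", "adult"), each = 2L * n_replicates)
    reps <- rep(rep(seq_len(n_replicates), each = 2L), times = 2L)
    trts <- rep(c("spider_web", "empty_web"), times = 2L * n_replicates)
    rel <- as.integer(ifelse(ages == "juvenile" & reps <= short_juvenile,
                             n_released - 1L, n_released))
    prob <- p[paste0(ages, "_",
                     ifelse(trts == "spider_web", "spider", "empty"))]
    data.frame(replicate = paste0(substr(ages, 1, 1), reps), age = ages,
               treatment = trts, n_released = rel,
               n_intercepted = stats::rbinom(length(rel), rel, prob))
  })
}

#' Write simulated inputs to the CSV formats the readers consume
#'
#' Generates a full synthetic study (spectra for all patches, field
#' observations for both stages, choice trials) and writes it under `dir`
#' in the same formats [read_spectra()], [read_field_csv()] and
#' [read_choice_csv()] parse.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_spectra Specimens per patch class.
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(dir, seed = 1, n_spectra = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra_dir <- file.path(dir, "spectra")
  dir.create(spectra_dir, showWarnings = FALSE)
  sets <- sim_spectra_study(n = n_spectra, seed = seed)
  for (nm in names(sets))
    write_spectra(sets[[nm]], file.path(spectra_dir, paste0(nm, ".csv")))
  fd <- sim_field_study(seed = seed)
  out <- data.frame(stage = fd$stage, web_height_cm = fd$web_height,
                    inclination_deg = fd$inclination, dv_cm = fd$d_v,
                    dh_cm = fd$d_h, free_zone_cm = fd$free_zone,
                    body_size_mm = fd$body_size,
                    damaged_areas = fd$damaged_areas)
  utils::write.csv(out, file.path(dir, "field.csv"), row.names = FALSE)
  utils::write.csv(sim_choice_trials(seed = seed),
                   file.path(dir, "choice.csv"), row.names = FALSE)
  invisible(dir)
}
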