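# Independently coded oracles, kept deliberately separate from the package
# implementation: explicit loops, their own integration rules, and their
# own formula transcriptions. They check the science, not the code path.

# trapezoid integral written as an explicit loop
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# A1 visual-pigment template transcribed independently
oracle_template <- function(lmax, wl) {
  out <- numeric(length(wl))
  for (i in seq_along(wl)) {
    x <- lmax / wl[i]
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    al <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                 exp(-14.9 * (1.104 - x)) + 0.674)
    be <- 0.26 * exp(-((wl[i] - (189 + 0.315 * lmax)) / (-40.5 + 0.195 * lmax))^2)
    out[i] <- al + be
  }
  out / max(out)
}

# standard D65 table (energy units) restated for the oracle
oracle_d65 <- function(wl) {
  tab_wl <- seq(300, 700, 10)
  tab <- c(0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383,
           52.0891, 49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823,
           104.865, 117.008, 117.812, 114.861, 115.923, 108.811, 109.354,
           107.802, 104.79, 107.689, 104.405, 104.046, 100, 96.3342, 95.788,
           88.6856, 90.0062, 89.5991, 87.6987, 83.2886, 83.6992, 80.0268,
           80.1207, 82.2778, 78.2842, 69.7213, 71.6091)
  stats::approx(tab_wl, tab, xout = wl)$y * wl  # quantal
}

# full spectra -> (chromatic, achromatic) pipeline, step by step
oracle_contrasts <- function(sample_values, background_values,
                             wl = seq(300, 700, 1),
                             lmax = c(344, 436, 544)) {
  illum <- oracle_d65(wl)
  catches <- numeric(3)
  for (r in 1:3) {
    sens <- oracle_template(lmax[r], wl)
    num <- oracle_trapz(wl, sample_values * sens * illum)
    den <- oracle_trapz(wl, background_values * sens * illum)
    catches[r] <- num / den
  }
  E <- catches / (catches + 1)
  xx <- sqrt(3) / 2 * (E[3] - E[1])
  yy <- E[2] - (E[1] + E[3]) / 2
  list(chromatic = sqrt(xx^2 + yy^2), achromatic = catches[3])
}

# rectangle-rule quantum catch on a fine grid (independent integration)
oracle_quantum_catch_fine <- function(sample_wl, sample_values,
                                      bg_wl, bg_values,
                                      lmax, step = 0.1) {
  wl <- seq(300, 700, step)
  sv <- stats::approx(sample_wl, sample_values, xout = wl, rule = 2)$y
  bv <- stats::approx(bg_wl, bg_values, xout = wl, rule = 2)$y
  sens <- oracle_template(lmax, wl)
  illum <- oracle_d65(wl)
  sum(sv * sens * illum * step) / sum(bv * sens * illum * step)
}

# Holm step-down by direct enumeration of the definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(running, 1)
  }
  adj
}

# Poisson log-likelihood and AIC written from the density
oracle_poisson_aic <- function(y, mu, n_par) {
  ll <- sum(y * log(mu) - mu - lgamma(y + 1))
  -2 * ll + 2 * n_par
}

# exhaustive all-subsets AIC minimization over candidate predictors
oracle_best_subset <- function(data, predictors, response = "damaged_areas") {
  best <- NULL
  best_aic <- Inf
  for (k in 0:length(predictors)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(predictors, k, simplify = FALSE)
    for (cmb in combos) {
      f <- stats::reformulate(if (length(cmb)) cmb else "1", response)
      a <- stats::AIC(stats::glm(f, stats::poisson(), data))
      if (a < best_aic - 1e-9) {
        best_aic <- a
        best <- cmb
      }
    }
  }
  list(terms = sort(best), aic = best_aic)
}

# beta log-density assembled from gamma functions (no dbeta)
oracle_beta_loglik <- function(y, mu, phi) {
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}
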