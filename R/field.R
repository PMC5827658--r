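# Web geometry and foraging-success modelling: ellipse-hub capture area,
# Poisson GLMs for damage counts, greedy AIC backward selection, and a
# variance-function-based coefficient of determination.

#' Orb-web capture area (ellipse-hub formula)
#'
#' The prey-intercepting area of an orb web: the ellipse spanned by the
#' vertical and horizontal diameters minus the circular free zone around
#' the hub,
#' \deqn{A = \pi (d_v/2)(d_h/2) - \pi (H/2)^2.}
#' A geometrically degenerate web (free zone larger than the ellipse)
#' yields 0 with a warning rather than a negative area.
#'
#' @param d_v,d_h Vertical and horizontal web diameters (cm), > 0.
#' @param free_zone Height of the free zone around the hub (cm), >= 0.
#' @return Capture area in cm^2 (vectorized).
#' @examples
#' capture_area(20, 16, 4)  # 76 * pi
#' @export
capture_area <- function(d_v, d_h, free_zone = 0) {
  if (any(d_v <= 0) || any(d_h <= 0))
    stop("web diameters must be positive", call. = FALSE)
  if (any(free_zone < 0))
    stop("free-zone height must be non-negative", call. = FALSE)
  # algebraically pi*(d_v/2)(d_h/2) - pi*(H/2)^2, arranged so the product
  # d_v*d_h keeps the function exactly symmetric in floating point
  a <- pi * (d_v * d_h - free_zone^2) / 4
  if (any(a < 0)) {
    warning("free zone exceeds the web ellipse: capture area clamped to 0",
            call. = FALSE)
    a[a < 0] <- 0
  }
  a
}

#' Fit a Poisson GLM for foraging success
#'
#' Log-link Poisson regression of damage counts on web and spider
#' predictors, fitted by iteratively reweighted least squares via
#' [stats::glm()]. Predictors enter untransformed and uncentred, so
#' coefficients read directly as log-rate change per unit of the predictor
#' (e.g. per cm of web height).
#'
#' @param data A data.frame holding the response and predictors.
#' @param predictors Character vector of predictor column names; may be
#'   empty for an intercept-only model.
#' @param response Response column name (non-negative integer counts).
#' @return A fitted `glm` object (family poisson).
#' @export
poisson_glm <- function(data,
                        predictors = c("web_height", "inclination",
                                       "capture_area", "body_size"),
                        response = "damaged_areas") {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts", call. = FALSE)
  if (nrow(data) < length(predictors) + 2L)
    stop("insufficient data: need more rows than parameters", call. = FALSE)
  f <- stats::reformulate(if (length(predictors)) predictors else "1", response)
  fit <- stats::glm(f, family = stats::poisson(), data = data,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("singular (rank-deficient) design matrix", call. = FALSE)
  if (!fit$converged)
    stop("IRLS did not converge in ", fit$iter, " iterations", call. = FALSE)
  fit
}

#' Tidy coefficient table for a GLM fit
#'
#' @param fit A fitted `glm`.
#' @return data.frame with term, coefficient, std_error, z, p.
#' @export
coef_table <- function(fit) {
  sm <- stats::summary.glm(fit)$coefficients
  data.frame(term = rownames(sm), coefficient = sm[, 1], std_error = sm[, 2],
             z = sm[, 3], p = sm[, 4], row.names = NULL)
}

glm_response_name <- function(fit) all.vars(stats::formula(fit))[1]

refit_with_terms <- function(fit, terms) {
  mf <- fit$model
  f <- stats::reformulate(if (length(terms)) terms else "1",
                          glm_response_name(fit))
  stats::glm(f, family = stats::poisson(), data = mf,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
}

#' Greedy backward model selection by AIC
#'
#' Starting from a fitted model, repeatedly removes the single term whose
#' removal lowers AIC the most, stopping when no removal lowers AIC. The
#' intercept is never dropped. The returned model's AIC is never higher
#' than the input model's.
#'
#' @param fit A fitted `glm` (Poisson).
#' @return The refitted reduced `glm`.
#' @export
backward_select <- function(fit) {
  repeat {
    terms <- attr(stats::terms(fit), "term.labels")
    if (length(terms) == 0L) return(fit)
    cand <- vapply(terms, function(tm)
      stats::AIC(refit_with_terms(fit, setdiff(terms, tm))), numeric(1))
    if (min(cand) >= stats::AIC(fit)) return(fit)
    fit <- refit_with_terms(fit, setdiff(terms, names(which.min(cand))))
  }
}

#' Coefficient of determination for a GLM
#'
#' The default (`type = "v"`) is the variance-function-based R-squared of
#' Zhang (2017): one minus the ratio of variance-function-standardized
#' residual sums for the fitted model versus the intercept-only model,
#' \deqn{R^2_V = 1 - \frac{\sum_i (y_i-\hat\mu_i)^2/V(\hat\mu_i)}
#'                        {\sum_i (y_i-\hat\mu_{0i})^2/V(\hat\mu_{0i})}.}
#' `type = "deviance"` gives the deviance-based alternative
#' \eqn{1 - D/D_0}.
#'
#' @param fit A fitted `glm` with its data.
#' @param type `"v"` (variance-function-based, default) or `"deviance"`.
#' @return The coefficient of determination.
#' @export
glm_r2 <- function(fit, type = c("v", "deviance")) {
  type <- match.arg(type)
  if (type == "deviance")
    return(1 - fit$deviance / fit$null.deviance)
  y <- fit$y %||% stats::model.response(fit$model)
  mu <- stats::fitted(fit)
  null_fit <- refit_with_terms(fit, character(0))
  mu0 <- stats::fitted(null_fit)
  V <- fit$family$variance
  denom <- sum((y - mu0)^2 / V(mu0))
  if (denom == 0)
    stop("degenerate null model: no variation to explain", call. = FALSE)
  num <- (y - mu)^2 / V(mu)
  num[(y - mu)^2 == 0] <- 0  # saturated fits: 0/0 -> 0
  1 - sum(num) / denom
}

#' Pearson dispersion diagnostic for a Poisson fit
#'
#' Pearson chi-square divided by residual degrees of freedom; values well
#' above 1 flag overdispersion. Reported for diagnosis only -- the foraging
#' models stay plain Poisson.
#'
#' @param fit A fitted `glm`.
#' @return Dispersion estimate.
#' @export
dispersion <- function(fit) {
  sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
}

#' Read field web observations from CSV
#'
#' Expects columns `stage, web_height_cm, inclination_deg, dv_cm, dh_cm,
#' free_zone_cm, body_size_mm, damaged_areas` and maps them onto the
#' internal names used by the models; `capture_area` is computed from the
#' geometry columns.
#'
#' @param path CSV path.
#' @return data.frame of web observations.
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("stage", "web_height_cm", "inclination_deg", "dv_cm", "dh_cm",
            "free_zone_cm", "body_size_mm", "damaged_areas")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("field CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(stage = factor(tab$stage, levels = c("juvenile", "adult")),
                    web_height = tab$web_height_cm,
                    inclination = tab$inclination_deg,
                    d_v = tab$dv_cm, d_h = tab$dh_cm,
                    free_zone = tab$free_zone_cm,
                    body_size = tab$body_size_mm,
                    damaged_areas = tab$damaged_areas)
  if (anyNA(out$stage)) stop("stage must be 'juvenile' or 'adult'", call. = FALSE)
  if (any(out$inclination < 0 | out$inclination > 90))
    stop("inclination must lie in [0, 90] degrees", call. = FALSE)
  out$capture_area <- capture_area(out$d_v, out$d_h, out$free_zone)
  out
}

#' Full field foraging-success analysis
#'
#' Per ontogenetic stage: the full Poisson GLM of damage counts on web
#' height, inclination, capture area and body size; the AIC
#' backward-selected reduced model with its R-squared; then across stages:
#' a pooled GLM with stage as the only predictor, a Wilcoxon rank-sum
#' comparison of body sizes, a Pearson collinearity check between web
#' height and body size within adults, and the overall body-size vs
#' web-height correlation.
#'
#' @param obs data.frame of web observations (see [read_field_csv()];
#'   `capture_area` is computed from the geometry columns if absent).
#' @param min_per_stage Minimum observations required per stage.
#' @return An object of class `"field_report"`.
#' @export
run_field_analysis <- function(obs, min_per_stage = 10) {
  stopifnot(is.data.frame(obs))
  if (!"capture_area" %in% names(obs))
    obs$capture_area <- capture_area(obs$d_v, obs$d_h, obs$free_zone)
  obs$stage <- factor(obs$stage, levels = c("juvenile", "adult"))
  counts <- table(obs$stage)
  if (any(counts < min_per_stage))
    stop("insufficient data: need at least ", min_per_stage,
         " observations per stage", call. = FALSE)
  preds <- c("web_height", "inclination", "capture_area", "body_size")
  stages <- list()
  for (st in levels(obs$stage)) {
    d <- obs[obs$stage == st, , drop = FALSE]
    if (all(d$damaged_areas == 0)) {
      warning("all damage counts are zero for stage '", st,
              "': no model selection performed", call. = FALSE)
      full <- poisson_glm(d, predictors = preds)
      stages[[st]] <- list(full = full, reduced = full,
                           r2 = NA_real_, r2_deviance = NA_real_,
                           dispersion = dispersion(full), degenerate = TRUE)
      next
    }
    full <- poisson_glm(d, predictors = preds)
    red <- backward_select(full)
    stages[[st]] <- list(full = full, reduced = red,
                         r2 = glm_r2(red), r2_deviance = glm_r2(red, "deviance"),
                         dispersion = dispersion(full), degenerate = FALSE)
  }
  pooled <- poisson_glm(obs, predictors = "stage")
  wil <- wilcoxon_two_group(obs$body_size[obs$stage == "juvenile"],
                            obs$body_size[obs$stage == "adult"])
  ad <- obs[obs$stage == "adult", ]
  collin <- pearson_cor_test(ad$web_height, ad$body_size)
  overall <- pearson_cor_test(obs$body_size, obs$web_height)
  structure(list(stages = stages, pooled = pooled,
                 body_size_wilcoxon = wil,
                 adult_wh_bs_collinearity = collin,
                 overall_bs_wh_correlation = overall,
                 n = counts),
            class = "field_report")
}

#' @export
print.field_report <- function(x, digits = 3, ...) {
  cat("Foraging-success analysis (Poisson GLMs)\n")
  cat(sprintf("  n = %d juveniles, %d adults\n\n",
              x$n[["juvenile"]], x$n[["adult"]]))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat(sprintf("-- Full model (%s), AIC = %.1f\n", st, stats::AIC(s$full)))
    print(format(coef_table(s$full), digits = digits), row.names = FALSE)
    cat(sprintf("-- Reduced model (%s), AIC = %.1f, R2 = %.2f\n",
                st, stats::AIC(s$reduced), s$r2))
    print(format(coef_table(s$reduced), digits = digits), row.names = FALSE)
    cat("\n")
  }
  ct <- coef_table(x$pooled)
  cat(sprintf("Pooled stage effect: Z = %.2f, P = %.3g\n",
              ct$z[2], ct$p[2]))
  cat(sprintf("Body size juvenile vs adult: Wilcoxon W = %g, P = %.3g\n",
              x$body_size_wilcoxon$statistic, x$body_size_wilcoxon$p))
  cat(sprintf("Adult WH-BS collinearity: r = %.2f, t = %.2f, df = %d, P = %.2g\n",
              x$adult_wh_bs_collinearity$estimate,
              x$adult_wh_bs_collinearity$statistic,
              x$adult_wh_bs_collinearity$df, x$adult_wh_bs_collinearity$p))
  cat(sprintf("Overall BS-WH correlation: r = %.2f, t = %.2f, df = %d, P = %.2g\n",
              x$overall_bs_wh_correlation$estimate,
              x$overall_bs_wh_correlation$statistic,
              x$overall_bs_wh_correlation$df, x$overall_bs_wh_correlation$p))
  invisible(x)
}

#' Write a field report as CSV tables
#'
#' Writes one coefficient table per model (full/reduced per stage plus the
#' pooled model) and a summary of the accompanying tests.
#'
#' @param report A `field_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_field_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (st in names(report$stages)) {
    for (which in c("full", "reduced")) {
      fit <- report$stages[[st]][[which]]
      tab <- coef_table(fit)
      tab <- cbind(stage = st, model = which, tab,
                   aic = stats::AIC(fit),
                   r2 = if (which == "reduced") report$stages[[st]]$r2 else NA)
      rows[[paste(st, which)]] <- tab
    }
  }
  pooled <- cbind(stage = "pooled", model = "stage-only", coef_table(report$pooled),
                  aic = stats::AIC(report$pooled), r2 = NA)
  out <- do.call(rbind, c(rows, list(pooled)))
  utils::write.csv(out, file.path(dir, "field_models.csv"), row.names = FALSE)
  tests <- data.frame(
    test = c("body_size_wilcoxon", "adult_wh_bs_collinearity",
             "overall_bs_wh_correlation"),
    statistic = c(report$body_size_wilcoxon$statistic,
                  report$adult_wh_bs_collinearity$statistic,
                  report$overall_bs_wh_correlation$statistic),
    estimate = c(NA, report$adult_wh_bs_collinearity$estimate,
                 report$overall_bs_wh_correlation$estimate),
    df = c(NA, report$adult_wh_bs_collinearity$df,
           report$overall_bs_wh_correlation$df),
    p = c(report$body_size_wilcoxon$p, report$adult_wh_bs_collinearity$p,
          report$overall_bs_wh_correlation$p))
  utils::write.csv(tests, file.path(dir, "field_tests.csv"), row.names = FALSE)
  invisible(dir)
}
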