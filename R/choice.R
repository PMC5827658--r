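# Beta regression for the frame-web-choice experiment: per-replicate
# interception proportions modelled with a logit-linked mean and a
# constant precision phi (log-parameterized internally), fitted by
# maximum likelihood.

#' Squeeze proportions off the boundary of \[0, 1\]
#'
#' The beta likelihood is undefined at 0 and 1, but observed interception
#' proportions can hit both. The standard boundary transformation
#' `y' = (y (n - 1) + 0.5) / n` is applied to all values, where `n` is the
#' total number of observations; it is order-preserving, maps \[0, 1\] into
#' (0, 1), and leaves 0.5 fixed.
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample size used in the transformation; defaults to `length(y)`.
#' @return Proportions strictly inside (0, 1).
#' @export
squeeze_proportions <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1) || anyNA(y))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  (y * (n - 1) + 0.5) / n
}

beta_negloglik <- function(par, X, y) {
  k <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(k)]))
  phi <- exp(par[k + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_negloglik_grad <- function(par, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(par[k + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  # d(loglik)/d(beta) with logit link: phi * (ystar - mustar) * mu(1-mu)
  gbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi_unit <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) + mu * log(y) + (1 - mu) * log1p(-y)
  c(-gbeta, -phi * sum(gphi_unit))
}

#' Maximum-likelihood beta regression
#'
#' Fits a beta regression with a logit link for the mean and a single
#' (log-parameterized) precision parameter phi, by quasi-Newton (BFGS)
#' maximization of the beta log-likelihood with an analytic gradient.
#' Starting values come from a least-squares fit on the logit scale and a
#' method-of-moments precision. Wald z and two-sided p-values are reported
#' for the mean-model coefficients.
#'
#' A response with (numerically) zero variance is degenerate: the fit is
#' returned with the intercept at the logit of the mean, all other
#' coefficients and z-values 0, and a warning.
#'
#' @param formula Model formula for the mean (response in (0, 1)).
#' @param data data.frame holding the variables.
#' @return An object of class `"beta_reg"` with elements `coefficients`
#'   (mean model), `phi`, `se`, `z`, `p`, `loglik`, `start_loglik`, `vcov`
#'   (mean model + log-phi), `fitted`, `converged`.
#' @export
beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y <= 0 | y >= 1))
    stop("response must lie strictly inside (0, 1); squeeze_proportions() first",
         call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("singular (rank-deficient) design matrix", call. = FALSE)
  if (nrow(X) < ncol(X) + 2L)
    stop("insufficient data: need more observations than parameters", call. = FALSE)
  k <- ncol(X)
  if (stats::var(y) < 1e-12) {
    warning("response has zero variance: degenerate beta-regression fit",
            call. = FALSE)
    cf <- c(stats::qlogis(mean(y)), rep(0, k - 1L))
    names(cf) <- colnames(X)
    return(structure(list(coefficients = cf, phi = NA_real_,
                          se = rep(NA_real_, k), z = rep(0, k),
                          p = rep(1, k), loglik = NA_real_,
                          start_loglik = NA_real_, vcov = NULL,
                          fitted = rep(mean(y), nrow(X)),
                          y = y, terms = stats::terms(mf),
                          converged = FALSE, degenerate = TRUE,
                          call = match.call()),
                     class = "beta_reg"))
  }
  # start: least squares on logits; moment estimate of phi
  z <- stats::qlogis(y)
  b0 <- stats::lm.fit(X, z)$coefficients
  mu0 <- stats::plogis(drop(X %*% b0))
  s2 <- max(stats::var(y - mu0), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 1.1)
  par0 <- c(b0, log(phi0))
  start_ll <- -beta_negloglik(par0, X, y)
  opt <- stats::optim(par0, beta_negloglik, gr = beta_negloglik_grad,
                      X = X, y = y, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("beta-regression optimizer failed to converge (code ",
         opt$convergence, ")", call. = FALSE)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc))
    stop("singular Hessian at the beta-regression optimum", call. = FALSE)
  cf <- opt$par[seq_len(k)]
  names(cf) <- colnames(X)
  se <- sqrt(diag(vc))[seq_len(k)]
  zval <- cf / se
  structure(list(coefficients = cf, phi = exp(opt$par[k + 1L]),
                 log_phi_se = sqrt(diag(vc))[k + 1L],
                 se = se, z = zval, p = 2 * stats::pnorm(-abs(zval)),
                 loglik = -opt$value, start_loglik = start_ll,
                 vcov = vc, fitted = stats::plogis(drop(X %*% cf)),
                 y = y, terms = stats::terms(mf),
                 converged = TRUE, degenerate = FALSE,
                 call = match.call()),
            class = "beta_reg")
}

#' @export
print.beta_reg <- function(x, digits = 4, ...) {
  cat("Beta regression (logit mean, constant precision)\n")
  tab <- data.frame(coefficient = x$coefficients, std_error = x$se,
                    z = x$z, p = x$p)
  print(format(tab, digits = digits))
  cat(sprintf("phi = %.3f, logLik = %.3f, converged = %s\n",
              x$phi, x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.beta_reg <- function(object, ...) object$coefficients

#' @export
vcov.beta_reg <- function(object, ...) object$vcov

#' @export
logLik.beta_reg <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' Wald test of a linear contrast of beta-regression coefficients
#'
#' @param fit A `beta_reg` fit.
#' @param weights Numeric contrast vector over the mean-model coefficients.
#' @return List with `estimate`, `se`, `z`, `p`.
#' @export
beta_contrast <- function(fit, weights) {
  k <- length(fit$coefficients)
  stopifnot(length(weights) == k)
  est <- sum(weights * fit$coefficients)
  v <- drop(t(weights) %*% fit$vcov[seq_len(k), seq_len(k)] %*% weights)
  se <- sqrt(v)
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Read choice-experiment trials from CSV
#'
#' Expects columns `replicate, age, treatment, n_released, n_intercepted`
#' with `age` in {juvenile, adult} and `treatment` in
#' {empty_web, spider_web}.
#'
#' @param path CSV path.
#' @return data.frame of trials with validated counts and factor columns.
#' @export
read_choice_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("replicate", "age", "treatment", "n_released", "n_intercepted")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("choice CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$age <- factor(tab$age, levels = c("juvenile", "adult"))
  tab$treatment <- factor(tab$treatment, levels = c("empty_web", "spider_web"))
  if (anyNA(tab$age) || anyNA(tab$treatment))
    stop("age must be juvenile/adult and treatment empty_web/spider_web",
         call. = FALSE)
  if (any(tab$n_released < 1) ||
      any(tab$n_intercepted < 0 | tab$n_intercepted > tab$n_released))
    stop("counts must satisfy 0 <= n_intercepted <= n_released, n_released >= 1",
         call. = FALSE)
  tab
}

#' Analyse the frame-web-choice experiment
#'
#' Per-replicate interception proportions (intercepted / released in that
#' replicate) are squeezed off the boundary and modelled by beta regression
#' with `treatment * age`. The report contains the interaction Wald test
#' and, per age, the treatment contrast (spider-bearing vs empty web)
#' obtained both by releveled refitting and as a linear contrast of the
#' interaction model; the two routes are checked to agree.
#'
#' @param trials data.frame as returned by [read_choice_csv()] or
#'   [sim_choice_trials()].
#' @param min_per_cell Minimum replicates required in each age x treatment
#'   cell (at least 2 for identifiability).
#' @return An object of class `"choice_report"`.
#' @export
run_choice_analysis <- function(trials, min_per_cell = 2) {
  stopifnot(is.data.frame(trials))
  trials$age <- factor(trials$age, levels = c("juvenile", "adult"))
  trials$treatment <- factor(trials$treatment,
                             levels = c("empty_web", "spider_web"))
  cells <- table(trials$age, trials$treatment)
  if (any(dim(cells) != c(2, 2)) || any(cells < max(2, min_per_cell)))
    stop("insufficient data: need at least ", max(2, min_per_cell),
         " replicates in every age x treatment cell", call. = FALSE)
  trials$proportion <- trials$n_intercepted / trials$n_released
  trials$y <- squeeze_proportions(trials$proportion, n = nrow(trials))
  full <- withCallingHandlers(
    beta_regression(y ~ treatment * age, trials),
    warning = function(w) {
      if (grepl("zero variance", conditionMessage(w))) {
        warning("all interception proportions identical: degenerate analysis, effects set to 0",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  inter_idx <- grep(":", names(full$coefficients))
  interaction <- list(estimate = full$coefficients[[inter_idx]],
                      se = full$se[[inter_idx]], z = full$z[[inter_idx]],
                      p = full$p[[inter_idx]])
  if (full$degenerate) {
    zero <- list(estimate = 0, se = NA_real_, z = 0, p = 1)
    contrasts <- relevel_fits <- list(juvenile = zero, adult = zero)
  } else {
    # treatment effect within each age, via linear contrasts of the full fit
    w_trt <- as.numeric(names(full$coefficients) == "treatmentspider_web")
    w_int <- as.numeric(seq_along(full$coefficients) == inter_idx)
    contrasts <- list(
      juvenile = beta_contrast(full, w_trt),
      adult = beta_contrast(full, w_trt + w_int))
    # same effects by releveled refits (reference age carries the main effect)
    relevel_fits <- lapply(c(juvenile = "juvenile", adult = "adult"), function(a) {
      d <- trials
      d$age <- stats::relevel(d$age, ref = a)
      fit <- beta_regression(y ~ treatment * age, d)
      i <- match("treatmentspider_web", names(fit$coefficients))
      list(estimate = fit$coefficients[[i]], se = fit$se[[i]],
           z = fit$z[[i]], p = fit$p[[i]])
    })
  }
  for (a in names(contrasts)) {
    if (abs(contrasts[[a]]$estimate - relevel_fits[[a]]$estimate) > 1e-6)
      warning("contrast and releveled-refit routes disagree for age '", a, "'",
              call. = FALSE)
  }
  summaries <- stats::aggregate(proportion ~ age + treatment, trials,
                                function(v) c(mean = mean(v), sd = stats::sd(v),
                                              median = stats::median(v),
                                              n = length(v)))
  structure(list(fit = full, interaction = interaction,
                 contrasts = contrasts, relevel_fits = relevel_fits,
                 cell_summaries = summaries, trials = trials),
            class = "choice_report")
}

#' @export
print.choice_report <- function(x, ...) {
  cat("Frame-web-choice experiment (beta regression)\n")
  cat(sprintf("  treatment x age interaction: z = %.2f, p = %.3g\n",
              x$interaction$z, x$interaction$p))
  for (a in names(x$contrasts)) {
    ct <- x$contrasts[[a]]
    cat(sprintf("  %s: spider_web vs empty_web z = %.2f, p = %.3g\n",
                a, ct$z, ct$p))
  }
  cat(sprintf("  phi = %.2f, logLik = %.2f\n", x$fit$phi, x$fit$loglik))
  invisible(x)
}

#' Write a choice report as CSV tables
#'
#' @param report A `choice_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_choice_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cf <- data.frame(term = names(report$fit$coefficients),
                   coefficient = report$fit$coefficients,
                   std_error = report$fit$se, z = report$fit$z,
                   p = report$fit$p, row.names = NULL)
  utils::write.csv(cf, file.path(dir, "choice_model.csv"), row.names = FALSE)
  ct <- do.call(rbind, lapply(names(report$contrasts), function(a) {
    c0 <- report$contrasts[[a]]
    data.frame(age = a, estimate = c0$estimate, se = c0$se, z = c0$z, p = c0$p)
  }))
  utils::write.csv(ct, file.path(dir, "choice_contrasts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Boxplot of interception proportions (choice experiment)
#'
#' Base-graphics boxplot of per-replicate interception proportions by
#' treatment, one panel pair per age class.
#'
#' @param report A `choice_report`.
#' @param ... Passed to [graphics::boxplot()].
#' @return The report, invisibly.
#' @export
plot_choice <- function(report, ...) {
  tr <- report$trials
  graphics::boxplot(proportion ~ treatment + age, data = tr,
                    ylab = "Proportion of bees intercepted",
                    xlab = "", las = 2, ...)
  invisible(report)
}
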