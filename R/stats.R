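# Elementary tests used throughout the analyses, wrapped to return a
# uniform result container and to handle the degenerate inputs that the
# base functions reject.

test_result <- function(method, statistic, df = NA_real_, p, estimate = NA_real_,
                        note = NULL) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p), estimate = unname(estimate),
                 note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              ifelse(is.na(x$df), "-", format(x$df)), x$p))
  if (!is.na(x$estimate))
    cat(sprintf("  estimate = %.4g\n", x$estimate))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' One-sample t-test
#'
#' Two-sided t-test of the sample mean against `mu0`, as used to compare
#' chromatic contrasts with the *Apis mellifera* detection threshold and
#' achromatic contrasts with equal brightness (1.0). A zero-variance sample
#' is handled as a degenerate case: p = 1 when the mean equals `mu0` and
#' p = 0 otherwise, with a warning.
#'
#' @param values Numeric sample, length >= 2.
#' @param mu0 Null mean.
#' @return A `test_result` with `statistic` (t), `df`, `p` and `estimate`
#'   (the sample mean).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("one_sample_t needs at least 2 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("zero-variance sample in one_sample_t: degenerate p-value", call. = FALSE)
    hit <- isTRUE(all.equal(mean(values), mu0))
    return(test_result("One-sample t-test (degenerate: zero variance)",
                       statistic = if (hit) 0 else Inf * sign(mean(values) - mu0),
                       df = length(values) - 1, p = if (hit) 1 else 0,
                       estimate = mean(values)))
  }
  tt <- stats::t.test(values, mu = mu0)
  test_result("One-sample t-test", tt$statistic, tt$parameter, tt$p.value,
              estimate = unname(tt$estimate))
}

#' Holm step-down adjustment of p-values
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order (monotone, capped at 1).
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1) || anyNA(p))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Wilcoxon two-group comparison
#'
#' Unpaired mode computes the rank-sum (Mann--Whitney) statistic, exactly
#' when the group-size product is at most 400 and there are no ties, and by
#' normal approximation with midranks otherwise. Paired mode computes the
#' signed-rank statistic; all-zero differences are degenerate (p = 1 with a
#' warning).
#'
#' @param a,b Numeric samples.
#' @param paired Use the signed-rank test on paired differences?
#' @param exact Force exact/approximate p; default chooses as above.
#' @return A `test_result` with the rank statistic as `statistic`.
#' @export
wilcoxon_two_group <- function(a, b, paired = FALSE, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (paired) {
    if (length(a) != length(b))
      stop("paired mode requires equal lengths", call. = FALSE)
    if (all(a - b == 0)) {
      warning("all paired differences are zero: degenerate signed-rank test",
              call. = FALSE)
      return(test_result("Wilcoxon signed-rank test (degenerate)", 0, NA, 1, 0))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = exact))
    return(test_result("Wilcoxon signed-rank test", wt$statistic, NA, wt$p.value))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result("Wilcoxon rank-sum test", wt$statistic, NA, wt$p.value)
}

#' Pearson correlation with t-test
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @return A `test_result` with `estimate` = r, `statistic` = t, `df` = n-2.
#' @export
pearson_cor_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("Pearson correlation t-test", ct$statistic, ct$parameter,
              ct$p.value, estimate = unname(ct$estimate))
}
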