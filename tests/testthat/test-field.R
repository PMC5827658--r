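test_that("ellipse-hub capture area matches direct arithmetic", {
  expect_equal(capture_area(10, 10, 0), 25 * pi)
  expect_equal(capture_area(20, 16, 4), 76 * pi)
  expect_warning(a <- capture_area(2, 2, 10), "clamped")
  expect_equal(a, 0)
  expect_error(capture_area(0, 10, 1), "positive")
  expect_error(capture_area(10, 10, -1), "non-negative")
})

test_that("capture area is symmetric in the diameters and decreasing in the free zone", {
  set.seed(14)
  for (i in 1:25) {
    dv <- stats::runif(1, 5, 40); dh <- stats::runif(1, 5, 40)
    h <- sort(stats::runif(2, 0, 4))
    expect_equal(capture_area(dv, dh, h[1]), capture_area(dh, dv, h[1]))
    expect_gte(capture_area(dv, dh, h[1]), capture_area(dv, dh, h[2]))
  }
})

test_that("Poisson fits reproduce closed-form group means", {
  d <- data.frame(damaged_areas = c(1, 2, 3))
  fit <- poisson_glm(d, predictors = character(0))
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-10)
  d2 <- data.frame(damaged_areas = c(1, 2, 3, 5, 6, 7),
                   grp = rep(c(0, 1), each = 3))
  fit2 <- poisson_glm(d2, predictors = "grp")
  expect_equal(unname(coef(fit2)), c(log(2), log(3)), tolerance = 1e-10)
})

test_that("the IRLS solution satisfies the Poisson score equations", {
  fd <- sim_field_data("adult", seed = 5)
  fit <- poisson_glm(fd)
  X <- stats::model.matrix(fit)
  score <- drop(crossprod(X, fd$damaged_areas - stats::fitted(fit)))
  expect_lt(max(abs(score)) / max(abs(crossprod(X, fd$damaged_areas))), 1e-8)
})

test_that("reported AIC equals the Poisson log-likelihood oracle", {
  fd <- sim_field_data("juvenile", seed = 6)
  fit <- poisson_glm(fd)
  expect_equal(stats::AIC(fit),
               oracle_poisson_aic(fd$damaged_areas, stats::fitted(fit),
                                  length(coef(fit))),
               tolerance = 1e-6)
})

test_that("rank-deficient designs and bad responses are rejected", {
  fd <- sim_field_data("juvenile", seed = 7)
  fd$dup <- fd$web_height
  expect_error(poisson_glm(fd, predictors = c("web_height", "dup")), "singular")
  fd$damaged_areas[1] <- 2.5
  expect_error(poisson_glm(fd), "integer counts")
  tiny <- sim_field_data("juvenile", seed = 7)[1:3, ]
  expect_error(poisson_glm(tiny), "insufficient")
})

test_that("backward selection removes noise terms and never raises AIC", {
  # strong web-height effect, pure-noise extra predictor; a noise term can
  # survive AIC by chance (|z| ~> 1.4), so the drop is asserted as a rate
  dropped <- 0L
  for (s in 1:10) {
    fd <- sim_field_data("juvenile", n = 60,
                         beta = c(web_height = 0.008, inclination = 0,
                                  capture_area = 0, body_size = 0), seed = s)
    set.seed(s)
    fd$noise <- stats::rnorm(nrow(fd))
    full <- poisson_glm(fd, predictors = c("web_height", "noise"))
    red <- backward_select(full)
    expect_lte(stats::AIC(red), stats::AIC(full))
    kept <- attr(stats::terms(red), "term.labels")
    expect_true("web_height" %in% kept)
    dropped <- dropped + !("noise" %in% kept)
    best <- oracle_best_subset(fd, c("web_height", "noise"))
    expect_equal(sort(kept), best$terms)
    expect_equal(stats::AIC(red), best$aic, tolerance = 1e-9)
  }
  expect_gte(dropped, 7L)
  # intercept-only input is returned unchanged
  fd <- sim_field_data("juvenile", seed = 1)
  i0 <- poisson_glm(fd, predictors = character(0))
  expect_identical(stats::AIC(backward_select(i0)), stats::AIC(i0))
})

test_that("GLM R-squared has its boundary values and matches the formula oracle", {
  fd <- sim_field_data("adult", seed = 8)
  null_fit <- poisson_glm(fd, predictors = character(0))
  expect_equal(glm_r2(null_fit), 0)
  expect_equal(glm_r2(null_fit, type = "deviance"), 0)
  # saturated fit on positive counts reproduces y exactly
  ds <- data.frame(damaged_areas = c(2, 5, 9), f = factor(1:3))
  sat <- stats::glm(damaged_areas ~ f, stats::poisson(), ds)
  expect_equal(glm_r2(sat), 1, tolerance = 1e-9)
  fit <- poisson_glm(fd)
  y <- fd$damaged_areas
  mu <- stats::fitted(fit)
  mu0 <- rep(mean(y), length(y))
  oracle <- 1 - sum((y - mu)^2 / mu) / sum((y - mu0)^2 / mu0)
  expect_equal(glm_r2(fit), oracle, tolerance = 1e-10)
  expect_equal(glm_r2(fit, type = "deviance"),
               1 - fit$deviance / fit$null.deviance, tolerance = 1e-12)
})

test_that("the field analysis assembles per-stage and pooled results", {
  fd <- sim_field_study(seed = 2)
  rep <- run_field_analysis(fd)
  expect_s3_class(rep, "field_report")
  expect_named(rep$stages, c("juvenile", "adult"))
  for (st in rep$stages) {
    expect_lte(stats::AIC(st$reduced), stats::AIC(st$full))
    expect_true(st$r2 >= 0 && st$r2 <= 1)
  }
  ct <- coef_table(rep$pooled)
  expect_equal(ct$term[2], "stageadult")
  expect_equal(rep$adult_wh_bs_collinearity$df, 26)
  expect_output(print(rep), "Reduced model")
})

test_that("degenerate and undersized field data are handled", {
  fd <- sim_field_study(seed = 3)
  expect_error(run_field_analysis(fd[fd$stage == "juvenile" | seq_len(nrow(fd)) > 60, ]),
               "insufficient")
  fd$damaged_areas <- 0L
  w <- capture_warnings(rep0 <- run_field_analysis(fd))
  expect_true(any(grepl("all damage counts are zero", w)))
  expect_true(rep0$stages$juvenile$degenerate)
})

test_that("field CSV round-trips through the writer and reader", {
  dir <- withr::local_tempdir()
  write_sim_study(dir, seed = 4, n_spectra = 2)
  fd <- read_field_csv(file.path(dir, "field.csv"))
  expect_equal(nrow(fd), 63)
  expect_equal(fd$capture_area,
               capture_area(fd$d_v, fd$d_h, fd$free_zone), tolerance = 1e-12)
  rep <- run_field_analysis(fd)
  out <- withr::local_tempdir()
  write_field_report(rep, out)
  expect_true(file.exists(file.path(out, "field_models.csv")))
  expect_true(file.exists(file.path(out, "field_tests.csv")))
})
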