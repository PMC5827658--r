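vs_default <- local({
  bg <- default_background()
  visual_system(bg)
})

test_that("quantum catch is von Kries normalized and linear", {
  bg <- vs_default$background
  expect_equal(unname(quantum_catch(bg, vs_default)), c(1, 1, 1))
  doubled <- spectrum(bg$wl, 2 * bg$value)
  expect_equal(unname(quantum_catch(doubled, vs_default)), c(2, 2, 2),
               tolerance = 1e-12)
  zero <- spectrum(bg$wl, rep(0, length(bg$wl)))
  expect_equal(unname(quantum_catch(zero, vs_default)), c(0, 0, 0))
})

test_that("trapezoid catches agree with a fine-grid rectangle oracle", {
  set.seed(21)
  bg <- vs_default$background
  for (i in 1:5) {
    s <- random_smooth_spectrum()
    for (r in c(uv = 344, blue = 436, green = 544)) {
      p <- quantum_catch(s, vs_default,
                         receptor = names(which(c(uv = 344, blue = 436, green = 544) == r)))
      p_oracle <- oracle_quantum_catch_fine(s$wl, s$value, bg$wl, bg$value, r)
      expect_equal(p, p_oracle, tolerance = 1e-4)
    }
  }
})

test_that("scaling the illuminant cancels in the von Kries normalization", {
  bg <- default_background()
  illum <- cie_d65()
  bright <- spectrum(illum$wl, pmin(illum$value * 7, 1000), kind = "irradiance")
  vs2 <- visual_system(bg, illuminant = bright)
  s <- sim_reflectance("yellow_adult", n = 1, seed = 3)$spectra[[1]]
  expect_equal(quantum_catch(s, vs_default), quantum_catch(s, vs2),
               tolerance = 1e-12)
  expect_equal(chromatic_contrast(s, vs_default), chromatic_contrast(s, vs2),
               tolerance = 1e-12)
})

test_that("excitation is the hyperbolic transform of the catch", {
  expect_equal(excitation(0), 0)
  expect_equal(excitation(1), 0.5)
  expect_equal(excitation(3), 0.75)
  expect_error(excitation(-0.1), "non-negative")
})

test_that("hexagon coordinates place background at origin and vertices at unit distance", {
  expect_equal(unname(hexagon_coords(c(0.5, 0.5, 0.5))), c(0, 0))
  expect_equal(unname(hexagon_coords(c(0, 1, 0))), c(0, 1))
  v <- hexagon_coords(c(0, 0, 1))
  expect_equal(unname(v), c(sqrt(3) / 2, -0.5))
  expect_equal(sqrt(sum(v^2)), 1)
})

test_that("chromatic contrast vanishes for the background and its flat scalings", {
  bg <- vs_default$background
  expect_equal(chromatic_contrast(bg, vs_default), 0)
  for (c0 in c(0.3, 2, 5)) {
    scaled <- suppressWarnings(spectrum(bg$wl, c0 * bg$value))
    expect_equal(chromatic_contrast(scaled, vs_default), 0, tolerance = 1e-12)
  }
})

test_that("hexagon distance from the origin never exceeds 1", {
  set.seed(17)
  E <- matrix(stats::runif(3 * 1000), ncol = 3)
  d <- sqrt(rowSums(hexagon_coords(E)^2))
  expect_true(all(d <= 1 + 1e-12))
})

test_that("achromatic contrast is the linear green-catch ratio", {
  bg <- vs_default$background
  expect_equal(achromatic_contrast(bg, vs_default), 1.0)
  doubled <- spectrum(bg$wl, 2 * bg$value)
  expect_equal(achromatic_contrast(doubled, vs_default), 2.0, tolerance = 1e-12)
  zero <- spectrum(bg$wl, rep(0, length(bg$wl)))
  expect_equal(achromatic_contrast(zero, vs_default), 0)
  # unbounded above, unlike an excitation ratio
  bright <- spectrum(bg$wl, pmin(5 * bg$value, 1))
  expect_gt(achromatic_contrast(bright, vs_default), 2)
})

test_that("full contrast pipeline matches the independent oracle", {
  set.seed(33)
  bg <- vs_default$background
  for (i in 1:10) {
    s <- random_smooth_spectrum()
    o <- oracle_contrasts(s$value, bg$value)
    expect_equal(chromatic_contrast(s, vs_default), o$chromatic, tolerance = 1e-6)
    expect_equal(achromatic_contrast(s, vs_default), o$achromatic, tolerance = 1e-6)
  }
})

test_that("receptor templates are max-normalized, unimodal around lambda_max", {
  for (lmax in c(344, 436, 544)) {
    tpl <- receptor_template(lmax)
    expect_equal(max(tpl$value), 1)
    expect_true(all(tpl$value >= 0 & tpl$value <= 1))
    # the beta band drags the short-wave peak a couple of nm below lambda_max
    expect_lte(abs(tpl$wl[which.max(tpl$value)] - lmax), 3)
  }
  expect_lte(abs(receptor_template(544)$wl[which.max(receptor_template(544)$value)] - 544), 1)
  expect_error(receptor_template(250), "within the wavelength grid")
})

test_that("UV and green templates cross where a dense-grid oracle says they do", {
  t_uv <- receptor_template(344)
  t_g <- receptor_template(544)
  diff_pkg <- t_uv$value - t_g$value
  between <- t_uv$wl >= 344 & t_uv$wl <= 544
  idx <- which(between)[which(diff(sign(diff_pkg[between])) != 0)][1]
  lo <- t_uv$wl[idx]; hi <- t_uv$wl[idx + 1L]
  wl_fine <- seq(344, 544, 0.01)
  diff_fine <- oracle_template(344, wl_fine) - oracle_template(544, wl_fine)
  cross_fine <- wl_fine[which(diff(sign(diff_fine)) != 0)[1]]
  expect_gte(cross_fine, lo - 0.01)
  expect_lte(cross_fine, hi + 0.01)
})

test_that("degenerate backgrounds are rejected", {
  dark <- spectrum(default_grid(), rep(0, length(default_grid())))
  expect_error(visual_system(dark), "degenerate background")
})

test_that("contrast records cover every specimen of every patch", {
  sets <- sim_spectra_study(n = 4, seed = 9)
  vs <- visual_system(sets$vegetation)
  rec <- contrast_records(sets[names(sets) != "vegetation"], vs)
  expect_equal(nrow(rec), 5 * 4)
  expect_true(all(rec$chromatic >= 0 & rec$chromatic <= 1))
  expect_true(all(rec$achromatic >= 0))
})
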