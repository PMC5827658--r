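test_that("CSV parsing yields one spectrum per measurement column", {
  p <- write_spectra_csv("wl,r\n300,0.1\n400,0.2\n500,0.3")
  set <- read_spectra(p)
  expect_s3_class(set, "spectrum_set")
  expect_length(set, 1L)
  expect_equal(set$spectra[[1]]$wl, c(300, 400, 500))
  expect_equal(set$spectra[[1]]$value, c(0.1, 0.2, 0.3))

  p5 <- write_spectra_csv(paste(
    "wl,a,b,c,d,e",
    "300,0.1,0.2,0.3,0.4,0.5",
    "400,0.1,0.2,0.3,0.4,0.5",
    "500,0.1,0.2,0.3,0.4,0.5", sep = "\n"))
  set5 <- read_spectra(p5)
  expect_length(set5, 5L)
  expect_true(all(vapply(set5$spectra, function(s)
    identical(s$wl, c(300, 400, 500)), logical(1))))
})

test_that("malformed spectra files are rejected", {
  expect_error(read_spectra(write_spectra_csv("wl,r\n500,0.1\n400,0.2\n300,0.3")),
               "unsorted|increasing")
  expect_error(read_spectra(write_spectra_csv("wl,r")), "measurement column")
  expect_error(read_spectra(write_spectra_csv("wl,r\n300,0.1\n400,oops\n500,0.3")),
               "non-numeric")
  expect_error(read_spectra("no/such/file.csv"), "not found")
})

test_that("spectrum validation enforces the invariants and unit handling", {
  expect_error(spectrum(c(300, 300, 400), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(c(100, 400), c(1, 2)), "200, 1000")
  expect_error(spectrum(300, 1), "at least 2")
  expect_error(spectrum(c(300, 400), c(0.1, NA)), "finite")
  # percent units detected and converted
  expect_message(s <- spectrum(c(300, 400), c(20, 40)), "percent")
  expect_equal(s$value, c(0.2, 0.4))
  # instrument noise below zero clamped, above white standard kept
  expect_warning(s2 <- spectrum(c(300, 400), c(-0.01, 0.5)), "clamped")
  expect_equal(s2$value, c(0, 0.5))
  expect_warning(s3 <- spectrum(c(300, 400), c(0.2, 1.2)), "white standard")
  expect_equal(s3$value[2], 1.2)
})

test_that("resampling interpolates linearly and is exact on source nodes", {
  s <- spectrum(c(300, 400), c(0, 1))
  expect_equal(resample(s, 350, 350.5, 0.5)$value[1], 0.5)
  # identity on its own grid
  s2 <- spectrum(c(300, 350, 400), c(0.1, 0.7, 0.2))
  expect_equal(resample(s2, 300, 400, 50)$value, s2$value)
  # hand-interpolated tent function
  s3 <- spectrum(c(300, 400, 500), c(0, 1, 0))
  expect_equal(resample(s3, 300, 500, 50)$value, c(0, 0.5, 1, 0.5, 0))
  # node exactness for irregular source grids: a grid whose endpoints are
  # source nodes returns the node values untouched
  set.seed(7)
  for (i in 1:10) {
    wl <- sort(stats::runif(8, 300, 700))
    v <- stats::runif(8, 0, 1)
    src <- spectrum(wl, v)
    r <- resample(src, wl[3], wl[4], step = wl[4] - wl[3])
    expect_equal(r$value, v[3:4])
  }
})

test_that("resampling outside the support requires explicit extrapolation", {
  s <- spectrum(c(350, 650), c(0.2, 0.4))
  expect_error(resample(s, 300, 700, 1), "outside measured support")
  r <- resample(s, 300, 700, 50, extrapolate = TRUE)
  expect_equal(r$value[1], 0.2)   # held at nearest endpoint
  expect_equal(r$value[length(r$value)], 0.4)
})

test_that("mean spectrum is the pointwise mean and needs a common grid", {
  a <- spectrum(c(300, 400), c(0.2, 0.2))
  b <- spectrum(c(300, 400), c(0.4, 0.4))
  expect_equal(mean_spectrum(spectrum_set(list(a, a)))$value, a$value)
  expect_equal(mean_spectrum(spectrum_set(list(a, b)))$value, c(0.3, 0.3))
  set.seed(11)
  spectra <- replicate(5, random_smooth_spectrum(), simplify = FALSE)
  m <- mean_spectrum(spectrum_set(spectra))
  brute <- numeric(length(m$wl))
  for (s in spectra) brute <- brute + s$value / 5
  expect_equal(m$value, brute)
  bad <- spectrum(c(300, 500), c(0.1, 0.1))
  expect_error(mean_spectrum(spectrum_set(list(a, bad))), "common grid")
  expect_error(spectrum_set(list()), "non-empty")
  expect_error(spectrum_set(list(a, spectrum(c(300, 400), c(1, 1), kind = "sensitivity"))),
               "same kind")
})

test_that("mean commutes with resampling on a shared grid", {
  set.seed(3)
  spectra <- replicate(4, random_smooth_spectrum(), simplify = FALSE)
  set <- spectrum_set(spectra)
  m1 <- resample(mean_spectrum(set), 320, 680, 5)
  m2 <- mean_spectrum(spectrum_set(lapply(spectra, resample, 320, 680, 5)))
  expect_equal(m1$value, m2$value, tolerance = 1e-12)
})

test_that("write -> read round-trips spectra bit-identically", {
  set.seed(5)
  spectra <- replicate(3, random_smooth_spectrum(), simplify = FALSE)
  names(spectra) <- c("s1", "s2", "s3")
  set <- spectrum_set(spectra, label = "fixture")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(set, path)
  back <- read_spectra(path)
  for (i in 1:3) {
    expect_identical(back$spectra[[i]]$wl, spectra[[i]]$wl)
    expect_identical(back$spectra[[i]]$value, spectra[[i]]$value)
  }
})
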