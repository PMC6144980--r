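test_that("read_spectra handles fraction and percent dialects and rejects bad tables", {
  p <- write_temp_csv(c("300,0.07", "700,0.07"))
  s <- read_spectra(p)
  expect_equal(nrow(s), 2)
  expect_equal(names(s)[1], "wavelength")
  expect_equal(s$value, c(0.07, 0.07))

  p2 <- write_temp_csv(c("300,7", "700,7"))
  expect_equal(read_spectra(p2, value_scale = "percent")$value, c(0.07, 0.07))

  p3 <- write_temp_csv(c("400,0.1", "300,0.2"))
  expect_error(read_spectra(p3), "strictly increasing")

  p4 <- write_temp_csv(c("300,0.1", "400,oops"))
  expect_error(read_spectra(p4), "non-numeric")
})

test_that("resample interpolates linearly, preserves nodes, and never extrapolates", {
  flat <- flat_reflectance(0.07, grid = c(300, 700))
  r <- resample_spectra(flat, 300:700)
  expect_equal(nrow(r), 401)
  expect_true(all(r$reflectance == 0.07))

  ramp <- tibble::tibble(wavelength = c(300, 700), value = c(0, 1))
  expect_equal(resample_spectra(ramp, 500)$value, 0.5)
  # values at original nodes unchanged
  expect_equal(resample_spectra(ramp, c(300, 700))$value, c(0, 1))
  expect_error(resample_spectra(ramp, 299:700), "extrapolation")

  # idempotent on its own grid
  once <- resample_spectra(ramp, seq(300, 700, 10))
  expect_equal(resample_spectra(once, seq(300, 700, 10)), once)
})

test_that("clamp_nonnegative zeroes negatives, counts them, and is idempotent", {
  s <- tibble::tibble(wavelength = c(300, 400), value = c(-0.01, 0.05))
  out <- clamp_nonnegative(s)
  expect_equal(out$value, c(0, 0.05))
  expect_equal(unname(attr(out, "n_clamped")), 1L)

  pos <- tibble::tibble(wavelength = c(300, 400), value = c(0.1, 0.2))
  expect_equal(clamp_nonnegative(pos)$value, pos$value)
  expect_equal(unname(attr(clamp_nonnegative(pos), "n_clamped")), 0L)

  neg <- tibble::tibble(wavelength = c(300, 400), value = c(-1, -2))
  expect_equal(clamp_nonnegative(neg)$value, c(0, 0))
  expect_equal(clamp_nonnegative(clamp_nonnegative(s))$value, out$value)
})

test_that("flat_reflectance is constant and validates its level", {
  s <- flat_reflectance(0.07)
  expect_true(all(s$reflectance == 0.07))
  expect_equal(nrow(s), 401)
  expect_true(all(flat_reflectance(0)$reflectance == 0))
  expect_true(all(flat_reflectance(0.95)$reflectance == 0.95))
  expect_error(flat_reflectance(1.2), "\\[0, 1\\]")
  expect_error(flat_reflectance(-0.1), "\\[0, 1\\]")
})

test_that("logistic_reflectance has the right centre, asymptote, bounds and monotonicity", {
  s <- logistic_reflectance(500, lower = 0.1, upper = 0.6, slope = 0.05)
  expect_equal(s$reflectance[s$wavelength == 500], 0.35) # (lower+upper)/2
  s2 <- logistic_reflectance(300, lower = 0.1, upper = 0.6, slope = 0.05)
  expect_lt(abs(s2$reflectance[s2$wavelength == 700] - 0.6), 1e-6)

  # bounded in (lower, upper) and strictly increasing, across parameter draws
  set.seed(11)
  for (k in 1:10) {
    mid <- runif(1, 350, 650); lo <- runif(1, 0, 0.3); hi <- runif(1, 0.4, 1)
    v <- logistic_reflectance(mid, lo, hi, slope = runif(1, 0.01, 0.05))$reflectance
    expect_true(all(v > lo & v < hi))
    expect_true(all(diff(v) > 0))
  }
  expect_error(logistic_reflectance(500, lower = 0.6, upper = 0.1), "lower")
})

test_that("the midpoint sweep specification yields 81 logistic spectra", {
  mids <- seq(300, 700, by = 5)
  expect_length(mids, 81)
  specs <- purrr::map(mids, ~ logistic_reflectance(.x))
  expect_length(specs, 81)
})

test_that("gaussian_reflectance matches its formula", {
  s <- gaussian_reflectance(500, sd = 50, peak = 0.6, baseline = 0)
  expect_equal(s$reflectance[s$wavelength == 500], 0.6)
  expect_equal(s$reflectance[s$wavelength == 550], 0.6 * exp(-0.5))
  expect_equal(s$reflectance[s$wavelength == 450], 0.6 * exp(-0.5))
  expect_lt(s$reflectance[s$wavelength == 300], 1e-3)
  expect_error(gaussian_reflectance(500, sd = -1, peak = 0.5), "positive")
})

test_that("shift_reflectance adds percentage points with a floor at zero", {
  expect_true(all(shift_reflectance(flat_reflectance(0.10), -10)$reflectance == 0))
  expect_equal(shift_reflectance(flat_reflectance(0.60), -10)$reflectance,
               rep(0.50, 401))
  s <- logistic_reflectance(500)
  expect_equal(shift_reflectance(s, 0), s)
})

test_that("gaussian_sensitivity peaks at one, is symmetric, and spans the screening set", {
  s <- gaussian_sensitivity(480, sd = 35)
  expect_equal(s$s480[s$wavelength == 480], 1)
  expect_equal(s$s480[s$wavelength == 430], s$s480[s$wavelength == 530])
  peaks <- seq(330, 630, by = 30)
  expect_length(peaks, 11)
  lib <- purrr::reduce(purrr::map(peaks, ~ gaussian_sensitivity(.x)[2]),
                       dplyr::bind_cols)
  expect_equal(ncol(lib), 11)
})

test_that("builtin illuminants load and unknown names fail", {
  fl <- builtin_illuminant("flat")
  expect_true(all(fl$irradiance == 1))
  d65 <- builtin_illuminant("D65")
  expect_equal(nrow(d65), 401)
  expect_true(all(d65$irradiance > 0))
  expect_gt(diff(range(d65$irradiance)), 0) # nonconstant
  expect_error(builtin_illuminant("D50x"), "unknown illuminant")
})

test_that("harmonize_spectra puts everything on one grid", {
  a <- flat_reflectance(0.2, grid = seq(300, 700, 10))
  b <- gaussian_sensitivity(500, grid = seq(300, 700, 2))
  out <- harmonize_spectra(a = a, b = b, grid = 300:700)
  expect_equal(out$wavelength, 300:700)
  expect_equal(names(out), c("wavelength", "a", "b"))
  expect_true(all(out$a == 0.2))
})

test_that("clamping and resampling commute on nonnegative data", {
  s <- gaussian_reflectance(450, sd = 60, peak = 0.8, grid = seq(300, 700, 5))
  g <- 300:700
  a <- clamp_nonnegative(resample_spectra(s, g))
  b <- resample_spectra(clamp_nonnegative(s), g)
  expect_equal(a$reflectance, b$reflectance)
})
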