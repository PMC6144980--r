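test_that("model_config enforces each model's definition", {
  ch <- model_config("CH")
  expect_equal(ch$transform, "hyperbolic")
  expect_equal(ch$scale_value, 1)
  em <- model_config("EM")
  expect_true(em$relative_outputs)
  expect_equal(em$scale_value, 0.75)

  expect_error(model_config("CH", noise = c(0.1, 0.1)), "does not use receptor noise")
  expect_error(model_config("EM", transform = "identity"), "fixes transform")
  expect_error(model_config("generic", transform = "custom"), "custom_f")

  # missing noise surfaces at run time for RNL kinds
  recs <- photoreceptor_set(fix_receptors()$sensitivity) # no noise attached
  bg <- flat_reflectance(0.07)
  expect_error(
    run_model(logistic_reflectance(500, name = "s"), bg, fix_flat_illum(), recs,
              model_config("RNL_log")),
    "requires receptor noise")
})

test_that("a stimulus identical to its background sits at the origin in every model", {
  recs <- fix_receptors()
  illum <- builtin_illuminant("D65")
  bg <- flat_reflectance(0.07)
  stim <- flat_reflectance(0.07, name = "same")
  for (kind in c("CH", "RNL_linear", "RNL_log")) {
    fit <- run_model(stim, bg, illum, recs, model_config(kind))
    r <- tidy(fit)
    expect_equal(r$delta_s, 0, tolerance = 1e-9)
    expect_equal(as.numeric(r[grep("^X", names(r))]), c(0, 0), tolerance = 1e-9)
  }
})

test_that("relative outputs concentrated in one corner reach the scaled maximum 0.75", {
  for (i in c(3, 4)) {
    V <- chromaticity_basis(i, "vector_length", 0.75)
    p <- c(1, rep(0, i - 1))
    x <- as.numeric(unclass(V) %*% p)
    expect_equal(sqrt(sum(x^2)), 0.75, tolerance = 1e-12)
  }
})

test_that("colour-hexagon loci stay strictly inside the unit circumradius", {
  recs <- fix_receptors()
  illum <- builtin_illuminant("D65")
  bg <- flat_reflectance(0.07)
  set.seed(3)
  stim <- tibble::tibble(wavelength = fix_grid)
  for (k in 1:12) {
    stim <- dplyr::bind_cols(
      stim,
      gaussian_reflectance(runif(1, 320, 680), sd = runif(1, 20, 90),
                           peak = runif(1, 0.2, 1), baseline = runif(1, 0, 0.1),
                           name = paste0("g", k))[2])
  }
  fit <- run_model(stim, bg, illum, recs, model_config("CH"))
  expect_true(all(tidy(fit)$delta_s < 1))
})

test_that("closed-form receptor-noise distances match their formulas", {
  expect_equal(round(rnl_delta_s_closed(c(0, 0, 1), c(0, 0, 0), rep(0.1, 3)), 4), 8.1650)
  expect_equal(round(rnl_delta_s_closed(c(0, 1), c(0, 0), c(0.1, 0.1)), 4), 7.0711)
  for (c0 in c(-2, 0.3, 5)) {
    expect_equal(rnl_delta_s_closed(rep(c0, 3), rep(0, 3), c(0.13, 0.06, 0.12)), 0,
                 tolerance = 1e-12)
  }
  expect_error(rnl_delta_s_closed(1:5, 1:5, rep(0.1, 5)), "closed forms")
  expect_error(rnl_delta_s_closed(c(0, 1), c(0, 0), c(0.1, -0.1)), "> 0")
})

test_that("the noise-space transform reproduces closed-form distances", {
  # equal noise, trichromat: V R V^T = e^2 (3/2) I, so s = x / (e sqrt(3/2))
  V <- chromaticity_basis(3)
  x <- matrix(c(0, 0, 1), 1) %*% t(unclass(V))
  s <- rnl_noise_space(x, V, rep(0.1, 3))
  expect_equal(as.matrix(s), x / (0.1 * sqrt(1.5)), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(round(sqrt(sum(as.matrix(s)^2)), 4), 8.1650)

  # origin maps to origin
  s0 <- rnl_noise_space(matrix(0, 1, 2), V, c(0.13, 0.06, 0.12))
  expect_equal(as.numeric(as.matrix(s0)), c(0, 0))

  # oracle equivalence on randomized inputs for 2-4 receptors
  set.seed(99)
  for (i in 2:4) {
    basis <- chromaticity_basis(i)
    for (rep_k in 1:50) {
      Ea <- runif(i, -1, 1); Eb <- runif(i, -1, 1)
      e <- runif(i, 0.02, 0.3)
      expect_equal(rnl_delta_s(Ea, Eb, e, basis),
                   rnl_delta_s_closed(Ea, Eb, e), tolerance = 1e-9)
    }
  }
})

test_that("the general receptor-noise distance is defined beyond four receptors", {
  expect_equal(rnl_delta_s(rep(0.4, 5), rep(0.4, 5), rep(0.1, 5)), 0, tolerance = 1e-12)
  set.seed(5)
  Ea <- runif(5); Eb <- runif(5); e <- runif(5, 0.05, 0.2)
  d1 <- rnl_delta_s(Ea, Eb, e)
  expect_gt(d1, 0)
  # homogeneity: scaling all noise by c scales the distance by 1/c
  expect_equal(rnl_delta_s(Ea, Eb, 3 * e), d1 / 3, tolerance = 1e-9)
  # noise space demands a unit-column basis
  expect_error(rnl_noise_space(matrix(0, 1, 2), chromaticity_basis(3, "vector_length", 0.75),
                               rep(0.1, 3)), "unit-column")
})

test_that("log-RNL distances are invariant to multiplicative stimulus scaling", {
  recs <- fix_receptors()
  illum <- builtin_illuminant("D65")
  leaf <- synthetic_leaf_background()
  cfg <- model_config("RNL_log")
  base <- flat_reflectance(0.2, name = "s")
  d0 <- tidy(run_model(base, leaf, illum, recs, cfg))$delta_s
  for (k in c(0.5, 2, 4)) {
    scaled <- base; scaled$s <- scaled$s * k
    dk <- tidy(run_model(scaled, leaf, illum, recs, cfg))$delta_s
    expect_equal(dk, d0, tolerance = 1e-9)
  }
})

test_that("tidy and glance summarise a model run", {
  recs <- fix_receptors()
  fit <- run_model(logistic_reflectance(520, name = "a"), flat_reflectance(0.07),
                   fix_flat_illum(), recs, model_config("CH"))
  td <- tidy(fit)
  expect_true(all(c("stimulus", "Q_s1", "q_s1", "E_s1", "X1", "X2",
                    "delta_s", "near_singular", "negative_output") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_stimuli, 1)
  expect_equal(g$kind, "CH")
})

test_that("abundance-derived noise pools cells as 1/sqrt(eta)", {
  e <- noise_from_abundance(0.05, c(a = 1, b = 4))
  expect_equal(unname(e), c(0.05 / sqrt(0.2), 0.05 / sqrt(0.8)))
  expect_equal(names(e), c("a", "b"))
  # scale-free in the abundances
  expect_equal(noise_from_abundance(0.05, c(2, 8)), e, ignore_attr = TRUE)
  expect_error(noise_from_abundance(-1, c(1, 1)), "positive")
  expect_error(noise_from_abundance(0.05, c(0, 1)), "> 0")
})

test_that("transform expressions parse safely", {
  f <- parse_transform("q/(q+1)")
  expect_equal(f(1), 0.5)
  expect_equal(f(c(0, 3)), c(0, 0.75))
  g <- parse_transform("log(q) + 0.5*sqrt(q)")
  expect_equal(g(4), log(4) + 1)
  expect_error(parse_transform("system('ls')"), "not allowed")
  expect_error(parse_transform("q + x"), "not allowed")
  expect_error(parse_transform("q +"), "cannot parse")
})
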