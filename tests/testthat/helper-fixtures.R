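# Shared fixtures: everything is generated in code at test time.

fix_grid <- 300:700

# Trichromatic Gaussian receptor set with honeybee noise values.
fix_receptors <- function(noise = c(0.13, 0.06, 0.12), grid = fix_grid, sd = 40) {
  sens <- harmonize_spectra(
    s1 = gaussian_sensitivity(350, sd = sd, grid = grid),
    s2 = gaussian_sensitivity(450, sd = sd, grid = grid),
    s3 = gaussian_sensitivity(550, sd = sd, grid = grid),
    grid = grid
  )
  photoreceptor_set(sens, noise = noise)
}

fix_flat_illum <- function(grid = fix_grid) builtin_illuminant("flat", grid)

write_temp_csv <- function(lines, header = "wavelength_nm,value") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

# One-row output tibble helper for vector-level ops.
E_row <- function(...) {
  v <- c(...)
  names(v) <- paste0("s", seq_along(v))
  dplyr::bind_cols(tibble::tibble(stimulus = "a"), tibble::as_tibble(as.list(v)))
}

# Random receptor-output vectors for property tests.
random_outputs <- function(i, n = 1, scale = 1) {
  matrix(stats::runif(i * n, -scale, scale), nrow = n)
}
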