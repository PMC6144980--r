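#' @importFrom rlang .data :=
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Default working wavelength grid
#'
#' The 300--700 nm range at 1-nm steps covers the visual range of most
#' insects and birds (ultraviolet through red) and is the grid on which
#' all packaged spectra and simulations operate by default.
#'
#' @return Integer vector of wavelengths (nm).
#' @export
default_grid <- function() 300:700

# Shared validator: wide spectra table, first column wavelength (nm),
# remaining columns numeric spectral values.
validate_spectra <- function(spec, arg = "spec") {
  if (!is.data.frame(spec) || ncol(spec) < 2) {
    stop(sprintf("`%s` must be a data frame with a wavelength column and at least one value column", arg),
         call. = FALSE)
  }
  wl <- spec[[1]]
  if (!is.numeric(wl)) {
    stop(sprintf("first column of `%s` must be numeric wavelengths (nm)", arg), call. = FALSE)
  }
  if (anyNA(wl) || any(diff(wl) <= 0)) {
    bad <- if (anyNA(wl)) which(is.na(wl))[1] else which(diff(wl) <= 0)[1] + 1
    stop(sprintf("wavelengths in `%s` must be strictly increasing (problem at row %d)", arg, bad),
         call. = FALSE)
  }
  for (j in seq(2, ncol(spec))) {
    if (!is.numeric(spec[[j]])) {
      stop(sprintf("column '%s' of `%s` is not numeric", names(spec)[j], arg), call. = FALSE)
    }
  }
  invisible(spec)
}

spectra_values <- function(spec) as.matrix(spec[, -1, drop = FALSE])

#' Read spectra from a CSV table
#'
#' Reads a wide CSV with wavelengths (nm) in the first column and one
#' spectrum per remaining column. A header row is required. Values may be
#' reflectance fractions (0--1), percent reflectance, irradiance or
#' sensitivity; percent tables are converted to the package-internal
#' fraction convention at read time.
#'
#' @param path Path to a CSV file. First column: wavelength in nm,
#'   strictly increasing. Remaining columns: spectral values.
#' @param value_scale Either `"fraction"` (values used as-is) or
#'   `"percent"` (values divided by 100 on read).
#' @return A tibble with column `wavelength` followed by one numeric
#'   column per spectrum in the file.
#' @examples
#' path <- system.file("extdata", "cie_d65_300_700_5nm.csv", package = "chromaspace")
#' d65 <- read_spectra(path)
#' @export
read_spectra <- function(path, value_scale = c("fraction", "percent")) {
  value_scale <- match.arg(value_scale)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2) stop("spectra CSV needs a wavelength column plus at least one value column", call. = FALSE)
  for (j in seq_len(ncol(raw))) {
    if (!is.numeric(raw[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))) & !is.na(raw[[j]]))[1]
      stop(sprintf("non-numeric value in column '%s' of %s (data row %s)",
                   names(raw)[j], basename(path), ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  names(raw)[1] <- "wavelength"
  out <- tibble::as_tibble(raw)
  validate_spectra(out, "path")
  if (value_scale == "percent") {
    out[-1] <- lapply(out[-1], function(v) v / 100)
  }
  out
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation of every spectrum column onto `grid`. No
#' extrapolation is ever performed: grids extending beyond the measured
#' range are an error, because silently extrapolated reflectance is a
#' classic source of spurious quantum catches.
#'
#' @param spec Wide spectra tibble (wavelength first column).
#' @param grid Target wavelengths (nm), within the range of `spec`.
#' @return Tibble on the new grid with the same value columns.
#' @export
resample_spectra <- function(spec, grid = default_grid()) {
  validate_spectra(spec)
  wl <- spec[[1]]
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    stop(sprintf("grid [%g, %g] extends beyond the measured range [%g, %g]; extrapolation is not supported",
                 min(grid), max(grid), min(wl), max(wl)), call. = FALSE)
  }
  grid <- sort(unique(grid))
  out <- tibble::tibble(wavelength = grid)
  for (nm in names(spec)[-1]) {
    out[[nm]] <- stats::approx(wl, spec[[nm]], xout = grid, method = "linear")$y
  }
  out
}

#' Clamp spectra to non-negative values
#'
#' Spectrometer noise commonly produces small negative reflectance
#' readings; these are physically meaningless and are converted to zero
#' before modelling. The number of clamped points is attached as
#' attribute `"n_clamped"` (named per column).
#'
#' @param spec Wide spectra tibble.
#' @return The same tibble with negative values replaced by 0.
#' @export
clamp_nonnegative <- function(spec) {
  validate_spectra(spec)
  counts <- integer(0)
  for (nm in names(spec)[-1]) {
    neg <- spec[[nm]] < 0
    counts[nm] <- sum(neg)
    spec[[nm]][neg] <- 0
  }
  attr(spec, "n_clamped") <- counts
  spec
}

#' Flat (achromatic) reflectance spectrum
#'
#' @param level Reflectance fraction in `[0, 1]`, constant across the grid.
#' @param grid Wavelengths (nm).
#' @param name Name of the value column.
#' @return Two-column tibble (`wavelength`, value).
#' @examples
#' bg <- flat_reflectance(0.07) # 7% achromatic background
#' @export
flat_reflectance <- function(level, grid = default_grid(), name = "reflectance") {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) || level < 0 || level > 1) {
    stop("`level` must be a single reflectance fraction in [0, 1]", call. = FALSE)
  }
  tibble::tibble(wavelength = grid, !!name := rep(level, length(grid)))
}

#' Logistic (sigmoid) reflectance spectrum
#'
#' Reflectance rising sigmoidally from `lower` to `upper` with inflection
#' at `midpoint`:
#' \deqn{R(\lambda) = lower + (upper - lower) / (1 + e^{-slope(\lambda - midpoint)})}
#' Step-like spectra of this shape mimic many natural colourants and,
#' swept across midpoints, trace a hue series from ultraviolet-reflecting
#' to red-reflecting stimuli.
#'
#' @param midpoint Inflection wavelength (nm).
#' @param lower,upper Lower/upper reflectance asymptotes (fractions),
#'   `lower < upper`.
#' @param slope Steepness per nm (> 0); the default 0.05 gives a
#'   transition roughly 100 nm wide.
#' @param grid Wavelengths (nm).
#' @param name Value column name.
#' @return Two-column tibble.
#' @export
logistic_reflectance <- function(midpoint, lower = 0.1, upper = 0.6, slope = 0.05,
                                 grid = default_grid(), name = "reflectance") {
  if (lower >= upper) stop("`lower` must be strictly below `upper`", call. = FALSE)
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  v <- lower + (upper - lower) / (1 + exp(-slope * (grid - midpoint)))
  tibble::tibble(wavelength = grid, !!name := v)
}

#' Gaussian (peaked) reflectance spectrum
#'
#' @param center Peak wavelength (nm).
#' @param sd Width (nm), > 0.
#' @param peak Reflectance at the peak (fraction).
#' @param baseline Reflectance far from the peak (fraction), < `peak`.
#' @param grid Wavelengths (nm).
#' @param name Value column name.
#' @return Two-column tibble.
#' @export
gaussian_reflectance <- function(center, sd, peak, baseline = 0,
                                 grid = default_grid(), name = "reflectance") {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (baseline < 0 || baseline >= peak || peak > 1) {
    stop("need 0 <= baseline < peak <= 1", call. = FALSE)
  }
  v <- baseline + (peak - baseline) * exp(-(grid - center)^2 / (2 * sd^2))
  tibble::tibble(wavelength = grid, !!name := v)
}

#' Shift reflectance by percentage points
#'
#' Adds `delta` percentage points (i.e. `delta/100` in fraction units) to
#' every value column and clamps at zero. Used to emulate small
#' measurement offsets, e.g. subtracting 10 points to push a stimulus
#' below its adapting background.
#'
#' @param spec Wide spectra tibble.
#' @param delta Shift in percentage points (may be negative).
#' @return Shifted tibble (values floored at 0).
#' @export
shift_reflectance <- function(spec, delta) {
  validate_spectra(spec)
  for (nm in names(spec)[-1]) {
    spec[[nm]] <- pmax(spec[[nm]] + delta / 100, 0)
  }
  spec
}

#' Gaussian photoreceptor sensitivity template
#'
#' Unit-peak Gaussian spectral sensitivity, a synthetic stand-in for
#' measured photoreceptor curves when only the peak wavelength matters
#' (e.g. when screening hypothetical receptor sets).
#'
#' @param lambda_max Peak sensitivity wavelength (nm).
#' @param sd Curve width (nm), > 0.
#' @param grid Wavelengths (nm).
#' @param name Value column name (defaults to `"s<lambda_max>"`).
#' @return Two-column tibble with value 1 at `lambda_max`.
#' @export
gaussian_sensitivity <- function(lambda_max, sd = 40, grid = default_grid(),
                                 name = paste0("s", lambda_max)) {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  v <- exp(-(grid - lambda_max)^2 / (2 * sd^2))
  tibble::tibble(wavelength = grid, !!name := v)
}

#' Packaged illuminants
#'
#' `"D65"` is the CIE D65 standard daylight illuminant (midday open-air
#' conditions), packaged as the standard 5-nm table over 300--700 nm and
#' interpolated onto `grid`. `"flat"` is an ideal equal-energy
#' illuminant (constant 1).
#'
#' @param name `"D65"` or `"flat"`.
#' @param grid Wavelengths (nm), within 300--700 for D65.
#' @return Tibble with columns `wavelength`, `irradiance` (relative units).
#' @export
builtin_illuminant <- function(name = c("D65", "flat"), grid = default_grid()) {
  if (!is.character(name) || length(name) != 1 || !(name %in% c("D65", "flat"))) {
    stop(sprintf("unknown illuminant '%s' (available: D65, flat)", paste(name, collapse = ",")),
         call. = FALSE)
  }
  if (name == "flat") {
    return(tibble::tibble(wavelength = grid, irradiance = rep(1, length(grid))))
  }
  path <- system.file("extdata", "cie_d65_300_700_5nm.csv", package = "chromaspace")
  d65 <- read_spectra(path)
  names(d65)[2] <- "irradiance"
  resample_spectra(d65, grid)
}

#' Synthetic leaf-like chromatic background
#'
#' A smooth stand-in for averaged vegetation reflectance: low in the
#' ultraviolet and blue, a chlorophyll-driven green bump near 550 nm,
#' and the beginning of the far-red rise towards 700 nm. Useful as a
#' chromatic adapting background when no measured vegetation average is
#' at hand; any measured spectrum can be supplied instead wherever this
#' is accepted.
#'
#' @param grid Wavelengths (nm).
#' @return Two-column tibble (`wavelength`, `reflectance`).
#' @export
synthetic_leaf_background <- function(grid = default_grid()) {
  v <- 0.02 +
    0.06 * exp(-(grid - 550)^2 / (2 * 40^2)) +
    0.30 / (1 + exp(-0.08 * (grid - 712)))
  tibble::tibble(wavelength = grid, reflectance = v)
}

#' Combine spectra onto one shared grid
#'
#' Resamples every supplied spectra table onto `grid` and binds the
#' value columns into one wide tibble. All inputs must cover `grid`.
#'
#' @param ... Wide spectra tibbles (named arguments rename single-column
#'   inputs).
#' @param grid Common wavelength grid (nm).
#' @return One wide tibble on `grid`.
#' @export
harmonize_spectra <- function(..., grid = default_grid()) {
  specs <- list(...)
  if (!length(specs)) stop("no spectra supplied", call. = FALSE)
  nms <- names(specs)
  out <- tibble::tibble(wavelength = sort(unique(grid)))
  for (k in seq_along(specs)) {
    s <- resample_spectra(specs[[k]], out$wavelength)
    vals <- s[, -1, drop = FALSE]
    if (!is.null(nms) && nzchar(nms[k]) && ncol(vals) == 1) names(vals) <- nms[k]
    out <- dplyr::bind_cols(out, vals)
  }
  out
}

same_grid <- function(a, b) {
  isTRUE(all.equal(as.numeric(a[[1]]), as.numeric(b[[1]]), tolerance = 1e-9))
}
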