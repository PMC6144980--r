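#' Logistic midpoint sweep
#'
#' Runs one configured model over a series of sigmoid reflectance
#' stimuli whose midpoints sweep the spectrum (by default 300--700 nm
#' in 5-nm steps, 81 stimuli), tracing a hue series against a fixed
#' background. `shift` adds that many percentage points to every
#' stimulus (clamped at zero) after generation; a negative shift pushes
#' stimuli below the background and exercises the spurious regimes of
#' log-transformed, relative-output models.
#'
#' @param receptors A [photoreceptor_set()].
#' @param illuminant Illuminant tibble.
#' @param background Background reflectance tibble (single spectrum).
#' @param config A [model_config()].
#' @param midpoints Logistic midpoints (nm).
#' @param lower,upper,slope Logistic parameters (see
#'   [logistic_reflectance()]).
#' @param shift Percentage points added to each stimulus (default 0).
#' @return A `sweep_result`; [tidy()] gives one row per midpoint with
#'   outputs, locus, `delta_s` and warning flags; [glance()] reports
#'   the peak.
#' @export
midpoint_sweep <- function(receptors, illuminant, background,
                           config = model_config("CH"),
                           midpoints = seq(300, 700, by = 5),
                           lower = 0.1, upper = 0.6, slope = 0.05,
                           shift = 0) {
  grid <- as.numeric(background[[1]])
  stimuli <- tibble::tibble(wavelength = grid)
  for (m in midpoints) {
    s <- logistic_reflectance(m, lower, upper, slope, grid = grid,
                              name = sprintf("m%g", m))
    stimuli <- dplyr::bind_cols(stimuli, s[2])
  }
  if (shift != 0) stimuli <- shift_reflectance(stimuli, shift)
  fit <- run_model(stimuli, background, illuminant, receptors, config)
  res <- dplyr::mutate(fit$results, midpoint = midpoints, .before = 1)
  structure(list(results = res, parameter = "midpoint", config = config,
                 basis = fit$basis, receptors = fit$receptors),
            class = c("sweep_result"))
}

#' Achromatic reflectance sweep
#'
#' Runs one model over flat (achromatic) stimuli of increasing
#' reflectance level (by default 5% to 95% in 10-point steps) against
#' an arbitrary — typically chromatic — background. Against a
#' chromatic background the achromatic stimuli do not sit at the
#' diagram centre; the log-RNL model then returns the same distance at
#' every level (ln differences are level-independent) while the linear
#' RNL distance grows with level.
#'
#' @inheritParams midpoint_sweep
#' @param levels Reflectance fractions to sweep.
#' @return A `sweep_result` keyed by `level`.
#' @export
achromatic_sweep <- function(receptors, illuminant, background,
                             config = model_config("CH"),
                             levels = seq(0.05, 0.95, by = 0.1)) {
  grid <- as.numeric(background[[1]])
  stimuli <- tibble::tibble(wavelength = grid)
  for (lv in levels) {
    s <- flat_reflectance(lv, grid = grid, name = sprintf("r%g", round(lv * 100)))
    stimuli <- dplyr::bind_cols(stimuli, s[2])
  }
  fit <- run_model(stimuli, background, illuminant, receptors, config)
  res <- dplyr::mutate(fit$results, level = levels, .before = 1)
  structure(list(results = res, parameter = "level", config = config,
                 basis = fit$basis, receptors = fit$receptors),
            class = c("sweep_result"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s over %d %s values>\n",
              x$config$kind, nrow(x$results), x$parameter))
  print(x$results, ...)
  invisible(x)
}

#' @rdname midpoint_sweep
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @export
tidy.sweep_result <- function(x, ...) x$results

#' @rdname midpoint_sweep
#' @export
glance.sweep_result <- function(x, ...) {
  r <- x$results
  peak <- which.max(r$delta_s)
  tibble::tibble(
    kind = x$config$kind,
    parameter = x$parameter,
    n = nrow(r),
    max_delta_s = r$delta_s[peak],
    peak_at = r[[x$parameter]][peak],
    n_near_singular = sum(r$near_singular),
    n_negative_output = sum(r$negative_output)
  )
}

#' Random flower-like reflectance spectra
#'
#' Generates `n` synthetic reflectance spectra loosely shaped like
#' flower petals: a random mixture of a sigmoid long-pass edge and a
#' Gaussian peak, with random asymptotes, positions and widths. A
#' stand-in for measured flower libraries when screening receptor sets
#' or comparing models on heterogeneous stimuli.
#'
#' @param n Number of spectra.
#' @param grid Wavelengths (nm).
#' @param seed Optional seed for reproducibility.
#' @return Wide tibble with columns `flower_1 ... flower_n`.
#' @export
synthetic_flower_spectra <- function(n = 50, grid = default_grid(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  out <- tibble::tibble(wavelength = grid)
  for (k in seq_len(n)) {
    w <- stats::runif(1)
    edge <- logistic_reflectance(stats::runif(1, 350, 650),
                                 lower = stats::runif(1, 0.01, 0.1),
                                 upper = stats::runif(1, 0.3, 0.9),
                                 slope = stats::runif(1, 0.02, 0.12),
                                 grid = grid)[[2]]
    bump <- gaussian_reflectance(stats::runif(1, 320, 680),
                                 sd = stats::runif(1, 25, 90),
                                 peak = stats::runif(1, 0.3, 0.9),
                                 baseline = stats::runif(1, 0.01, 0.1),
                                 grid = grid)[[2]]
    out[[sprintf("flower_%d", k)]] <- w * edge + (1 - w) * bump
  }
  out
}

#' Screen photoreceptor sets for stimulus discriminability
#'
#' Enumerates every combination of candidate peak wavelengths at each
#' requested set size, builds unit-peak Gaussian sensitivities for each
#' combination, and scores the combination by the mean chromatic
#' distance of all stimuli from the background under the chosen model.
#' The best receptor set (per size and overall) is the one maximising
#' mean \eqn{\Delta S}. Enumeration is exhaustive:
#' \eqn{\sum_k \binom{|peaks|}{k}} combinations are evaluated.
#'
#' @param stimuli Wide reflectance tibble (the stimulus library).
#' @param background Background reflectance tibble.
#' @param illuminant Illuminant tibble.
#' @param candidate_peaks Candidate \eqn{\lambda_{max}} values (nm),
#'   distinct.
#' @param set_sizes Receptor counts to screen (each >= 2).
#' @param kind Model kind: `"RNL_log"`, `"RNL_linear"`, `"CH"`, `"EM"`
#'   or `"generic"`.
#' @param noise_value Weber fraction applied to every receptor (RNL
#'   kinds).
#' @param scale_mode,scale_value Basis scaling passed to the model
#'   (e.g. a fixed vertex distance across sizes).
#' @param sensitivity_sd Width (nm) of the Gaussian sensitivity
#'   template.
#' @param n_sample Optionally subsample this many stimulus columns.
#' @param seed Seed used for the subsample (ignored otherwise).
#' @return A `receptor_screen`; [tidy()] gives one row per combination
#'   (`size`, `peaks`, `mean_delta_s`, `rank`), [glance()] the best
#'   combination per size.
#' @export
screen_receptor_sets <- function(stimuli, background, illuminant,
                                 candidate_peaks = seq(330, 630, by = 30),
                                 set_sizes = 2:5,
                                 kind = "RNL_log", noise_value = 0.1,
                                 scale_mode = "vector_length", scale_value = 1,
                                 sensitivity_sd = 40,
                                 n_sample = NULL, seed = NULL) {
  if (anyDuplicated(candidate_peaks)) stop("candidate peaks must be distinct", call. = FALSE)
  if (any(set_sizes < 2)) stop("set sizes must be >= 2", call. = FALSE)
  if (any(set_sizes > length(candidate_peaks))) {
    stop("a set size exceeds the number of candidate peaks", call. = FALSE)
  }
  validate_spectra(stimuli, "stimuli")
  if (!is.null(n_sample)) {
    cols <- names(stimuli)[-1]
    if (n_sample < length(cols)) {
      if (!is.null(seed)) set.seed(seed)
      keep <- sort(sample(seq_along(cols), n_sample))
      stimuli <- stimuli[c(1, keep + 1)]
    }
  }
  grid <- as.numeric(stimuli[[1]])
  sens_all <- tibble::tibble(wavelength = grid)
  for (p in candidate_peaks) {
    sens_all <- dplyr::bind_cols(sens_all, gaussian_sensitivity(p, sd = sensitivity_sd, grid = grid)[2])
  }
  recs_all <- photoreceptor_set(sens_all)
  # catches once for all candidate receptors; combinations subset columns
  Qall  <- as.matrix(quantum_catch(stimuli, illuminant, recs_all)[recs_all$receptors])
  QBall <- as.numeric(quantum_catch(background, illuminant, recs_all)[1, recs_all$receptors])
  if (any(QBall <= 0)) stop("degenerate background: zero background catch for some candidate receptor", call. = FALSE)
  qall <- sweep(Qall, 2, QBall, "/")

  cfg0 <- if (kind %in% c("RNL_log", "RNL_linear")) {
    model_config(kind, noise = rep(noise_value, 2))
  } else {
    model_config(kind, scale_mode = scale_mode, scale_value = scale_value)
  }
  fn <- transform_fun(cfg0$transform, cfg0$custom_f)

  rows <- list()
  for (sz in sort(set_sizes)) {
    basis <- chromaticity_basis(sz, cfg0$scale_mode,
                                if (kind %in% c("RNL_log", "RNL_linear")) 1 else cfg0$scale_value)
    V <- unclass(basis)
    W <- if (cfg0$use_noise) {
      inv_sqrtm_spd(V %*% diag(rep(noise_value^2, sz)) %*% t(V))
    } else NULL
    combs <- utils::combn(sort(candidate_peaks), sz)
    for (cc in seq_len(ncol(combs))) {
      pk <- combs[, cc]
      idx <- match(pk, candidate_peaks)
      qs <- qall[, idx, drop = FALSE]
      if (identical(cfg0$transform, "ln") && any(qs <= 0)) {
        stop("ln transform undefined for a zero relative catch during screening", call. = FALSE)
      }
      E <- fn(qs)
      if (cfg0$relative_outputs) E <- sweep(E, 1, rowSums(E), "/")
      if (cfg0$use_noise) {
        Ebg <- fn(rep(1, sz))
        D <- sweep(E, 2, Ebg, "-")
        S <- (D %*% t(V)) %*% t(W)
        ds <- sqrt(rowSums(S^2))
      } else {
        X <- E %*% t(V)
        ds <- sqrt(rowSums(X^2))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size = sz,
        peaks = paste(pk, collapse = "+"),
        mean_delta_s = mean(ds)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$mean_delta_s), .data$peaks)
  tab$rank <- seq_len(nrow(tab))
  tab <- dplyr::arrange(tab, .data$size, .data$rank)
  structure(list(results = tab, kind = kind, noise_value = noise_value,
                 n_stimuli = ncol(stimuli) - 1,
                 candidate_peaks = sort(candidate_peaks), set_sizes = sort(set_sizes)),
            class = "receptor_screen")
}

#' @export
print.receptor_screen <- function(x, ...) {
  cat(sprintf("<receptor_screen: %s, %d combination(s) of %d candidate peaks over %d stimulus/stimuli>\n",
              x$kind, nrow(x$results), length(x$candidate_peaks), x$n_stimuli))
  print(glance(x))
  invisible(x)
}

#' @rdname screen_receptor_sets
#' @param x A `receptor_screen`.
#' @param ... Unused.
#' @export
tidy.receptor_screen <- function(x, ...) x$results

#' @rdname screen_receptor_sets
#' @export
glance.receptor_screen <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$size) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(best_peaks = "peaks", best_mean_delta_s = "mean_delta_s")
}

#' Rank concordance between models
#'
#' Spearman rank correlation between the chromatic-distance columns of
#' a table in which each column holds one model's \eqn{\Delta S} values
#' over a common, paired stimulus set. Rank correlation is used because
#' the model outputs live on different, non-linearly related scales.
#'
#' @param delta_s_table Data frame of paired numeric \eqn{\Delta S}
#'   columns, one per model (non-numeric columns are ignored).
#' @return Tibble with one row per model pair: `model_a`, `model_b`,
#'   `rho`, `n`, `p_value` (two-sided, ties handled by average ranks).
#' @export
compare_models <- function(delta_s_table) {
  num <- delta_s_table[vapply(delta_s_table, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least two numeric delta-S columns", call. = FALSE)
  if (anyNA(num)) stop("delta-S columns contain missing values; lists must be paired", call. = FALSE)
  nms <- names(num)
  pairs <- utils::combn(nms, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- num[[pairs[1, k]]]
    b <- num[[pairs[2, k]]]
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
    tibble::tibble(model_a = pairs[1, k], model_b = pairs[2, k],
                   rho = unname(ct$estimate), n = length(a), p_value = ct$p.value)
  })
}
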