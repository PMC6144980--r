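#' Configure a colour vision model
#'
#' The four named models are fixed points of one generic recipe
#' (catch, von Kries adaptation, receptor transform, optional
#' sum-to-one outputs, projection through an equidistant basis):
#'
#' * `"CH"` — colour hexagon: hyperbolic transform \eqn{q/(q+1)},
#'   vector length 1, no noise. Loci are confined inside the unit
#'   circumradius because outputs are bounded in `[0, 1)`.
#' * `"EM"` — Endler--Mielke: ln transform, sum-to-one relative
#'   outputs, vector length 0.75, no noise. The maximum attainable
#'   distance from the background is 0.75 (a simplex corner).
#' * `"RNL_linear"` / `"RNL_log"` — receptor-noise-limited with
#'   identity / ln transform; per-receptor Weber noise is required and
#'   distances are measured in noise units (just-noticeable
#'   differences), independent of diagram geometry.
#' * `"generic"` — any combination of transform, output convention,
#'   scaling and noise, for user-defined models.
#'
#' @param kind Model kind (above).
#' @param transform Receptor transform (see [transform_output()]);
#'   defaults depend on `kind`, and the named models reject overrides
#'   that contradict their definition.
#' @param relative_outputs Use sum-to-one outputs (EM convention)?
#' @param scale_mode,scale_value Basis scaling (see
#'   [chromaticity_basis()]).
#' @param noise Per-receptor Weber fractions (RNL kinds and noisy
#'   generic models). May also be left `NULL` here and supplied on the
#'   receptor set.
#' @param custom_f Transform function when `transform = "custom"`.
#' @return A `model_config` object.
#' @examples
#' model_config("CH")
#' model_config("RNL_log", noise = c(0.13, 0.06, 0.12))
#' model_config("generic", transform = "hyperbolic",
#'              scale_mode = "vertex_distance", scale_value = 3)
#' @export
model_config <- function(kind = c("CH", "EM", "RNL_linear", "RNL_log", "generic"),
                         transform = NULL, relative_outputs = NULL,
                         scale_mode = NULL, scale_value = NULL,
                         noise = NULL, custom_f = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    CH         = list(transform = "hyperbolic", relative_outputs = FALSE,
                      scale_mode = "vector_length", scale_value = 1, use_noise = FALSE),
    EM         = list(transform = "ln", relative_outputs = TRUE,
                      scale_mode = "vector_length", scale_value = 0.75, use_noise = FALSE),
    RNL_linear = list(transform = "identity", relative_outputs = FALSE,
                      scale_mode = "vector_length", scale_value = 1, use_noise = TRUE),
    RNL_log    = list(transform = "ln", relative_outputs = FALSE,
                      scale_mode = "vector_length", scale_value = 1, use_noise = TRUE),
    generic    = list(transform = "identity", relative_outputs = FALSE,
                      scale_mode = "vector_length", scale_value = 1, use_noise = !is.null(noise))
  )
  fixed <- kind != "generic"
  pick <- function(user, def, what) {
    if (is.null(user)) return(def)
    if (fixed && !identical(user, def) && kind %in% c("CH", "EM") &&
        what %in% c("transform", "relative_outputs")) {
      stop(sprintf("%s model fixes %s = %s; use kind = 'generic' to change it",
                   kind, what, format(def)), call. = FALSE)
    }
    user
  }
  cfg <- list(
    kind = kind,
    transform = pick(transform, defaults$transform, "transform"),
    relative_outputs = pick(relative_outputs, defaults$relative_outputs, "relative_outputs"),
    scale_mode = scale_mode %||% defaults$scale_mode,
    scale_value = scale_value %||% defaults$scale_value,
    use_noise = defaults$use_noise,
    noise = noise,
    custom_f = custom_f
  )
  if (kind %in% c("CH", "EM") && !is.null(noise)) {
    stop(sprintf("%s model does not use receptor noise; drop `noise` or use an RNL/generic kind", kind),
         call. = FALSE)
  }
  if (identical(cfg$transform, "custom") && !is.function(cfg$custom_f)) {
    stop("transform = 'custom' requires `custom_f`", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: %s | transform %s%s | %s = %g%s>\n",
              x$kind,
              if (is.function(x$transform)) "<function>" else x$transform,
              if (x$relative_outputs) " | relative outputs" else "",
              x$scale_mode, x$scale_value,
              if (x$use_noise) sprintf(" | noise %s",
                                       if (is.null(x$noise)) "(from receptor set)"
                                       else paste(format(x$noise), collapse = ", "))
              else ""))
  invisible(x)
}

resolve_noise <- function(config, receptors, i) {
  noise <- config$noise %||% receptors$noise
  if (!config$use_noise) return(NULL)
  if (is.null(noise)) {
    stop(sprintf("%s model requires receptor noise: supply `noise` in model_config() or photoreceptor_set()",
                 config$kind), call. = FALSE)
  }
  if (length(noise) != i) stop(sprintf("noise has %d entries for %d receptors", length(noise), i), call. = FALSE)
  if (any(noise <= 0)) stop("receptor noise values must be > 0", call. = FALSE)
  as.numeric(noise)
}

#' Run a colour vision model over a set of stimuli
#'
#' The full pipeline for one configured model: quantum catches
#' \eqn{Q_i}, background adaptation \eqn{q_i = Q_i/Q_{B,i}}, receptor
#' transform \eqn{E_i}, optional sum-to-one outputs, colour loci
#' \eqn{x = Vp}, and the chromatic distance of every stimulus to the
#' background (Euclidean, or noise-weighted for RNL kinds).
#'
#' Spurious regimes are reported, not suppressed: rows whose relative
#' outputs were near-singular carry `near_singular = TRUE`, and rows
#' with any negative receptor output carry `negative_output = TRUE`.
#'
#' @param stimuli Wide reflectance tibble (one column per stimulus).
#' @param background Single-spectrum reflectance tibble (the adapting
#'   background).
#' @param illuminant Illuminant tibble (e.g. [builtin_illuminant()]).
#' @param receptors A [photoreceptor_set()].
#' @param config A [model_config()] (default `"CH"`).
#' @return A `vision_model` object; use [tidy()] for the per-stimulus
#'   table, [glance()] for a one-row summary, [autoplot()] for the
#'   chromaticity diagram.
#' @examples
#' recs <- synthetic_bee_receptors()
#' res <- run_model(
#'   logistic_reflectance(500, name = "s500"),
#'   flat_reflectance(0.07), builtin_illuminant("D65"), recs,
#'   model_config("CH")
#' )
#' tidy(res)
#' @export
run_model <- function(stimuli, background, illuminant, receptors,
                      config = model_config("CH")) {
  stopifnot(inherits(config, "model_config"), inherits(receptors, "photoreceptor_set"))
  validate_spectra(background, "background")
  if (ncol(background) != 2) stop("`background` must contain exactly one spectrum column", call. = FALSE)
  check_shared_grid(stimuli, illuminant, receptors)
  if (!same_grid(background, stimuli)) {
    stop("background is not on the stimulus grid; see harmonize_spectra()", call. = FALSE)
  }

  i <- length(receptors$receptors)
  noise <- resolve_noise(config, receptors, i)
  basis <- chromaticity_basis(i, config$scale_mode, config$scale_value)

  Q  <- quantum_catch(stimuli, illuminant, receptors)
  QB <- quantum_catch(background, illuminant, receptors)
  q  <- relative_catch(Q, QB)
  E  <- transform_output(q, config$transform, f = config$custom_f)

  rec <- receptors$receptors
  outputs <- E
  near <- rep(FALSE, nrow(E))
  if (config$relative_outputs) {
    outputs <- withCallingHandlers(
      em_relative(E),
      warning = function(w) invokeRestart("muffleWarning")
    )
    near <- outputs$near_singular
  }

  loci <- color_locus(outputs, basis)
  Emat <- as.matrix(E[rec])

  if (config$use_noise) {
    E_bg <- transform_fun(config$transform, config$custom_f)(rep(1, i))
    ds <- vapply(seq_len(nrow(Emat)), function(r) {
      rnl_delta_s(Emat[r, ], E_bg, noise)
    }, numeric(1))
  } else {
    ds <- delta_s(loci)
  }

  results <- tibble::tibble(stimulus = Q$stimulus)
  for (k in seq_along(rec)) results[[paste0("Q_", rec[k])]] <- Q[[rec[k]]]
  for (k in seq_along(rec)) results[[paste0("q_", rec[k])]] <- q[[rec[k]]]
  for (k in seq_along(rec)) results[[paste0("E_", rec[k])]] <- outputs[[rec[k]]]
  X <- locus_coords(loci)
  for (k in seq_len(ncol(X))) results[[colnames(X)[k]]] <- X[, k]
  results$delta_s <- ds
  results$near_singular <- near
  results$negative_output <- rowSums(as.matrix(outputs[rec]) < 0) > 0

  structure(list(results = results, config = config, basis = basis,
                 receptors = rec, noise = noise),
            class = "vision_model")
}

#' @export
print.vision_model <- function(x, ...) {
  cat(sprintf("<vision_model: %s, %d stimulus/stimuli, %d receptor(s)>\n",
              x$config$kind, nrow(x$results), length(x$receptors)))
  print(x$results, ...)
  invisible(x)
}

#' @rdname run_model
#' @param x A `vision_model`.
#' @param ... Unused.
#' @export
tidy.vision_model <- function(x, ...) x$results

#' @rdname run_model
#' @export
glance.vision_model <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    kind = x$config$kind,
    n_stimuli = nrow(r),
    n_receptors = length(x$receptors),
    max_delta_s = max(r$delta_s),
    which_max = r$stimulus[which.max(r$delta_s)],
    n_near_singular = sum(r$near_singular),
    n_negative_output = sum(r$negative_output)
  )
}

# ---- receptor-noise-limited distances -------------------------------------

#' Closed-form receptor-noise chromatic distance (2-4 receptors)
#'
#' The classical receptor-noise-limited \eqn{\Delta S} formulas for
#' di-, tri- and tetrachromats, in which output differences
#' \eqn{\Delta f_i = E_{a,i} - E_{b,i}} are weighted by the Weber
#' fractions \eqn{e_i}. For a dichromat
#' \deqn{\Delta S = |\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2},}
#' with the standard quadratic forms for three and four receptors.
#' These serve as the independent check on the general noise-space
#' route ([rnl_delta_s()]), which extends the model to any receptor
#' count.
#'
#' @param E_a,E_b Receptor output vectors of equal length 2, 3 or 4.
#' @param noise Positive Weber fractions, one per receptor.
#' @return Chromatic distance in noise units (JND).
#' @export
rnl_delta_s_closed <- function(E_a, E_b, noise) {
  i <- length(E_a)
  if (length(E_b) != i || length(noise) != i) stop("E_a, E_b and noise must have equal length", call. = FALSE)
  if (any(noise <= 0)) stop("receptor noise values must be > 0", call. = FALSE)
  if (!(i %in% 2:4)) stop("closed forms exist for 2-4 receptors; use rnl_delta_s() for larger sets", call. = FALSE)
  df <- E_a - E_b
  e <- noise
  if (i == 2) {
    abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
  } else if (i == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 + e[3]^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    sqrt(num / den)
  } else {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
           (e[1] * e[3])^2 * (df[4] - df[2])^2 +
           (e[1] * e[4])^2 * (df[3] - df[2])^2 +
           (e[2] * e[3])^2 * (df[4] - df[1])^2 +
           (e[2] * e[4])^2 * (df[3] - df[1])^2 +
           (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
           (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    sqrt(num / den)
  }
}

# Symmetric positive-definite inverse square root via eigendecomposition.
inv_sqrtm_spd <- function(M, tol = 1e-12) {
  eg <- eigen(M, symmetric = TRUE)
  if (any(eg$values <= tol * max(eg$values))) {
    stop("noise covariance in diagram coordinates is singular", call. = FALSE)
  }
  eg$vectors %*% diag(1 / sqrt(eg$values), nrow = length(eg$values)) %*% t(eg$vectors)
}

#' Noise-space transform of colour loci
#'
#' Rescales colour loci so that Euclidean distance equals the
#' receptor-noise chromatic distance:
#' \deqn{s = \left[(V R V^T)^{1/2}\right]^{-1} x,}
#' where \eqn{R = diag(e_i^2)} is the (diagonal) covariance of receptor
#' outputs and \eqn{V} the unit-column basis. The square root makes
#' lengths in the transformed space equal \eqn{\Delta S} itself rather
#' than its square, so RNL results can be drawn in a diagram where
#' distance between any two points is their discriminability.
#'
#' @param loci Locus tibble/matrix (coordinates `X1..Xn` from a
#'   unit-column basis).
#' @param basis The unit-column [chromaticity_basis()] used to produce
#'   `loci`.
#' @param noise Positive Weber fractions, one per receptor.
#' @return Tibble of transformed coordinates `s1..sn`.
#' @export
rnl_noise_space <- function(loci, basis, noise) {
  i <- attr(basis, "i")
  if (length(noise) != i) stop("noise length does not match basis receptor count", call. = FALSE)
  if (any(noise <= 0)) stop("receptor noise values must be > 0", call. = FALSE)
  if (abs(attr(basis, "column_length") - 1) > 1e-9) {
    stop("the noise-space transform is defined for a unit-column basis (vector_length 1)", call. = FALSE)
  }
  V <- unclass(basis)
  W <- inv_sqrtm_spd(V %*% diag(noise^2, nrow = i) %*% t(V))
  X <- locus_coords(loci)
  S <- X %*% t(W)
  colnames(S) <- paste0("s", seq_len(ncol(S)))
  out <- tibble::as_tibble(S)
  if (is.data.frame(loci) && "stimulus" %in% names(loci)) {
    out <- dplyr::bind_cols(loci["stimulus"], out)
  }
  out
}

#' General receptor-noise chromatic distance (any receptor count)
#'
#' Projects the output difference through the unit-column equidistant
#' basis and measures its length in noise space:
#' \eqn{\Delta S = |[(V R V^T)^{1/2}]^{-1} V \Delta f|}. Agrees with
#' [rnl_delta_s_closed()] for 2-4 receptors and extends the model to
#' pentachromats and beyond.
#'
#' @param E_a,E_b Receptor output vectors (length `i >= 2`).
#' @param noise Positive Weber fractions, one per receptor.
#' @param basis Optional precomputed unit-column basis (for repeated
#'   calls).
#' @return Chromatic distance in noise units (JND).
#' @export
rnl_delta_s <- function(E_a, E_b, noise, basis = NULL) {
  i <- length(E_a)
  if (i < 2) stop("at least two receptors are required", call. = FALSE)
  if (length(E_b) != i || length(noise) != i) stop("E_a, E_b and noise must have equal length", call. = FALSE)
  basis <- basis %||% chromaticity_basis(i, "vector_length", 1)
  x <- matrix(E_a - E_b, nrow = 1) %*% t(unclass(basis))
  s <- rnl_noise_space(x, basis, noise)
  sqrt(sum(as.matrix(s)^2))
}

#' Weber fractions from relative receptor abundances
#'
#' A convenience following the receptor-noise literature: when
#' per-channel noise has not been measured, it is commonly derived from
#' the relative abundance \eqn{\eta_i} of each receptor type in the
#' retina as \eqn{e_i = \nu / \sqrt{\eta_i}}, where \eqn{\nu} is the
#' noise of a single cell. Channels pooled over more cells are less
#' noisy. Measured Weber fractions should be preferred whenever
#' available.
#'
#' @param nu Single-cell noise (> 0).
#' @param abundance Relative abundances (> 0), one per receptor;
#'   normalised internally to sum to one.
#' @return Named numeric vector of Weber fractions.
#' @examples
#' noise_from_abundance(0.05, c(1, 2, 2, 4))
#' @export
noise_from_abundance <- function(nu, abundance) {
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0) stop("`nu` must be a single positive number", call. = FALSE)
  if (any(abundance <= 0)) stop("abundances must be > 0", call. = FALSE)
  eta <- abundance / sum(abundance)
  out <- nu / sqrt(eta)
  names(out) <- names(abundance)
  out
}

# ---- user-defined transform expressions (CLI surface) ---------------------

#' Parse a receptor-transform expression
#'
#' Turns a short arithmetic expression in the variable `q` (e.g.
#' `"q/(q+1)"` or `"log(q)"`) into a transform function, admitting only
#' arithmetic operators, parentheses, numbers and the functions `log`,
#' `exp` and `sqrt`. This is the safe surface through which
#' user-defined models can be specified on the command line.
#'
#' @param text Expression string in `q`.
#' @return A function of `q`.
#' @examples
#' f <- parse_transform("q/(q+1)")
#' f(1) # 0.5
#' @export
parse_transform <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop(sprintf("cannot parse transform expression: %s", text), call. = FALSE)
  })
  allowed <- c("+", "-", "*", "/", "^", "(", "log", "exp", "sqrt", "q")
  walk <- function(e) {
    if (is.numeric(e)) return(invisible(TRUE))
    if (is.name(e)) {
      if (!as.character(e) %in% allowed) {
        stop(sprintf("symbol '%s' is not allowed in transform expressions", as.character(e)), call. = FALSE)
      }
      return(invisible(TRUE))
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% allowed) {
        stop(sprintf("'%s' is not allowed in transform expressions", op), call. = FALSE)
      }
      for (k in seq_along(e)[-1]) walk(e[[k]])
      return(invisible(TRUE))
    }
    stop("unsupported construct in transform expression", call. = FALSE)
  }
  walk(expr)
  function(q) eval(expr, envir = list(q = q), enclos = baseenv())
}
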