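#' Bundle photoreceptor sensitivities (and noise) into a receptor set
#'
#' @param sensitivity Wide spectra tibble: `wavelength` plus one
#'   sensitivity column per receptor type, ordered short to long
#'   \eqn{\lambda_{max}}.
#' @param noise Optional numeric vector of Weber-fraction noise values
#'   \eqn{e_i}, one strictly positive entry per receptor (required by
#'   receptor-noise-limited models). Names, if present, must match the
#'   sensitivity columns.
#' @return An object of class `photoreceptor_set`.
#' @examples
#' recs <- photoreceptor_set(
#'   harmonize_spectra(gaussian_sensitivity(350), gaussian_sensitivity(450),
#'                     gaussian_sensitivity(550)),
#'   noise = c(0.13, 0.06, 0.12)
#' )
#' @export
photoreceptor_set <- function(sensitivity, noise = NULL) {
  validate_spectra(sensitivity, "sensitivity")
  rec_names <- names(sensitivity)[-1]
  if (length(rec_names) < 1) stop("at least one sensitivity column is required", call. = FALSE)
  if (!is.null(noise)) {
    if (length(noise) != length(rec_names)) {
      stop(sprintf("`noise` has %d entries for %d receptors", length(noise), length(rec_names)),
           call. = FALSE)
    }
    if (any(!is.finite(noise)) || any(noise <= 0)) {
      stop("all receptor noise values must be finite and > 0", call. = FALSE)
    }
    if (!is.null(names(noise)) && !identical(names(noise), rec_names)) {
      stop("names of `noise` do not match sensitivity columns", call. = FALSE)
    }
    names(noise) <- rec_names
  }
  structure(list(sensitivity = sensitivity, noise = noise, receptors = rec_names),
            class = "photoreceptor_set")
}

#' @export
print.photoreceptor_set <- function(x, ...) {
  cat(sprintf("<photoreceptor_set: %d receptor type(s) on %d wavelengths [%g-%g nm]>\n",
              length(x$receptors), nrow(x$sensitivity),
              min(x$sensitivity$wavelength), max(x$sensitivity$wavelength)))
  cat("  receptors:", paste(x$receptors, collapse = ", "), "\n")
  if (!is.null(x$noise)) {
    cat("  noise e_i:", paste(format(x$noise), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Synthetic honeybee-like trichromatic receptor set
#'
#' Gaussian stand-ins for the honeybee (*Apis mellifera*) ultraviolet,
#' blue and green photoreceptors: unit-peak curves at
#' \eqn{\lambda_{max}} 344, 436 and 556 nm (width 40 nm), with the
#' measured honeybee Weber-fraction noise values 0.13, 0.06 and 0.12.
#' The curves are synthetic (a Gaussian template, no beta-band), so
#' results differ quantitatively from measured honeybee sensitivities
#' while preserving the trichromatic ultraviolet/blue/green structure.
#'
#' @param grid Wavelengths (nm).
#' @param sd Curve width (nm).
#' @return A `photoreceptor_set` with noise attached.
#' @export
synthetic_bee_receptors <- function(grid = default_grid(), sd = 40) {
  sens <- harmonize_spectra(
    uv    = gaussian_sensitivity(344, sd = sd, grid = grid),
    blue  = gaussian_sensitivity(436, sd = sd, grid = grid),
    green = gaussian_sensitivity(556, sd = sd, grid = grid),
    grid = grid
  )
  photoreceptor_set(sens, noise = c(uv = 0.13, blue = 0.06, green = 0.12))
}

# Matrix core: stimuli values (wl x m), illuminant values (wl), sens (wl x i)
# -> Q matrix (m x i) of trapezoidal integrals of R * I * S_i.
catch_matrix <- function(wl, refl, illum, sens) {
  m <- ncol(refl)
  i <- ncol(sens)
  Q <- matrix(NA_real_, m, i, dimnames = list(colnames(refl), colnames(sens)))
  for (a in seq_len(m)) {
    for (b in seq_len(i)) {
      Q[a, b] <- pracma::trapz(wl, refl[, a] * illum * sens[, b])
    }
  }
  Q
}

check_shared_grid <- function(stimuli, illuminant, receptors) {
  if (!same_grid(stimuli, illuminant) || !same_grid(stimuli, receptors$sensitivity)) {
    stop("stimuli, illuminant and receptor sensitivities must share one wavelength grid; see harmonize_spectra()",
         call. = FALSE)
  }
}

#' Photoreceptor quantum catches
#'
#' For each stimulus column and receptor type \eqn{i}, the absolute
#' quantum catch
#' \deqn{Q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda}
#' integrated by the trapezoidal rule on the shared wavelength grid.
#'
#' @param stimuli Wide reflectance tibble (one or more stimulus columns).
#' @param illuminant Illuminant tibble on the same grid.
#' @param receptors A [photoreceptor_set()] on the same grid.
#' @return Tibble: one row per stimulus (`stimulus` column), one catch
#'   column per receptor.
#' @export
quantum_catch <- function(stimuli, illuminant, receptors) {
  validate_spectra(stimuli, "stimuli")
  validate_spectra(illuminant, "illuminant")
  stopifnot(inherits(receptors, "photoreceptor_set"))
  check_shared_grid(stimuli, illuminant, receptors)
  Q <- catch_matrix(as.numeric(stimuli[[1]]), spectra_values(stimuli),
                    illuminant[[2]], spectra_values(receptors$sensitivity))
  dplyr::bind_cols(tibble::tibble(stimulus = rownames(Q)),
                   tibble::as_tibble(Q))
}

#' Background-relative catches (von Kries adaptation)
#'
#' Divides each stimulus catch by the catch of the adapting background,
#' \eqn{q_i = Q_i / Q_{B,i}}, so that the background itself maps to
#' \eqn{q = 1} in every channel. This emulates receptor adaptation to
#' the ambient light and provides colour constancy.
#'
#' @param Q Catch tibble from [quantum_catch()] (a `stimulus` column
#'   plus receptor columns).
#' @param Q_background One-row catch tibble (or named numeric vector)
#'   for the background; all entries must be strictly positive.
#' @return Tibble of the same shape as `Q` with relative catches.
#' @export
relative_catch <- function(Q, Q_background) {
  qb <- if (is.data.frame(Q_background)) {
    as.numeric(spectra_row(Q_background))
  } else {
    as.numeric(Q_background)
  }
  rec <- setdiff(names(Q), "stimulus")
  if (length(qb) != length(rec)) stop("background catch length does not match receptor columns", call. = FALSE)
  if (any(!is.finite(qb)) || any(qb <= 0)) {
    stop("degenerate background: every background quantum catch must be > 0", call. = FALSE)
  }
  for (k in seq_along(rec)) Q[[rec[k]]] <- Q[[rec[k]]] / qb[k]
  Q
}

spectra_row <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) == 1)
  unlist(x[setdiff(names(x), "stimulus")])
}

transform_fun <- function(kind, f = NULL) {
  if (is.function(kind)) return(kind)
  switch(kind,
    identity   = function(q) q,
    ln         = function(q) log(q),
    hyperbolic = function(q) q / (q + 1),
    custom     = {
      if (!is.function(f)) stop("transform 'custom' requires a function `f`", call. = FALSE)
      f
    },
    stop(sprintf("unknown transform '%s'", kind), call. = FALSE)
  )
}

#' Photoreceptor input-to-output transform
#'
#' Maps background-relative catches \eqn{q} to receptor outputs
#' \eqn{E}: `"identity"` (\eqn{E = q}, the linear receptor-noise
#' convention, valid near the adaptation point), `"ln"`
#' (\eqn{E = \ln q}, the Fechner--Weber law), `"hyperbolic"`
#' (\eqn{E = q/(q+1)}, a saturating response bounded in `[0, 1)`), or a
#' user-supplied function of `q`.
#'
#' Negative outputs (from `ln` of \eqn{q < 1}) are legal and propagate
#' unchanged: downstream models must see them to reproduce their
#' documented failure modes.
#'
#' @param q Relative-catch tibble from [relative_catch()].
#' @param kind `"identity"`, `"ln"`, `"hyperbolic"`, `"custom"`, or a
#'   function.
#' @param f Transform function when `kind = "custom"`.
#' @return Tibble of receptor outputs, same shape as `q`.
#' @export
transform_output <- function(q, kind = c("identity", "ln", "hyperbolic", "custom"), f = NULL) {
  if (!is.function(kind)) kind <- match.arg(kind)
  fn <- transform_fun(kind, f)
  rec <- setdiff(names(q), "stimulus")
  is_ln <- identical(kind, "ln")
  for (nm in rec) {
    v <- q[[nm]]
    if (is_ln && any(v <= 0)) {
      stop(sprintf("ln transform undefined: receptor '%s' has relative catch <= 0 (zero photons caught)", nm),
           call. = FALSE)
    }
    out <- fn(v)
    if (any(!is.finite(out))) {
      stop(sprintf("transform returned non-finite output for receptor '%s'", nm), call. = FALSE)
    }
    q[[nm]] <- out
  }
  q
}

#' Relative (sum-to-one) receptor outputs
#'
#' Divides each row of outputs by its sum, \eqn{e_i = E_i / \sum_j E_j},
#' the convention of models that use only relative receptor outputs.
#' When the row sum approaches zero the quotients blow up; rows where
#' the sum has nearly cancelled — `|sum(E)| < tol * sum(|E|)` — are
#' flagged in a `near_singular` column (and a warning is raised) rather
#' than sanitised, because this spurious regime is a real, documented
#' failure mode of such models. The criterion is relative to the output
#' magnitudes, so it is invariant to the overall scale of `E`. A row
#' sum of exactly zero is an error.
#'
#' @param E Output tibble from [transform_output()].
#' @param tol Near-singular threshold on `|sum(E)| / sum(|E|)` (default
#'   `0.1`).
#' @return `E` rescaled row-wise, with a logical `near_singular` column.
#' @export
em_relative <- function(E, tol = 0.1) {
  rec <- setdiff(names(E), c("stimulus", "near_singular"))
  M <- as.matrix(E[rec])
  s <- rowSums(M)
  if (any(s == 0)) {
    stop(sprintf("relative outputs undefined: receptor outputs sum exactly to zero (row %d)",
                 which(s == 0)[1]), call. = FALSE)
  }
  near <- abs(s) < tol * rowSums(abs(M))
  if (any(near)) {
    warning(sprintf("%d stimulus/stimuli with nearly cancelling output sums: relative outputs are near-singular",
                    sum(near)), call. = FALSE)
  }
  M <- sweep(M, 1, s, "/")
  for (k in seq_along(rec)) E[[rec[k]]] <- M[, k]
  E$near_singular <- near
  E
}

`%||%` <- function(a, b) if (is.null(a)) b else a
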