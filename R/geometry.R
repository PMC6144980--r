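#' Pairwise angle between receptor vectors
#'
#' In an opponent colour space of dimension \eqn{n = i - 1}, the \eqn{i}
#' receptor vectors are placed equidistantly so that equal outputs sum
#' to the zero vector; their common pairwise angle is
#' \eqn{\theta = \arccos(-1/n)}: 180 degrees for a dichromat (n = 1),
#' 120 for a trichromat, 109.47 for a tetrachromat.
#'
#' @param n Colour-space dimensionality (receptor count minus one),
#'   `n >= 1`.
#' @return Angle in radians.
#' @export
pairwise_angle <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be a single value >= 1", call. = FALSE)
  acos(-1 / n)
}

#' Generic unit vector of the equidistant construction
#'
#' The seed vector of the recursive regular-simplex construction: its
#' last component is \eqn{\cos\theta} and each earlier component
#' \eqn{v_{n-k} = -\frac{1}{n-k}\sqrt{1 - \sum_{m>n-k} v_m^2}}. All
#' components are negative and the vector has unit length.
#'
#' @param n Dimensionality, `n >= 1`.
#' @return Numeric unit vector of length `n`.
#' @export
generic_unit_vector <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  v <- numeric(n)
  v[n] <- cos(pairwise_angle(n))
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      j <- n - k
      v[j] <- -(1 / j) * sqrt(1 - sum(v[(j + 1):n]^2))
    }
  }
  v
}

# i unit column vectors in R^(i-1), pairwise dot -1/(i-1), summing to zero.
# Recursive: embed the (i-1)-receptor solution scaled by sin(theta) with a
# shared last coordinate cos(theta), plus the north-pole vector e_n.
simplex_columns <- function(i) {
  if (i == 2) return(matrix(c(1, -1), nrow = 1))
  n <- i - 1
  ct <- -1 / n
  lower <- simplex_columns(i - 1)
  top <- rbind(lower * sqrt(1 - ct^2), rep(ct, i - 1))
  cbind(top, c(rep(0, n - 1), 1))
}

#' Build a chromaticity basis of equidistant receptor vectors
#'
#' Constructs the matrix \eqn{V} whose \eqn{i} columns are the receptor
#' vectors of an \eqn{(i-1)}-dimensional chromaticity diagram: equal
#' length, pairwise angle \eqn{\arccos(-1/n)}, and zero sum (so equal
#' receptor outputs land on the origin, where the adapting background
#' sits by construction). The orientation is one fixed, reproducible
#' choice among the infinitely many rotations, all of which give
#' identical distances.
#'
#' Two scaling conventions are supported. `"vector_length"` fixes the
#' length of each column (1 for the colour hexagon, 0.75 for the
#' Endler--Mielke space). `"vertex_distance"` fixes the distance between
#' adjacent diagram vertices (column tips) instead; for unit columns
#' that distance is \eqn{\sqrt{2i/(i-1)}}, so holding it constant while
#' changing `i` trades off against the centre-to-vertex length.
#'
#' @param i Number of receptor types, `i >= 2`.
#' @param scale_mode `"vector_length"` or `"vertex_distance"`.
#' @param scale_value Target length or vertex distance (> 0).
#' @return An `n x i` matrix of class `chromaticity_basis` with
#'   attributes `i`, `n`, `theta`, `scale_mode`, `scale_value`,
#'   `column_length`.
#' @examples
#' V <- chromaticity_basis(3)                       # unit hexagon basis
#' chromaticity_basis(4, "vertex_distance", sqrt(2)) # fixed-edge tetrachromat
#' @export
chromaticity_basis <- function(i, scale_mode = c("vector_length", "vertex_distance"),
                               scale_value = 1) {
  scale_mode <- match.arg(scale_mode)
  if (!is.numeric(i) || length(i) != 1 || i < 2 || i != round(i)) {
    stop("`i` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(scale_value) || length(scale_value) != 1 || scale_value <= 0) {
    stop("`scale_value` must be a single positive number", call. = FALSE)
  }
  n <- i - 1
  V <- simplex_columns(i)
  len <- if (scale_mode == "vector_length") {
    scale_value
  } else {
    scale_value / sqrt(2 * i / (i - 1))
  }
  V <- V * len
  dimnames(V) <- list(paste0("X", seq_len(n)), paste0("r", seq_len(i)))
  check_basis_invariants(V, len)
  structure(V, class = c("chromaticity_basis", "matrix", "array"),
            i = i, n = n, theta = pairwise_angle(n),
            scale_mode = scale_mode, scale_value = scale_value,
            column_length = len)
}

check_basis_invariants <- function(V, len, tol = 1e-10) {
  i <- ncol(V)
  n <- nrow(V)
  G <- crossprod(V)
  if (max(abs(diag(G) - len^2)) > tol * max(1, len^2)) {
    stop("basis invariant violated: unequal column lengths", call. = FALSE)
  }
  off <- G[upper.tri(G)]
  if (max(abs(off - (-len^2 / n))) > tol * max(1, len^2)) {
    stop("basis invariant violated: pairwise dot products differ from -L^2/n", call. = FALSE)
  }
  if (max(abs(rowSums(V))) > tol * max(1, len)) {
    stop("basis invariant violated: columns do not sum to zero", call. = FALSE)
  }
  invisible(V)
}

#' @export
print.chromaticity_basis <- function(x, ...) {
  cat(sprintf("<chromaticity_basis: i = %d receptors, n = %d dimensions, %s = %g (column length %.6g)>\n",
              attr(x, "i"), attr(x, "n"), attr(x, "scale_mode"),
              attr(x, "scale_value"), attr(x, "column_length")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Distance between adjacent vertices of a basis
#'
#' @param basis A [chromaticity_basis()].
#' @return Tip-to-tip (edge) distance between any two receptor vectors.
#' @export
vertex_distance <- function(basis) {
  attr(basis, "column_length") * sqrt(2 * attr(basis, "i") / (attr(basis, "i") - 1))
}

locus_matrix <- function(outputs, basis) {
  rec <- setdiff(colnames(outputs), c("stimulus", "near_singular"))
  P <- as.matrix(outputs[, rec, drop = FALSE])
  if (ncol(P) != attr(basis, "i")) {
    stop(sprintf("outputs have %d receptor columns but the basis expects %d",
                 ncol(P), attr(basis, "i")), call. = FALSE)
  }
  if (any(!is.finite(P))) stop("receptor outputs must be finite", call. = FALSE)
  P %*% t(unclass(basis))
}

#' Map receptor outputs to colour loci
#'
#' The colour locus of a stimulus is \eqn{x = V p}: the sum of the
#' receptor vectors weighted by the outputs \eqn{p}. Because the
#' columns of \eqn{V} sum to zero, adding a constant to every output
#' leaves the locus unchanged — only differences between receptor
#' outputs matter, and the background (equal outputs) sits at the
#' origin.
#'
#' @param outputs Tibble with one row per stimulus and one receptor
#'   output column per receptor (a `stimulus` id column and a
#'   `near_singular` flag are carried through if present).
#' @param basis A [chromaticity_basis()] with matching receptor count.
#' @return Tibble with coordinate columns `X1..Xn` (plus carried-through
#'   columns).
#' @export
color_locus <- function(outputs, basis) {
  X <- locus_matrix(outputs, basis)
  out <- tibble::as_tibble(X)
  keep <- intersect(c("stimulus", "near_singular"), colnames(outputs))
  if (length(keep)) out <- dplyr::bind_cols(outputs[keep], out)
  out
}

#' Euclidean chromatic distance between loci
#'
#' \eqn{\Delta S = \sqrt{\sum_k (X_{k,a} - X_{k,b})^2}}, row by row.
#' With `b = NULL` distances are taken to the origin, i.e. to the
#' adapting background.
#'
#' @param a Locus tibble (coordinate columns `X1..Xn`) or numeric
#'   matrix/vector.
#' @param b Second locus (same dimension), recycled row-wise if a single
#'   locus; `NULL` for the origin.
#' @return Numeric vector of distances, one per row of `a`.
#' @export
delta_s <- function(a, b = NULL) {
  A <- locus_coords(a)
  if (is.null(b)) {
    B <- matrix(0, nrow(A), ncol(A))
  } else {
    B <- locus_coords(b)
    if (ncol(B) != ncol(A)) stop("loci have different dimensions", call. = FALSE)
    if (nrow(B) == 1 && nrow(A) > 1) B <- B[rep(1, nrow(A)), , drop = FALSE]
    if (nrow(B) != nrow(A)) stop("loci have different numbers of rows", call. = FALSE)
  }
  sqrt(rowSums((A - B)^2))
}

locus_coords <- function(x) {
  if (is.data.frame(x)) {
    cols <- grep("^X[0-9]+$", names(x), value = TRUE)
    if (!length(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
    as.matrix(x[cols])
  } else if (is.matrix(x)) {
    x
  } else {
    matrix(as.numeric(x), nrow = 1)
  }
}
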