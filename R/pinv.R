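#' Moore-Penrose pseudoinverse
#'
#' Computes the Moore-Penrose pseudoinverse (MPP) of a real matrix from its
#' singular value decomposition, `A+ = V S+ U'`. Singular values below
#' `rtol * max(s)` are treated as exactly zero, which fixes the numerical rank
#' and guarantees that the derived projection operators are idempotent and
#' symmetric even for rank-deficient input.
#'
#' The MPP is the unique matrix satisfying the four Penrose conditions
#' `A A+ A = A`, `A+ A A+ = A+`, `(A A+)' = A A+`, `(A+ A)' = A+ A`, and it
#' yields the minimum-norm least-squares solution `x = A+ b` of `A x = b`.
#'
#' @param A real matrix (or vector, treated as a one-column matrix).
#' @param rtol relative singular-value cutoff (default `1e-10`); values below
#'   `rtol * sigma_max` are zeroed.
#' @return the `n x m` pseudoinverse of the `m x n` input.
#' @examples
#' pinv(matrix(c(1, 1), 1, 2))  # t(c(0.5, 0.5))
#' @export
pinv <- function(A, rtol = 1e-10) {
  A <- as_real_matrix(A, "A")
  if (rtol <= 0) stop("rtol must be > 0", call. = FALSE)
  sv <- svd(A)
  if (length(sv$d) == 0L || max(sv$d) == 0) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  keep <- sv$d > rtol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  d_inv <- 1 / sv$d[keep]
  sv$v[, keep, drop = FALSE] %*% (d_inv * t(sv$u[, keep, drop = FALSE]))
}

#' Projection operators of a linear map
#'
#' Builds, from a single singular value decomposition of `A` (m x n), the four
#' orthogonal projection operators associated with its fundamental subspaces:
#' the range projector `T = A A+` (onto the column space), the row projector
#' `F = A+ A` (onto the row space), and their complements `N_T = I - T`
#' (onto the left null space, `N_T A = 0`) and `N_F = I - F` (onto the right
#' null space, `A N_F = 0`). All four are symmetric and idempotent; their
#' traces equal the dimensions of the subspaces they project onto.
#'
#' @inheritParams pinv
#' @return an object of class `projector_bundle`: a list with elements
#'   `source_matrix`, `pinv`, `range_proj` (T), `row_proj` (F),
#'   `left_null_proj` (N_T), `right_null_proj` (N_F), `rank`, `rtol`.
#' @examples
#' pb <- projectors(matrix(c(1, 0), 1, 2))
#' pb$row_proj        # diag(c(1, 0))
#' pb$right_null_proj # diag(c(0, 1))
#' @export
projectors <- function(A, rtol = 1e-10) {
  A <- as_real_matrix(A, "A")
  if (rtol <= 0) stop("rtol must be > 0", call. = FALSE)
  m <- nrow(A); n <- ncol(A)
  sv <- svd(A)
  keep <- if (length(sv$d) && max(sv$d) > 0) sv$d > rtol * max(sv$d) else rep(FALSE, length(sv$d))
  r <- sum(keep)
  if (r > 0) {
    Ur <- sv$u[, keep, drop = FALSE]
    Vr <- sv$v[, keep, drop = FALSE]
    Ap <- Vr %*% ((1 / sv$d[keep]) * t(Ur))
    Tp <- Ur %*% t(Ur)     # projector onto C(A)
    Fp <- Vr %*% t(Vr)     # projector onto R(A)
    # symmetrize to kill roundoff asymmetry from the matrix products
    Tp <- (Tp + t(Tp)) / 2
    Fp <- (Fp + t(Fp)) / 2
  } else {
    Ap <- matrix(0, n, m)
    Tp <- matrix(0, m, m)
    Fp <- matrix(0, n, n)
  }
  structure(
    list(
      source_matrix = A,
      pinv = Ap,
      range_proj = Tp,
      row_proj = Fp,
      left_null_proj = diag(m) - Tp,
      right_null_proj = diag(n) - Fp,
      rank = r,
      rtol = rtol
    ),
    class = "projector_bundle"
  )
}

#' @export
print.projector_bundle <- function(x, ...) {
  cat(sprintf(
    "<projector_bundle> %d x %d matrix, rank %d (rtol %.1e)\n",
    nrow(x$source_matrix), ncol(x$source_matrix), x$rank, x$rtol
  ))
  cat(sprintf(
    "  range dim %d | row dim %d | left null dim %d | right null dim %d\n",
    x$rank, x$rank, nrow(x$source_matrix) - x$rank, ncol(x$source_matrix) - x$rank
  ))
  invisible(x)
}

#' Particular / null-space decomposition of a linear system solution
#'
#' For a consistent underdetermined system `A x = b`, returns the general
#' solution split `x = x_par + x_perp`: the minimum-norm particular solution
#' `x_par = A+ b` (in the row space of `A`) and the null-space component
#' `x_perp = N_F x0` obtained by projecting an arbitrary vector `x0` onto the
#' null space of `A`. The two components are orthogonal, and
#' `A (x_par + x_perp) = b`.
#'
#' Consistency of `b` is checked via the range projector: the system is
#' declared inconsistent when `||(I - T) b|| > 1e-8 * (1 + ||b||)`, in which
#' case the error message reports the residual norm.
#'
#' @inheritParams pinv
#' @param b right-hand-side vector (length `m`).
#' @param x0 arbitrary vector (length `n`) supplying the null-space component.
#' @return list with elements `x_par` and `x_perp` (numeric vectors of length
#'   `n`).
#' @export
decompose_solution <- function(A, b, x0, rtol = 1e-10) {
  pb <- projectors(A, rtol)
  b <- as_real_vector(b, "b", nrow(pb$source_matrix))
  x0 <- as_real_vector(x0, "x0", ncol(pb$source_matrix))
  resid <- sqrt(sum((b - pb$range_proj %*% b)^2))
  if (resid > 1e-8 * (1 + sqrt(sum(b^2)))) {
    stop(sprintf(
      "inconsistent system: ||(I - T) b|| = %.3e exceeds tolerance", resid
    ), call. = FALSE)
  }
  list(
    x_par = drop(pb$pinv %*% b),
    x_perp = drop(pb$right_null_proj %*% x0)
  )
}

# ---- input validation helpers -------------------------------------------

as_real_matrix <- function(A, name) {
  if (is.vector(A) && is.numeric(A)) A <- matrix(A, ncol = 1)
  if (!is.matrix(A) || !is.numeric(A)) {
    stop(sprintf("%s must be a numeric matrix", name), call. = FALSE)
  }
  storage.mode(A) <- "double"
  if (!all(is.finite(A))) {
    stop(sprintf("%s contains non-finite entries", name), call. = FALSE)
  }
  A
}

as_real_vector <- function(x, name, len = NULL) {
  x <- drop(x)
  if (!is.numeric(x) || !is.null(dim(x))) {
    stop(sprintf("%s must be a numeric vector", name), call. = FALSE)
  }
  x <- as.double(x)
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite entries", name), call. = FALSE)
  }
  if (!is.null(len) && length(x) != len) {
    stop(sprintf("%s must have length %d (got %d)", name, len, length(x)),
         call. = FALSE)
  }
  x
}
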