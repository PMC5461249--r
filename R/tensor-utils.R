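# Basic multilinear algebra on base-R arrays.
#
# Unfoldings follow the standard convention: the mode-n unfolding puts mode n
# on the rows and orders the columns by the remaining modes in increasing
# mode order (column-major within that ordering, matching R's array layout
# after aperm()).

#' Mode-n unfolding of an array
#'
#' @param x N-way numeric array.
#' @param mode Mode to put on the rows (1-based).
#' @return A matrix with `dim(x)[mode]` rows.
#' @export
unfold <- function(x, mode) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  stopifnot(mode >= 1, mode <= length(d))
  perm <- c(mode, seq_along(d)[-mode])
  m <- aperm(x, perm)
  dim(m) <- c(d[mode], prod(d[-mode]))
  m
}

#' Fold a mode-n unfolding back into an array
#'
#' @param m Matrix as produced by [unfold()].
#' @param mode Mode that is on the rows of `m`.
#' @param dims Target array dimensions.
#' @return An array with `dim == dims`.
#' @export
fold <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Mode-n product of an array with a matrix
#'
#' Contracts mode `mode` of `x` with the columns of `mat`, so the result has
#' `nrow(mat)` along that mode.
#'
#' @param x N-way array.
#' @param mat Matrix with `ncol(mat) == dim(x)[mode]`.
#' @param mode Mode to contract.
#' @export
ttm <- function(x, mat, mode) {
  d <- dim(x)
  stopifnot(ncol(mat) == d[mode])
  newd <- d
  newd[mode] <- nrow(mat)
  fold(mat %*% unfold(x, mode), mode, newd)
}

#' Mode product along several modes
#'
#' @param x N-way array.
#' @param mats List of matrices.
#' @param modes Integer vector, same length as `mats`.
#' @export
ttml <- function(x, mats, modes) {
  for (i in seq_along(mats)) x <- ttm(x, mats[[i]], modes[i])
  x
}

#' Frobenius norm of an array
#' @param x Numeric array.
#' @export
tnorm <- function(x) sqrt(sum(x^2))

# Fix the sign of each column of a (semi-)orthonormal matrix so that its
# largest-magnitude entry (first such entry on ties) is positive. Removes
# the sign indeterminacy of singular vectors.
fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

# Leading eigenvectors of the symmetric PSD matrix crossprod-style gram of a
# mode unfolding; deterministic column signs.
top_eigvecs <- function(g, k) {
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  fix_signs(e$vectors[, seq_len(k), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not disturb the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
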