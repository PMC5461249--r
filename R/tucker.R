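# Orthogonal Tucker decomposition via the higher-order SVD (HOSVD), plus a
# sequential (streaming) update mode used for near-real-time operation.
#
# The decomposition is non-iterative: each factor is taken from the leading
# singular vectors of the corresponding mode unfolding, and the core is the
# projection of the tensor onto those bases. No alternating-least-squares
# refinement is performed.

#' Orthogonal Tucker decomposition (higher-order SVD)
#'
#' Factors each mode of `x` by the leading left singular vectors of its
#' unfolding and projects `x` onto those bases to obtain the core. Factor
#' column signs are fixed so the largest-magnitude entry of each column is
#' positive; ties in singular values keep the first column by order, so the
#' result is deterministic.
#'
#' @param x N-way numeric array.
#' @param ranks Integer vector of per-mode ranks (same length as `dim(x)`).
#' @return An object of class `tucker_model`: list with `core`, `factors`
#'   (list of orthonormal matrices), `ranks`, `fit` (relative reconstruction
#'   error), `mode_sv` (per-mode singular values of the unfoldings), and
#'   `total_energy` (squared Frobenius norm of `x`).
#' @export
tucker_decompose <- function(x, ranks) {
  d <- dim(x)
  if (is.null(d)) stop("x must be an array with at least 2 modes")
  if (length(ranks) != length(d)) stop("ranks must have one entry per mode")
  if (any(ranks < 1) || any(ranks > d)) {
    stop(sprintf("invalid ranks: each rank must lie in [1, mode dimension]; got (%s) for dims (%s)",
                 paste(ranks, collapse = ","), paste(d, collapse = ",")))
  }
  factors <- vector("list", length(d))
  mode_sv <- vector("list", length(d))
  for (n in seq_along(d)) {
    un <- unfold(x, n)
    g <- tcrossprod(un)
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
    mode_sv[[n]] <- sqrt(pmax(e$values, 0))
    factors[[n]] <- fix_signs(e$vectors[, seq_len(ranks[n]), drop = FALSE])
  }
  core <- x
  for (n in seq_along(d)) core <- ttm(core, t(factors[[n]]), n)
  total <- sum(x^2)
  # direct residual: the energy identity total - ||core||^2 suffers
  # catastrophic cancellation near full rank
  rec <- core
  for (n in seq_along(d)) rec <- ttm(rec, factors[[n]], n)
  out <- list(core = core, factors = factors, ranks = as.integer(ranks),
              fit = if (total > 0) sqrt(sum((x - rec)^2) / total) else 0,
              mode_sv = mode_sv, total_energy = total)
  class(out) <- "tucker_model"
  out
}

#' Reconstruct the tensor approximated by a Tucker model
#'
#' @param model A `tucker_model`.
#' @return An array with the original tensor's dimensions.
#' @export
tucker_reconstruct <- function(model) {
  x <- model$core
  for (n in seq_along(model$factors)) x <- ttm(x, model$factors[[n]], n)
  x
}

#' @export
print.tucker_model <- function(x, ...) {
  cat("Tucker model: ranks (", paste(x$ranks, collapse = ", "),
      "), relative error ", signif(x$fit, 4), "\n", sep = "")
  invisible(x)
}

#' Start a sequential Tucker model for streaming mode-1 slices
#'
#' Creates an empty model whose mode-1 dimension grows as slices arrive via
#' [tucker_update()]. Modes 2..N are factored from running Gram-matrix
#' accumulators; mode 1 is tracked by an incremental SVD of the mode-1
#' unfolding, truncated at `ranks[1]` (use `ranks[1] >= ` expected number of
#' slices for an untruncated stream).
#'
#' @param slice_dims Dimensions of one incoming slice (modes 2..N).
#' @param ranks Per-mode ranks `(R1, R2, ..., RN)`; `R1` caps the mode-1 rank.
#' @return A `tucker_stream` object; pass it to [tucker_update()].
#' @export
tucker_stream <- function(slice_dims, ranks) {
  stopifnot(length(ranks) == length(slice_dims) + 1)
  if (any(ranks[-1] < 1) || any(ranks[-1] > slice_dims)) {
    stop("invalid ranks for slice dimensions")
  }
  out <- list(slice_dims = as.integer(slice_dims), ranks = as.integer(ranks),
              n_slices = 0L, total_energy = 0,
              grams = lapply(slice_dims, function(dk) matrix(0, dk, dk)),
              # incremental SVD state of the mode-1 unfolding: X1 ~ U S V'
              U = NULL, S = numeric(0),
              V = matrix(0, prod(slice_dims), 0),
              discarded = 0)
  class(out) <- "tucker_stream"
  out
}

#' Append a mode-1 slice to a sequential Tucker model
#'
#' Updates the model to approximate the tensor with `new_slice` appended
#' along mode 1, without recomputing the batch decomposition: modes 2..N are
#' re-factored from updated Gram accumulators and mode 1 by a rank-truncated
#' incremental SVD.
#'
#' @param model A `tucker_stream` (or the result of a previous update).
#' @param new_slice Array (or vector for 2-way streams) conforming to modes
#'   2..N of the stream.
#' @return The updated `tucker_stream`. Use [tucker_stream_model()] to
#'   extract a `tucker_model` view (core, factors, fit).
#' @export
tucker_update <- function(model, new_slice) {
  stopifnot(inherits(model, "tucker_stream"))
  sd <- model$slice_dims
  if (length(sd) == 1L) new_slice <- array(new_slice, dim = sd)
  if (!identical(as.integer(dim(new_slice) %||% length(new_slice)), sd)) {
    stop("new_slice dimensions do not conform to the stream's modes 2..N")
  }
  y <- as.numeric(new_slice)
  model$n_slices <- model$n_slices + 1L
  model$total_energy <- model$total_energy + sum(y^2)
  # Gram accumulators for modes 2..N
  for (k in seq_along(sd)) {
    uk <- if (length(sd) == 1L) matrix(y, nrow = sd) else unfold(array(y, sd), k)
    model$grams[[k]] <- model$grams[[k]] + tcrossprod(uk)
  }
  # incremental SVD of the growing mode-1 unfolding (rows = slices)
  r1max <- model$ranks[1]
  p <- drop(crossprod(model$V, y))
  e <- y - model$V %*% p
  rho <- sqrt(sum(e^2))
  tol <- 1e-12 * max(sqrt(model$total_energy), 1)
  r <- length(model$S)
  if (rho > tol) {
    K <- rbind(cbind(diag(model$S, r, r), matrix(0, r, 1)),
               c(p, rho))
    Vext <- cbind(model$V, e / rho)
  } else {
    K <- rbind(cbind(diag(model$S, r, r), matrix(0, r, 1)),
               c(p, 0))
    Vext <- cbind(model$V, 0 * y)
  }
  Uold <- model$U
  if (is.null(Uold)) Uold <- matrix(0, 0, 0)
  Uext <- rbind(cbind(Uold, matrix(0, nrow(Uold), 1)),
                c(rep(0, ncol(Uold)), 1))
  sv <- svd(K)
  keep <- seq_len(min(r1max, length(sv$d), model$n_slices))
  model$discarded <- model$discarded + sum(sv$d[-keep]^2)
  model$U <- Uext %*% sv$u[, keep, drop = FALSE]
  model$S <- sv$d[keep]
  model$V <- Vext %*% sv$v[, keep, drop = FALSE]
  model
}

#' Materialize a `tucker_model` view of a sequential stream
#'
#' @param model A `tucker_stream` with at least one slice.
#' @return A `tucker_model` (core, factors, ranks, fit) for the tensor of all
#'   appended slices.
#' @export
tucker_stream_model <- function(model) {
  stopifnot(inherits(model, "tucker_stream"), model$n_slices > 0)
  sd <- model$slice_dims
  r1 <- min(model$ranks[1], model$n_slices)
  factors <- vector("list", length(sd) + 1)
  factors[[1]] <- fix_signs(model$U[, seq_len(r1), drop = FALSE])
  # sign flips must be mirrored in S V' to keep U S V' unchanged
  flip <- sign(colSums(factors[[1]] * model$U[, seq_len(r1), drop = FALSE]))
  for (k in seq_along(sd)) {
    factors[[k + 1]] <- top_eigvecs(model$grams[[k]], min(model$ranks[k + 1], sd[k]))
  }
  # core_(1) = U' X1 (kron of factors) ~ diag(S) V' projected per column block
  proj <- diag(flip * model$S, r1, r1) %*% t(model$V[, seq_len(r1), drop = FALSE])
  # fold each row of proj as a slice tensor and project onto modes 2..N
  rk <- vapply(factors[-1], ncol, 1L)
  core1 <- matrix(0, r1, prod(rk))
  for (i in seq_len(r1)) {
    sl <- array(proj[i, ], dim = sd)
    for (k in seq_along(sd)) sl <- ttm(sl, t(factors[[k + 1]]), k)
    core1[i, ] <- as.numeric(sl)
  }
  core <- fold(core1, 1, c(r1, rk))
  total <- model$total_energy
  err2 <- max(total - sum(core^2), 0)
  out <- list(core = core, factors = factors, ranks = c(r1, rk),
              fit = if (total > 0) sqrt(err2 / total) else 0,
              mode_sv = NULL, total_energy = total)
  class(out) <- "tucker_model"
  out
}
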