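#' Alternating least-squares non-negative matrix factorization
#'
#' Approximates a non-negative genes-by-voxels matrix `A` as the product
#' `W %*% H` of a non-negative m-by-s basis matrix (signature expression
#' profiles) and a non-negative s-by-n weight matrix, by alternating least
#' squares with negative clamping. Each iteration performs exactly four
#' steps: solve the normal equations `(W'W) H = W'A` for `H`; set negative
#' elements of `H` to 0; solve `(HH') W' = H A'` for `W`; set negative
#' elements of `W` to 0. Iteration stops after `max_iter` rounds (default
#' 1000), or earlier if `tol > 0` and the relative change in reconstruction
#' error between successive iterations falls below `tol`.
#'
#' ALS-NMF is non-convex: the factorization is run from `restarts`
#' independent uniform-random initializations (seeded deterministically
#' from `seed`) and the run with the lowest relative reconstruction error
#' is returned. After clamping, the normal-equation systems can become
#' singular; they are then solved in the minimum-norm least-squares sense
#' via the Moore-Penrose pseudoinverse. A factor column/row that collapses
#' to all zeros is re-seeded once with small positive noise; a second
#' collapse marks that restart degenerate and it is excluded (an error is
#' raised only if every restart degenerates).
#'
#' @param A Non-negative numeric matrix (m x n).
#' @param s Subspace size (rank), `1 <= s <= min(m, n)`. The number of
#'   genomic territories sought in a parcellation.
#' @param max_iter Maximum ALS iterations per restart.
#' @param tol Early-stop threshold on the relative change of the
#'   reconstruction error; 0 (default) disables early stopping so exactly
#'   `max_iter` iterations run.
#' @param seed Integer master seed; identical `(A, s, seed, restarts)`
#'   give bit-identical results.
#' @param restarts Number of independent random initializations.
#' @param check If `TRUE`, assert non-negativity of both factors after
#'   every iteration (used by the test suite; small overhead).
#' @return An object of class `nmf_fit`: list with `W`, `H`, `s`,
#'   `iterations_run`, `relative_error`, `first_iter_error`, `seed`,
#'   `restarts_used`, `restart_errors`.
#' @examples
#' A <- matrix(c(3, 1, 6, 2), 2, 2)  # rank 1
#' fit <- als_nmf(A, s = 1, max_iter = 50, restarts = 2, seed = 1)
#' fit$relative_error
#' @export
als_nmf <- function(A, s, max_iter = 1000L, tol = 0, seed = 1L,
                    restarts = 10L, check = FALSE) {
  if (!is.matrix(A) || !is.numeric(A)) stop("`A` must be a numeric matrix", call. = FALSE)
  if (any(A < 0)) stop("`A` must be non-negative", call. = FALSE)
  m <- nrow(A); n <- ncol(A)
  if (s < 1L || s > min(m, n)) {
    stop(sprintf("subspace size s = %d out of range [1, %d]", s, min(m, n)), call. = FALSE)
  }
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  norm_a <- sqrt(sum(A^2))
  if (norm_a == 0) stop("`A` is all-zero; nothing to factorize", call. = FALSE)

  restart_seeds <- withr::with_seed(seed, sample.int(2147483646L, restarts))
  runs <- lapply(restart_seeds, function(rs) {
    withr::with_seed(rs, als_nmf_single(A, s, max_iter, tol, norm_a, check))
  })
  errs <- vapply(runs, function(x) x$relative_error, 0)
  if (all(!is.finite(errs))) {
    stop("all restarts degenerated (rank collapse in W or H)", call. = FALSE)
  }
  best <- runs[[which.min(errs)]]
  rownames(best$W) <- rownames(A)
  colnames(best$W) <- rownames(best$H) <- sprintf("W%d", seq_len(s))
  colnames(best$H) <- colnames(A)
  structure(list(
    W = best$W, H = best$H, s = as.integer(s),
    iterations_run = best$iterations_run,
    relative_error = best$relative_error,
    first_iter_error = best$first_iter_error,
    seed = as.integer(seed),
    restarts_used = as.integer(restarts),
    restart_errors = errs
  ), class = "nmf_fit")
}

# one ALS run from a fresh random initialization; RNG already seeded
als_nmf_single <- function(A, s, max_iter, tol, norm_a, check) {
  m <- nrow(A); n <- ncol(A)
  W <- matrix(stats::runif(m * s), m, s) * mean(A)
  H <- NULL
  reseeded_w <- FALSE
  reseeded_h <- FALSE
  err <- Inf
  first_err <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- clamped_solve(crossprod(W), crossprod(W, A))
    bad <- rowSums(H) == 0
    if (any(bad)) {
      if (reseeded_h) return(list(relative_error = Inf))
      H[bad, ] <- stats::runif(sum(bad) * n) * 1e-4 * mean(A)
      reseeded_h <- TRUE
    }
    W <- t(clamped_solve(tcrossprod(H), tcrossprod(H, A)))
    bad <- colSums(W) == 0
    if (any(bad)) {
      if (reseeded_w) return(list(relative_error = Inf))
      W[, bad] <- stats::runif(sum(bad) * m) * 1e-4 * mean(A)
      reseeded_w <- TRUE
    }
    if (check) {
      stopifnot(all(W >= 0), all(H >= 0))
    }
    prev <- err
    err <- sqrt(sum((A - W %*% H)^2)) / norm_a
    if (it == 1L) first_err <- err
    if (tol > 0 && it > 1L && is.finite(prev) &&
        abs(prev - err) <= tol * max(prev, .Machine$double.eps)) {
      break
    }
  }
  list(W = W, H = H, iterations_run = it, relative_error = err,
       first_iter_error = first_err)
}

# solve G X = B for X in the least-squares sense, then clamp negatives;
# falls back to the pseudoinverse when G is singular after clamping
clamped_solve <- function(G, B) {
  X <- tryCatch(solve(G, B), error = function(e) MASS::ginv(G) %*% B)
  X[X < 0] <- 0
  X
}

#' Relative reconstruction error of a factorization
#'
#' The Frobenius norm of `A - W %*% H` divided by the Frobenius norm of
#' `A`: 0 iff the factorization is exact, 1 for the trivial zero
#' factorization.
#'
#' @param A Data matrix (m x n).
#' @param W Basis matrix (m x s).
#' @param H Weight matrix (s x n).
#' @return A non-negative scalar.
#' @export
reconstruction_error <- function(A, W, H) {
  if (nrow(W) != nrow(A) || ncol(H) != ncol(A) || ncol(W) != nrow(H)) {
    stop("shape mismatch between A, W and H", call. = FALSE)
  }
  norm_a <- sqrt(sum(A^2))
  if (norm_a == 0) stop("`A` is all-zero; relative error undefined", call. = FALSE)
  sqrt(sum((A - W %*% H)^2)) / norm_a
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> s = %d, %d x %d basis, %d iterations, relative error %.4g (best of %d restarts)\n",
    x$s, nrow(x$W), ncol(x$H), x$iterations_run, x$relative_error, x$restarts_used
  ))
  invisible(x)
}
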