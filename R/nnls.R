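# Linear-algebra helpers shared across the solvers.

# Moore-Penrose pseudoinverse via SVD (used for rank-deficient systems).
pinv <- function(M, tol = NULL) {
  M <- as.matrix(M)
  s <- svd(M)
  if (length(s$d) == 0L) return(t(M))
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(s$d)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Unconstrained least squares min ||A X - B||_F with the least-norm
# convention for rank-deficient A.
ls_solve <- function(A, B) {
  pinv(A) %*% as.matrix(B)
}

# Solve the normal equations restricted to per-column passive sets.
# AtA: n x n, AtB: n x p, P: n x p logical (TRUE = free/passive variable).
# Columns sharing a passive-set pattern are solved together.
cssls <- function(AtA, AtB, P = NULL) {
  n <- nrow(AtB); p <- ncol(AtB)
  X <- matrix(0, n, p)
  if (is.null(P)) {
    X[] <- solve_sym(AtA, AtB)
    return(X)
  }
  codes <- apply(P, 2, function(z) paste(which(z), collapse = ","))
  for (code in unique(codes)) {
    cols <- which(codes == code)
    idx <- P[, cols[1]]
    if (!any(idx)) next
    X[idx, cols] <- solve_sym(AtA[idx, idx, drop = FALSE],
                              AtB[idx, cols, drop = FALSE])
  }
  X
}

solve_sym <- function(G, b) {
  tryCatch(solve(G, b), error = function(e) pinv(G) %*% b)
}

#' Non-negative least squares with multiple right-hand sides
#'
#' Solves `min ||A X - B||_F` subject to `X >= 0`, column by column, with a
#' combinatorial active-set strategy: all columns share the cross-products
#' `A'A` and `A'B`, the unconstrained solution seeds the passive sets, and
#' columns with identical passive sets are solved as one linear system.
#' Optimality is certified through the dual variables (gradient nonpositive
#' on the active set, zero on the passive set). Rank-deficient `A` is
#' handled by the least-norm convention, not as an error.
#'
#' @param A numeric matrix (m x n).
#' @param B numeric matrix or vector (m x p).
#' @param tol relative tolerance for the dual-optimality test; defaults to
#'   a multiple of machine epsilon scaled by `A'A`.
#' @return The n x p solution matrix with all entries `>= 0`.
#' @examples
#' A <- diag(3)
#' nonnegative_lsq(A, c(1, -2, 3))  # clips the negative coordinate
#' @export
nonnegative_lsq <- function(A, B, tol = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    stop("A and B are not conformable: ", nrow(A), " vs ", nrow(B), " rows")
  }
  n <- ncol(A); p <- ncol(B)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  if (is.null(tol)) tol <- 1e-12
  scale <- max(abs(AtA), 1e-300)
  zero_tol <- 100 * n * .Machine$double.eps * scale
  dual_scale <- pmax(apply(abs(AtB), 2, max), scale)

  # Warm start: passive sets seeded by the sign pattern of the
  # unconstrained solution.
  Y <- cssls(AtA, AtB)
  P <- Y > 0
  X <- matrix(0, n, p)
  feasible <- colSums(P & Y < 0) == 0L
  X[, feasible] <- pmax(Y[, feasible, drop = FALSE], 0)

  active_cols <- seq_len(p)   # all columns still need the dual check
  max_outer <- 50L * (n + 2L)
  outer <- 0L
  while (length(active_cols) > 0L && outer < max_outer) {
    outer <- outer + 1L
    Y <- cssls(AtA, AtB[, active_cols, drop = FALSE],
               P[, active_cols, drop = FALSE])
    Y[!P[, active_cols, drop = FALSE]] <- 0
    # feasibility: shrink passive sets where the restricted solution is
    # negative (each shrink removes at least one variable, so this phase
    # terminates)
    keep <- logical(length(active_cols))
    for (jj in seq_along(active_cols)) {
      col <- active_cols[jj]
      if (any(Y[, jj] < -zero_tol)) {
        P[, col] <- P[, col] & (Y[, jj] > zero_tol)
        keep[jj] <- TRUE
      }
    }
    if (any(keep)) {
      # refit shrunk columns before the dual test
      next_cols <- active_cols[keep]
      done_cols <- active_cols[!keep]
    } else {
      next_cols <- integer(0)
      done_cols <- active_cols
    }
    if (length(done_cols) > 0L) {
      jj_done <- match(done_cols, active_cols)
      Yd <- Y[, jj_done, drop = FALSE]
      X[, done_cols] <- pmax(Yd, 0)
      W <- AtB[, done_cols, drop = FALSE] - AtA %*% X[, done_cols, drop = FALSE]
      for (ii in seq_along(done_cols)) {
        col <- done_cols[ii]
        act <- !P[, col]
        if (any(act)) {
          w_act <- W[act, ii]
          if (max(w_act) > tol * dual_scale[col]) {
            add <- which(act)[which.max(w_act)]
            P[add, col] <- TRUE
            next_cols <- c(next_cols, col)
          }
        }
      }
    }
    active_cols <- sort(next_cols)
  }
  if (length(active_cols) > 0L) {
    warning("nonnegative_lsq: iteration cap reached for ",
            length(active_cols), " column(s); returning clipped solution")
  }
  X[X < 0] <- 0
  X
}
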