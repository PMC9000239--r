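# Khatri-Rao product: column n = kron(A[, n], B[, n]).
khatri_rao <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (n in seq_len(ncol(A))) out[, n] <- kronecker(A[, n], B[, n])
  out
}

trilinear_result <- function(C, S, Z, lof_trace, n_iter, converged, X_aug,
                             method) {
  # resolve the sign indeterminacy: orient C and S components positive
  # (by their element sums), compensating in Z so the model is unchanged
  for (n in seq_len(ncol(C))) {
    if (sum(C[, n]) < 0) { C[, n] <- -C[, n]; Z[, n] <- -Z[, n] }
    if (sum(S[, n]) < 0) { S[, n] <- -S[, n]; Z[, n] <- -Z[, n] }
  }
  # normalization convention: unit-norm C and S columns, magnitude in Z
  nc <- sqrt(colSums(C^2)); nc[nc == 0] <- 1
  ns <- sqrt(colSums(S^2)); ns[ns == 0] <- 1
  C <- sweep(C, 2, nc, "/")
  S <- sweep(S, 2, ns, "/")
  Z <- sweep(Z, 2, nc * ns, "*")
  C_aug <- khatri_rao(Z, C)
  recon <- C_aug %*% t(S)
  lof <- lack_of_fit(X_aug, recon)
  structure(list(C = C, S = S, Z = Z, C_aug = C_aug,
                 lof_percent = lof, r2_percent = 100 - lof^2 / 100,
                 fit_trace = lof_trace, n_iter = n_iter,
                 converged = converged, method = method),
            class = "trilinear_fit")
}

#' @export
print.trilinear_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d components, lof %.4g%%, R2 %.4g%%, %d iterations%s\n",
              toupper(x$method), ncol(x$S), x$lof_percent, x$r2_percent,
              x$n_iter, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' PARAFAC by alternating least squares
#'
#' Strict trilinear decomposition `x_ijk = sum_n c_in s_jn z_kn`: cyclic
#' least-squares updates of the sample amounts `Z`, the concentration
#' profiles `C`, and the spectra `S` from the three matricized forms of
#' the cube, each step assuming the other two factor matrices known.
#' Optional non-negativity on all three factors via NNLS. Plain ALS, no
#' line search or acceleration.
#'
#' @param X a [three_way_array].
#' @param N number of components.
#' @param tol relative lof-change stopping threshold (default 1e-3).
#' @param max_iter maximum sweeps (default 200).
#' @param nonneg apply non-negativity to all factors (default TRUE).
#' @param seed seed for the default initialization.
#' @param S_init optional `J x N` initial spectra; by default the solver
#'   starts from its own seeded random nonnegative spectra (the method's
#'   standard standalone configuration), e.g. pass
#'   `purest_rows(...)$spectra` to share the MCR initialization.
#' @return A `trilinear_fit`: `C` (`I x N`, unit columns), `S` (`J x N`,
#'   unit columns), `Z` (`K x N`, carrying the magnitude), `C_aug`,
#'   `lof_percent`, `r2_percent`, `fit_trace`, `n_iter`, `converged`.
#' @export
fit_parafac <- function(X, N, tol = 1e-3, max_iter = 200L, nonneg = TRUE,
                        seed = 1L, S_init = NULL) {
  stopifnot(inherits(X, "three_way_array"), N >= 1L)
  v <- X$values
  d <- dim(v); I <- d[1]; J <- d[2]; K <- d[3]
  X_aug <- augment(X, "columnwise")$values
  Xr <- matrix(v, I, J * K)        # mode-1 unfolding, j fast / k slow
  Xm <- matrix(v, I * J, K)        # vec(X_k) columns, i fast / j slow

  S <- if (!is.null(S_init)) as.matrix(S_init) else random_spectra(J, N, seed)
  C <- with_seed(seed, matrix(abs(stats::rnorm(I * N)), I, N))
  Z <- matrix(1, K, N)

  solve_step <- function(A, B) {
    if (nonneg) nonnegative_lsq(A, B) else ls_solve(A, B)
  }
  lof_trace <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  best <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    Z <- t(solve_step(khatri_rao(S, C), Xm))
    C <- t(solve_step(khatri_rao(Z, S), t(Xr)))
    S <- t(solve_step(khatri_rao(Z, C), X_aug))
    # rescale to keep the factors bounded
    nc <- sqrt(colSums(C^2)); nc[nc == 0] <- 1
    ns <- sqrt(colSums(S^2)); ns[ns == 0] <- 1
    C <- sweep(C, 2, nc, "/"); S <- sweep(S, 2, ns, "/")
    Z <- sweep(Z, 2, nc * ns, "*")
    recon <- khatri_rao(Z, C) %*% t(S)
    lof <- lack_of_fit(X_aug, recon)
    lof_trace <- c(lof_trace, lof)
    if (is.null(best) || lof < best$lof) best <- list(C = C, S = S, Z = Z, lof = lof)
    if (is.finite(lof_prev) &&
        (abs(lof_prev - lof) / max(lof_prev, .Machine$double.eps) < tol ||
         lof < 1e-10)) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  trilinear_result(best$C, best$S, best$Z, lof_trace, n_iter, converged,
                   X_aug, "parafac")
}

sweep_unit <- function(S) {
  ns <- sqrt(colSums(S^2)); ns[ns == 0] <- 1
  sweep(S, 2, ns, "/")
}

#' ATLD: alternating trilinear decomposition
#'
#' Trilinear decomposition using the canonical alternating update
#' equations based on truncated Moore-Penrose pseudoinverses of the
#' running factor estimates: each row of a factor matrix is the diagonal
#' of a slice sandwiched between the pseudoinverses of the other two
#' factors. No non-negativity is imposed (the method's standard form).
#'
#' @inheritParams fit_parafac
#' @return A `trilinear_fit` (same layout as [fit_parafac()]).
#' @export
fit_atld <- function(X, N, tol = 1e-3, max_iter = 200L, seed = 1L,
                     S_init = NULL) {
  stopifnot(inherits(X, "three_way_array"), N >= 1L)
  v <- X$values
  d <- dim(v); I <- d[1]; J <- d[2]; K <- d[3]
  X_aug <- augment(X, "columnwise")$values
  Xm1 <- matrix(v, I, J * K)                       # i rows; (j fast, k slow)
  Xm2 <- matrix(aperm(v, c(2, 1, 3)), J, I * K)    # j rows; (i fast, k slow)
  Xm3 <- matrix(v, I * J, K)                       # columns vec(X_k), i fast

  S <- if (!is.null(S_init)) as.matrix(S_init) else random_spectra(J, N, seed)
  C <- with_seed(seed, matrix(abs(stats::rnorm(I * N)), I, N))
  Z <- matrix(1, K, N)

  lof_trace <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  best <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # z_k = diag( pinv(C) X_k pinv(S') )
    Pc <- pinv(C); Qs <- pinv(t(S))   # Qs: J x N
    for (n in seq_len(N)) {
      Z[, n] <- crossprod(Xm3, as.vector(outer(Pc[n, ], Qs[, n])))
    }
    # c_i = diag( pinv(S) X_i pinv(Z') )
    Ps <- pinv(S); Qz <- pinv(t(Z))   # Qz: K x N
    for (n in seq_len(N)) {
      C[, n] <- Xm1 %*% as.vector(outer(Ps[n, ], Qz[, n]))
    }
    # s_j = diag( pinv(Z) X_j pinv(C') )
    Pz <- pinv(Z); Qc <- pinv(t(C))   # Qc: I x N
    for (n in seq_len(N)) {
      S[, n] <- Xm2 %*% as.vector(outer(Qc[, n], Pz[n, ]))
    }
    nc <- sqrt(colSums(C^2)); nc[nc == 0] <- 1
    ns <- sqrt(colSums(S^2)); ns[ns == 0] <- 1
    C <- sweep(C, 2, nc, "/"); S <- sweep(S, 2, ns, "/")
    Z <- sweep(Z, 2, nc * ns, "*")
    recon <- khatri_rao(Z, C) %*% t(S)
    lof <- lack_of_fit(X_aug, recon)
    lof_trace <- c(lof_trace, lof)
    if (is.null(best) || lof < best$lof) best <- list(C = C, S = S, Z = Z, lof = lof)
    if (is.finite(lof_prev) &&
        (abs(lof_prev - lof) / max(lof_prev, .Machine$double.eps) < tol ||
         lof < 1e-10)) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  trilinear_result(best$C, best$S, best$Z, lof_trace, n_iter, converged,
                   X_aug, "atld")
}
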