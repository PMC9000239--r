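# Independent oracles and small fixture builders used across the suite.

# Brute-force NNLS for one right-hand side: enumerate every active set,
# solve the restricted least-squares problem, keep the feasible candidate
# with the smallest residual. Valid because the optimum is the restricted
# LS solution on its own (feasible) passive set.
brute_nnls <- function(A, b) {
  n <- ncol(A)
  best_x <- rep(0, n)
  best_obj <- sum(b^2)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  for (r in seq_len(nrow(subsets))) {
    idx <- as.logical(subsets[r, ])
    if (!any(idx)) next
    Ai <- A[, idx, drop = FALSE]
    xi <- tryCatch(qr.solve(Ai, b), error = function(e) NULL)
    if (is.null(xi) || any(xi < 0)) next
    x <- rep(0, n)
    x[idx] <- xi
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_x <- x
    }
  }
  best_x
}

# Independent permutation enumerator (grid-based, unlike the package's
# recursive construction).
perm_grid <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Noiseless exactly-trilinear cube from random nonnegative independent
# factors, built element-wise from the trilinear sum (no package reshapes).
build_trilinear_cube <- function(I, J, K, N, seed = 1) {
  set.seed(seed)
  C <- matrix(runif(I * N, 0.1, 1), I, N)
  S <- matrix(runif(J * N, 0.1, 1), J, N)
  Z <- matrix(runif(K * N, 0.2, 1), K, N)
  v <- array(0, c(I, J, K))
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
    v[i, j, k] <- sum(C[i, ] * S[j, ] * Z[k, ])
  }
  list(X = three_way_array(v), C = C, S = S, Z = Z)
}

# Smooth structured trilinear cube (Gaussian peaks / distinct spectra),
# well-conditioned for recovery tests.
build_peaky_trilinear_cube <- function(I = 40, J = 30, K = 6, N = 3,
                                       seed = 1) {
  set.seed(seed)
  tgrid <- seq_len(I)
  centers <- round(seq(0.25, 0.75, length.out = N) * I)
  C <- sapply(centers, function(m) exp(-0.5 * ((tgrid - m) / (I / 15))^2))
  xg <- seq_len(J)
  sc <- seq(0.2, 0.8, length.out = N) * J
  S <- sapply(sc, function(m) exp(-0.5 * ((xg - m) / (J / 8))^2))
  Z <- matrix(runif(K * N, 0.3, 1), K, N)
  v <- array(0, c(I, J, K))
  for (k in seq_len(K)) v[, , k] <- C %*% diag(Z[k, ]) %*% t(S)
  list(X = three_way_array(v), C = C, S = S, Z = Z)
}

min_matched_cosine <- function(est, ref) {
  m <- match_components(est, ref)
  min(vapply(seq_len(ncol(ref)), function(n) {
    cosine_similarity(est[, m$permutation[n]], ref[, n])
  }, numeric(1)))
}
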