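#' Purest-row (SIMPLISMA-style) initial spectra estimates
#'
#' Selects the `N` most mutually different rows of the column-wise
#' augmented data matrix as initial spectra estimates for the ALS
#' optimization. For row `i` with mean `mu_i` and standard deviation
#' `sigma_i` (across channels), the purity is `sigma_i / (mu_i + alpha)`
#' with the noise offset `alpha` set to `noise_allowance`% of the largest
#' row mean. The first pick maximizes purity; every subsequent pick
#' maximizes purity times an independence weight -- the determinant of the
#' correlation-around-origin matrix of the candidate together with the
#' rows already picked -- so an exact duplicate of a picked row has weight
#' zero and is never selected. Ties are broken by the lowest row index.
#'
#' @param X_aug numeric matrix whose rows are candidate spectra (typically
#'   the column-wise augmented data matrix, `(I*K) x J`).
#' @param N number of components to select (`1 <= N <= nrow(X_aug)`).
#' @param noise_allowance noise offset, percent of the maximum row mean
#'   (default 5).
#' @return A list of class `initial_estimate`: `spectra` (`J x N`
#'   nonnegative matrix, one selected row per column, negatives clipped to
#'   0), `selected_rows` (integer length `N`), `purity_trace` (the
#'   weighted purity value of each pick).
#' @export
purest_rows <- function(X_aug, N, noise_allowance = 5) {
  X_aug <- as.matrix(X_aug)
  nr <- nrow(X_aug)
  if (N < 1L) stop("N must be >= 1")
  if (N > nr) stop("N = ", N, " exceeds the number of rows (", nr, ")")
  mu <- rowMeans(X_aug)
  sigma <- sqrt(rowMeans(X_aug^2) - mu^2)
  sigma[sigma < 0] <- 0
  if (max(sigma) == 0) {
    stop("constant matrix: no variance to rank rows by purity")
  }
  alpha <- noise_allowance / 100 * max(mu)
  purity <- sigma / (mu + alpha)
  # length-normalized rows for the correlation-around-origin determinant
  len <- sqrt(rowSums(X_aug^2))
  len[len == 0] <- 1
  U <- X_aug / len
  selected <- integer(N)
  trace <- numeric(N)
  weighted <- purity
  for (pick in seq_len(N)) {
    weighted[selected[seq_len(pick - 1L)]] <- -Inf
    best <- which.max(weighted)   # lowest index on ties
    selected[pick] <- best
    trace[pick] <- weighted[best]
    if (pick == N) break
    Us <- U[selected[seq_len(pick)], , drop = FALSE]
    G_ss <- tcrossprod(Us)
    g_cand <- U %*% t(Us)          # nr x pick
    # det of [[1, g'], [g, G_ss]] = det(G_ss) * (1 - g' G_ss^-1 g)
    det_ss <- det(G_ss)
    Ginv <- tryCatch(solve(G_ss), error = function(e) pinv(G_ss))
    schur <- 1 - rowSums((g_cand %*% Ginv) * g_cand)
    indep <- pmax(det_ss * schur, 0)
    weighted <- purity * indep
  }
  spectra <- t(X_aug[selected, , drop = FALSE])
  spectra[spectra < 0] <- 0
  structure(list(spectra = spectra, selected_rows = selected,
                 purity_trace = trace),
            class = "initial_estimate")
}

#' Seeded random nonnegative initial spectra
#'
#' Fallback initializer for degenerate inputs: i.i.d. uniform nonnegative
#' spectra with unit-norm columns.
#'
#' @param J number of channels.
#' @param N number of components.
#' @param seed integer seed.
#' @return `J x N` nonnegative matrix with unit-norm columns.
#' @export
random_spectra <- function(J, N, seed = 1L) {
  S <- with_seed(seed, matrix(stats::runif(J * N), J, N))
  sweep(S, 2, sqrt(colSums(S^2)), "/")
}

# Evaluate an expression under a fixed seed without disturbing the
# caller's random-number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, envir = .GlobalEnv)
  } else if (exists(".Random.seed", envir = .GlobalEnv)) {
    rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}
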