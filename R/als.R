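#' Lack of fit, percent
#'
#' `lof = 100 * sqrt(sum((d - dhat)^2) / sum(d^2))` over all elements: the
#' relative residual norm of the factor model, in the same relative units
#' as the measurement error. Linked to the explained variance by
#' `R2 = 100 - lof^2 / 100`.
#'
#' @param X data (matrix, array, or [three_way_array]).
#' @param Xhat reconstruction of the same shape.
#' @return lof in percent (`>= 0`; 0 for a perfect fit).
#' @export
lack_of_fit <- function(X, Xhat) {
  d <- as_values(X); dhat <- as_values(Xhat)
  if (length(d) != length(dhat)) stop("X and Xhat have different sizes")
  ss <- sum(d^2)
  if (ss == 0) stop("lack of fit undefined: all-zero data")
  100 * sqrt(sum((d - dhat)^2) / ss)
}

#' Explained variance, percent
#'
#' `R2 = 100 * (1 - sum(e^2) / sum(d^2))` with `e = X - Xhat`; equals
#' `100 - lof^2/100` by construction.
#'
#' @inheritParams lack_of_fit
#' @return R-squared in percent (`<= 100`).
#' @export
explained_variance <- function(X, Xhat) {
  d <- as_values(X); dhat <- as_values(Xhat)
  if (length(d) != length(dhat)) stop("X and Xhat have different sizes")
  ss <- sum(d^2)
  if (ss == 0) stop("explained variance undefined: all-zero data")
  100 * (1 - sum((d - dhat)^2) / ss)
}

as_values <- function(X) {
  if (inherits(X, "three_way_array")) return(X$values)
  if (inherits(X, "augmented_matrix")) return(X$values)
  X
}

#' Model specification for the constrained ALS engine
#'
#' @param n_components number of components `N`.
#' @param codes per-component constraint codes (0 bilinear, 1 trilinear,
#'   2 trilinear with shift correction); recycled if a single value.
#' @param nonneg_C,nonneg_S apply non-negativity to the concentration /
#'   spectral factors (default TRUE, the usual chemometric setting).
#' @param max_iter maximum ALS sweeps (default 100).
#' @param tol convergence threshold on the relative change of the lack of
#'   fit between sweeps (default 1e-3, i.e. 0.1%).
#' @param init `"purest"` (default), `"random"`, or `"user"` (requires
#'   `S_init` in [fit_mcr_als()]).
#' @param seed integer seed for any stochastic path (random init).
#' @param reference reference rule for shift synchronization, see
#'   [detect_peak_shifts()].
#' @param warm_start number of unconstrained bilinear ALS sweeps run before
#'   the trilinearity constraint is engaged (default 10; ignored when all
#'   codes are 0). The synchronization shifts are thereby estimated from
#'   the optimal bilinear decomposition rather than from the raw initial
#'   estimates, which keeps narrow, strongly shifted peaks out of poor
#'   local minima. The warm-up ends early once the bilinear lof change
#'   drops below `tol`.
#' @return A list of class `mcr_spec`.
#' @export
mcr_spec <- function(n_components, codes = 1, nonneg_C = TRUE,
                     nonneg_S = TRUE, max_iter = 100L, tol = 1e-3,
                     init = c("purest", "random", "user"), seed = 1L,
                     reference = "tallest", warm_start = 10L) {
  if (n_components < 1L) stop("n_components must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (length(codes) == 1L) codes <- rep(codes, n_components)
  codes <- constraint_codes(codes, n_components)
  structure(list(n_components = as.integer(n_components), codes = codes,
                 nonneg_C = isTRUE(nonneg_C), nonneg_S = isTRUE(nonneg_S),
                 max_iter = as.integer(max_iter), tol = tol,
                 init = match.arg(init), seed = as.integer(seed),
                 reference = reference,
                 warm_start = as.integer(warm_start)),
            class = "mcr_spec")
}

#' Fit MCR-ALS with the flexible trilinearity constraint
#'
#' Alternating least squares on the column-wise augmented matrix
#' `X_aug = C_aug S' + E`, each sweep doing: (1) update `C_aug` given `S`
#' (non-negative least squares when `nonneg_C`); (2) apply the
#' per-component trilinearity constraint to `C_aug` (fold, optional shift
#' synchronization, rank-one projection, rebuild; see
#' [apply_trilinearity()]); (3) update `S` given the constrained `C_aug`;
#' (4) normalize the columns of `S` to unit norm, carrying the magnitude
#' into `C_aug`; (5) evaluate the lack of fit. Iterations stop when the
#' relative lof change drops below `spec$tol` or `spec$max_iter` is
#' reached. Hard constraint projections do not guarantee a monotone lof,
#' so the best sweep seen is kept and returned if the final sweep is
#' worse.
#'
#' @param X a [three_way_array].
#' @param spec an [mcr_spec()].
#' @param S_init optional `J x N` initial spectra (used when
#'   `spec$init == "user"`, or in place of the purest-variable estimate).
#' @return A list of class `mcr_fit`: `factors` (list with `C_aug`, `S`,
#'   `Z`, `shifts`, `C`), `lof_percent`, `r2_percent`, `n_iter`,
#'   `converged`, `lof_trace`, `reconstruction`, `flags`, and the `spec`.
#' @examples
#' sim <- simulate_lcdad(I = 60, J = 20, K = 4, shift_range = 5, seed = 2)
#' fit <- fit_mcr_als(sim$data, mcr_spec(3, codes = 2))
#' fit$lof_percent
#' @export
fit_mcr_als <- function(X, spec, S_init = NULL) {
  stopifnot(inherits(X, "three_way_array"), inherits(spec, "mcr_spec"))
  d <- dim(X$values); I <- d[1]; J <- d[2]; K <- d[3]
  N <- spec$n_components
  if (N > min(I * K, J)) {
    stop("N = ", N, " exceeds min(I*K, J) = ", min(I * K, J))
  }
  X_aug <- augment(X, "columnwise")$values

  S <- init_spectra(X_aug, J, N, spec, S_init)

  # warm-up: unconstrained bilinear sweeps so that the synchronization
  # shifts are read off the optimal bilinear decomposition, not off the
  # raw initial estimates
  warm_trace <- numeric(0)
  if (any(spec$codes > 0L) && spec$warm_start > 0L) {
    warm_prev <- Inf
    for (wt in seq_len(spec$warm_start)) {
      C_aug <- if (spec$nonneg_C) t(nonnegative_lsq(S, t(X_aug))) else
        t(ls_solve(S, t(X_aug)))
      S <- if (spec$nonneg_S) t(nonnegative_lsq(C_aug, X_aug)) else
        t(ls_solve(C_aug, X_aug))
      norms <- sqrt(colSums(S^2)); norms[norms == 0] <- 1
      S <- sweep(S, 2, norms, "/")
      C_aug <- sweep(C_aug, 2, norms, "*")
      lof_w <- lack_of_fit(X_aug, C_aug %*% t(S))
      warm_trace <- c(warm_trace, lof_w)
      if (is.finite(warm_prev) &&
          abs(warm_prev - lof_w) / max(warm_prev, .Machine$double.eps) <
            spec$tol) break
      warm_prev <- lof_w
    }
  }

  lof_trace <- numeric(0)
  best <- NULL
  lof_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  flags <- character(0)
  for (it in seq_len(spec$max_iter)) {
    n_iter <- it
    # (1) concentration update
    if (spec$nonneg_C) {
      C_aug <- t(nonnegative_lsq(S, t(X_aug)))
    } else {
      C_aug <- t(ls_solve(S, t(X_aug)))
    }
    # (2) flexible trilinearity constraint
    tri <- apply_trilinearity(C_aug, spec$codes, I, K,
                              reference = spec$reference)
    C_aug <- tri$C_aug
    if (any(tri$flags != "ok")) {
      flags <- unique(c(flags, paste0("component ",
                                      which(tri$flags != "ok"),
                                      " collapsed to zero")))
    }
    # (3) spectral update
    if (spec$nonneg_S) {
      S <- t(nonnegative_lsq(C_aug, X_aug))
    } else {
      S <- t(ls_solve(C_aug, X_aug))
    }
    # (4) normalization convention: unit-norm spectra
    norms <- sqrt(colSums(S^2))
    norms[norms == 0] <- 1
    S <- sweep(S, 2, norms, "/")
    C_aug <- sweep(C_aug, 2, norms, "*")
    if (!all(is.finite(C_aug)) || !all(is.finite(S))) {
      stop("non-finite values encountered in ALS sweep ", it,
           "; the model may be degenerate (N too large?)")
    }
    # (5) fit quality
    recon <- C_aug %*% t(S)
    lof <- lack_of_fit(X_aug, recon)
    lof_trace <- c(lof_trace, lof)
    if (is.null(best) || lof < best$lof) {
      best <- list(C_aug = C_aug, S = S, lof = lof, recon = recon)
    }
    if (is.finite(lof_prev)) {
      denom <- max(lof_prev, .Machine$double.eps)
      if (abs(lof_prev - lof) / denom < spec$tol || lof < 1e-10) {
        converged <- TRUE
        break
      }
    } else if (lof < 1e-10) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  # report the best sweep; final constraint application yields C, Z, shifts
  C_aug <- best$C_aug; S <- best$S
  tri <- apply_trilinearity(C_aug, spec$codes, I, K,
                            reference = spec$reference)
  lof <- best$lof
  r2 <- 100 - lof^2 / 100
  structure(list(
    factors = list(C_aug = tri$C_aug, S = S, Z = tri$Z, C = tri$C,
                   shifts = tri$shifts),
    lof_percent = lof, r2_percent = r2, n_iter = n_iter,
    converged = converged, lof_trace = lof_trace, warm_trace = warm_trace,
    reconstruction = tri$C_aug %*% t(S),
    flags = flags, spec = spec, dims = d),
    class = "mcr_fit")
}

init_spectra <- function(X_aug, J, N, spec, S_init) {
  if (!is.null(S_init)) {
    S_init <- as.matrix(S_init)
    if (nrow(S_init) != J || ncol(S_init) != N) {
      stop("S_init must be ", J, " x ", N)
    }
    return(S_init)
  }
  if (spec$init == "user") stop("init = 'user' requires S_init")
  if (spec$init == "random") return(random_spectra(J, N, spec$seed))
  est <- tryCatch(purest_rows(X_aug, N),
                  error = function(e) NULL)
  if (is.null(est)) return(random_spectra(J, N, spec$seed))
  S <- est$spectra
  norms <- sqrt(colSums(S^2))
  norms[norms == 0] <- 1
  sweep(S, 2, norms, "/")
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat(sprintf("MCR-ALS fit: %d components, codes (%s)\n",
              x$spec$n_components, paste(x$spec$codes, collapse = ",")))
  cat(sprintf("  lof %.4g%%  R2 %.4g%%  iterations %d%s\n",
              x$lof_percent, x$r2_percent, x$n_iter,
              if (x$converged) " (converged)" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
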