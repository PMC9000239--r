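#' Cosine similarity between two profiles
#'
#' The plain (not mean-centered) cosine `r = x.y / (||x|| ||y||)`, the
#' profile-recovery coefficient used throughout the recovery tables.
#' Chemometric usage often labels this quantity "r2" although it is a
#' signed cosine; it is kept unsquared here, so anti-correlated profiles
#' give negative values.
#'
#' @param x,y numeric vectors of equal length, neither all-zero.
#' @return The cosine, in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("profiles have different lengths: ", length(x), " vs ", length(y))
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Angle between two profiles, in degrees
#'
#' `(180/pi) * acos(r)` with the cosine clamped to `[-1, 1]` to absorb
#' rounding; 0 for collinear profiles, 90 for orthogonal, 180 for
#' sign-flipped.
#'
#' @inheritParams cosine_similarity
#' @return Angle in degrees, in `[0, 180]`.
#' @export
vector_angle <- function(x, y) {
  r <- cosine_similarity(x, y)
  angle_from_cosine(r)
}

#' Convert a cosine to an angle in degrees
#'
#' @param r cosine value (clamped to `[-1, 1]`).
#' @return `(180/pi) * acos(r)`.
#' @export
angle_from_cosine <- function(r) {
  180 / pi * acos(pmin(pmax(r, -1), 1))
}

#' Match estimated components to reference components
#'
#' Trilinear and bilinear factorizations recover components in arbitrary
#' order; this finds the permutation of the estimated components that
#' maximizes the summed cosine with the reference profiles in the chosen
#' mode. Exhaustive search over permutations for `N <= 8`, greedy
#' best-pair assignment for larger `N`. Ties are broken by lexicographic
#' permutation order.
#'
#' @param estimated,reference matrices with one component profile per
#'   column (equal column counts; equal row counts within each mode).
#' @return A list with `permutation` (index `p` such that
#'   `estimated[, p[n]]` matches `reference[, n]`), `total_cosine`, and
#'   `ambiguous` (TRUE when another permutation comes within `1e-12` of
#'   the best total).
#' @export
match_components <- function(estimated, reference) {
  estimated <- as.matrix(estimated); reference <- as.matrix(reference)
  if (ncol(estimated) != ncol(reference)) {
    stop("component counts differ: ", ncol(estimated), " vs ",
         ncol(reference))
  }
  N <- ncol(estimated)
  cosmat <- matrix(0, N, N)   # [ref, est]
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      cosmat[a, b] <- cosine_similarity(reference[, a], estimated[, b])
    }
  }
  if (N <= 8L) {
    perms <- all_permutations(N)
    totals <- vapply(seq_len(nrow(perms)), function(i) {
      sum(cosmat[cbind(seq_len(N), perms[i, ])])
    }, numeric(1))
    best <- which.max(totals)   # lexicographic tie-break: first maximum
    perm <- perms[best, ]
    ambiguous <- sum(totals >= totals[best] - 1e-12) > 1L
    total <- totals[best]
  } else {
    # greedy assignment: repeatedly take the best remaining (ref, est) pair
    perm <- integer(N)
    free_ref <- rep(TRUE, N); free_est <- rep(TRUE, N)
    work <- cosmat
    for (step in seq_len(N)) {
      work[!free_ref, ] <- -Inf
      work[, !free_est] <- -Inf
      idx <- arrayInd(which.max(work), dim(work))
      perm[idx[1]] <- idx[2]
      free_ref[idx[1]] <- FALSE
      free_est[idx[2]] <- FALSE
    }
    total <- sum(cosmat[cbind(seq_len(N), perm)])
    ambiguous <- FALSE
  }
  list(permutation = perm, total_cosine = total, ambiguous = ambiguous)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (first in seq_len(n)) {
    rest <- matrix(c(seq_len(n))[-first][sub], nrow(sub), n - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  out
}

#' Profile-recovery report against reference profiles
#'
#' Matches estimated components to the reference (by default in the
#' spectral mode, whose profiles are usually the best determined), then
#' reports the cosine and angle per component and per available mode.
#' Elution profiles are compared as whole augmented `(I*K)` vectors, which
#' keeps shifted, unsynchronized runs comparable without splitting the two
#' embedded modes. Recoveries with `r < 0.9` are flagged.
#'
#' @param fit a list with any of `C_aug` (`(I*K) x N`), `S` (`J x N`),
#'   `Z` (`K x N`) -- e.g. the `factors` element of [fit_mcr_als()] output
#'   or a [fit_parafac()] result.
#' @param truth a list with the same optional elements holding reference
#'   profiles (e.g. the truth bundle of the synthetic generators).
#' @param match_mode mode used for matching: `"spectra"` (default),
#'   `"elution"`, or `"sample"`.
#' @param flag_threshold recoveries below this cosine are flagged
#'   (default 0.9).
#' @return A data frame of class `recovery_report` with columns
#'   `component`, `mode`, `r`, `angle`, `flagged`, plus attributes
#'   `permutation` and `ambiguous`.
#' @export
recovery_report <- function(fit, truth, match_mode = c("spectra", "elution",
                                                       "sample"),
                            flag_threshold = 0.9) {
  match_mode <- match.arg(match_mode)
  pairs <- list(
    elution = list(est = fit$C_aug, ref = truth$C_aug),
    spectra = list(est = fit$S, ref = truth$S),
    sample  = list(est = fit$Z, ref = truth$Z))
  avail <- names(pairs)[vapply(pairs, function(p) {
    !is.null(p$est) && !is.null(p$ref)
  }, logical(1))]
  if (length(avail) == 0L) stop("no mode has both estimated and reference profiles")
  mm <- if (match_mode %in% avail) match_mode else avail[1]
  m <- match_components(pairs[[mm]]$est, pairs[[mm]]$ref)
  N <- length(m$permutation)
  rows <- list()
  for (mode in avail) {
    est <- as.matrix(pairs[[mode]]$est)
    ref <- as.matrix(pairs[[mode]]$ref)
    for (n in seq_len(N)) {
      r <- cosine_similarity(est[, m$permutation[n]], ref[, n])
      rows[[length(rows) + 1L]] <- data.frame(
        component = n, mode = mode, r = r,
        angle = angle_from_cosine(r),
        flagged = r < flag_threshold)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "permutation") <- m$permutation
  attr(out, "ambiguous") <- m$ambiguous
  attr(out, "missing_modes") <- setdiff(names(pairs), avail)
  class(out) <- c("recovery_report", class(out))
  out
}
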