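#' Singular value spectrum of a matrix
#'
#' Descending singular values of `M`, computed without forming the
#' singular vector matrices.
#'
#' @param M numeric matrix with finite entries.
#' @return Numeric vector of `min(dim(M))` nonnegative singular values,
#'   sorted in descending order.
#' @export
singular_spectrum <- function(M) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("matrix has non-finite entries")
  if (min(dim(M)) == 0L) return(numeric(0))
  svd(M, nu = 0, nv = 0)$d
}

#' Estimate the chemical rank from a singular value spectrum
#'
#' The number of singular values standing clearly above the experimental
#' noise floor. The floor is the median of the trailing half of the spectrum
#' (indices `ceiling(m/2)+1 .. m`; for fewer than 4 values, the last value),
#' and a singular value counts toward the rank when it exceeds
#' `floor_factor` times the floor. For (near-)noiseless data the floor is
#' bounded below by `1e-10` times the leading singular value, so
#' numerically-zero trailing values do not count toward the rank.
#'
#' @param sv descending singular values (length >= 2).
#' @param floor_factor multiplier on the noise floor (default 10).
#' @return A list with `rank` (integer) and `noise_floor`.
#' @export
estimate_chemical_rank <- function(sv, floor_factor = 10) {
  sv <- as.numeric(sv)
  if (length(sv) < 2L) stop("need at least 2 singular values")
  if (is.unsorted(rev(sv))) sv <- sort(sv, decreasing = TRUE)
  if (all(sv == 0)) return(list(rank = 0L, noise_floor = 0))
  m <- length(sv)
  floor_val <- if (m < 4L) sv[m] else stats::median(sv[(ceiling(m / 2) + 1L):m])
  # guard for (near-)noiseless data: numerically-zero trailing values can
  # median to 0; anything within a relative machine-precision band of the
  # leading singular value is treated as zero-rank noise
  floor_val <- max(floor_val, 1e-10 * sv[1])
  rank <- sum(sv > floor_factor * floor_val)
  list(rank = as.integer(rank), noise_floor = floor_val)
}

#' Augmented-mode rank diagnostics and model-scenario classification
#'
#' Computes the singular value spectra of the three augmented matrices of a
#' cube (column-wise `(I*K) x J`, row-wise `I x (J*K)`, slice-wise
#' `K x (I*J)`), estimates the chemical rank of each, and classifies the
#' data structure:
#'
#' * `trilinear` — all three ranks agree: the standard trilinear model fits.
#' * `rank_deficient_sample_mode` — column- and row-wise ranks agree but the
#'   slice-wise rank is lower: linear dependencies among the sample amounts.
#' * `shifted_nontrilinear` — the row-wise rank exceeds the column-wise
#'   rank: unsynchronized (shifted) profiles in the time mode break the
#'   trilinear model.
#' * `indeterminate` — any other pattern.
#'
#' @param X a [three_way_array].
#' @param floor_factor passed to [estimate_chemical_rank()].
#' @return An object of class `rank_report`: lists `singular_values`,
#'   `chemical_rank`, `noise_floor` (each per mode), and `scenario`.
#' @export
trilinearity_report <- function(X, floor_factor = 10) {
  stopifnot(inherits(X, "three_way_array"))
  modes <- c("columnwise", "rowwise", "slicewise")
  sv <- lapply(modes, function(m) singular_spectrum(augment(X, m)$values))
  names(sv) <- modes
  est <- lapply(sv, estimate_chemical_rank, floor_factor = floor_factor)
  ranks <- vapply(est, `[[`, integer(1), "rank")
  floors <- vapply(est, `[[`, numeric(1), "noise_floor")
  rc <- ranks[["columnwise"]]; rr <- ranks[["rowwise"]]; rs <- ranks[["slicewise"]]
  scenario <- if (rc == rr && rr == rs) {
    "trilinear"
  } else if (rc == rr && rr > rs) {
    "rank_deficient_sample_mode"
  } else if (rr > rc) {
    "shifted_nontrilinear"
  } else {
    "indeterminate"
  }
  structure(list(singular_values = sv, chemical_rank = ranks,
                 noise_floor = floors, scenario = scenario,
                 floor_factor = floor_factor),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, n = 8, ...) {
  cat("Augmented-mode rank diagnostics\n")
  for (m in names(x$singular_values)) {
    sv <- x$singular_values[[m]]
    shown <- utils::head(sv, n)
    cat(sprintf("  %-10s rank %d (noise floor %.3g): %s%s\n", m,
                x$chemical_rank[[m]], x$noise_floor[[m]],
                paste(signif(shown, 4), collapse = " "),
                if (length(sv) > n) " ..." else ""))
  }
  cat("  scenario:", x$scenario, "\n")
  invisible(x)
}
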