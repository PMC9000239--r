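# Gaussian elution shape on an integer time grid, unit peak height.
gauss_peak <- function(I, center, width) {
  exp(-0.5 * ((seq_len(I) - center) / width)^2)
}

# Smooth nonnegative spectra: sums of 2-3 broad Gaussians per component,
# primary bands spread over the channel range so components stay
# spectrally distinct (pairwise cosine < max_cos).
smooth_spectra <- function(J, N, max_cos = 0.98, n_attempts = 50) {
  for (attempt in seq_len(n_attempts)) {
    S <- matrix(0, J, N)
    x <- seq_len(J)
    anchors <- seq(0.15, 0.85, length.out = N) * J
    for (n in seq_len(N)) {
      nb <- sample(2:3, 1)
      centers <- anchors[n] + stats::runif(nb, -0.08, 0.08) * J
      centers[1] <- anchors[n]
      widths <- stats::runif(nb, 0.05, 0.12) * J
      heights <- c(1, stats::runif(nb - 1, 0.2, 0.6))
      for (b in seq_len(nb)) {
        S[, n] <- S[, n] + heights[b] * exp(-0.5 * ((x - centers[b]) / widths[b])^2)
      }
    }
    ok <- TRUE
    for (a in seq_len(N - 1)) {
      for (b in (a + 1):N) {
        if (cosine_similarity(S[, a], S[, b]) >= max_cos) ok <- FALSE
      }
    }
    if (ok) return(S)
  }
  stop("could not draw spectra with pairwise cosine < ", max_cos)
}

# Sparse nonnegative mass spectrum with nnz peaks among the given channels.
sparse_spectrum <- function(J, nnz, channels = seq_len(J)) {
  s <- numeric(J)
  pos <- sample(channels, nnz)
  s[pos] <- stats::runif(nnz, 0.1, 1)
  s
}

check_peak_window <- function(I, centers, widths, max_shift, margin = 3) {
  lo <- centers - max_shift - margin * widths
  hi <- centers + max_shift + margin * widths
  if (any(lo < 1) || any(hi > I)) {
    stop("shift range +/-", max_shift, " pushes a peak (center ",
         paste(centers, collapse = ","), ", width ",
         paste(signif(widths, 3), collapse = ","),
         ") to the boundary of the ", I, "-point time window")
  }
}

# Shifts stored in the truth are expressed relative to the slice with the
# largest peak amplitude of that component, so detect_peak_shifts() on the
# noiseless profiles recovers them exactly.
relative_shifts <- function(offsets, amplitudes) {
  ref <- which.max(amplitudes)
  as.integer(offsets - offsets[ref])
}

assemble_cube <- function(profiles, S, Z, noise_sd_rel, I, J, K, N) {
  # profiles: I x N x K unit-height elution shapes; Z: K x N amplitudes
  signal <- array(0, c(I, J, K))
  for (k in seq_len(K)) {
    Ck <- profiles[, , k, drop = FALSE]
    dim(Ck) <- c(I, N)
    signal[, , k] <- (Ck %*% diag(Z[k, ], N, N)) %*% t(S)
  }
  if (noise_sd_rel > 0) {
    noise_raw <- array(stats::rnorm(I * J * K, sd = noise_sd_rel * max(signal)),
                       c(I, J, K))
    values <- pmax(signal + noise_raw, 0)
  } else {
    values <- signal
  }
  noise <- values - signal   # stored realization, exact by construction
  list(values = values, noise = noise)
}

make_truth <- function(profiles, S, Z, shifts, noise, seed, noise_sd_rel) {
  I <- dim(profiles)[1]; N <- dim(profiles)[2]; K <- dim(profiles)[3]
  C_aug <- matrix(0, I * K, N)
  for (k in seq_len(K)) {
    C_aug[(k - 1L) * I + seq_len(I), ] <- profiles[, , k] %*% diag(Z[k, ], N, N)
  }
  list(C_per_slice = profiles, S = S, Z = Z, C_aug = C_aug,
       shifts = shifts, noise = noise, noise_sd_rel = noise_sd_rel,
       seed = seed)
}

#' Simulate an LC-DAD-like cube with strongly shifted elution peaks
#'
#' Emulates a liquid-chromatography / diode-array experiment: `N`
#' components with fixed-shape Gaussian elution peaks whose positions are
#' shifted per run by integers drawn uniformly from
#' `[-shift_range, shift_range]`, smooth distinct UV spectra (pairwise
#' cosine < 0.98), independently varying positive sample amounts, and
#' additive i.i.d. Gaussian noise (relative SD `noise_sd_rel` of the
#' maximum signal) clipped at zero. The default dimensions match an 11-run,
#' 600-time, 96-wavelength experiment.
#'
#' @param I,J,K,N cube dimensions and component count.
#' @param shift_range maximum absolute per-run peak shift in time points.
#' @param peak_widths Gaussian widths (length `N`, default `I/40`).
#' @param noise_sd_rel relative noise SD (default 1e-3).
#' @param seed integer seed; the same seed reproduces the cube exactly.
#' @return A list with `data` (a [three_way_array]) and `truth` (list with
#'   `C_per_slice` `I x N x K` unit-height profiles, `S` `J x N`, `Z`
#'   `K x N`, `C_aug` true augmented profiles, `shifts` `K x N` integer
#'   shifts relative to each component's tallest slice, `noise`,
#'   `noise_sd_rel`, `seed`).
#' @export
simulate_lcdad <- function(I = 600, J = 96, K = 11, N = 3, shift_range = 30,
                           peak_widths = NULL, noise_sd_rel = 1e-3,
                           seed = 1L) {
  if (is.null(peak_widths)) peak_widths <- rep(I / 40, N)
  centers <- round(seq(0.3, 0.7, length.out = N) * I)
  check_peak_window(I, centers, peak_widths, shift_range)
  with_seed(seed, {
    S <- smooth_spectra(J, N)
    pool <- seq.int(-shift_range, shift_range)
    offsets <- matrix(pool[sample.int(length(pool), K * N, replace = TRUE)],
                      K, N)
    Z <- matrix(stats::runif(K * N, 0.3, 1), K, N)
    profiles <- array(0, c(I, N, K))
    for (k in seq_len(K)) {
      for (n in seq_len(N)) {
        profiles[, n, k] <- gauss_peak(I, centers[n] + offsets[k, n],
                                       peak_widths[n])
      }
    }
    shifts <- vapply(seq_len(N), function(n) {
      relative_shifts(offsets[, n], Z[, n])
    }, integer(K))
    cube <- assemble_cube(profiles, S, Z, noise_sd_rel, I, J, K, N)
    list(data = three_way_array(cube$values),
         truth = make_truth(profiles, S, Z, shifts, cube$noise, seed,
                            noise_sd_rel))
  })
}

#' Simulate a GC-MS-like cube with shifting peaks and a varying background
#'
#' Emulates a short GC-MS elution window: `analytes` components with
#' sparse nonnegative mass spectra (5-15 nonzero mass channels each) and
#' fixed-shape Gaussian elution peaks shifted per run by integers from
#' `[-shift_range, shift_range]`, plus (optionally) one background
#' component with a broad, run-invariant elution shape whose amplitude
#' varies from run to run and a sparse low-mass spectrum (carrier-gas-like
#' channels). Defaults match a 25-time, 200-mass, 44-run window.
#'
#' @param I,J,K cube dimensions.
#' @param analytes number of shifting analyte components.
#' @param shift_range maximum absolute per-run peak shift in time points.
#' @param background include the background component (default TRUE).
#' @param background_amp_var relative spread of the background amplitude
#'   across runs (0 = constant).
#' @param noise_sd_rel relative noise SD (default 1e-3).
#' @param seed integer seed.
#' @return As [simulate_lcdad()]; with the background, the truth holds
#'   `analytes + 1` components, the background last with all shifts 0.
#' @export
simulate_gcms <- function(I = 25, J = 200, K = 44, analytes = 2,
                          shift_range = 4, background = TRUE,
                          background_amp_var = 0.4, noise_sd_rel = 1e-3,
                          seed = 1L) {
  widths <- rep(1.6, analytes)
  centers <- round(seq(0.38, 0.62, length.out = analytes) * I)
  check_peak_window(I, centers, widths, shift_range)
  N <- analytes + as.integer(background)
  with_seed(seed, {
    S <- matrix(0, J, N)
    for (n in seq_len(analytes)) {
      S[, n] <- sparse_spectrum(J, sample(5:15, 1),
                                channels = seq(41L, J))
    }
    offsets <- matrix(0L, K, N)
    pool <- seq.int(-shift_range, shift_range)
    offsets[, seq_len(analytes)] <- pool[sample.int(length(pool),
                                                    K * analytes,
                                                    replace = TRUE)]
    Z <- matrix(stats::runif(K * N, 0.3, 1), K, N)
    profiles <- array(0, c(I, N, K))
    for (k in seq_len(K)) {
      for (n in seq_len(analytes)) {
        profiles[, n, k] <- gauss_peak(I, centers[n] + offsets[k, n],
                                       widths[n])
      }
    }
    if (background) {
      # broad run-invariant elution shape: a wide hump over the window
      bshape <- 0.6 + gauss_peak(I, round(I / 2), I / 2.5)
      bshape <- bshape / max(bshape)
      S[, N] <- sparse_spectrum(J, 4, channels = seq_len(40L))
      Z[, N] <- 1 + background_amp_var * (stats::runif(K) - 0.5) * 2
      for (k in seq_len(K)) profiles[, N, k] <- bshape
    }
    shifts <- vapply(seq_len(N), function(n) {
      relative_shifts(offsets[, n], Z[, n])
    }, integer(K))
    cube <- assemble_cube(profiles, S, Z, noise_sd_rel, I, J, K, N)
    list(data = three_way_array(cube$values),
         truth = make_truth(profiles, S, Z, shifts, cube$noise, seed,
                            noise_sd_rel))
  })
}

#' Simulate an FIA-like cube with pH-driven acid-base speciation
#'
#' Emulates flow injection analysis under a pH gradient with UV detection:
#' `compounds` acids, each present as an acid/base conjugate pair, giving
#' `2 * compounds` absorbing species. Every species' time profile is a
#' shared Gaussian dispersion envelope multiplied by its
#' Henderson-Hasselbalch fraction of the run-invariant monotone pH(t)
#' gradient, so acid + base fractions close to 1 at every time point. The
#' two species of a compound share one sample-amount column (the
#' speciation depends only on pH, not on the total concentration), so the
#' sample-mode factor has only `compounds` distinct columns -- the
#' rank-deficient sample mode characteristic of this experiment. Defaults
#' match an 89-time, 100-wavelength, 12-sample experiment.
#'
#' @param I,J,K cube dimensions.
#' @param compounds number of acid-base compounds (species count is twice
#'   this).
#' @param pKa acidity constants, one per compound (default equally spaced
#'   in the pH gradient range, distinct).
#' @param pH_range endpoints of the monotone pH gradient over flow time.
#' @param noise_sd_rel relative noise SD (default 1e-3).
#' @param seed integer seed.
#' @return As [simulate_lcdad()]; truth components are ordered (compound 1
#'   acid, compound 1 base, compound 2 acid, ...), all shifts 0, and
#'   `truth$pH`, `truth$pKa`, `truth$fractions` (`I x 2*compounds`) are
#'   included.
#' @export
simulate_fia <- function(I = 89, J = 100, K = 12, compounds = 3,
                         pKa = NULL, pH_range = c(3, 11),
                         noise_sd_rel = 1e-3, seed = 1L) {
  if (is.null(pKa)) {
    pKa <- seq(pH_range[1] + 1.5, pH_range[2] - 1.5, length.out = compounds)
  }
  if (length(pKa) != compounds || anyDuplicated(pKa)) {
    stop("pKa must give one distinct value per compound")
  }
  N <- 2L * compounds
  pH <- seq(pH_range[1], pH_range[2], length.out = I)
  with_seed(seed, {
    S <- smooth_spectra(J, N)
    env <- gauss_peak(I, round(I * 0.45), I / 6)
    fractions <- matrix(0, I, N)
    profiles <- array(0, c(I, N, K))
    amounts <- matrix(stats::runif(K * compounds, 0.2, 1), K, compounds)
    Z <- matrix(0, K, N)
    for (cpd in seq_len(compounds)) {
      f_acid <- 1 / (1 + 10^(pH - pKa[cpd]))
      na <- 2L * cpd - 1L; nb <- 2L * cpd
      fractions[, na] <- f_acid
      fractions[, nb] <- 1 - f_acid
      for (k in seq_len(K)) {
        profiles[, na, k] <- env * f_acid
        profiles[, nb, k] <- env * (1 - f_acid)
      }
      Z[, na] <- amounts[, cpd]
      Z[, nb] <- amounts[, cpd]
    }
    shifts <- matrix(0L, K, N)
    cube <- assemble_cube(profiles, S, Z, noise_sd_rel, I, J, K, N)
    truth <- make_truth(profiles, S, Z, shifts, cube$noise, seed,
                        noise_sd_rel)
    truth$pH <- pH
    truth$pKa <- pKa
    truth$fractions <- fractions
    list(data = three_way_array(cube$values), truth = truth)
  })
}
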