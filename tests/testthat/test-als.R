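test_that("lack of fit and explained variance follow their definitions", {
  X <- matrix(c(3, 4), 1, 2)
  expect_equal(lack_of_fit(X, X), 0)
  expect_equal(explained_variance(X, X), 100)
  expect_equal(lack_of_fit(X, 0 * X), 100)
  set.seed(41)
  A <- matrix(runif(20), 4, 5); B <- matrix(runif(20), 4, 5)
  expect_equal(lack_of_fit(A, B),
               100 * sqrt(sum((A - B)^2) / sum(A^2)))
  expect_equal(explained_variance(A, B),
               100 * (1 - sum((A - B)^2) / sum(A^2)))
  expect_equal(explained_variance(A, B), 100 - lack_of_fit(A, B)^2 / 100,
               tolerance = 1e-12)
  expect_error(lack_of_fit(0 * A, B), "all-zero")
})

test_that("trilinear ALS recovers a noiseless trilinear cube", {
  cube <- build_peaky_trilinear_cube(40, 30, 6, 3, seed = 1)
  fit <- fit_mcr_als(cube$X, mcr_spec(3, codes = 1, tol = 1e-6,
                                      max_iter = 300))
  expect_lt(fit$lof_percent, 0.1)
  expect_gt(min_matched_cosine(fit$factors$S, cube$S), 0.999)
  # invariants of every returned fit
  expect_equal(fit$r2_percent, 100 - fit$lof_percent^2 / 100,
               tolerance = 1e-9)
  expect_equal(unname(colSums(fit$factors$S^2)), rep(1, 3),
               tolerance = 1e-9)
  expect_lte(fit$lof_percent, fit$lof_trace[1] + 1e-9)
})

test_that("shift-corrected trilinearity recovers a shifted cube exactly", {
  sim <- simulate_lcdad(I = 120, J = 30, K = 6, N = 3, shift_range = 10,
                        noise_sd_rel = 0, seed = 6)
  fit <- fit_mcr_als(sim$data, mcr_spec(3, codes = 2))
  expect_lt(fit$lof_percent, 1)
  rep <- recovery_report(fit$factors, sim$truth)
  expect_gt(min(rep$r[rep$mode == "spectra"]), 0.999)
  perm <- attr(rep, "permutation")
  expect_identical(fit$factors$shifts[, perm], sim$truth$shifts)
  # strict synchronization cannot model the shifts: much worse fit
  fit1 <- fit_mcr_als(sim$data, mcr_spec(3, codes = 1))
  expect_gt(fit1$lof_percent, 5 * max(fit$lof_percent, 1e-6))
})

test_that("unconstrained bilinear sweeps never increase the residual", {
  cube <- build_peaky_trilinear_cube(25, 15, 4, 2, seed = 3)
  fit <- fit_mcr_als(cube$X, mcr_spec(2, codes = 0, nonneg_C = FALSE,
                                      nonneg_S = FALSE, tol = 1e-9,
                                      max_iter = 40))
  expect_true(all(diff(fit$lof_trace) <= 1e-9))
})

test_that("mixed models resolve shifting analytes over a trilinear background", {
  sim <- simulate_gcms(K = 10, noise_sd_rel = 0, seed = 8)
  # practitioner workflow: resolve bilinearly, identify the components,
  # then assign shift-corrected trilinearity to the analytes and plain
  # trilinearity to the run-invariant background
  f0 <- fit_mcr_als(sim$data, mcr_spec(3, codes = 0))
  m <- match_components(f0$factors$S, sim$truth$S)
  codes <- integer(3)
  codes[m$permutation] <- c(2, 2, 1)   # truth order: analyte, analyte, bg
  fit <- fit_mcr_als(sim$data, mcr_spec(3, codes = codes),
                     S_init = f0$factors$S)
  expect_lt(fit$lof_percent, 1)
  f111 <- fit_mcr_als(sim$data, mcr_spec(3, codes = 1))
  expect_lt(fit$lof_percent, f111$lof_percent)
  # every constrained component is rank 1 after synchronization
  I <- 25; K <- 10
  for (n in which(codes > 0)) {
    Cn <- fold_component_profile(fit$factors$C_aug[, n], I, K)
    sync <- sapply(seq_len(K), function(k) {
      shift_profile(Cn[, k], fit$factors$shifts[k, n])
    })
    sv <- singular_spectrum(sync)
    # rank 1 up to the zero-filled window edges lost in the restore step
    expect_lt(sv[2] / sv[1], 1e-3)
  }
  # the trilinear background component carries no shifts
  expect_identical(fit$factors$shifts[, which(codes == 1)], integer(10))
})

test_that("degenerate inputs are rejected with informative errors", {
  cube <- build_peaky_trilinear_cube(10, 5, 2, 2, seed = 4)
  expect_error(fit_mcr_als(cube$X, mcr_spec(8)), "exceeds")
  expect_error(mcr_spec(2, codes = c(1, 1, 1)), "per component")
  expect_error(mcr_spec(2, tol = 0), "tol")
})
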