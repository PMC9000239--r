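gauss_col <- function(I, center, width = 2) {
  exp(-0.5 * ((seq_len(I) - center) / width)^2)
}

test_that("peak shifts are measured against the tallest slice", {
  I <- 30
  C_n <- cbind(1.0 * gauss_col(I, 10), 0.9 * gauss_col(I, 14),
               0.8 * gauss_col(I, 7))
  det <- detect_peak_shifts(C_n)
  expect_identical(det$reference_slice, 1L)
  expect_identical(det$reference_position, 10L)
  expect_identical(det$shifts, c(0L, 4L, -3L))

  # K = 1 trivially has shift 0
  expect_identical(detect_peak_shifts(cbind(gauss_col(I, 12)))$shifts, 0L)

  # an absent component in one run gets shift 0, others unaffected
  C_n[, 2] <- 0
  det2 <- detect_peak_shifts(C_n)
  expect_identical(det2$shifts, c(0L, 0L, -3L))
  expect_false(det2$present[2])

  z <- detect_peak_shifts(matrix(0, 5, 3))
  expect_true(z$all_zero)
  expect_identical(z$shifts, integer(3))
})

test_that("shift_profile moves data by whole time points with zero fill", {
  expect_equal(shift_profile(c(0, 1, 0, 0), 1), c(1, 0, 0, 0))
  expect_equal(shift_profile(c(0, 1, 0, 0), -1, fill = 9), c(9, 0, 1, 0))
  v <- rnorm(10)
  expect_identical(shift_profile(v, 0), v)
  # round trip on an interior-supported peak
  w <- c(0, 0, 0, 5, 7, 3, 0, 0, 0, 0)
  for (s in c(-3, -1, 2, 3)) {
    expect_equal(shift_profile(shift_profile(w, s), -s), w)
  }
  expect_error(shift_profile(1:4, 4), "shift")
})

test_that("rank-one projection is the Eckart-Young optimum", {
  # exact rank-1 input is a fixed point
  M <- outer(c(1, 2, 3), c(4, 0.5, 2, 1))
  r1 <- rank_one_projection(M)
  expect_equal(r1$m1, M, tolerance = 1e-12)
  expect_equal(r1$m1, outer(r1$c, r1$z))
  expect_equal(sum(r1$c^2), 1)
  # closed form for a diagonal matrix
  expect_equal(rank_one_projection(diag(c(3, 1)))$m1, diag(c(3, 0)),
               tolerance = 1e-12)
  # Monte-Carlo oracle: no random rank-1 matrix comes closer
  set.seed(31)
  M <- matrix(rnorm(12), 4, 3)
  best <- sum((M - rank_one_projection(M)$m1)^2)
  for (t in 1:200) {
    R <- outer(rnorm(4), rnorm(3))
    expect_gte(sum((M - R)^2), best - 1e-12)
  }
  expect_true(rank_one_projection(matrix(0, 3, 2))$all_zero)
})

test_that("code 0 passes profiles through unchanged", {
  set.seed(32)
  C_aug <- matrix(runif(24), 12, 2)
  out <- apply_trilinearity(C_aug, c(0, 0), I = 4, K = 3)
  expect_identical(out$C_aug, C_aug)
  expect_identical(out$shifts, matrix(0L, 3, 2))
})

test_that("code 1 projects each folded component to rank one", {
  I <- 8; K <- 3
  c_true <- gauss_col(I, 4); z_true <- c(2, 1, 0.5)
  col_fixed <- as.vector(outer(c_true, z_true))
  set.seed(33)
  col_noisy <- runif(I * K)
  C_aug <- cbind(col_fixed, col_noisy)
  out <- apply_trilinearity(C_aug, c(1, 1), I, K)
  # a rank-1 column is a fixed point
  expect_equal(out$C_aug[, 1], col_fixed, tolerance = 1e-12)
  # every constrained folded component has numerical rank 1
  for (n in 1:2) {
    sv <- singular_spectrum(fold_component_profile(out$C_aug[, n], I, K))
    expect_lt(sv[2] / sv[1], 1e-12)
  }
  # and the projection is idempotent
  out2 <- apply_trilinearity(out$C_aug, c(1, 1), I, K)
  expect_equal(out2$C_aug, out$C_aug, tolerance = 1e-12)
})

test_that("code 2 synchronizes, projects, and restores peak positions", {
  I <- 40; K <- 3
  shape <- c(rep(0, 15), 1, 3, 7, 10, 7, 3, 1, rep(0, 18))  # compact support
  shifts_true <- c(0L, 5L, -3L)
  heights <- c(1, 0.5, 0.25)
  Cn <- sapply(1:K, function(k) {
    heights[k] * shift_profile(shape, -shifts_true[k])
  })
  col <- as.vector(Cn)
  out <- apply_trilinearity(cbind(col), 2, I, K)
  expect_lt(sqrt(sum((out$C_aug[, 1] - col)^2) / sum(col^2)), 1e-10)
  expect_identical(out$shifts[, 1], shifts_true)
  expect_equal(out$Z[, 1] / out$Z[1, 1], heights, tolerance = 1e-10)
  # idempotent (compactly supported peak: nothing is lost at the edges)
  out2 <- apply_trilinearity(out$C_aug, 2, I, K)
  expect_equal(out2$C_aug, out$C_aug, tolerance = 1e-12)
  # folded matrix has rank 1 after synchronization
  sync <- sapply(1:K, function(k) {
    shift_profile(fold_component_profile(out$C_aug[, 1], I, K)[, k],
                  out$shifts[k, 1])
  })
  sv <- singular_spectrum(sync)
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("all-zero components are passed through and flagged", {
  C_aug <- cbind(rep(0, 12), runif(12))
  out <- apply_trilinearity(C_aug, c(1, 1), I = 4, K = 3)
  expect_identical(out$flags, c("all_zero", "ok"))
  expect_identical(out$C_aug[, 1], C_aug[, 1])
  expect_error(constraint_codes(c(0, 3), 2), "codes")
  expect_error(constraint_codes(c(1, 1), 3), "per component")
})
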