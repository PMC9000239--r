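test_that("generators are deterministic given the seed", {
  a <- simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6, seed = 71)
  b <- simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6, seed = 71)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth$shifts, b$truth$shifts)
  c <- simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6, seed = 72)
  expect_false(identical(a$data$values, c$data$values))
  g1 <- simulate_gcms(K = 8, seed = 73)
  g2 <- simulate_gcms(K = 8, seed = 73)
  expect_identical(g1$data$values, g2$data$values)
  f1 <- simulate_fia(seed = 74)
  f2 <- simulate_fia(seed = 74)
  expect_identical(f1$data$values, f2$data$values)
})

test_that("cube equals truth reconstruction plus the stored noise, exactly", {
  for (sim in list(simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6,
                                  seed = 75),
                   simulate_gcms(K = 8, seed = 76),
                   simulate_fia(K = 6, seed = 77))) {
    tr <- sim$truth
    d <- dim(sim$data$values)
    signal <- array(0, d)
    N <- ncol(tr$S)
    for (k in seq_len(d[3])) {
      signal[, , k] <- tr$C_per_slice[, , k] %*% diag(tr$Z[k, ], N, N) %*%
        t(tr$S)
    }
    expect_identical(sim$data$values, signal + tr$noise)
    expect_true(all(sim$data$values >= 0))
    expect_true(all(tr$C_per_slice >= 0) && all(tr$S >= 0) &&
                  all(tr$Z >= 0))
  }
})

test_that("true shifts are recovered from the noiseless profiles", {
  sim <- simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6,
                        noise_sd_rel = 0, seed = 78)
  I <- 80; K <- 5
  for (n in 1:3) {
    Cn <- sapply(seq_len(K), function(k) {
      sim$truth$Z[k, n] * sim$truth$C_per_slice[, n, k]
    })
    det <- detect_peak_shifts(Cn)
    expect_identical(det$shifts, sim$truth$shifts[, n])
  }
})

test_that("generated spectra are mutually distinct", {
  sim <- simulate_lcdad(I = 80, J = 24, K = 5, shift_range = 6, seed = 79)
  S <- sim$truth$S
  for (a in 1:2) for (b in (a + 1):3) {
    expect_lt(cosine_similarity(S[, a], S[, b]), 0.98)
  }
})

test_that("the FIA truth encodes speciation closure and shared amounts", {
  sim <- simulate_fia(K = 6, noise_sd_rel = 0, seed = 80)
  fr <- sim$truth$fractions
  # acid + base fractions close to 1 at every flow time
  for (cpd in 1:3) {
    expect_equal(fr[, 2 * cpd - 1] + fr[, 2 * cpd], rep(1, 89))
  }
  # acid/base pairs share one sample-amount column
  for (cpd in 1:3) {
    expect_identical(sim$truth$Z[, 2 * cpd - 1], sim$truth$Z[, 2 * cpd])
  }
  # pH gradient is monotone
  expect_true(all(diff(sim$truth$pH) > 0))
  expect_error(simulate_fia(pKa = c(5, 5, 7)), "distinct")
})

test_that("the GC-MS background is run-invariant in shape, varying in amount", {
  sim <- simulate_gcms(K = 10, noise_sd_rel = 0, seed = 81)
  bg <- sim$truth$C_per_slice[, 3, ]
  for (k in 2:10) expect_identical(bg[, k], bg[, 1])
  expect_gt(stats::sd(sim$truth$Z[, 3]), 0)
  expect_identical(sim$truth$shifts[, 3], integer(10))
  # analyte mass spectra are sparse
  expect_lte(sum(sim$truth$S[, 1] > 0), 15)
  expect_gte(sum(sim$truth$S[, 1] > 0), 5)
})

test_that("peaks pushed to the window boundary are rejected", {
  expect_error(simulate_lcdad(I = 60, J = 10, K = 3, shift_range = 40),
               "boundary")
  expect_error(simulate_gcms(I = 25, shift_range = 12), "boundary")
})
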