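test_that("singular spectrum matches closed forms and the eigen oracle", {
  u <- c(3, 4) / 5; v <- c(1, 2, 2) / 3
  expect_equal(singular_spectrum(outer(u, v)), c(1, 0), tolerance = 1e-12)
  expect_equal(singular_spectrum(diag(2)), c(1, 1))
  set.seed(3)
  M <- matrix(rnorm(20), 5, 4)
  expect_equal(singular_spectrum(M),
               sqrt(rev(eigen(crossprod(M), symmetric = TRUE)$values)[4:1]),
               tolerance = 1e-10)
  expect_error(singular_spectrum(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("chemical rank counts values above the trailing-half noise floor", {
  est <- estimate_chemical_rank(c(100, 50, 20, rep(0.1, 5)))
  expect_identical(est$rank, 3L)
  expect_equal(est$noise_floor, 0.1)
  # noiseless rank-2 matrix built from two outer products
  M <- outer(1:6, 1:5) + outer(6:1, (1:5)^2)
  expect_identical(estimate_chemical_rank(singular_spectrum(M))$rank, 2L)
  expect_identical(estimate_chemical_rank(rep(2, 6))$rank, 0L)
  z <- estimate_chemical_rank(rep(0, 6))
  expect_identical(z$rank, 0L)
  expect_identical(z$noise_floor, 0)
  expect_error(estimate_chemical_rank(5), "at least 2")
})

test_that("rank estimate is scale invariant and stable under tiny noise", {
  cube <- build_peaky_trilinear_cube(30, 20, 5, 3, seed = 9)
  r1 <- trilinearity_report(cube$X)
  X2 <- three_way_array(cube$X$values * 1e4)
  r2 <- trilinearity_report(X2)
  expect_identical(r1$chemical_rank, r2$chemical_rank)
  set.seed(10)
  noisy <- cube$X$values +
    array(rnorm(length(cube$X$values), sd = 1e-6 * max(abs(cube$X$values))),
          dim(cube$X$values))
  r3 <- trilinearity_report(three_way_array(noisy))
  expect_identical(r1$chemical_rank, r3$chemical_rank)
})

test_that("scenario classification follows the augmented-mode rank pattern", {
  # exactly trilinear: all three ranks equal the number of components
  cube <- build_peaky_trilinear_cube(40, 24, 6, 3, seed = 2)
  rep_tri <- trilinearity_report(cube$X)
  expect_identical(unname(rep_tri$chemical_rank), c(3L, 3L, 3L))
  expect_identical(rep_tri$scenario, "trilinear")

  # shifted elution peaks: row-wise rank exceeds the column-wise rank
  sh <- simulate_lcdad(I = 150, J = 30, K = 6, N = 3, shift_range = 12,
                       noise_sd_rel = 0, seed = 4)
  rep_sh <- trilinearity_report(sh$data)
  expect_identical(rep_sh$chemical_rank[["columnwise"]], 3L)
  expect_gt(rep_sh$chemical_rank[["rowwise"]], 3L)
  expect_identical(rep_sh$scenario, "shifted_nontrilinear")

  # FIA speciation: 6 spectrally active species, 3 independent sample
  # amounts (acid/base pairs share theirs)
  fia <- simulate_fia(noise_sd_rel = 0, seed = 3)
  rep_fia <- trilinearity_report(fia$data)
  expect_identical(rep_fia$chemical_rank[["columnwise"]], 6L)
  expect_identical(rep_fia$chemical_rank[["slicewise"]], 3L)

  # proportional sample amounts on an otherwise trilinear cube:
  # rank-deficient sample mode
  set.seed(5)
  C <- cube$C; S <- cube$S
  Zdef <- cbind(runif(6, .3, 1), runif(6, .3, 1))
  Zdef <- cbind(Zdef, 0.5 * Zdef[, 1])   # third column proportional to first
  v <- array(0, c(40, 24, 6))
  for (k in 1:6) v[, , k] <- C %*% diag(Zdef[k, ]) %*% t(S)
  rep_def <- trilinearity_report(three_way_array(v))
  expect_identical(rep_def$scenario, "rank_deficient_sample_mode")
  expect_identical(rep_def$chemical_rank[["slicewise"]], 2L)
})
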