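test_that("coherence factors stay in [0,1] and hit the closed-form cases", {
  expect_equal(coherence_factor(rep(1, 4)), 1)
  expect_equal(coherence_factor(c(1, -1, 1, -1)), 0)
  expect_equal(coherence_factor(c(1, 1, 0, 0)), 0.5)
  expect_equal(coherence_factor(numeric(8)), 0)

  N <- 16L
  expect_equal(generalized_cf(rep(2.5, N), 0), 1)
  expect_equal(generalized_cf(rep(c(1, -1), N / 2), 1), 0)
  set.seed(11)
  x <- random_cx(N)
  expect_equal(generalized_cf(x, N / 2), 1, tolerance = 1e-12)

  # bounds + GCF monotone in M0, over many random vectors
  n_rand <- 1e5L
  X <- matrix(random_cx(8L * n_rand), 8L)
  cf <- Mod(colSums(X))^2 / (8 * colSums(Mod(X)^2))
  expect_true(all(cf >= 0 & cf <= 1 + 1e-12))
  S2 <- Mod(mvfft(X))^2
  tot <- colSums(S2)
  g_prev <- S2[1, ] / tot
  expect_true(all(g_prev >= 0 & g_prev <= 1 + 1e-12))
  for (M0 in 1:4) {
    ks <- unique(((-M0):M0) %% 8L) + 1L
    g <- colSums(S2[ks, , drop = FALSE]) / tot
    expect_true(all(g >= g_prev - 1e-12))
    g_prev <- g
  }
  expect_true(all(abs(g_prev - 1) < 1e-9))   # M0 = N/2 covers the whole band
})

test_that("aperture ASD matches the moment-formula oracle", {
  expect_equal(aperture_asd(rep(3.7, 8)), 0)
  expect_equal(aperture_asd(c(1, -1)), 1)
  set.seed(12)
  x <- random_cx(32)
  expect_equal(aperture_asd(x),
               sqrt(mean(Mod(x)^2) - Mod(mean(x))^2), tolerance = 1e-12)
})

test_that("ASD normalization is a reverse-ordered map onto (0, 1]", {
  expect_equal(normalize_asd(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_asd(c(1, 8)), c(1, 0.5))
  set.seed(13)
  s <- runif(50, 0.1, 5)
  sp <- normalize_asd(s)
  expect_equal(max(sp), 1)
  expect_identical(order(sp), rev(order(s)))
  expect_error(normalize_asd(c(0, 0)), "degenerate")
})

test_that("dynamic subarray length floors and clamps", {
  expect_identical(dynamic_subarray_length(1, 32L), 32L)
  expect_identical(dynamic_subarray_length(0.51, 32L), 16L)
  expect_identical(dynamic_subarray_length(0.05, 32L), 2L)
})

test_that("spatial smoothing, rotary averaging, and diagonal reducing are exact", {
  expect_equal(unclass(smooth_covariance(rep(1+0i, 4), 2)),
               matrix(1+0i, 2, 2))
  set.seed(14)
  for (i in 1:20) {
    N <- sample(4:16, 1); Lp <- sample(2:N, 1)
    x <- random_cx(N)
    got <- smooth_covariance(x, Lp)
    expect_equal(dim(got), c(Lp, Lp))
    expect_lt(max(Mod(got - Conj(t(got)))), 1e-12)
    ref <- oracle_smooth(x, Lp)
    expect_lt(max(Mod(got - ref)) / max(Mod(ref)), 1e-12)
  }

  expect_equal(rotary_average(diag(2) + 0i), matrix(0.5+0i, 2, 2))
  ones3 <- matrix(1+0i, 3, 3)
  expect_equal(rotary_average(ones3), ones3)
  R3 <- matrix(random_cx(9), 3)
  expect_lt(max(Mod(rotary_average(R3) - oracle_rotary(R3))), 1e-14)
  # idempotent on symmetric-persymmetric matrices
  Rsp <- oracle_rotary((R3 + t(R3)) / 2)
  expect_lt(max(Mod(rotary_average(Rsp) - Rsp)), 1e-12)

  D <- diag(c(2, 4)) + 0i
  expect_equal(diagonal_reduce(D, 0), D)
  expect_equal(diagonal_reduce(D, 0.5), diag(c(1, 2)) + 0i)
  R2 <- matrix(random_cx(4), 2)
  z <- diagonal_reduce(R2, 1)
  expect_true(all(Mod(diag(z)) == 0))
  expect_identical(z[1, 2], R2[1, 2])
  expect_error(diagonal_reduce(D, 1.5), "\\[0, 1\\]")
})

test_that("matrix MSR matches hand arithmetic and guards degeneracy", {
  expect_equal(matrix_msr(matrix(c(0, 1, 1, 0), 2)), 1)
  expect_equal(matrix_msr(matrix(c(1, 3, 2, 4), 2)), 2.5 / sqrt(1.25))
  expect_equal(matrix_msr(matrix(5, 3, 3), cap = 1e6), 1e6)
  expect_equal(matrix_msr(matrix(0, 3, 3)), 0)
  set.seed(15)
  M <- matrix(random_cx(16), 4)
  expect_equal(matrix_msr(M), oracle_msr(M), tolerance = 1e-12)
})

test_that("adaptive delta follows the coherence power law", {
  expect_equal(adaptive_delta(1, 0.7, 0.8), 0.8)
  expect_equal(adaptive_delta(0.25, 0.5, 1), 0.5)
  expect_equal(adaptive_delta(0, 0.5, 1), 0)
})

test_that("CMSF weight equals its closed form for coherent input and ranks clutter low", {
  cfg <- bf_config(16L, delta = 1)
  # coherent x = ones, delta = 1: all-ones covariance, diagonal zeroed,
  # two-level matrix -> MSR = sqrt(L' - 1) (independent closed form)
  sp <- 1
  Lp <- dynamic_subarray_length(sp, cfg$L_max)
  expect_equal(cmsf_weight(rep(1+0i, 16), sp, cfg), sqrt(Lp - 1),
               tolerance = 1e-12)

  # strong off-axis (alternating) sits strictly below coherent at equal L'
  expect_lt(cmsf_weight(rep(c(1, -1) + 0i, 8), sp, cfg),
            cmsf_weight(rep(1+0i, 16), sp, cfg))

  # composition identity: pipeline equals step-by-step chaining
  set.seed(16)
  x <- random_cx(16)
  sp2 <- 0.63
  ref <- matrix_msr(diagonal_reduce(rotary_average(
    smooth_covariance(x, dynamic_subarray_length(sp2, cfg$L_max))),
    cfg$delta), cfg$msr_cap)
  expect_equal(cmsf_weight(x, sp2, cfg), ref, tolerance = 1e-14)
})

test_that("CMSAW reduces to its limiting cases and chains the adaptive delta", {
  # W_CF = 1 pixels: CMSAW equals CMSF with delta = delta_max
  cfg <- bf_config(16L, delta = 0.6, delta_max = 0.6)
  expect_equal(cmsaw_weight(rep(1+0i, 16), 0.8, cfg),
               cmsf_weight(rep(1+0i, 16), 0.8, cfg), tolerance = 1e-12)

  # delta_max = 0: MSR of the rotary-averaged matrix, no reducing
  cfg0 <- bf_config(16L, delta_max = 0)
  set.seed(17)
  x <- random_cx(16)
  sp <- 0.77
  ref0 <- matrix_msr(rotary_average(smooth_covariance(
    x, dynamic_subarray_length(sp, cfg0$L_max))), cfg0$msr_cap)
  expect_identical(cmsaw_weight(x, sp, cfg0), ref0)

  # generic composition oracle
  cfg1 <- bf_config(16L, delta_max = 0.9)
  dac <- adaptive_delta(coherence_factor(x), sp, 0.9)
  ref1 <- matrix_msr(diagonal_reduce(rotary_average(smooth_covariance(
    x, dynamic_subarray_length(sp, cfg1$L_max))), dac), cfg1$msr_cap)
  expect_equal(cmsaw_weight(x, sp, cfg1), ref1, tolerance = 1e-14)
})

test_that("canonical aperture-vector categories rank as expected", {
  fx <- make_fixtures(1L)
  w <- fx$golden$cmsf
  expect_lt(w[["alternating"]], w[["coherent"]])
  expect_lt(w[["noise"]], w[["coherent"]])
})

test_that("weight maps multiply images element-wise", {
  set.seed(18)
  img <- matrix(random_cx(12), 3)
  expect_identical(apply_pixel_weight(matrix(1, 3, 4), img), 1 * img)
  expect_true(all(apply_pixel_weight(matrix(0, 3, 4), img) == 0))
  expect_error(apply_pixel_weight(matrix(1, 2, 2), img), "dimensions")

  # GCF map applied to MV reproduces the GCF-MV pipeline image
  r <- toy_run()
  expect_identical(r$images$images$`GCF-MV`,
                   apply_pixel_weight(r$images$weights$gcf,
                                      r$images$images$MV))
})

test_that("adaptive speckle preservation holds end-to-end at full aperture", {
  r <- full_run()
  expect_lte(metric_of(r, "CMSAW-MV", "cr_db"), metric_of(r, "MV", "cr_db"))
  expect_gte(metric_of(r, "CMSAW-MV", "ssnr"), metric_of(r, "CMSF-MV", "ssnr"))
})
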