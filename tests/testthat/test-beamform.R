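test_that("DAS pixel values follow the transmit window", {
  expect_equal(das_pixel(rep(1, 4)), 4)
  expect_equal(das_pixel(rep(c(1, -1), 3)), 0)
  set.seed(4)
  x <- random_cx(8)
  ex <- (seq_len(8) - 4.5) * 0.3e-3
  wh <- aperture_window(ex, window = "hamming")
  expect_equal(das_pixel(x, ex, window = "hamming"), sum(wh * x),
               tolerance = 1e-14)
})

test_that("smoothed covariance matches the brute-force loop oracle", {
  R <- mv_covariance(rep(1+0i, 4), 2)
  expect_equal(unclass(R)[1:2, 1:2], matrix(1+0i, 2, 2), ignore_attr = TRUE)

  set.seed(5)
  for (i in 1:20) {
    N <- sample(4:16, 1)
    L <- sample(2:N, 1)
    K <- sample(0:2, 1)
    xs <- matrix(random_cx(N * (2 * K + 1)), N)
    got <- mv_covariance(xs, L)
    ref <- oracle_cov(xs, L)
    expect_lt(max(Mod(got - ref)) / max(Mod(ref)), 1e-12)
    expect_lt(max(Mod(got - Conj(t(got)))), 1e-10)
    expect_gt(min(Re(eigen(got, symmetric = TRUE, only.values = TRUE)$values)),
              -1e-8 * Re(sum(diag(got))))
  }
  expect_error(mv_covariance(random_cx(4), 5), "exceeds")
})

test_that("diagonal loading shifts the spectrum by delta * trace", {
  expect_equal(diagonal_load(diag(2) + 0i, 0.05), 1.1 * diag(2) + 0i)

  set.seed(6)
  L <- 8L
  R <- random_hermitian_psd(L)
  Rh <- diagonal_load(R, 0.1 / L)
  expect_equal(Re(sum(diag(Rh))), 1.1 * Re(sum(diag(R))), tolerance = 1e-12)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  evh <- eigen(Rh, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(evh, ev + 0.1 / L * Re(sum(diag(R))), tolerance = 1e-10)

  expect_warning(diagonal_load(matrix(0+0i, 2, 2), 0.1), "zero-trace")
})

test_that("MV weights satisfy the distortionless constraint and minimize power", {
  expect_equal(mv_weights(diag(4) + 0i), rep(0.25+0i, 4))
  expect_equal(mv_weights(diag(c(1, 2)) + 0i), c(2/3, 1/3) + 0i,
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    L <- sample(3:12, 1)
    Rh <- diagonal_load(random_hermitian_psd(L), 0.1 / L)
    w <- mv_weights(Rh)
    expect_lt(Mod(sum(Conj(w)) - 1), 1e-10)
    # Capon optimality vs the uniform vector
    p_mv <- Re(Conj(w) %*% Rh %*% w)
    p_das <- Re(rep(1 / L, L) %*% Rh %*% rep(1 / L, L))
    expect_lte(p_mv, p_das + 1e-12)
  }

  # dense-grid oracle on L = 2
  for (i in 1:5) {
    Rh <- diagonal_load(random_hermitian_psd(2), 0.05)
    w <- mv_weights(Rh)
    p <- Re(Conj(w) %*% Rh %*% w)
    expect_lte(p, oracle_mv_power_min2(Rh) + 1e-6)
  }
})

test_that("MV pixel output honors the subarray average and the unit constraint", {
  cfg <- bf_config(8L, L = 4L, K = 0L)
  expect_equal(mv_pixel(rep(1+0i, 8), cfg), 1+0i, tolerance = 1e-10)

  # handmade two-subarray check, N = 4, L = 2 (identity covariance route)
  x <- c(1, 2, 3, 4) + 0i
  cfg4 <- bf_config(4L, L = 2L, K = 0L)
  R <- mv_covariance(x, 2L)
  w <- mv_weights(diagonal_load(R, cfg4$delta_load))
  manual <- (sum(Conj(w) * x[1:2]) + sum(Conj(w) * x[2:3]) +
               sum(Conj(w) * x[3:4])) / 3
  expect_equal(mv_pixel(x, cfg4), manual, tolerance = 1e-12)

  # L = N degenerate: single subarray, output = w^H x
  cfgN <- bf_config(4L, L = 4L, K = 0L)
  set.seed(8)
  xr <- random_cx(4)
  wN <- mv_weights(diagonal_load(mv_covariance(xr, 4L), cfgN$delta_load))
  expect_equal(mv_pixel(xr, cfgN), sum(Conj(wN) * xr), tolerance = 1e-12)
})

test_that("ESBMV projects onto the dominant eigen-subspace", {
  # diag(4,1), gamma = 0.5: signal space is the first axis
  cfg <- bf_config(4L, L = 2L, K = 0L, gamma = 0.5)
  Rh <- diag(c(4, 1)) + 0i
  w <- mv_weights(Rh)
  e <- eigen(Rh, symmetric = TRUE)
  Es <- e$vectors[, 1, drop = FALSE]
  w_proj <- as.vector(Es %*% (Conj(t(Es)) %*% w))
  expect_equal(Mod(w_proj), c(Mod(w[1]), 0), tolerance = 1e-12)

  set.seed(9)
  xs <- matrix(random_cx(8 * 3), 8)
  cfg8 <- bf_config(8L, L = 4L, K = 1L, gamma = 1e-12)
  expect_identical(esbmv_pixel(xs, cfg8), mv_pixel(xs, cfg8))

  # projector idempotent + Hermitian, and output equals a full-eigen oracle
  cfg_g <- bf_config(8L, L = 4L, K = 1L, gamma = 0.5)
  R <- mv_covariance(xs, 4L)
  Rh2 <- diagonal_load(R, cfg_g$delta_load)
  e2 <- eigen(Rh2, symmetric = TRUE)
  sel <- e2$values >= cfg_g$gamma * e2$values[1]
  Es2 <- e2$vectors[, sel, drop = FALSE]
  P <- Es2 %*% Conj(t(Es2))
  expect_lt(max(Mod(P %*% P - P)), 1e-10)
  expect_lt(max(Mod(P - Conj(t(P)))), 1e-10)
  w2 <- mv_weights(Rh2)
  xc <- xs[, 2]
  manual <- mean(vapply(1:5, function(l)
    sum(Conj(as.vector(P %*% w2)) * xc[l:(l + 3)]), 0+0i))
  expect_equal(esbmv_pixel(xs, cfg_g), manual, tolerance = 1e-10)
})

test_that("compiled image passes agree with the per-pixel reference chain", {
  set.seed(10)
  N <- 16L; Pz <- 7L; Px <- 3L
  A <- matrix(random_cx(N * Pz * Px), N)
  cfg <- bf_config(N, L = 8L, K = 2L, gamma = 0.5)

  p1 <- cmsaw:::pass1_cpp(A, rep(1, N), cfg$M0)
  sp <- normalize_asd(matrix(p1$sigma, Pz, Px), cfg$asd_exponent)
  p2 <- cmsaw:::pass2_cpp(A, Pz, Px, as.vector(sp), p1$cf,
                          cfg$L, cfg$K, cfg$delta_load, cfg$gamma,
                          cfg$L_max, cfg$delta, cfg$delta_max, cfg$msr_cap,
                          TRUE, TRUE, TRUE, TRUE)
  for (ix in seq_len(Px)) for (iz in seq_len(Pz)) {
    p <- (ix - 1L) * Pz + iz
    x <- A[, p]
    expect_equal(p1$das[p], sum(x), tolerance = 1e-12)
    expect_equal(p1$cf[p], coherence_factor(x), tolerance = 1e-12)
    expect_equal(p1$gcf[p], generalized_cf(x, cfg$M0), tolerance = 1e-12)
    expect_equal(p1$sigma[p], aperture_asd(x), tolerance = 1e-12)
    kmax <- min(cfg$K, iz - 1L, Pz - iz)
    xs <- A[, (p - kmax):(p + kmax), drop = FALSE]
    expect_equal(p2$mv[p], mv_pixel(xs, cfg), tolerance = 1e-8)
    expect_equal(p2$esbmv[p], esbmv_pixel(xs, cfg), tolerance = 1e-8)
    expect_equal(p2$w_cmsf[p], cmsf_weight(x, sp[iz, ix], cfg),
                 tolerance = 1e-8)
    expect_equal(p2$w_cmsaw[p], cmsaw_weight(x, sp[iz, ix], cfg),
                 tolerance = 1e-8)
  }
})

test_that("on the toy phantom MV resolves the point better than DAS", {
  r <- toy_run()
  expect_lt(metric_of(r, "MV", "fwhm_mm"), metric_of(r, "DAS", "fwhm_mm"))
})
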