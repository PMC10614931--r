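test_that("theoretical_phi is exactly 1/M under identity LD", {
  w <- toy_weights(m = 30)
  expect_identical(theoretical_phi(w, diag(30), M = 999), 1 / 999)
  expect_identical(theoretical_phi(w, diag(30)), 1 / 30)
  # degree-0 homogeneity: rescaling the weights changes nothing
  expect_equal(theoretical_phi(2 * w$weights, diag(30)),
               theoretical_phi(w$weights, diag(30)), tolerance = 1e-15)
})

test_that("theoretical_phi matches brute-force quadratic-form arithmetic", {
  # 3x3 exchangeable rho = 0.5, gamma = (1,1,0), M = 3
  sigma <- matrix(0.5, 3, 3)
  diag(sigma) <- 1
  g <- c(1, 1, 0)
  num <- 0
  den <- 0
  for (j in 1:3) for (k in 1:3) {
    den <- den + g[j] * sigma[j, k] * g[k]
    for (l in 1:3) num <- num + g[j] * sigma[j, l] * sigma[l, k] * g[k]
  }
  expect_equal(theoretical_phi(g, sigma, M = 3), num / (3 * den),
               tolerance = 1e-12)
  expect_equal(theoretical_phi(g, sigma, M = 3), 5.5 / 9, tolerance = 1e-12)

  # a larger dense-LD example against the same elementwise oracle
  ld <- ld_spec(7, block_sizes = c(4, 3),
                within_block_correlation = c(0.7, 0.3))
  sigma7 <- ld_matrix(ld)
  g7 <- c(0.3, -1.2, 0, 0.5, 2, -0.7, 0.1)
  num <- den <- 0
  for (j in 1:7) for (k in 1:7) {
    den <- den + g7[j] * sigma7[j, k] * g7[k]
    for (l in 1:7) num <- num + g7[j] * sigma7[j, l] * sigma7[l, k] * g7[k]
  }
  expect_equal(theoretical_phi(g7, sigma7, M = 7), num / (7 * den),
               tolerance = 1e-12)
})

test_that("theoretical_phi pads sparse weights and rejects null-space weights", {
  sigma <- diag(5)
  rownames(sigma) <- paste0("snp_", 1:5)
  w <- weight_set("g", c("snp_4", "snp_2"), c(1, -2))
  expect_equal(theoretical_phi(w, sigma), 1 / 5)
  # weights annihilated by a rank-deficient sigma are an error, not 0
  sing <- matrix(1, 3, 3)
  expect_error(theoretical_phi(c(1, -1, 0), sing), "null space")
})

test_that("expected_z_variance follows 1 + N h2 phi and is monotone", {
  expect_equal(expected_z_variance(1000, 0, 1 / 999), 1)
  expect_equal(expected_z_variance(1000, 0.5, 0), 1)
  expect_equal(expected_z_variance(1000, 0.5, 1 / 999), 1 + 500 / 999)
  expect_error(expected_z_variance(1000, 0.5, -1e-5), ">= 0")
  grid <- expand.grid(N = c(10, 100, 1000), h2 = c(0.1, 0.5, 0.9),
                      phi = c(1e-5, 1e-3))
  v <- with(grid, expected_z_variance(N, h2, phi))
  for (col in names(grid)) {
    for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
      other <- setdiff(names(grid), col)
      if (all(grid[i, other] == grid[j, other]) &&
          grid[i, col] < grid[j, col]) {
        expect_lt(v[i], v[j])
      }
    }
  }
})

test_that("expected_z2_alternative reduces to the null formula at beta 0", {
  set.seed(10)
  for (rep in 1:25) {
    spec <- alternative_spec(beta = 0, tau2 = runif(1, 0.1, 1),
                             sigma_T2 = runif(1, 0.5, 2),
                             sigma_Y2 = runif(1, 0.5, 2),
                             h2_delta = runif(1, 0, 0.9))
    N <- sample(1000:100000, 1)
    phi <- runif(1, 0, 1e-4)
    expect_equal(expected_z2_alternative(spec, N, phi),
                 expected_z_variance(N, spec$h2_delta, phi),
                 tolerance = 1e-12)
  }
  # pure-signal term with no polygenic channel
  spec <- alternative_spec(beta = 0.2, tau2 = 0.8, sigma_T2 = 1,
                           sigma_Y2 = 1, h2_delta = 0)
  expect_equal(expected_z2_alternative(spec, 5000, 0),
               1 + 5000 * 0.8 * 0.04 / (1 - 0.8 * 0.04), tolerance = 1e-12)
})

test_that("simulation_grid rejects unidentifiable designs", {
  expect_error(simulation_grid(c(1000, 2000), 0), "unidentifiable")
  expect_error(simulation_grid(1000, c(0, 0.5, 1)), "\\[0, 1\\)")
  g <- simulation_grid(c(1000, 2000), c(0, 0.5), 50, seed = 3)
  expect_equal(nrow(g$cells), 4L)
})

test_that("empirical phi recovers the identity-LD oracle on a small fixture", {
  G <- simulate_genotypes(2000, identity_ld(100), seed = 21)
  w <- simulate_mediator_weights(100, seed = 22)
  grid <- simulation_grid(c(500, 1000, 2000), c(0, 0.4, 0.8),
                          n_reps_per_cell = 200, seed = 23)
  est <- estimate_phi_empirical(G, w, grid)
  expect_s3_class(est, "phi_estimate")
  expect_lt(abs(est$phi - 1 / 100), 3 * est$se)
  expect_lt(abs(est$intercept - 1), 3 * est$intercept_se)
  expect_gt(est$r_squared, 0.9)
  expect_false(est$clamped)
  expect_equal(est$phi, max(est$phi_raw, 0))
  # determinism of the whole grid machinery
  est2 <- estimate_phi_empirical(G, w, grid)
  expect_identical(est$cells$mean_z2, est2$cells$mean_z2)
})

test_that("negative raw slopes are clamped to zero and flagged", {
  G <- simulate_genotypes(200, identity_ld(150), seed = 42)
  w <- simulate_mediator_weights(150, seed = 43)
  # tiny-replicate grid in a near-zero-slope regime: raw slope goes
  # negative by Monte Carlo noise
  grid <- simulation_grid(c(50, 100), c(0, 0.5), n_reps_per_cell = 5,
                          seed = 3)
  est <- estimate_phi_empirical(G, w, grid)
  expect_lt(est$phi_raw, 0)
  expect_identical(est$phi, 0)
  expect_true(est$clamped)
  expect_gt(est$se, 0)
})

test_that("empirical phi precondition failures are informative", {
  G <- simulate_genotypes(100, identity_ld(20), seed = 1)
  w <- toy_weights(m = 20)
  grid <- simulation_grid(c(500, 1000), c(0, 0.5), 10, seed = 1)
  expect_error(estimate_phi_empirical(G, w, grid), "grid asks for N")
})
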