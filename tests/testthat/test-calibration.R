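test_that("z_sample_variance is the mean squared Z by default", {
  expect_equal(z_sample_variance(c(1, -1, 1, -1)), 1)
  expect_equal(z_sample_variance(rep(0, 5)), 0)
  expect_equal(z_sample_variance(c(2, 2), center = TRUE), 0)
  expect_error(z_sample_variance(1), "at least 2")
  z <- withr::with_seed(5, rnorm(1000))
  iv <- null_variance_interval(1000, 0.95)
  v <- z_sample_variance(z)
  expect_gt(v, iv[1])
  expect_lt(v, iv[2])
})

test_that("null_variance_interval matches the chi-square reference", {
  iv <- null_variance_interval(1000, 0.95)
  expect_equal(iv, 1 + c(-1, 1) * qnorm(0.975) * sqrt(2 / 1000),
               tolerance = 1e-12)
  expect_equal(iv[1], 0.912, tolerance = 1e-3)
  expect_equal(iv[2], 1.088, tolerance = 1e-3)
  # exact gamma endpoints agree closely at n = 1000
  ivg <- null_variance_interval(1000, 0.95, method = "gamma")
  expect_lt(max(abs(iv - ivg)), 0.005)
  # the interval collapses onto 1 as n grows
  iv_big <- null_variance_interval(1e7, 0.95)
  expect_lt(max(abs(iv_big - 1)), 1e-3)
})

test_that("uniformity_test implements the one-sample KS statistic", {
  n <- 100
  grid <- (seq_len(n) - 0.5) / n
  u <- uniformity_test(grid)
  expect_equal(u$ks_stat, 0.5 / n, tolerance = 1e-12)
  expect_equal(uniformity_test(rep(0.5, 50))$ks_stat, 0.5)
  expect_error(uniformity_test(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(uniformity_test(c(0.5, 1.2)), "\\(0, 1\\]")
  # level: uniform draws are rarely rejected
  ok <- vapply(1:100, function(s)
    uniformity_test(withr::with_seed(s, runif(1000)))$ks_p > 0.01,
    logical(1))
  expect_gte(sum(ok), 98)
})

test_that("qq_points returns sorted -log10 coordinates, thinned", {
  n <- 200
  p <- (seq_len(n)) / (n + 1)
  q <- qq_points(p)
  expect_equal(nrow(q), n)
  expect_false(is.unsorted(q$expected))
  expect_equal(q$observed, q$expected, tolerance = 1e-12)

  # inflation shows up as tail points above the diagonal
  p_infl <- p
  p_infl[seq(1, n, 2)] <- p_infl[seq(1, n, 2)] / 100
  qi <- qq_points(p_infl)
  tail_pts <- qi[qi$expected > 1.5, ]
  expect_true(all(tail_pts$observed > tail_pts$expected))

  expect_equal(nrow(qq_points(p, n_points = 1e6)), n)
  expect_lte(nrow(qq_points(p, n_points = 50)), 50)
})

test_that("calibration_report flags inflated and calibrated Z sets", {
  z_null <- withr::with_seed(9, rnorm(1000))
  rep_null <- calibration_report(z_null)
  expect_equal(rep_null$n_tests, 1000L)
  expect_gt(rep_null$ks_p, 0.01)
  expect_lt(rep_null$z_sample_variance, rep_null$z_var_null_interval[2])

  z_infl <- withr::with_seed(9, rnorm(1000, sd = sqrt(2)))
  rep_infl <- calibration_report(z_infl)
  expect_lt(rep_infl$ks_p, 0.01)
  expect_gt(rep_infl$z_sample_variance, rep_infl$z_var_null_interval[2])
})

test_that("toy pipeline separates polygenic from non-polygenic traits", {
  # reduced-size version of the single-mediator experiment: the average
  # squared Z over replicates sits inside the chi-square reference band
  # for non-polygenic traits and above it for strongly polygenic ones
  n <- 500
  m <- 499
  reps <- 400
  G <- simulate_genotypes(n, identity_ld(m), seed = 61)
  w <- simulate_mediator_weights(m, seed = 62)
  tp <- predict_mediator(G, w)
  z_null <- vapply(seq_len(reps), function(r)
    association_test(tp, simulate_null_trait(n, seed = 6000 + r))$z,
    numeric(1))
  z_poly <- vapply(seq_len(reps), function(r)
    association_test(tp, simulate_polygenic_trait(G, 0.6,
                                                  seed = 7000 + r))$z,
    numeric(1))
  iv <- null_variance_interval(reps, 0.99)
  expect_gt(z_sample_variance(z_null), iv[1])
  expect_lt(z_sample_variance(z_null), iv[2])
  expect_gt(z_sample_variance(z_poly), iv[2])
  # and the polygenic variance is near its analytic value 1 + N h2 / M
  expect_lt(abs(z_sample_variance(z_poly) - (1 + n * 0.6 / m)),
            3 * sd(z_poly^2) / sqrt(reps))
})

test_that("null traits are uncorrelated with predicted mediators on average", {
  n <- 200
  G <- toy_genotypes(n = n, m = 40, seed = 71)
  tp <- predict_mediator(G, toy_weights(m = 40, seed = 72))
  Y <- withr::with_seed(73, matrix(rnorm(n * 1000), n, 1000))
  r <- drop(cor(tp, Y))
  expect_lt(abs(mean(r)), 3 / sqrt(1000 * n))
})
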