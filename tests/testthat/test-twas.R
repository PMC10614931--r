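test_that("predict_mediator is the weighted sum of dosage columns", {
  D <- matrix(c(1, 0, 1, 0, 2, 1), nrow = 3) # [[1,0],[0,2],[1,1]]
  G <- genotype_matrix(D, variant_ids = c("v1", "v2"))
  w <- weight_set("g1", c("v1", "v2"), c(0.5, -1))
  expect_equal(as.numeric(predict_mediator(G, w)), c(0.5, -2, -0.5))

  # selector and annihilator limits
  sel <- weight_set("g2", c("v2"), 1)
  expect_equal(as.numeric(predict_mediator(G, sel)), D[, 2])
  ann <- weight_set("g3", c("v1", "v2"), c(1, 0))
  expect_equal(as.numeric(predict_mediator(G, ann)), D[, 1])
})

test_that("missing-variant policy errors by default, drops on request", {
  G <- toy_genotypes(n = 50, m = 5)
  w <- weight_set("g", c("snp_1", "nope_1", "nope_2"), c(1, 2, 3))
  expect_error(predict_mediator(G, w), "missing from the genotype matrix")
  expect_warning(t_drop <- predict_mediator(G, w, missing = "drop"),
                 "dropping 2")
  expect_equal(as.numeric(t_drop), G$dosages[, 1])
  all_gone <- weight_set("g", c("x", "y"), c(1, 1))
  expect_error(predict_mediator(G, all_gone, missing = "drop"),
               "all model variants")
})

test_that("association_test matches the closed-form OLS oracle", {
  x <- c(1.2, -0.4, 0.7, 2.2, -1.5, 0.3)
  y <- c(0.5, 0.1, -0.2, 1.9, -1.0, 0.4)
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  res <- association_test(x, y)
  expect_equal(res$beta_hat, sm["x", "Estimate"], tolerance = 1e-10)
  expect_equal(res$se, sm["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(res$z, sm["x", "t value"], tolerance = 1e-10)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
})

test_that("orthogonal and self-regression limits behave", {
  x <- c(-1.5, -0.5, 0.5, 1.5)
  y_orth <- c(1, -1, -1, 1) # uncorrelated with x in-sample
  res <- association_test(x, y_orth)
  expect_equal(res$beta_hat, 0)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  set.seed(1)
  y <- rnorm(10)
  res2 <- association_test(y + rnorm(10, sd = 1e-4), y)
  expect_gt(abs(res2$z), 50)
  expect_lt(res2$p, 1e-100)

  expect_error(association_test(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(association_test(1:10, 2 * (1:10) + 3), "perfect fit")
  expect_error(association_test(1:2, rnorm(2)), "at least 3")
})

test_that("z is scale-equivariant and location-invariant", {
  set.seed(42)
  x <- rnorm(60)
  y <- 0.3 * x + rnorm(60)
  base <- association_test(x, y)
  for (c_scale in c(0.01, -3)) {
    r <- association_test(c_scale * x, y)
    expect_equal(r$beta_hat, base$beta_hat / c_scale, tolerance = 1e-10)
    expect_equal(r$z, sign(c_scale) * base$z, tolerance = 1e-10)
    expect_equal(r$p, base$p, tolerance = 1e-10)
  }
  r2 <- association_test(x + 100, y - 50)
  expect_equal(r2$z, base$z, tolerance = 1e-8)
})

test_that("run_twas tests every usable mediator and logs skips", {
  G <- toy_genotypes(n = 120, m = 20)
  W <- lapply(1:5, function(k)
    simulate_mediator_weights(20, seed = 300 + k,
                              mediator_id = paste0("med_", k)))
  y <- simulate_null_trait(120, seed = 77)
  res <- run_twas(G, W, y)
  expect_equal(nrow(res), 5L)
  expect_equal(res$mediator_id, paste0("med_", 1:5))
  # batch path agrees with the scalar test
  one <- association_test(predict_mediator(G, W[[3]]), y)
  expect_equal(res$z[3], one$z, tolerance = 1e-12)
  expect_equal(res$p[3], one$p, tolerance = 1e-12)

  # a mediator with all variants missing is skipped with a logged reason
  W2 <- c(W, list(weight_set("ghost", c("no_such"), 1)))
  expect_message(res2 <- run_twas(G, W2, y), "skipped 1 mediator")
  expect_equal(nrow(res2), 5L)
  expect_equal(attr(res2, "skipped")$mediator_id, "ghost")

  dup <- c(W, list(simulate_mediator_weights(20, seed = 301,
                                             mediator_id = "med_1")))
  expect_error(run_twas(G, dup, y), "duplicate mediator_id")
  expect_error(run_twas(G, list(weight_set("ghost", "no_such", 1)), y),
               "no usable mediator")
})

test_that("p-values are jointly uniform for a non-polygenic null trait", {
  G <- toy_genotypes(n = 200, m = 30, seed = 55)
  W <- lapply(1:100, function(k)
    simulate_mediator_weights(30, seed = 400 + k,
                              mediator_id = paste0("med_", k)))
  ok <- vapply(1:10, function(s) {
    y <- simulate_null_trait(200, seed = 5000 + s)
    uniformity_test(run_twas(G, W, y)$p)$ks_p > 0.01
  }, logical(1))
  expect_gte(sum(ok), 9)
})
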