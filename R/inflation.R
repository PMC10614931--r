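#' Closed-form inflation slope from weights and LD
#'
#' The per-mediator inflation slope is the LD quadratic-form ratio
#' \deqn{\Phi = \frac{1}{M}\,
#'   \frac{\tilde\gamma' \Sigma^2 \tilde\gamma}
#'        {\tilde\gamma' \Sigma \tilde\gamma},}
#' where \eqn{\Sigma} is the variant correlation (LD) matrix, \eqn{M} the
#' effective number of causal variants of the target trait, and
#' \eqn{\tilde\gamma} the prediction weights. Under a polygenic null the
#' Z-score variance is `1 + N * h2 * Phi`. The ratio is invariant to
#' rescaling of the weights.
#'
#' @param w A `weight_set`, or a bare numeric weight vector.
#' @param sigma LD correlation matrix (symmetric PSD), or an [ld_spec()].
#'   When `sigma` has row names (or comes from an `ld_spec` paired with
#'   named weights) the weight vector is matched by variant id and padded
#'   with zeros to the dimension of `sigma`; otherwise lengths must agree.
#' @param M Effective number of causal variants (`M >= 1`). Defaults to
#'   `nrow(sigma)`, the convention for fully polygenic simulated traits
#'   where every variant is causal.
#' @return The scalar inflation slope `Phi >= 0`.
#' @examples
#' w <- simulate_mediator_weights(10, seed = 1)
#' theoretical_phi(w, diag(10))  # identity LD: exactly 1/M
#' @export
theoretical_phi <- function(w, sigma, M = NULL) {
  if (inherits(sigma, "ld_spec")) sigma <- ld_matrix(sigma)
  sigma <- as.matrix(sigma)
  m <- nrow(sigma)
  if (ncol(sigma) != m) stop("sigma must be square")
  if (max(abs(sigma - t(sigma))) > 1e-10) stop("sigma must be symmetric")
  if (is.null(M)) M <- m
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (inherits(w, "weight_set")) {
    gamma <- numeric(m)
    if (!is.null(rownames(sigma))) {
      pos <- match(w$variant_ids, rownames(sigma))
      if (anyNA(pos)) stop("model variants missing from sigma's row names")
      gamma[pos] <- w$weights
    } else {
      if (length(w$weights) > m) stop("weight vector longer than dim(sigma)")
      gamma[seq_along(w$weights)] <- w$weights
    }
  } else {
    gamma <- as.numeric(w)
    if (length(gamma) > m) stop("weight vector longer than dim(sigma)")
    gamma <- c(gamma, numeric(m - length(gamma)))
  }
  sg <- drop(sigma %*% gamma)
  q1 <- sum(gamma * sg)
  if (q1 <= .Machine$double.eps * max(1, sum(gamma^2))) {
    stop("gamma' Sigma gamma = 0: the weights lie in the null space of ",
         "the LD matrix, Phi is undefined")
  }
  sum(sg^2) / (M * q1)
}

#' Simulation grid for empirical inflation-slope estimation
#'
#' The design over which polygenic null traits are simulated: the cross of
#' sample sizes `N` and heritabilities `h2` (or an explicit set of cells),
#' with `n_reps_per_cell` null traits per cell.
#'
#' @param N Integer vector of GWAS sample sizes.
#' @param h2 Numeric vector of trait heritabilities in `[0, 1)`.
#' @param n_reps_per_cell Replicates per cell (default 300).
#' @param seed Integer seed driving all randomness of the estimation.
#' @return A `simulation_grid` with a `cells` data.frame.
#' @export
simulation_grid <- function(N, h2, n_reps_per_cell = 300, seed = 1) {
  cells <- expand.grid(N = as.integer(N), h2 = as.numeric(h2),
                       KEEP.OUT.ATTRS = FALSE)
  if (any(cells$N < 3)) stop("all N must be >= 3")
  if (any(cells$h2 < 0 | cells$h2 >= 1)) stop("all h2 must lie in [0, 1)")
  if (length(unique(cells$N * cells$h2)) < 2L) {
    stop("grid is unidentifiable: need at least 2 distinct values of N*h2 ",
         "to estimate a slope")
  }
  structure(list(cells = cells,
                 n_reps_per_cell = as.integer(n_reps_per_cell),
                 seed = as.integer(seed)),
            class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat("simulation_grid:", nrow(x$cells), "cells x", x$n_reps_per_cell,
      "reps (seed", paste0(x$seed, ")"), "\n")
  cat("  N:", paste(sort(unique(x$cells$N)), collapse = ", "), "\n")
  cat("  h2:", paste(sort(unique(x$cells$h2)), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical inflation-slope estimate from a simulation grid
#'
#' For each grid cell `(N, h2)`: subsample `N` individuals from the
#' reference genotypes (without replacement), simulate `n_reps_per_cell`
#' polygenic null traits at heritability `h2`, regress each on the
#' predicted mediator, and average the squared Z-scores. The inflation
#' slope is the ordinary-least-squares coefficient of the cell-mean
#' \eqn{\bar{Z^2}} on \eqn{N h^2}, with a free intercept (its closeness to
#' 1 is a calibration diagnostic). Negative slope estimates are clamped to
#' zero, the lowest admissible value, with `clamped = TRUE`.
#'
#' @param G_ref Reference `genotype_matrix` with at least `max(N)` rows.
#' @param w The mediator's `weight_set`.
#' @param grid A [simulation_grid()].
#' @param effect_dist,df,noise_dist Trait-simulation options, as in
#'   [simulate_polygenic_trait()].
#' @param fix_intercept Force the regression intercept to 1 instead of
#'   fitting it (default `FALSE`).
#' @param weighted Weight cells by the inverse variance of their mean
#'   squared Z-score instead of equally (default `FALSE`).
#' @details Cell means are heteroskedastic (the Monte Carlo variance of a
#'   mean of squared Z-scores grows with the inflation), so the reported
#'   standard errors propagate each cell's Monte Carlo standard error
#'   through the regression weights rather than using the residual-based
#'   formula, which is both noisy and anti-conservative with a handful of
#'   cells.
#' @return A `phi_estimate`: list with `mediator_id`, `phi`, `phi_raw`,
#'   `se`, `intercept`, `intercept_se`, `r_squared`, `clamped`, the
#'   per-cell means (`cells`), `n_reps_per_cell` and `seed`.
#' @export
estimate_phi_empirical <- function(G_ref, w, grid,
                                   effect_dist = c("normal", "student_t"),
                                   df = 5, noise_dist = effect_dist,
                                   fix_intercept = FALSE,
                                   weighted = FALSE) {
  effect_dist <- match.arg(effect_dist)
  noise_dist <- match.arg(noise_dist, c("normal", "student_t"))
  stopifnot(inherits(G_ref, "genotype_matrix"), inherits(w, "weight_set"),
            inherits(grid, "simulation_grid"))
  n_ref <- nrow(G_ref$dosages)
  m <- ncol(G_ref$dosages)
  cells <- grid$cells
  if (max(cells$N) > n_ref) {
    stop("G_ref has ", n_ref, " individuals but the grid asks for N = ",
         max(cells$N))
  }
  t_full <- predict_mediator(G_ref, w)
  reps <- grid$n_reps_per_cell

  res <- withr::with_seed(grid$seed, {
    lapply(seq_len(nrow(cells)), function(i) {
      N <- cells$N[i]
      h2 <- cells$h2[i]
      idx <- if (N == n_ref) seq_len(n_ref) else sample.int(n_ref, N)
      tp <- t_full[idx]
      Xs <- G_ref$dosages[idx, , drop = FALSE]
      Y <- if (h2 > 0) {
        D <- matrix(r_effects(m * reps, effect_dist, df), m, reps)
        Gd <- Xs %*% D
        Gd <- sweep(Gd, 2L, colMeans(Gd))
        Gd <- sweep(Gd, 2L, sqrt(h2) / apply(Gd, 2L, stats::sd), `*`)
        Gd + sqrt(1 - h2) * matrix(r_effects(N * reps, noise_dist, df),
                                   N, reps)
      } else {
        matrix(r_effects(N * reps, noise_dist, df), N, reps)
      }
      z <- ols_batch_y(tp, Y)$z
      c(mean_z2 = mean(z^2), se_z2 = stats::sd(z^2) / sqrt(reps))
    })
  })
  cells$mean_z2 <- vapply(res, `[[`, numeric(1), "mean_z2")
  cells$se_z2 <- vapply(res, `[[`, numeric(1), "se_z2")
  x <- cells$N * cells$h2
  y <- cells$mean_z2
  wgt <- if (weighted) 1 / pmax(cells$se_z2, 1e-12)^2 else rep(1, length(x))

  # linear estimators: coefficient = sum(a_i * y_i); their sampling SEs
  # propagate the known per-cell MC standard errors through a_i
  if (fix_intercept) {
    sxx <- sum(wgt * x^2)
    a_slope <- wgt * x / sxx
    phi_raw <- sum(a_slope * (y - 1))
    se <- sqrt(sum(a_slope^2 * cells$se_z2^2))
    intercept <- 1
    intercept_se <- 0
    fitted <- 1 + phi_raw * x
  } else {
    xbar <- sum(wgt * x) / sum(wgt)
    sxx <- sum(wgt * (x - xbar)^2)
    a_slope <- wgt * (x - xbar) / sxx
    phi_raw <- sum(a_slope * y)
    a_int <- wgt / sum(wgt) - xbar * a_slope
    intercept <- sum(a_int * y)
    se <- sqrt(sum(a_slope^2 * cells$se_z2^2))
    intercept_se <- sqrt(sum(a_int^2 * cells$se_z2^2))
    fitted <- intercept + phi_raw * x
  }
  r_squared <- 1 - sum(wgt * (y - fitted)^2) /
    sum(wgt * (y - sum(wgt * y) / sum(wgt))^2)
  # The per-cell MC standard errors are a lower bound on cell dispersion:
  # finite-reference-panel LD and per-cell subsampling add systematic
  # offsets that trait redraws do not average out. When the standardized
  # residual scatter exceeds its MC prediction, rescale the SEs by the
  # excess dispersion (floored at 1, quasi-likelihood style).
  dof <- length(x) - if (fix_intercept) 1L else 2L
  if (dof > 0) {
    dispersion <- sum(((y - fitted) / pmax(cells$se_z2, 1e-12))^2) / dof
    infl <- sqrt(max(1, dispersion))
    se <- se * infl
    intercept_se <- intercept_se * infl
  }
  structure(
    list(mediator_id = w$mediator_id,
         phi = max(phi_raw, 0), phi_raw = phi_raw, se = se,
         intercept = intercept, intercept_se = intercept_se,
         r_squared = r_squared,
         clamped = phi_raw < 0,
         cells = cells, n_reps_per_cell = reps, seed = grid$seed,
         build_id = w$build_id),
    class = "phi_estimate"
  )
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat("phi_estimate for ", x$mediator_id, ": phi = ", signif(x$phi, 4),
      " (raw ", signif(x$phi_raw, 4), ", se ", signif(x$se, 3), ")",
      if (x$clamped) " [clamped at 0]" else "", "\n", sep = "")
  cat("  grid: ", nrow(x$cells), " cells x ", x$n_reps_per_cell,
      " reps; intercept = ", signif(x$intercept, 4),
      ", R^2 = ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Expected Z-score variance under a polygenic null
#'
#' `var(Z) ~ 1 + N * h2 * Phi`: strictly increasing in each argument when
#' the other two are positive.
#'
#' @param N GWAS sample size (`N >= 1`).
#' @param h2 Target-trait polygenic heritability in `[0, 1]`.
#' @param phi Inflation slope (`phi >= 0`; clamp negative estimates
#'   upstream).
#' @return The expected Z-score variance (>= 1).
#' @export
expected_z_variance <- function(N, h2, phi) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (any(phi < 0)) stop("phi must be >= 0 (clamp negative estimates first)")
  1 + N * h2 * phi
}

#' Expected squared Z-score under the alternative
#'
#' Evaluates
#' \deqn{E[Z^2] \approx 1
#'   + \frac{N h_\delta^2 \sigma_Y^2}{\sigma_Y^2 - \tau^2\beta^2\sigma_T^2}\Phi
#'   + \frac{N \tau^2 \beta^2 \sigma_T^2}{\sigma_Y^2 - \tau^2\beta^2\sigma_T^2}.}
#' With `beta = 0` this reduces exactly to [expected_z_variance()]: under
#' the null, prediction precision `tau2` has no effect on type-I error.
#'
#' @param spec An [alternative_spec()].
#' @param N GWAS sample size.
#' @param phi Inflation slope (`phi >= 0`).
#' @return The expected squared Z-score.
#' @export
expected_z2_alternative <- function(spec, N, phi) {
  stopifnot(inherits(spec, "alternative_spec"))
  if (any(N < 1)) stop("N must be >= 1")
  if (any(phi < 0)) stop("phi must be >= 0")
  den <- spec$sigma_Y2 - spec$tau2 * spec$beta^2 * spec$sigma_T2
  if (den <= 0) {
    stop("sigma_Y2 - tau2 * beta^2 * sigma_T2 must be positive")
  }
  1 + N * spec$h2_delta * spec$sigma_Y2 / den * phi +
    N * spec$tau2 * spec$beta^2 * spec$sigma_T2 / den
}
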