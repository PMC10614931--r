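#' Target trait vectors
#'
#' A `trait_vector` is a numeric vector of per-individual phenotype values
#' with attributes recording how it was generated: `h2` (polygenic
#' heritability of the trait; 0 for a non-polygenic null), `kind`
#' (`"null_nonpolygenic"`, `"null_polygenic"` or `"alternative"`),
#' `effect_dist`, and `seed`.
#'
#' @param values Numeric vector.
#' @param h2 Polygenic heritability in `[0, 1]`.
#' @param kind Trait kind tag.
#' @param effect_dist Distribution tag used for effects/noise.
#' @param seed Generating seed (may be `NA` for externally supplied traits).
#' @return A `trait_vector`.
#' @export
trait_vector <- function(values, h2, kind, effect_dist = "normal",
                         seed = NA_integer_) {
  kind <- match.arg(kind,
                    c("null_nonpolygenic", "null_polygenic", "alternative"))
  if (h2 == 0 && kind == "null_polygenic") kind <- "null_nonpolygenic"
  if (kind == "null_nonpolygenic" && h2 != 0) {
    stop("a non-polygenic null trait must have h2 = 0")
  }
  structure(as.numeric(values), h2 = h2, kind = kind,
            effect_dist = effect_dist, seed = seed,
            class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("trait_vector (", attr(x, "kind"), "): n = ", length(x),
      ", h2 = ", attr(x, "h2"),
      ", sample var = ", signif(stats::var(as.numeric(x)), 4), "\n", sep = "")
  invisible(x)
}

#' Simulate a non-polygenic null target trait
#'
#' Values are i.i.d. unit-variance draws (standard normal, or Student-t
#' rescaled to unit variance), unrelated to any genotype or mediator.
#'
#' @param n Number of individuals (`n >= 2`).
#' @param dist `"normal"` or `"student_t"`.
#' @param df Degrees of freedom for the t option (default 5).
#' @param seed Integer seed.
#' @return A `trait_vector` of kind `"null_nonpolygenic"`.
#' @export
simulate_null_trait <- function(n, dist = c("normal", "student_t"), df = 5,
                                seed) {
  dist <- match.arg(dist)
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  withr::with_seed(seed, {
    trait_vector(r_effects(n, dist, df), h2 = 0, kind = "null_nonpolygenic",
                 effect_dist = dist, seed = seed)
  })
}

#' Simulate a polygenic null target trait
#'
#' Builds \eqn{Y = s \cdot G\delta + \epsilon} with per-variant effects
#' \eqn{\delta} drawn i.i.d. from `effect_dist`, the genetic component
#' rescaled so its sample variance equals `h2` exactly (removing one Monte
#' Carlo noise source from downstream inflation-slope estimation;
#' `exact_h2 = FALSE` uses expectation-only scaling), and i.i.d. noise with
#' variance `1 - h2`. Every variant of `G` contributes, i.e. the trait is
#' fully polygenic (infinitesimal architecture) and unrelated to any
#' particular mediator.
#'
#' @param G A `genotype_matrix` (standardized recommended).
#' @param h2 Polygenic heritability in `[0, 1)`; `h2 = 1` is allowed only
#'   with `allow_noise_free = TRUE`.
#' @param effect_dist Distribution of the variant effects.
#' @param df Degrees of freedom for the t option.
#' @param seed Integer seed.
#' @param noise_dist Distribution of the non-genetic noise (default normal).
#' @param exact_h2 Rescale the genetic component to hit `h2` exactly
#'   in-sample (default) rather than in expectation.
#' @param allow_noise_free Permit the degenerate `h2 = 1` trait.
#' @return A `trait_vector` of kind `"null_polygenic"` (or
#'   `"null_nonpolygenic"` when `h2 = 0`).
#' @export
simulate_polygenic_trait <- function(G, h2,
                                     effect_dist = c("normal", "student_t"),
                                     df = 5, seed,
                                     noise_dist = effect_dist,
                                     exact_h2 = TRUE,
                                     allow_noise_free = FALSE) {
  effect_dist <- match.arg(effect_dist)
  noise_dist <- match.arg(noise_dist, c("normal", "student_t"))
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  if (m < 1L) stop("G has no variants")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (h2 == 1 && !allow_noise_free) {
    stop("h2 = 1 gives a degenerate noise-free trait; ",
         "set allow_noise_free = TRUE to request it explicitly")
  }
  withr::with_seed(seed, {
    genetic <- 0
    if (h2 > 0) {
      delta <- r_effects(m, effect_dist, df)
      g <- drop(G$dosages %*% delta)
      s <- if (exact_h2) sqrt(h2 / stats::var(g)) else sqrt(h2 / m)
      genetic <- (g - if (exact_h2) mean(g) else 0) * s
    } else {
      # keep the RNG stream aligned with the h2 > 0 case
      delta <- r_effects(m, effect_dist, df)
    }
    eps <- if (h2 < 1) sqrt(1 - h2) * r_effects(n, noise_dist, df) else 0
    trait_vector(genetic + eps, h2 = h2,
                 kind = if (h2 == 0) "null_nonpolygenic" else "null_polygenic",
                 effect_dist = effect_dist, seed = seed)
  })
}

#' Parameters of an alternative-hypothesis (true-effect) scenario
#'
#' @param beta True effect of the mediator on the target trait.
#' @param tau2 Prediction precision `var(T)/var(T~)` in `(0, 1]`.
#' @param sigma_T2 Variance of the true genetic mediator (> 0).
#' @param sigma_Y2 Variance of the target trait (> 0).
#' @param h2_delta Polygenic heritability of the target trait's background
#'   in `[0, 1)`.
#' @return An `alternative_spec`.
#' @export
alternative_spec <- function(beta, tau2 = 1, sigma_T2 = 1, sigma_Y2 = 1,
                             h2_delta = 0) {
  if (tau2 <= 0 || tau2 > 1) stop("tau2 must lie in (0, 1]")
  if (sigma_T2 <= 0 || sigma_Y2 <= 0) stop("variances must be positive")
  if (h2_delta < 0 || h2_delta >= 1) stop("h2_delta must lie in [0, 1)")
  if (sigma_Y2 - tau2 * beta^2 * sigma_T2 <= 0) {
    stop("invalid alternative: sigma_Y2 - tau2 * beta^2 * sigma_T2 must be ",
         "positive (the expected-Z^2 denominator)")
  }
  structure(list(beta = beta, tau2 = tau2, sigma_T2 = sigma_T2,
                 sigma_Y2 = sigma_Y2, h2_delta = h2_delta),
            class = "alternative_spec")
}

#' Simulate a target trait with a true mediator effect
#'
#' Builds \eqn{Y = \beta T +} polygenic background \eqn{+} noise, where
#' \eqn{T = G\gamma} is the true genetic mediator (from `w$true_weights`,
#' rescaled to sample variance `sigma_T2`), the polygenic background has
#' sample variance `h2_delta * sigma_Y2`, and i.i.d. noise makes the total
#' variance `sigma_Y2`. The observable (noisy) prediction is
#' `predict_mediator(G, w)` using `w$weights`, typically produced by
#' [perturb_weights()] at precision `tau2`.
#'
#' The random draw order matches [simulate_polygenic_trait()], so with
#' `beta = 0` and `sigma_Y2 = 1` the same seed reproduces the polygenic
#' null trait exactly.
#'
#' @param G A standardized `genotype_matrix`.
#' @param w A `weight_set` with `true_weights`.
#' @param spec An [alternative_spec()].
#' @param seed Integer seed.
#' @param effect_dist,df,noise_dist Distribution options as in
#'   [simulate_polygenic_trait()].
#' @return A `trait_vector` of kind `"alternative"` (or the corresponding
#'   null kind when `beta = 0`).
#' @export
simulate_alternative_trait <- function(G, w, spec, seed,
                                       effect_dist = c("normal", "student_t"),
                                       df = 5, noise_dist = effect_dist) {
  effect_dist <- match.arg(effect_dist)
  noise_dist <- match.arg(noise_dist, c("normal", "student_t"))
  stopifnot(inherits(G, "genotype_matrix"), inherits(w, "weight_set"),
            inherits(spec, "alternative_spec"))
  if (is.null(w$true_weights)) {
    stop("simulate_alternative_trait needs w$true_weights")
  }
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  noise_var <- spec$sigma_Y2 * (1 - spec$h2_delta) -
    spec$beta^2 * spec$sigma_T2
  if (noise_var <= 0) {
    stop("variance budget exhausted: sigma_Y2*(1 - h2_delta) - ",
         "beta^2*sigma_T2 must be positive")
  }
  cols <- match(w$variant_ids, G$variant_ids)
  if (anyNA(cols)) stop("model variants missing from G")
  t_true <- drop(G$dosages[, cols, drop = FALSE] %*% w$true_weights)
  t_true <- (t_true - mean(t_true)) *
    sqrt(spec$sigma_T2 / stats::var(t_true))
  withr::with_seed(seed, {
    genetic <- 0
    delta <- r_effects(m, effect_dist, df)
    if (spec$h2_delta > 0) {
      g <- drop(G$dosages %*% delta)
      genetic <- (g - mean(g)) *
        sqrt(spec$h2_delta * spec$sigma_Y2 / stats::var(g))
    }
    eps <- sqrt(noise_var) * r_effects(n, noise_dist, df)
    kind <- if (spec$beta == 0) {
      if (spec$h2_delta == 0) "null_nonpolygenic" else "null_polygenic"
    } else "alternative"
    trait_vector(spec$beta * t_true + genetic + eps,
                 h2 = spec$h2_delta, kind = kind,
                 effect_dist = effect_dist, seed = seed)
  })
}
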