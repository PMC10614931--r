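#' Construct a mediator prediction-weight set
#'
#' A `weight_set` holds the per-variant prediction weights of one mediator
#' (a gene, metabolite, brain feature, ...). `weights` are the weights used
#' for prediction; when the mediator is simulated, `true_weights` holds the
#' generating weights so that noisy-prediction scenarios can be built with
#' [perturb_weights()].
#'
#' @param mediator_id Character identifier.
#' @param variant_ids Character vector.
#' @param weights Numeric vector, same length; at least one nonzero.
#' @param true_weights Optional numeric vector of generating weights.
#' @param ref_allele,alt_allele Optional allele annotations carried through
#'   I/O; not used by the simulators.
#' @param build_id Optional model-store build identifier.
#' @return A `weight_set`.
#' @export
weight_set <- function(mediator_id, variant_ids, weights, true_weights = NULL,
                       ref_allele = NULL, alt_allele = NULL, build_id = NULL) {
  variant_ids <- as.character(variant_ids)
  weights <- as.numeric(weights)
  if (length(variant_ids) != length(weights)) {
    stop("variant_ids and weights must have the same length")
  }
  if (anyDuplicated(variant_ids)) {
    stop("duplicate variant ids in weight set ", mediator_id)
  }
  if (all(weights == 0)) {
    stop("weight set ", mediator_id, " has no nonzero weight; ",
         "an all-zero mediator model is unusable")
  }
  if (!is.null(true_weights) && length(true_weights) != length(weights)) {
    stop("true_weights must match weights in length")
  }
  structure(
    list(mediator_id = as.character(mediator_id), variant_ids = variant_ids,
         weights = weights, true_weights = true_weights,
         ref_allele = ref_allele, alt_allele = alt_allele,
         n_model_variants = sum(weights != 0), build_id = build_id),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set ", x$mediator_id, ": ", length(x$weights), " variants, ",
      x$n_model_variants, " nonzero",
      if (!is.null(x$true_weights)) ", true weights attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate mediator prediction weights
#'
#' Draws `n_nonzero` nonzero weights at seeded positions among `m` variants,
#' from a standard normal or a unit-variance Student-t distribution. The
#' result carries `true_weights` equal to the drawn weights, i.e. it plays
#' the role of the true genetic architecture; use [perturb_weights()] for a
#' noisy prediction model.
#'
#' @param m Number of variants covered by the model.
#' @param n_nonzero Number of nonzero weights (`1 <= n_nonzero <= m`);
#'   `m` gives a dense (fully polygenic) mediator, 1 a single-eQTL model.
#' @param dist `"normal"` or `"student_t"` (scaled to unit variance).
#' @param df Degrees of freedom for `"student_t"` (default 5).
#' @param seed Integer seed.
#' @param variant_ids Optional ids (default `snp_1..m`, matching
#'   [simulate_genotypes()]).
#' @param mediator_id Identifier for the mediator (default `"mediator_1"`).
#' @return A `weight_set`.
#' @export
simulate_mediator_weights <- function(m, n_nonzero = m,
                                      dist = c("normal", "student_t"),
                                      df = 5, seed,
                                      variant_ids = NULL,
                                      mediator_id = "mediator_1") {
  dist <- match.arg(dist)
  m <- as.integer(m)
  n_nonzero <- as.integer(n_nonzero)
  if (n_nonzero < 1L || n_nonzero > m) {
    stop("n_nonzero must be between 1 and m; a mediator with no nonzero ",
         "weight is unusable")
  }
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(m))
  withr::with_seed(seed, {
    pos <- sort(sample.int(m, n_nonzero))
    w <- numeric(m)
    w[pos] <- r_effects(n_nonzero, dist, df)
    weight_set(mediator_id, variant_ids, w, true_weights = w)
  })
}

#' Add prediction error to a weight set at a given precision
#'
#' Models the practical setting where the available weights differ from the
#' generating ones: the prediction \eqn{\tilde T = G \tilde\gamma} equals the
#' true genetic mediator \eqn{T = G\gamma} plus an independent error
#' component, scaled so that the in-sample prediction precision
#' \eqn{\tau^2 = var(T)/var(\tilde T)} is exact. The error component is
#' orthogonalized against \eqn{T} in-sample, so `tau2 = 1` returns the true
#' weights unchanged.
#'
#' @param w A `weight_set` with `true_weights`.
#' @param G A standardized `genotype_matrix` covering the model variants.
#' @param tau2 Prediction precision in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `weight_set` whose `weights` are the noisy prediction weights;
#'   `true_weights` is preserved.
#' @export
perturb_weights <- function(w, G, tau2, seed) {
  stopifnot(inherits(w, "weight_set"), inherits(G, "genotype_matrix"))
  if (is.null(w$true_weights)) {
    stop("perturb_weights needs a weight set with true_weights")
  }
  if (!G$standardized) stop("G must be standardized")
  if (!is.numeric(tau2) || tau2 <= 0 || tau2 > 1) {
    stop("tau2 must lie in (0, 1]")
  }
  if (tau2 == 1) {
    w$weights <- w$true_weights
    return(w)
  }
  cols <- match(w$variant_ids, G$variant_ids)
  if (anyNA(cols)) stop("model variants missing from G")
  X <- G$dosages[, cols, drop = FALSE]
  gamma <- w$true_weights
  t_true <- drop(X %*% gamma)
  withr::with_seed(seed, {
    e <- stats::rnorm(length(gamma))
    u <- drop(X %*% e)
    # orthogonalize the error direction against T in-sample, then scale so
    # var(T + u) = var(T) / tau2 exactly
    c_proj <- sum(u * t_true) / sum(t_true^2)
    e <- e - c_proj * gamma
    u <- u - c_proj * t_true
    s <- sqrt(stats::var(t_true) * (1 / tau2 - 1) / stats::var(u))
    w$weights <- gamma + s * e
    w
  })
}

# unit-variance effect/trait draws
r_effects <- function(k, dist = c("normal", "student_t"), df = 5) {
  dist <- match.arg(dist)
  if (dist == "normal") {
    stats::rnorm(k)
  } else {
    if (df <= 2) stop("student_t draws need df > 2 for finite variance")
    stats::rt(k, df) / sqrt(df / (df - 2))
  }
}
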