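#' Predict a mediator from genotypes and weights
#'
#' The genetically predicted mediator is the weighted sum of dosage columns,
#' \eqn{\tilde T_i = \sum_k \tilde\gamma_k X_{ik}}.
#'
#' @param G A `genotype_matrix`.
#' @param w A `weight_set`; its variants are matched to `G` by identifier.
#' @param missing Policy for model variants absent from `G`: `"error"`
#'   (default) or `"drop"` (drop them with a warning).
#' @return Numeric vector of length `n`, with attributes `n_variants_used`
#'   and `n_variants_missing`.
#' @export
predict_mediator <- function(G, w, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(G, "genotype_matrix"), inherits(w, "weight_set"))
  cols <- match(w$variant_ids, G$variant_ids)
  absent <- is.na(cols)
  if (all(absent)) {
    stop("all model variants of mediator ", w$mediator_id,
         " are missing from the genotype matrix")
  }
  if (any(absent)) {
    if (missing == "error") {
      stop(sum(absent), " model variant(s) of mediator ", w$mediator_id,
           " missing from the genotype matrix (first: ",
           w$variant_ids[absent][1], "); use missing = \"drop\" to drop them")
    }
    warning("dropping ", sum(absent), " missing variant(s) for mediator ",
            w$mediator_id)
  }
  keep <- !absent
  t_pred <- drop(G$dosages[, cols[keep], drop = FALSE] %*% w$weights[keep])
  attr(t_pred, "n_variants_used") <- sum(keep)
  attr(t_pred, "n_variants_missing") <- sum(absent)
  t_pred
}

# closed-form simple OLS (with intercept) of each column of Y on x.
# Returns beta, se (residual-based, n - 2 dof), z = beta/se and r.
ols_batch_y <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sxy <- drop(crossprod(Yc, xc))
  syy <- colSums(Yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  list(beta = beta, se = se, z = beta / se, r2 = sxy^2 / (sxx * syy), n = n)
}

# same, one y against each column of X
ols_batch_x <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Xc <- sweep(X, 2L, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  beta <- sxy / sxx
  rss <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  list(beta = beta, se = se, z = beta / se, r2 = sxy^2 / (sxx * syy), n = n)
}

#' Single-mediator TWAS association test
#'
#' Ordinary least squares of the target trait on the predicted mediator
#' (with intercept). The Z-score is the effect estimate divided by its
#' residual-based standard error (n - 2 degrees of freedom); the p-value
#' uses the standard normal reference by default (the t reference is
#' available and indistinguishable at TWAS sample sizes).
#'
#' @param t_pred Predicted mediator (numeric, non-constant).
#' @param y Target trait (`trait_vector` or numeric), same length.
#' @param mediator_id Optional identifier recorded in the result.
#' @param reference `"normal"` (default) or `"t"` for the p-value.
#' @return A one-row `data.frame` with columns `mediator_id`, `n`,
#'   `beta_hat`, `se`, `z`, `p`, plus `NA` placeholders for `phi`,
#'   `correction_factor`, `z_corrected`, `p_corrected`.
#' @export
association_test <- function(t_pred, y, mediator_id = NA_character_,
                             reference = c("normal", "t")) {
  reference <- match.arg(reference)
  y <- as.numeric(y)
  t_pred <- as.numeric(t_pred)
  n <- length(y)
  if (length(t_pred) != n) stop("t_pred and y must have the same length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(t_pred) == 0) {
    stop("zero-variance mediator: the predicted mediator is constant")
  }
  fit <- ols_batch_y(t_pred, matrix(y, ncol = 1L))
  if (fit$se == 0 || !is.finite(fit$z)) {
    if (fit$beta == 0 && fit$se == 0) {
      stop("degenerate fit: the target trait is constant")
    }
    stop("degenerate fit: zero residual variance (perfect fit)")
  }
  z <- fit$z
  p <- if (reference == "normal") 2 * stats::pnorm(-abs(z))
       else 2 * stats::pt(-abs(z), df = n - 2)
  data.frame(mediator_id = mediator_id, n = n, beta_hat = fit$beta,
             se = fit$se, z = z, p = p,
             phi = NA_real_, correction_factor = NA_real_,
             z_corrected = NA_real_, p_corrected = NA_real_,
             stringsAsFactors = FALSE)
}

#' Run a TWAS: many mediators against one target trait
#'
#' Predicts every mediator from `G` and tests each against `y`. Mediators
#' that fail their preconditions (all variants missing, constant
#' prediction, ...) are skipped with a logged reason, never silently
#' dropped; the skipped set is attached as attribute `"skipped"`.
#'
#' @param G A `genotype_matrix`.
#' @param weights A list of `weight_set` objects with unique mediator ids.
#' @param y Target trait, length `nrow(G$dosages)`.
#' @param missing Missing-variant policy passed to [predict_mediator()].
#' @return A `data.frame` with one row per tested mediator, columns as in
#'   [association_test()].
#' @export
run_twas <- function(G, weights, y, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(G, "genotype_matrix"), is.list(weights),
            length(weights) >= 1L)
  if (inherits(weights, "weight_set")) weights <- list(weights)
  ids <- vapply(weights, function(w) w$mediator_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate mediator_id in weights: ", ids[duplicated(ids)][1])
  }
  y <- as.numeric(y)
  n <- nrow(G$dosages)
  if (length(y) != n) stop("y must have length nrow(G$dosages)")

  preds <- vector("list", length(weights))
  reasons <- character(length(weights))
  for (i in seq_along(weights)) {
    val <- tryCatch(
      withCallingHandlers(
        predict_mediator(G, weights[[i]], missing = missing),
        warning = function(wn) invokeRestart("muffleWarning")
      ),
      error = function(e) {
        reasons[i] <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(val) && stats::sd(val) == 0) {
      reasons[i] <- "constant predicted mediator"
      val <- NULL
    }
    preds[i] <- list(val)
  }
  usable <- !vapply(preds, is.null, logical(1))
  if (!any(usable)) stop("no usable mediator in the weight list")
  skipped <- data.frame(mediator_id = ids[!usable],
                        reason = reasons[!usable],
                        stringsAsFactors = FALSE)
  if (nrow(skipped) > 0) {
    message("run_twas: skipped ", nrow(skipped), " mediator(s): ",
            paste0(skipped$mediator_id, " (", skipped$reason, ")",
                   collapse = "; "))
  }
  TT <- do.call(cbind, preds[usable])
  fit <- ols_batch_x(TT, y)
  out <- data.frame(mediator_id = ids[usable], n = fit$n,
                    beta_hat = fit$beta, se = fit$se, z = fit$z,
                    p = 2 * stats::pnorm(-abs(fit$z)),
                    phi = NA_real_, correction_factor = NA_real_,
                    z_corrected = NA_real_, p_corrected = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}
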