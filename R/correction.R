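#' Variance-control correction factor
#'
#' The factor by which an inflated Z-score is divided:
#' \eqn{\sqrt{1 + N h^2 \Phi} \ge 1}. With `phi = 0` or `h2 = 0` no
#' correction is applied.
#'
#' @param N GWAS sample size (`N >= 1`).
#' @param h2 Target-trait polygenic heritability in `[0, 1]`.
#' @param phi Per-mediator inflation slope (`phi >= 0`); vectorized.
#' @return Correction factor(s) `>= 1`.
#' @examples
#' correction_factor(100000, 0.5, 2e-5)  # sqrt(2)
#' @export
correction_factor <- function(N, h2, phi) {
  sqrt(expected_z_variance(N, h2, phi))
}

#' Apply variance control to a TWAS result table
#'
#' Divides each Z-score by its mediator-specific correction factor
#' \eqn{\sqrt{1 + N h^2 \Phi}} and recomputes the two-sided normal p-value.
#' Original `z` and `p` are preserved. Rows whose mediator has no matching
#' inflation slope are left uncorrected and flagged (default) or dropped.
#'
#' @param results A TWAS result `data.frame` (from [run_twas()] or
#'   [read_results()]) with at least `mediator_id` and `z`.
#' @param N GWAS sample size.
#' @param h2 Target-trait polygenic heritability in `[0, 1]`.
#' @param phis Per-mediator inflation slopes: a `data.frame` with columns
#'   `mediator_id` and `phi`, a single `phi_estimate`, a list of them, or a
#'   single number applied to all rows.
#' @param missing_phi `"keep"` (default: leave uncorrected, message) or
#'   `"drop"`.
#' @param binary_trait Set to `TRUE` when the GWAS outcome is
#'   case-control: the correction is derived under linear regression and
#'   is only a good approximation for balanced designs, so a warning is
#'   logged; no effective-sample-size adjustment is applied.
#' @return The result table with `phi`, `correction_factor`, `z_corrected`
#'   and `p_corrected` filled in for matched rows.
#' @export
apply_correction <- function(results, N, h2, phis,
                             missing_phi = c("keep", "drop"),
                             binary_trait = FALSE) {
  missing_phi <- match.arg(missing_phi)
  if (isTRUE(binary_trait)) {
    warning("binary target trait: the variance-control factor assumes ",
            "linear regression and is reliable only for balanced ",
            "case-control designs; no effective-N adjustment is applied")
  }
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("mediator_id", "z") %in% names(results)))
  if (length(h2) != 1 || h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (length(N) != 1 || N < 1) stop("N must be a single value >= 1")

  phi_tab <- as_phi_table(phis, results$mediator_id)
  if (anyDuplicated(phi_tab$mediator_id)) {
    stop("duplicate mediator_id in phis: ",
         phi_tab$mediator_id[duplicated(phi_tab$mediator_id)][1])
  }
  if (any(phi_tab$phi < 0, na.rm = TRUE)) {
    stop("negative phi supplied; clamp estimates at 0 first")
  }
  idx <- match(results$mediator_id, phi_tab$mediator_id)
  matched <- !is.na(idx)
  if (!all(matched)) {
    message("apply_correction: no inflation slope for ",
            sum(!matched), " mediator(s); ",
            if (missing_phi == "keep") "left uncorrected" else "dropped")
    if (missing_phi == "drop") {
      results <- results[matched, , drop = FALSE]
      idx <- idx[matched]
      matched <- rep(TRUE, nrow(results))
    }
  }
  phi <- ifelse(matched, phi_tab$phi[idx], NA_real_)
  cf <- ifelse(matched, correction_factor(N, h2, ifelse(matched, phi, 0)),
               NA_real_)
  results$phi <- phi
  results$correction_factor <- cf
  results$z_corrected <- results$z / cf
  results$p_corrected <- 2 * stats::pnorm(-abs(results$z_corrected))
  rownames(results) <- NULL
  results
}

# coerce the accepted phi inputs into a (mediator_id, phi) table
as_phi_table <- function(phis, result_ids) {
  if (inherits(phis, "phi_estimate")) phis <- list(phis)
  if (is.list(phis) && !is.data.frame(phis) &&
      all(vapply(phis, inherits, logical(1), "phi_estimate"))) {
    phis <- data.frame(
      mediator_id = vapply(phis, `[[`, character(1), "mediator_id"),
      phi = vapply(phis, `[[`, numeric(1), "phi"),
      stringsAsFactors = FALSE
    )
  }
  if (is.numeric(phis) && length(phis) == 1L) {
    phis <- data.frame(mediator_id = unique(result_ids), phi = phis,
                       stringsAsFactors = FALSE)
  }
  if (!is.data.frame(phis) ||
      !all(c("mediator_id", "phi") %in% names(phis))) {
    stop("phis must provide columns mediator_id and phi")
  }
  phis
}

#' Count Bonferroni-significant results before and after correction
#'
#' Applies the threshold `alpha / n_tested` separately to the raw and the
#' corrected p-values, where `n_tested` counts the rows carrying a p-value
#' of that kind.
#'
#' @param results A TWAS result table with `p` and (optionally)
#'   `p_corrected`.
#' @param alpha Family-wise error rate in `(0, 1)` (default 0.05).
#' @return A list with `n_significant_raw`, `n_significant_corrected`,
#'   `n_tested_raw`, `n_tested_corrected` and `alpha`.
#' @export
bonferroni_summary <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            "p" %in% names(results))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p_raw <- results$p[!is.na(results$p)]
  n_raw <- length(p_raw)
  n_sig_raw <- if (n_raw > 0) sum(p_raw < alpha / n_raw) else 0L
  p_cor <- if ("p_corrected" %in% names(results)) {
    results$p_corrected[!is.na(results$p_corrected)]
  } else numeric(0)
  n_cor <- length(p_cor)
  if (n_cor == 0L) {
    message("bonferroni_summary: no corrected p-values present; ",
            "corrected count computed over zero rows")
  }
  n_sig_cor <- if (n_cor > 0) sum(p_cor < alpha / n_cor) else 0L
  list(n_significant_raw = as.integer(n_sig_raw),
       n_significant_corrected = as.integer(n_sig_cor),
       n_tested_raw = n_raw, n_tested_corrected = n_cor, alpha = alpha)
}
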