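#' Simulate a genotype dosage matrix under block LD
#'
#' Draws biallelic dosages (0/1/2) for `n` individuals at the variants
#' described by an [ld_spec()]. Independent variants are Binomial(2, f)
#' draws. Within a correlated block, each of the two allele copies is
#' generated by thresholding a latent Gaussian vector with exchangeable
#' (or explicit) correlation; for exchangeable blocks the latent
#' correlation is calibrated by tetrachoric inversion so the realized
#' dosage correlation matches the requested one (plain thresholding
#' attenuates the correlation). Explicit block matrices are used directly
#' as latent correlations.
#'
#' @param n Number of individuals (`n >= 2`).
#' @param ld An [ld_spec()] (or an integer, shorthand for `identity_ld`).
#' @param maf_range Length-2 interval within `(0, 0.5]` from which each
#'   variant's minor-allele frequency is drawn uniformly. A degenerate
#'   interval (e.g. `c(0.5, 0.5)`) fixes the MAF.
#' @param seed Integer seed; identical seeds and parameters give
#'   bit-identical output.
#' @param standardize If `TRUE` (default) columns are centered and scaled
#'   to unit sample variance.
#' @param variant_ids Optional variant identifiers (default `snp_1..m`).
#' @return A `genotype_matrix`: list with `dosages` (n x m), `variant_ids`,
#'   `allele_freqs`, `standardized`, `ld_spec`.
#' @examples
#' G <- simulate_genotypes(100, identity_ld(5), seed = 1)
#' dim(G$dosages)
#' @export
simulate_genotypes <- function(n, ld, maf_range = c(0.05, 0.5), seed,
                               standardize = TRUE, variant_ids = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2 individuals")
  if (is.numeric(ld) && length(ld) == 1L) ld <- identity_ld(ld)
  stopifnot(inherits(ld, "ld_spec"))
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  m <- ld$m_variants
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(m))
  stopifnot(length(variant_ids) == m, !anyDuplicated(variant_ids))

  withr::with_seed(seed, {
    mafs <- stats::runif(m, maf_range[1], maf_range[2])
    dosages <- matrix(0L, n, m)
    off <- 0L
    for (b in seq_along(ld$block_sizes)) {
      sz <- ld$block_sizes[b]
      idx <- off + seq_len(sz)
      blk <- ld$blocks[[b]]
      if (!is.matrix(blk) && (sz == 1L || blk == 0)) {
        dosages[, idx] <- vapply(mafs[idx],
                                 function(f) stats::rbinom(n, 2L, f),
                                 integer(n))
      } else {
        dosages[, idx] <- simulate_ld_block(n, sz, blk, mafs[idx])
      }
      off <- off + sz
    }
    colnames(dosages) <- variant_ids
    out <- genotype_matrix(dosages, variant_ids, mafs,
                           standardized = FALSE, ld = ld)
    if (standardize) out <- standardize_genotypes(out)
    out
  })
}

# one correlated block: Gaussian-copula thresholding of two haplotype
# layers; exchangeable latent correlation is calibrated so the dosage
# correlation hits the target (at the block's mean MAF)
simulate_ld_block <- function(n, sz, blk, mafs) {
  thresholds <- stats::qnorm(mafs)
  if (is.matrix(blk)) {
    cf <- tryCatch(chol(blk), error = function(e) NULL)
    if (is.null(cf)) {
      ev <- eigen(blk, symmetric = TRUE)
      ev$values <- pmax(ev$values, 0)
      rt <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
      draw <- function() matrix(stats::rnorm(n * sz), n, sz) %*% rt
    } else {
      draw <- function() matrix(stats::rnorm(n * sz), n, sz) %*% cf
    }
  } else {
    rl <- latent_rho_for(blk, mean(mafs))
    draw <- function() {
      shared <- stats::rnorm(n)
      sqrt(rl) * shared + sqrt(1 - rl) * matrix(stats::rnorm(n * sz), n, sz)
    }
  }
  a1 <- sweep(draw(), 2L, thresholds, `<`)
  a2 <- sweep(draw(), 2L, thresholds, `<`)
  a1 + a2
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho
pbinorm <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  s <- sqrt(1 - rho^2)
  stats::integrate(
    function(z) stats::pnorm((b - rho * z) / s) * stats::dnorm(z),
    -Inf, a, rel.tol = 1e-9
  )$value
}

# correlation of two threshold indicators 1{Z < qnorm(f)} at latent rho
binary_corr_from_latent <- function(rho, f) {
  a <- stats::qnorm(f)
  (pbinorm(a, a, rho) - f^2) / (f * (1 - f))
}

# invert the attenuation: latent correlation whose thresholded indicators
# have the target correlation at MAF f
latent_rho_for <- function(target, f) {
  if (target <= 0) return(0)
  upper <- 0.9999
  hi <- binary_corr_from_latent(upper, f)
  if (target >= hi) {
    warning("within-block correlation ", signif(target, 3),
            " not attainable at MAF ", signif(f, 3),
            "; using the maximum (", signif(hi, 3), ")")
    return(upper)
  }
  stats::uniroot(function(r) binary_corr_from_latent(r, f) - target,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' Construct a genotype matrix object
#'
#' @param dosages Numeric `n x m` matrix (raw 0-2 dosages or standardized).
#' @param variant_ids Character vector of length `m`.
#' @param allele_freqs Numeric vector of allele frequencies in `(0, 1)`.
#' @param standardized Logical flag.
#' @param ld Optional [ld_spec()] provenance.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_ids = colnames(dosages),
                            allele_freqs = NULL, standardized = FALSE,
                            ld = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(m))
  if (length(variant_ids) != m) {
    stop("variant_ids length (", length(variant_ids),
         ") does not match the number of columns (", m, ")")
  }
  if (is.null(allele_freqs)) allele_freqs <- colMeans(dosages) / 2
  if (length(allele_freqs) != m) {
    stop("allele_freqs length does not match the number of columns")
  }
  colnames(dosages) <- variant_ids
  structure(
    list(dosages = dosages, variant_ids = as.character(variant_ids),
         allele_freqs = as.numeric(allele_freqs),
         standardized = isTRUE(standardized), ld_spec = ld),
    class = "genotype_matrix"
  )
}

#' Standardize genotype columns to mean 0, variance 1
#'
#' @param G A `genotype_matrix`.
#' @return The same object with standardized dosages and the flag set.
#' @export
standardize_genotypes <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (G$standardized) return(G)
  sds <- apply(G$dosages, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- G$variant_ids[sds == 0][1]
    stop("cannot standardize: variant ", bad,
         " is monomorphic in this sample")
  }
  G$dosages <- scale(G$dosages)
  attr(G$dosages, "scaled:center") <- NULL
  attr(G$dosages, "scaled:scale") <- NULL
  G$standardized <- TRUE
  G
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants",
      if (x$standardized) "(standardized)" else "(raw dosages)", "\n")
  cat("  MAF range:", paste(signif(range(x$allele_freqs), 3),
                            collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)
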