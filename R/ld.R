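#' Block linkage-disequilibrium specification
#'
#' Describes the target correlation structure of a panel of `m_variants`
#' simulated variants as a block-diagonal matrix: within each block the
#' dosage correlation is exchangeable at `within_block_correlation`, or an
#' explicit correlation matrix may be supplied per block. Blocks of size 1
#' (or correlation 0) yield independent variants.
#'
#' @param m_variants Total number of variants.
#' @param block_sizes Integer vector of block sizes summing to `m_variants`.
#'   Defaults to all blocks of size 1 (identity LD).
#' @param within_block_correlation Either a single correlation in `[0, 1)`
#'   recycled across blocks, a vector with one value per block, or a list
#'   with one element per block where each element is a scalar correlation
#'   or an explicit square correlation matrix of the block's size.
#' @return An object of class `ld_spec`.
#' @examples
#' identity_ld(10)
#' ld_spec(6, block_sizes = c(3, 3), within_block_correlation = 0.5)
#' @export
ld_spec <- function(m_variants,
                    block_sizes = rep(1L, m_variants),
                    within_block_correlation = 0) {
  m_variants <- as.integer(m_variants)
  stopifnot(m_variants >= 1L)
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1L)) {
    stop("all block sizes must be >= 1")
  }
  if (sum(block_sizes) != m_variants) {
    stop("block_sizes must sum to m_variants (", m_variants, "), got ",
         sum(block_sizes))
  }
  nb <- length(block_sizes)
  if (!is.list(within_block_correlation)) {
    rho <- rep_len(as.numeric(within_block_correlation), nb)
    blocks <- as.list(rho)
  } else {
    if (length(within_block_correlation) != nb) {
      stop("need one correlation entry per block")
    }
    blocks <- within_block_correlation
  }
  for (b in seq_len(nb)) {
    blk <- blocks[[b]]
    if (is.matrix(blk)) {
      if (nrow(blk) != block_sizes[b] || ncol(blk) != block_sizes[b]) {
        stop("block ", b, ": correlation matrix must be ",
             block_sizes[b], "x", block_sizes[b])
      }
      if (max(abs(blk - t(blk))) > 1e-10) {
        stop("block ", b, ": correlation matrix is not symmetric")
      }
      if (max(abs(diag(blk) - 1)) > 1e-10) {
        stop("block ", b, ": correlation matrix must have unit diagonal")
      }
      ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        stop("block ", b, ": correlation matrix is not positive ",
             "semi-definite (min eigenvalue ", signif(min(ev), 3), ")")
      }
    } else {
      blk <- as.numeric(blk)
      if (length(blk) != 1L || is.na(blk) || blk < 0 || blk >= 1) {
        stop("block ", b, ": exchangeable correlation must be a single ",
             "value in [0, 1)")
      }
      blocks[[b]] <- blk
    }
  }
  structure(
    list(m_variants = m_variants, block_sizes = block_sizes, blocks = blocks),
    class = "ld_spec"
  )
}

#' Identity (independent-variant) LD specification
#'
#' @param m_variants Number of independent variants.
#' @return An `ld_spec` with all blocks of size 1.
#' @export
identity_ld <- function(m_variants) {
  ld_spec(m_variants)
}

#' @export
print.ld_spec <- function(x, ...) {
  nb <- length(x$block_sizes)
  cat("ld_spec:", x$m_variants, "variants in", nb, "block(s)\n")
  if (is_identity_ld(x)) {
    cat("  identity LD (all variants independent)\n")
  } else {
    show <- utils::head(seq_len(nb), 5L)
    for (b in show) {
      blk <- x$blocks[[b]]
      desc <- if (is.matrix(blk)) "explicit matrix" else paste0("rho = ", blk)
      cat("  block ", b, ": size ", x$block_sizes[b], ", ", desc, "\n",
          sep = "")
    }
    if (nb > 5L) cat("  ...\n")
  }
  invisible(x)
}

# identity iff every block is size 1 or has zero correlation
is_identity_ld <- function(ld) {
  all(vapply(seq_along(ld$block_sizes), function(b) {
    blk <- ld$blocks[[b]]
    ld$block_sizes[b] == 1L ||
      (!is.matrix(blk) && blk == 0) ||
      (is.matrix(blk) && max(abs(blk - diag(nrow(blk)))) == 0)
  }, logical(1)))
}

#' Dense LD (correlation) matrix implied by an `ld_spec`
#'
#' @param ld An [ld_spec()].
#' @return The `m x m` block-diagonal target correlation matrix.
#' @export
ld_matrix <- function(ld) {
  stopifnot(inherits(ld, "ld_spec"))
  m <- ld$m_variants
  sigma <- diag(m)
  off <- 0L
  for (b in seq_along(ld$block_sizes)) {
    sz <- ld$block_sizes[b]
    idx <- off + seq_len(sz)
    blk <- ld$blocks[[b]]
    if (is.matrix(blk)) {
      sigma[idx, idx] <- blk
    } else if (blk != 0) {
      sigma[idx, idx] <- blk
      sigma[cbind(idx, idx)] <- 1
    }
    off <- off + sz
  }
  sigma
}
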