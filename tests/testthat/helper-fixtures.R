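# shared small fixtures, built in code at test time

toy_genotypes <- function(n = 300, m = 50, seed = 101, ...) {
  simulate_genotypes(n, identity_ld(m), seed = seed, ...)
}

toy_weights <- function(m = 50, seed = 202, ...) {
  simulate_mediator_weights(m, seed = seed, ...)
}

# a small TWAS result table with known raw/corrected significance counts
toy_results <- function(n_rows = 100, n = 1000) {
  p <- seq(0.5, 0.99, length.out = n_rows)
  # 3 rows below the raw Bonferroni cut 0.05/100; at a sqrt(2) correction
  # factor only the first survives
  p[1:3] <- c(1e-9, 2e-5, 4e-4)
  z <- qnorm(p / 2, lower.tail = FALSE)
  data.frame(
    mediator_id = paste0("med_", seq_len(n_rows)), n = n,
    beta_hat = z / sqrt(n), se = 1 / sqrt(n), z = z, p = p,
    phi = NA_real_, correction_factor = NA_real_,
    z_corrected = NA_real_, p_corrected = NA_real_,
    stringsAsFactors = FALSE
  )
}
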