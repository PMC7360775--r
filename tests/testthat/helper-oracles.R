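# Independent oracles used against the package's constructions.

# Allele-copy gene dropping: each founder gamete carries an independent
# N(0, 1) effect; a non-founder gamete COPIES one of its parent's two gamete
# effects with probability 1/2 each. No variance recursion enters, so the
# empirical covariance of the gamete effects is an oracle for the gametic
# relationship matrix (its expectation is exactly G, entry by entry).
# Returns the 2N x 2N empirical covariance plus its per-entry Monte-Carlo
# standard errors, vectorized over `reps` replicates.
gene_drop_cov_oracle <- function(ped, reps) {
  n <- n_individuals(ped)
  M <- matrix(0, 2L * n, reps)
  for (i in seq_len(n)) {
    for (k in 1:2) {
      g <- 2L * (i - 1L) + k
      p <- if (k == 1L) ped$sire_idx[i] else ped$dam_idx[i]
      if (is.na(p)) {
        M[g, ] <- stats::rnorm(reps)
      } else {
        pick <- stats::runif(reps) < 0.5
        M[g, ] <- ifelse(pick, M[2L * p - 1L, ], M[2L * p, ])
      }
    }
  }
  Ghat <- tcrossprod(M) / reps
  second <- tcrossprod(M^2) / reps          # E[m_u^2 m_v^2]
  se <- sqrt(pmax(second - Ghat^2, 0) / reps)
  list(cov = Ghat, se = se)
}

# Closed-form residual-only REML log-likelihood of a fixed-effects
# regression (the zero-variance limit of every model in the ladder).
residual_reml_loglik <- function(y, X, sigma_e2) {
  qrX <- qr(X)
  p <- qrX$rank
  n <- length(y)
  rss <- sum(qr.resid(qrX, y)^2)
  R <- qr.R(qrX)
  -0.5 * ((n - p) * (log(sigma_e2) + log(2 * pi)) +
            2 * sum(log(abs(diag(R)))) + rss / sigma_e2)
}
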