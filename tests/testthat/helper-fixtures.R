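# Small pedigrees and datasets built in code for the tests.

trio_pedigree <- function() {
  pedigree(id = c("C", "S", "D"), sire = c("S", "0", "0"),
           dam = c("D", "0", "0"))
}

# offspring X of full sibs A1 x B1 (F_X = 0.25)
fullsib_pedigree <- function() {
  pedigree(id = c("S", "D", "A1", "B1", "X"),
           sire = c("0", "0", "S", "S", "A1"),
           dam = c("0", "0", "D", "D", "B1"))
}

# Random pedigree: individual i draws each parent from earlier individuals
# (or unknown); used for property-style tests over pedigree space.
random_pedigree <- function(N, p_unknown = 0.2, n_founders = max(4L, N %/% 5L)) {
  id <- sprintf("I%03d", seq_len(N))
  sire <- dam <- rep(NA_character_, N)
  for (i in seq_len(N)) {
    if (i <= n_founders) next
    pool <- seq_len(i - 1L)
    if (stats::runif(1) > p_unknown) sire[i] <- id[sample(pool, 1L)]
    if (stats::runif(1) > p_unknown) {
      cand <- setdiff(pool, match(sire[i], id))
      if (length(cand)) dam[i] <- id[sample(cand, 1L)]
    }
  }
  pedigree(id, sire, dam)
}

# Small simulated dataset for REML tests.
small_dataset <- function(seed = 1L, n_founders = 40L, n_generations = 4L,
                          true_vc = list(sigma_s2 = 0.3, sigma_d2 = 0.1,
                                         sigma_sd = 0.1, sigma_c2 = 0.1,
                                         sigma_e2 = 0.6),
                          trait_mode = "linear", ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    mean_family_size = 3, true_vc = true_vc,
                    trait_mode = trait_mode, ...)
  simulate_dataset(cfg, seed = seed)
}

# random variance-component draws valid for a given design
random_vc <- function(design) {
  vc <- list(sigma_e2 = stats::runif(1, 0.3, 1.5))
  comp <- imprintvc:::vc_components(design)
  if ("sigma_g2" %in% comp) vc$sigma_g2 <- stats::runif(1, 0.05, 0.6)
  if ("sigma_s2" %in% comp) {
    s2 <- stats::runif(1, 0.05, 0.6)
    d2 <- stats::runif(1, 0.05, 0.6)
    rho <- stats::runif(1, -0.8, 0.95)
    vc$sigma_s2 <- s2; vc$sigma_d2 <- d2; vc$sigma_sd <- rho * sqrt(s2 * d2)
  }
  if ("sigma_c2" %in% comp) vc$sigma_c2 <- stats::runif(1, 0.02, 0.4)
  if ("sigma_m2" %in% comp) vc$sigma_m2 <- stats::runif(1, 0.02, 0.4)
  vc
}
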