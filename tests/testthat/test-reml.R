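test_that("with all variances zero the likelihood equals the closed-form residual REML", {
  ds <- small_dataset(seed = 11L, n_founders = 24L, n_generations = 3L)
  spec <- model_spec("y", fixed = list(term_factor("sex")))
  d <- build_design(spec, ds$pedigree, ds$phenotypes)
  for (se2 in c(0.4, 1, 2.3)) {
    ll <- reml_loglik_direct(d, list(sigma_g2 = 0, sigma_e2 = se2))
    expect_equal(ll, residual_reml_loglik(d$y, d$Xr, se2), tolerance = 1e-10)
  }
})

test_that("direct and MME evaluators agree across models and parameter draws", {
  set.seed(21)
  ds <- small_dataset(seed = 12L, n_founders = 20L, n_generations = 3L)
  specs <- list(
    model_spec("y", genetic = "mendelian"),
    model_spec("y", fixed = list(term_factor("sex")), genetic = "mendelian",
               maternal_env = TRUE),
    model_spec("y", genetic = "imprinting", maternal_env = TRUE,
               maternal_gen = TRUE)
  )
  for (spec in specs) {
    d <- build_design(spec, ds$pedigree, ds$phenotypes)
    for (r in 1:5) {
      vc <- random_vc(d)
      expect_equal(reml_loglik_direct(d, vc), reml_loglik_mme(d, vc),
                   tolerance = 1e-8)
    }
  }
})

test_that("the likelihood is invariant to permuting the phenotype records", {
  ds <- small_dataset(seed = 13L, n_founders = 20L, n_generations = 3L)
  spec <- model_spec("y", fixed = list(term_factor("sex")),
                     genetic = "imprinting", maternal_env = TRUE)
  phen <- ds$phenotypes
  set.seed(1)
  perm <- sample(nrow(phen))
  phen_p <- phen[perm, ]
  attributes(phen_p)[c("trait", "trait_kind", "covariates", "class")] <-
    attributes(phen)[c("trait", "trait_kind", "covariates", "class")]
  d1 <- build_design(spec, ds$pedigree, phen)
  d2 <- build_design(spec, ds$pedigree, phen_p)
  vc <- list(sigma_s2 = 0.3, sigma_d2 = 0.1, sigma_sd = 0.1,
             sigma_c2 = 0.1, sigma_e2 = 0.6)
  expect_equal(reml_loglik_direct(d1, vc), reml_loglik_direct(d2, vc),
               tolerance = 1e-9)
})

test_that("the Mendelian model is the constrained imprinting model", {
  ds <- small_dataset(seed = 14L, n_founders = 24L, n_generations = 3L)
  dm <- build_design(model_spec("y", genetic = "mendelian"),
                     ds$pedigree, ds$phenotypes)
  di <- build_design(model_spec("y", genetic = "imprinting"),
                     ds$pedigree, ds$phenotypes)
  for (g2 in c(0.05, 0.2, 0.5)) {
    ll_m <- reml_loglik_direct(dm, list(sigma_g2 = g2, sigma_e2 = 0.7))
    ll_i <- reml_loglik_direct(di, list(sigma_s2 = g2, sigma_d2 = g2,
                                        sigma_sd = g2, sigma_e2 = 0.7))
    expect_equal(ll_m, ll_i, tolerance = 1e-10)
  }
})

test_that("singular covariances raise classed errors", {
  ds <- small_dataset(seed = 15L, n_founders = 16L, n_generations = 3L)
  d <- build_design(model_spec("y", genetic = "imprinting"),
                    ds$pedigree, ds$phenotypes)
  expect_error(
    reml_loglik_direct(d, list(sigma_s2 = 0.3, sigma_d2 = 0.1, sigma_sd = 0.3,
                               sigma_e2 = 0.6)),
    class = "imprintvc_domain_error"   # Sigma not PSD
  )
  expect_error(
    reml_loglik_mme(d, list(sigma_s2 = 0.4, sigma_d2 = 0.1, sigma_sd = 0.2,
                            sigma_e2 = 0.6)),
    class = "imprintvc_singular_covariance"   # Sigma singular: no MME route
  )
})

test_that("pure-noise data drives the genetic variance to the boundary", {
  set.seed(31)
  meds <- replicate(8, {
    ds <- small_dataset(seed = sample.int(1e6, 1), n_founders = 24L,
                        n_generations = 3L,
                        true_vc = list(sigma_s2 = 0, sigma_d2 = 0,
                                       sigma_sd = 0, sigma_e2 = 1))
    d <- build_design(model_spec("y", genetic = "mendelian"),
                      ds$pedigree, ds$phenotypes)
    fit <- suppressWarnings(fit_reml(d, blups = FALSE))
    fit$vc$sigma_g2 / fit$vc$sigma_e2
  })
  expect_lt(stats::median(meds), 0.05)
})

test_that("BLUPs satisfy the mixed-model-equations identities at the optimum", {
  ds <- small_dataset(seed = 16L, n_founders = 24L, n_generations = 3L)
  spec <- model_spec("y", fixed = list(term_factor("sex")),
                     genetic = "mendelian", maternal_env = TRUE)
  d <- build_design(spec, ds$pedigree, ds$phenotypes)
  fit <- fit_reml(d)
  vc <- fit$vc
  b <- fit$fixef$estimate[!fit$fixef$aliased]
  u_g <- fit$blups$g
  u_c <- fit$blups$c
  resid <- d$y - as.vector(d$Xr %*% b) -
    (u_g[d$pat] + u_g[d$mat]) - as.vector(d$Z_c %*% u_c)
  # fixed-effect equations: X' R^-1 e = 0
  expect_lt(max(abs(crossprod(d$Xr, resid) / vc$sigma_e2)), 1e-6)
  # random-effect equations: Z' R^-1 e = G_u^-1 u
  lhs_g <- as.vector(Matrix::crossprod(d$Z_g, resid)) / vc$sigma_e2
  rhs_g <- as.vector(solve(unclass(d$G), u_g)) / vc$sigma_g2
  expect_lt(max(abs(lhs_g - rhs_g)), 1e-6)
  lhs_c <- as.vector(Matrix::crossprod(d$Z_c, resid)) / vc$sigma_e2
  expect_lt(max(abs(lhs_c - u_c / vc$sigma_c2)), 1e-6)
})

test_that("REML recovers the generating components on average (imprinting + c)", {
  # fixed pedigree, phenotypes redrawn; scaled-down recovery check
  set.seed(77)
  cfg <- sim_config(n_founders = 80L, n_generations = 4L,
                    mean_family_size = 3,
                    true_vc = list(sigma_s2 = 0.3, sigma_d2 = 0.1,
                                   sigma_sd = 0.1, sigma_c2 = 0.1,
                                   sigma_e2 = 0.6))
  ped <- simulate_pedigree(cfg, seed = 770L)
  relmat <- list(G = gametic_matrix(ped), A = NULL)
  spec <- model_spec("y", genetic = "imprinting", maternal_env = TRUE)
  nrep <- 10L
  est <- matrix(NA_real_, nrep, 5L)
  for (r in seq_len(nrep)) {
    phen <- simulate_phenotypes(ped, cfg, seed = 770L + r)
    d <- build_design(spec, ped, phen, relmat = relmat)
    fit <- suppressWarnings(fit_reml(d, blups = FALSE))
    est[r, ] <- unlist(fit$vc)
  }
  truth <- c(0.3, 0.1, 0.1, 0.1, 0.6)
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrep)
  # loose 3-SE gate at this reduced size; the acceptance suite runs the
  # full-size 2-SE version
  expect_true(all(abs(colMeans(est) - truth) <= 3 * mc_se + 0.02))
})

test_that("non-convergence surfaces as a classed warning with the state attached", {
  ds <- small_dataset(seed = 17L, n_founders = 16L, n_generations = 3L)
  d <- build_design(model_spec("y", genetic = "imprinting", maternal_env = TRUE),
                    ds$pedigree, ds$phenotypes)
  expect_warning(
    fit <- fit_reml(d, control = reml_control(max_iter = 1L), blups = FALSE),
    class = "imprintvc_no_convergence"
  )
  expect_false(fit$converged)
  expect_true(is.finite(fit$loglik))
})
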