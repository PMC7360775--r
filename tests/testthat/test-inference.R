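test_that("chi-square mixture survival function handles point mass, tails and reductions", {
  expect_equal(mixture_chi2_sf(0, null_imprinting()), 1)
  expect_equal(mixture_chi2_sf(0, null_boundary_1()), 1)
  # 0.5 * upper tail of chi2_1 at 2.706 ~ 0.5 * 0.100
  expect_equal(mixture_chi2_sf(2.706, null_boundary_1()),
               0.5 * stats::pchisq(2.706, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(mixture_chi2_sf(2.706, null_boundary_1()), 3), 0.050)
  # single-df mixture reduces to the plain chi-square survival function
  for (s in c(0.5, 2, 7)) {
    expect_equal(mixture_chi2_sf(s, null_chi2_1()),
                 stats::pchisq(s, 1, lower.tail = FALSE))
  }
  # strictly decreasing and vanishing
  stats_grid <- seq(0.5, 30, by = 0.5)
  ps <- vapply(stats_grid, mixture_chi2_sf, 0, null = null_imprinting())
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[length(ps)], 1e-4)
  expect_error(mixture_chi2_sf(-1, null_chi2_1()),
               class = "imprintvc_domain_error")
})

test_that("RLRT clips negative statistics and flags them", {
  t1 <- rlrt(-100, -100, null_chi2_1())
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1)
  expect_false(t1$negative_stat_flag)

  t2 <- rlrt(-102, -100, null_chi2_1())
  expect_equal(t2$statistic, 4)

  # alternative below null (the flat-likelihood situation): clipped + flagged
  t3 <- rlrt(8408.88, 8408.70, null_imprinting())
  expect_equal(t3$statistic, 0)
  expect_true(t3$negative_stat_flag)
  expect_equal(t3$p_value, 1)
})

test_that("derived parameters reproduce the printed-formula arithmetic exactly", {
  d <- derived_parameters(list(sigma_g2 = 0.1, sigma_e2 = 0.9),
                          model_kind = "mendelian", variant = "as_printed")
  expect_equal(d$sigma_a2, 0.2)
  expect_equal(d$sigma_p2, 1.0)
  expect_equal(d$h2, 0.2)

  # no imprinting: sigma_i2 = 0
  di <- derived_parameters(list(sigma_s2 = 0.4, sigma_d2 = 0.4,
                                sigma_sd = 0.4, sigma_e2 = 0.2),
                          variant = "as_printed")
  expect_equal(di$sigma_i2, 0)

  # full imprinting: sigma_i2 = 2, relative imprinting variance 1
  d2 <- derived_parameters(list(sigma_s2 = 1, sigma_d2 = 1, sigma_sd = 0,
                                sigma_e2 = 1))
  expect_equal(d2$sigma_i2, 2)
  expect_equal(d2$i2_rel, 1.0)

  # maternal ratios under Mendelian model 3
  d3 <- derived_parameters(list(sigma_g2 = 0.1, sigma_c2 = 0.2,
                                sigma_m2 = 0.1, sigma_e2 = 0.6),
                          model_kind = "mendelian", variant = "as_printed")
  expect_equal(d3$sigma_p2, 1.0)
  expect_equal(d3$c2, 0.2)
  expect_equal(d3$m2, 0.1)

  expect_error(derived_parameters(list(sigma_g2 = 0, sigma_e2 = 0),
                                  model_kind = "mendelian"),
               class = "imprintvc_domain_error")
})

test_that("as-printed h2 can exceed one (flagged); the consistent variant cannot", {
  vc <- list(sigma_g2 = 0.9, sigma_e2 = 0.1)
  expect_warning(d <- derived_parameters(vc, model_kind = "mendelian",
                                         variant = "as_printed"),
                 class = "imprintvc_h2_above_one")
  expect_gt(d$h2, 1)
  dc <- derived_parameters(vc, model_kind = "mendelian", variant = "consistent")
  expect_lte(dc$h2, 1)
})

test_that("consistent-variant ratios are invariant to rescaling all components", {
  vc <- list(sigma_s2 = 0.3, sigma_d2 = 0.1, sigma_sd = 0.1,
             sigma_c2 = 0.1, sigma_e2 = 0.6)
  d1 <- derived_parameters(vc, variant = "consistent")
  vc_scaled <- lapply(vc, `*`, 7.3)
  d2 <- derived_parameters(vc_scaled, variant = "consistent")
  for (nm in c("h2", "c2", "i2_rel")) expect_equal(d2[[nm]], d1[[nm]])
})

test_that("delta-method ratio standard errors shrink with sample size", {
  ses <- vapply(c(30L, 80L, 160L), function(nf) {
    ds <- small_dataset(seed = 50L + nf, n_founders = nf, n_generations = 4L)
    d <- build_design(model_spec("y", genetic = "mendelian",
                                 maternal_env = TRUE),
                      ds$pedigree, ds$phenotypes)
    fit <- suppressWarnings(fit_reml(d, blups = FALSE))
    derived_parameters(fit, variant = "consistent")$table |>
      (\(t) t$se[t$parameter == "h2"])()
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("incremental Wald F equals classical ANOVA F in a balanced one-way layout", {
  set.seed(61)
  n_lv <- 4L; per <- 25L
  f <- rep(sprintf("L%d", seq_len(n_lv)), each = per)
  y <- stats::rnorm(n_lv * per, mean = rep(c(0, 0.4, -0.2, 0.1), each = per))
  ped <- pedigree(id = sprintf("P%03d", seq_len(n_lv * per)),
                  sire = rep("0", n_lv * per), dam = rep("0", n_lv * per))
  phen <- phenotypes(data.frame(id = ped$id, y = y, grp = f), "y",
                     covariates = "grp", pedigree = ped)
  d <- build_design(model_spec("y", fixed = list(term_factor("grp")),
                               genetic = "none"), ped, phen)
  fit <- fit_reml(d)
  w <- wald_incremental(fit)
  oracle <- stats::anova(stats::lm(y ~ f))
  expect_equal(w$F[1], oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(w$DF[1], oracle$Df[1])
  expect_equal(w$DF_den[1], oracle$Df[2])
  expect_equal(w$P[1], oracle$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("a term repeated after its alias yields a DF = 0 NA row, and order matters", {
  ds <- small_dataset(seed = 62L, n_founders = 40L, n_generations = 3L)
  spec <- model_spec("y", fixed = list(term_factor("sex"), term_factor("sex")),
                     genetic = "mendelian")
  d <- build_design(spec, ds$pedigree, ds$phenotypes)
  fit <- suppressWarnings(fit_reml(d, blups = FALSE))
  w <- wald_incremental(fit)
  expect_equal(w$DF[2], 0L)
  expect_true(is.na(w$P[2]))

  # order sensitivity with correlated terms (sex and sex:sei share structure)
  spec2 <- model_spec("y", fixed = list(term_factor("sex"), term_factor("sei"),
                                        term_interaction(c("sex", "sei"))),
                      genetic = "mendelian")
  d2 <- build_design(spec2, ds$pedigree, ds$phenotypes)
  fit2 <- suppressWarnings(fit_reml(d2, blups = FALSE))
  w_fwd <- wald_incremental(fit2)
  w_rev <- wald_incremental(fit2, term_order = rev(names(d2$term_spans)))
  expect_false(isTRUE(all.equal(
    w_fwd$F[w_fwd$term == "sex"], w_rev$F[w_rev$term == "sex"])))
})

test_that("genetic-prediction correlation behaves at its fixed points", {
  ds <- small_dataset(seed = 63L, n_founders = 30L, n_generations = 3L)
  d <- build_design(model_spec("y", genetic = "mendelian"),
                    ds$pedigree, ds$phenotypes)
  fit <- suppressWarnings(fit_reml(d))
  expect_equal(compare_genetic_predictions(fit, fit), 1)
  fit_neg <- fit
  fit_neg$blups$g <- -fit_neg$blups$g
  expect_equal(compare_genetic_predictions(fit, fit_neg), -1)

  # independent random predictions decorrelate
  set.seed(64)
  fit_a <- fit; fit_b <- fit
  n2 <- length(fit$blups$g)
  fit_a$blups$g <- stats::rnorm(n2)
  fit_b$blups$g <- stats::rnorm(n2)
  expect_lt(abs(compare_genetic_predictions(fit_a, fit_b)), 0.15)

  fit_z <- fit
  fit_z$blups$g <- rep(0, n2)
  expect_error(compare_genetic_predictions(fit, fit_z),
               class = "imprintvc_domain_error")
})
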