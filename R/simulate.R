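#' Simulation configuration
#'
#' Describes a synthetic study population with the exact statistical
#' structure the models assume: a multi-generation pedigree from random
#' mating, per-gamete bivariate effect pairs with covariance `G (x) Sigma`
#' realized by gene dropping, maternal environmental effects shared within
#' sibships, maternal genetic effects with covariance `A sigma_m^2`,
#' categorical and smooth fixed effects, and a continuous or binary trait.
#'
#' Defaults emulate a registry-style disease cohort: five generations,
#' case/control status only in the most recent two generations (ancestors
#' lack phenotypes), sex and a 6-level maternal socio-economic factor, a
#' birth-year trend, a time-under-observation covariate acting through
#' cubic Legendre polynomials, and a population case rate of 0.38 in the
#' binary modes.
#'
#' @param n_founders founder count (split evenly between the sexes).
#' @param n_generations total generations including the founders (study
#'   pedigrees of this kind span five).
#' @param mean_family_size mean offspring count per mating (Poisson).
#' @param true_vc named list of generating variance components in the
#'   imprinting form: `sigma_s2`, `sigma_d2`, `sigma_sd`, optional
#'   `sigma_c2`, `sigma_m2`, and `sigma_e2`.
#' @param maternal_gen_corr correlation between the maternal-genetic trait
#'   and the direct gametic effects (default 0, the assumption of the
#'   fitted models; nonzero values probe that assumption's failure mode).
#' @param fixed_effects list with entries `sex` (scalar effect of female
#'   vs male), `sei` (vector of 6 level effects for the maternal
#'   socio-economic factor), `birth_year_slope` (linear trend per year on
#'   the trait scale) and `legendre` (length-3 coefficients on the
#'   time-under-observation Legendre polynomials).
#' @param trait_mode `"linear"`, `"logit_binary"` (Bernoulli with logistic
#'   probability, the correctly specified threshold-model generator) or
#'   `"liability_binary"` (thresholds the linear phenotype at the
#'   `base_rate` quantile; a link-misspecification probe).
#' @param base_rate marginal case probability for the binary modes.
#' @param phenotyped_generations how many of the most recent generations
#'   carry phenotypes (records without a known dam are skipped when
#'   maternal structure is generated).
#' @return list of class `imp_sim_config`.
#' @export
sim_config <- function(n_founders = 200L, n_generations = 5L,
                       mean_family_size = 3,
                       true_vc = list(sigma_s2 = 0.3, sigma_d2 = 0.1,
                                      sigma_sd = 0.1, sigma_c2 = 0.1,
                                      sigma_e2 = 0.6),
                       maternal_gen_corr = 0,
                       fixed_effects = list(
                         sex = 0.1,
                         sei = c(0, 0.05, -0.05, 0.1, 0.02, 0),
                         birth_year_slope = 0.01,
                         legendre = c(0.1, -0.05, 0.02)),
                       trait_mode = c("linear", "logit_binary",
                                      "liability_binary"),
                       base_rate = 0.38,
                       phenotyped_generations = 2L) {
  trait_mode <- match.arg(trait_mode)
  stopifnot(n_founders >= 2L, n_generations >= 1L, mean_family_size > 0)
  if (base_rate <= 0 || base_rate >= 1) {
    abort_imp("SPEC_ERROR", "base_rate must be in (0, 1)")
  }
  S <- matrix(c(true_vc$sigma_s2, true_vc$sigma_sd,
                true_vc$sigma_sd, true_vc$sigma_d2), 2, 2)
  if (any(diag(S) < 0) || S[1, 2]^2 > S[1, 1] * S[2, 2] + 1e-12) {
    abort_imp("SPEC_ERROR", "generating gametic covariance must be positive semidefinite")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 mean_family_size = mean_family_size,
                 true_vc = true_vc, maternal_gen_corr = maternal_gen_corr,
                 fixed_effects = fixed_effects, trait_mode = trait_mode,
                 base_rate = base_rate,
                 phenotyped_generations = as.integer(phenotyped_generations)),
            class = "imp_sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are split evenly between the sexes. In each later generation,
#' the previous generation's males and females are paired at random
#' (monogamous random mating within generation) and each couple draws a
#' Poisson(`mean_family_size`) offspring count; offspring sexes alternate
#' so the sex ratio stays balanced. Birth years advance by generation with
#' within-generation scatter.
#'
#' @param config an [sim_config()].
#' @param seed integer seed; identical `(config, seed)` gives an identical
#'   pedigree.
#' @return an `imp_pedigree` with `sex`, `birth_year` and a `generation`
#'   attribute (integer vector aligned with the records).
#' @export
simulate_pedigree <- function(config, seed = 1L) {
  set.seed(seed)
  id <- sprintf("F0_%04d", seq_len(config$n_founders))
  sex <- rep_len(c(1L, 2L), config$n_founders)
  gen <- rep(0L, config$n_founders)
  sire <- rep(NA_character_, config$n_founders)
  dam <- rep(NA_character_, config$n_founders)
  year0 <- 1944L
  gen_gap <- 16L
  birth_year <- year0 + sample(0:7, config$n_founders, replace = TRUE)

  cur_ids <- id; cur_sex <- sex
  for (g in seq_len(config$n_generations - 1L)) {
    males <- cur_ids[cur_sex == 1L]
    females <- cur_ids[cur_sex == 2L]
    nc <- min(length(males), length(females))
    if (nc == 0L) {
      abort_imp("SIM_ERROR",
                sprintf("no matings possible in generation %d", g))
    }
    males <- sample(males, nc)
    females <- sample(females, nc)
    counts <- stats::rpois(nc, config$mean_family_size)
    tot <- sum(counts)
    if (tot == 0L) {
      abort_imp("SIM_ERROR",
                sprintf("generation %d went extinct (no offspring drawn)", g))
    }
    off_sire <- rep(males, counts)
    off_dam <- rep(females, counts)
    off_id <- sprintf("F%d_%04d", g, seq_len(tot))
    off_sex <- rep_len(c(1L, 2L), tot)
    off_year <- year0 + g * gen_gap + sample(0:7, tot, replace = TRUE)
    id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    sex <- c(sex, off_sex); birth_year <- c(birth_year, off_year)
    gen <- c(gen, rep(g, tot))
    cur_ids <- off_id; cur_sex <- off_sex
  }
  ped <- pedigree(id, sire, dam, sex, birth_year)
  # records keep their construction order (parents precede offspring)
  attr(ped, "generation") <- gen[match(ped$id, id)]
  ped
}

#' Gene-drop bivariate gametic effects down a pedigree
#'
#' Realizes per-gamete effect pairs `(g_s, g_d)` whose joint covariance
#' across all `2N` gametes is exactly `G (x) Sigma`: founder gametes draw
#' independent bivariate normals with covariance `Sigma`; the gamete an
#' individual received from parent `p` is the mean of `p`'s two gamete
#' pairs plus an independent Mendelian-sampling residual with covariance
#' `0.5 (1 - F_p) Sigma`, where `F_p` is the parent's inbreeding
#' coefficient. Gametes from unknown parents are drawn as founder gametes.
#'
#' @param pedigree an `imp_pedigree`.
#' @param sigma named list with `sigma_s2`, `sigma_d2`, `sigma_sd`.
#' @param seed integer seed (NULL: use the current RNG stream).
#' @param inbreeding optional precomputed `F` vector (from
#'   [inbreeding()]); computed when missing.
#' @return `2N x 2` matrix of gamete effect pairs, columns `s` and `d`,
#'   rows aligned with the gamete slots of [gamete_index()].
#' @export
gene_drop_gametic <- function(pedigree, sigma, seed = NULL,
                              inbreeding = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(c(sigma$sigma_s2, sigma$sigma_sd,
                sigma$sigma_sd, sigma$sigma_d2), 2, 2)
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)   # PSD-safe root
  n <- n_individuals(pedigree)
  Fv <- inbreeding %||% if (all(pedigree$founder)) {
    numeric(n)                              # founders are non-inbred
  } else {
    diag(unclass(additive_matrix(pedigree))) - 1
  }
  E <- matrix(0, 2L * n, 2L, dimnames = list(NULL, c("s", "d")))
  for (i in seq_len(n)) {
    for (k in 1:2) {
      g <- 2L * (i - 1L) + k
      p <- if (k == 1L) pedigree$sire_idx[i] else pedigree$dam_idx[i]
      if (is.na(p)) {
        E[g, ] <- L %*% stats::rnorm(2)
      } else {
        mend <- sqrt(0.5 * (1 - Fv[p]))
        E[g, ] <- 0.5 * (E[2L * p - 1L, ] + E[2L * p, ]) +
          mend * (L %*% stats::rnorm(2))
      }
    }
  }
  E
}

# scalar additive gene drop (breeding values with Var = A * s2)
gene_drop_additive <- function(pedigree, s2, inbreeding = NULL) {
  n <- n_individuals(pedigree)
  Fv <- inbreeding %||% (diag(unclass(additive_matrix(pedigree))) - 1)
  a <- numeric(n)
  sdev <- sqrt(s2)
  for (i in seq_len(n)) {
    s <- pedigree$sire_idx[i]; d <- pedigree$dam_idx[i]
    pa <- 0
    f_par <- 0
    n_known <- 0L
    if (!is.na(s)) { pa <- pa + 0.5 * a[s]; f_par <- f_par + Fv[s]; n_known <- n_known + 1L }
    if (!is.na(d)) { pa <- pa + 0.5 * a[d]; f_par <- f_par + Fv[d]; n_known <- n_known + 1L }
    mend_var <- s2 * (1 - 0.25 * n_known) - 0.25 * f_par * s2
    a[i] <- pa + stats::rnorm(1, sd = sqrt(max(mend_var, 0)))
  }
  a
}

#' Simulate phenotypes on a pedigree
#'
#' Assembles the trait as `y = X b + g_s[paternal gamete] + g_d[maternal
#' gamete] + c[dam] + m[dam] + e` over the phenotyped individuals (the most
#' recent `phenotyped_generations` generations with a known dam when
#' maternal structure is generated). The maternal environmental effect `c`
#' is iid per mother; the maternal genetic effect `m` is a scalar additive
#' gene-drop with variance `sigma_m^2` (the dam's own value applies to all
#' her offspring). `"logit_binary"` draws `y ~ Bernoulli(expit(eta))` with
#' `eta` the linear predictor plus an intercept solving the base rate;
#' `"liability_binary"` thresholds the linear phenotype at the
#' `1 - base_rate` quantile.
#'
#' @param pedigree an `imp_pedigree` from [simulate_pedigree()] (its
#'   `generation` attribute selects the phenotyped set).
#' @param config an [sim_config()].
#' @param seed integer seed.
#' @return an `imp_phenotypes` with covariates `sex`, `birth_year`, `sei`,
#'   `years_obs`, and attribute `truth` (list with the realized gamete
#'   effect pairs, maternal effects, fixed-effect values and the generating
#'   `true_vc`).
#' @export
simulate_phenotypes <- function(pedigree, config, seed = 1L) {
  set.seed(seed)
  tv <- config$true_vc
  n <- n_individuals(pedigree)
  gen <- attr(pedigree, "generation")
  if (is.null(gen)) gen <- rep(0L, n)
  maternal_structure <- (tv$sigma_c2 %||% 0) > 0 || (tv$sigma_m2 %||% 0) > 0

  Fv <- diag(unclass(additive_matrix(pedigree))) - 1
  E <- gene_drop_gametic(pedigree, tv, seed = NULL, inbreeding = Fv)

  keep_gen <- gen > max(gen) - config$phenotyped_generations
  keep <- keep_gen & (!maternal_structure | !is.na(pedigree$dam_idx))
  if (!any(keep)) abort_imp("SIM_ERROR", "no phenotypable individuals")
  if (maternal_structure && all(is.na(pedigree$dam_idx[keep_gen]))) {
    abort_imp("SIM_ERROR", "maternal structure requested but no known dams")
  }
  idx <- which(keep)
  m <- length(idx)

  # maternal effects: c per mother (iid), m as a maternal additive trait
  cvals <- numeric(n)
  if ((tv$sigma_c2 %||% 0) > 0) {
    dams <- unique(stats::na.omit(pedigree$dam_idx))
    cvals[dams] <- stats::rnorm(length(dams), sd = sqrt(tv$sigma_c2))
  }
  mvals <- if ((tv$sigma_m2 %||% 0) > 0) {
    if (config$maternal_gen_corr != 0) {
      # correlate the maternal trait with the individual's mean direct effect
      rho <- config$maternal_gen_corr
      direct <- (E[2 * seq_len(n) - 1L, "s"] + E[2 * seq_len(n), "d"])
      dsd <- stats::sd(direct)
      indep <- gene_drop_additive(pedigree, tv$sigma_m2, inbreeding = Fv)
      rho * sqrt(tv$sigma_m2) * direct / max(dsd, 1e-12) +
        sqrt(1 - rho^2) * indep
    } else {
      gene_drop_additive(pedigree, tv$sigma_m2, inbreeding = Fv)
    }
  } else numeric(n)

  fe <- config$fixed_effects
  sex <- pedigree$sex[idx]
  sex[is.na(sex)] <- rep_len(c(1L, 2L), sum(is.na(sex)))
  birth_year <- pedigree$birth_year[idx]
  if (anyNA(birth_year)) birth_year[is.na(birth_year)] <- stats::median(birth_year, na.rm = TRUE)
  sei <- sample(seq_along(fe$sei), m, replace = TRUE)
  end_year <- max(birth_year)
  years_obs <- end_year - birth_year + stats::runif(m, 0, 4)
  leg <- legendre_covariates(years_obs, 3L, range = c(0, max(years_obs)))

  xb <- fe$sex * (sex == 2L) +
    fe$sei[sei] +
    fe$birth_year_slope * (birth_year - stats::median(birth_year)) +
    as.vector(leg %*% fe$legendre)

  gpat <- E[2L * idx - 1L, "s"]
  gmat <- E[2L * idx, "d"]
  dam_of <- pedigree$dam_idx[idx]
  cpart <- ifelse(is.na(dam_of), 0, cvals[dam_of])
  mpart <- ifelse(is.na(dam_of), 0, mvals[dam_of])
  e <- stats::rnorm(m, sd = sqrt(tv$sigma_e2))
  lin <- xb + gpat + gmat + cpart + mpart + e

  y <- switch(config$trait_mode,
    linear = lin,
    logit_binary = {
      eta0 <- lin - e                       # logit-scale predictor, no residual
      mu0 <- stats::qlogis(config$base_rate)
      icpt <- stats::uniroot(function(a) mean(stats::plogis(a + eta0)) - config$base_rate,
                             interval = mu0 + c(-20, 20))$root
      stats::rbinom(m, 1L, stats::plogis(icpt + eta0))
    },
    liability_binary = as.numeric(lin >= stats::quantile(lin, 1 - config$base_rate))
  )

  df <- data.frame(id = pedigree$id[idx], y = y,
                   sex = factor(sex), birth_year = birth_year,
                   sei = factor(sei), years_obs = years_obs,
                   stringsAsFactors = FALSE)
  out <- phenotypes(df, trait = "y",
                    covariates = c("sex", "birth_year", "sei", "years_obs"),
                    pedigree = pedigree)
  attr(out, "truth") <- list(gamete_effects = E, c = cvals, m = mvals,
                             xb = xb, true_vc = tv,
                             trait_mode = config$trait_mode,
                             phenotyped_idx = idx)
  out
}

#' Simulate a complete dataset
#'
#' @param config an [sim_config()].
#' @param seed master seed; the pedigree and the phenotypes draw from
#'   derived streams so the whole dataset is reproducible from
#'   `(config, seed)`.
#' @return list of class `imp_dataset` with `pedigree`, `phenotypes`,
#'   `truth` and `config`.
#' @export
simulate_dataset <- function(config, seed = 1L) {
  ped <- simulate_pedigree(config, seed = seed)
  phen <- simulate_phenotypes(ped, config, seed = seed + 1L)
  structure(list(pedigree = ped, phenotypes = phen,
                 truth = attr(phen, "truth"), config = config),
            class = "imp_dataset")
}

#' Write a dataset as plain-text fixtures
#'
#' Emits `pedigree.tsv`, `phenotypes.tsv` and `truth.yaml` into a
#' directory, in the dialect [read_pedigree()] and [read_phenotypes()]
#' consume, so a round trip reproduces the dataset.
#'
#' @param dataset an `imp_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- dataset$pedigree
  pf <- file.path(dir, "pedigree.tsv")
  pdf <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex, birth_year = ped$birth_year)
  utils::write.table(pdf, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  ff <- file.path(dir, "phenotypes.tsv")
  utils::write.table(as.data.frame(dataset$phenotypes), ff, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tf <- file.path(dir, "truth.yaml")
  cfg <- dataset$config
  yaml::write_yaml(list(true_vc = cfg$true_vc,
                        trait_mode = cfg$trait_mode,
                        base_rate = cfg$base_rate,
                        n_founders = cfg$n_founders,
                        n_generations = cfg$n_generations,
                        mean_family_size = cfg$mean_family_size), tf)
  invisible(c(pedigree = pf, phenotypes = ff, truth = tf))
}
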