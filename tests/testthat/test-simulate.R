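test_that("simulation is reproducible and degenerate configs behave", {
  cfg <- sim_config(n_founders = 20L, n_generations = 3L)
  p1 <- simulate_pedigree(cfg, seed = 5L)
  p2 <- simulate_pedigree(cfg, seed = 5L)
  expect_identical(p1, p2)
  d1 <- simulate_dataset(cfg, seed = 5L)
  d2 <- simulate_dataset(cfg, seed = 5L)
  expect_identical(d1$phenotypes$y, d2$phenotypes$y)
  d3 <- simulate_dataset(cfg, seed = 6L)
  expect_false(identical(d1$phenotypes$y, d3$phenotypes$y))

  # a single generation: everyone is a founder
  ped0 <- simulate_pedigree(sim_config(n_founders = 12L, n_generations = 1L),
                            seed = 1L)
  expect_true(all(ped0$founder))
})

test_that("pedigree growth follows the branching-process mean", {
  cfg <- sim_config(n_founders = 30L, n_generations = 3L,
                    mean_family_size = 3)
  set.seed(8)
  sizes <- replicate(40, {
    n_individuals(simulate_pedigree(cfg, seed = sample.int(1e6, 1)))
  })
  # E[N] = f * (1 + g + g^2) with g = mean_family_size / 2 couples-per-pair
  expected <- 30 * (1 + 1.5 + 1.5^2)
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("founder gamete pairs draw from the generating covariance", {
  ped <- pedigree(id = sprintf("F%05d", 1:20000), sire = rep("0", 20000),
                  dam = rep("0", 20000))
  sig <- list(sigma_s2 = 0.5, sigma_d2 = 0.2, sigma_sd = -0.1)
  E <- gene_drop_gametic(ped, sig, seed = 9L)
  emp <- stats::cov(E)
  # 3 MC standard errors for a covariance over 40k iid draws
  n_g <- nrow(E)
  tol <- 3 * sqrt((outer(diag(emp), diag(emp)) + emp^2) / n_g)
  target <- matrix(c(0.5, -0.1, -0.1, 0.2), 2, 2)
  expect_true(all(abs(emp - target) <= tol))

  # rank-1 Sigma: the two effects of every gamete perfectly correlated
  E1 <- gene_drop_gametic(ped, list(sigma_s2 = 0.4, sigma_d2 = 0.1,
                                    sigma_sd = 0.2), seed = 10L)
  expect_gt(stats::cor(E1[, "s"], E1[, "d"]), 0.999999)
})

test_that("gene dropping realizes the G-Kronecker covariance on a small pedigree", {
  # 10-individual pedigree with inbreeding; empirical cross-gamete second
  # moments over many replicates must match G (x) Sigma entrywise
  ped <- pedigree(
    id = c("S", "D", "A", "B", "X", "Y", "Z", "W", "Q", "R"),
    sire = c("0", "0", "S", "S", "A", "A", "X", "X", "Z", "Z"),
    dam = c("0", "0", "D", "D", "B", "B", "Y", "Y", "W", "W")
  )
  sig <- list(sigma_s2 = 0.6, sigma_d2 = 0.3, sigma_sd = 0.2)
  G <- unclass(gametic_matrix(ped))
  n2 <- nrow(G)
  reps <- 20000L
  set.seed(11)
  S_acc <- matrix(0, 2L * n2, 2L * n2)
  draws <- array(NA_real_, dim = c(reps, n2, 2))
  for (r in seq_len(reps)) {
    draws[r, , ] <- gene_drop_gametic(ped, sig, seed = NULL)
  }
  # gamete-major stacking: (gamete 1 s, gamete 1 d, gamete 2 s, ...)
  flat <- matrix(NA_real_, reps, 2L * n2)
  for (g in seq_len(n2)) {
    flat[, 2L * g - 1L] <- draws[, g, 1]
    flat[, 2L * g] <- draws[, g, 2]
  }
  emp <- crossprod(flat) / reps            # effects have mean zero
  Sig <- matrix(c(sig$sigma_s2, sig$sigma_sd, sig$sigma_sd, sig$sigma_d2), 2, 2)
  target <- kronecker(G, Sig)
  second <- crossprod(flat^2) / reps
  se <- sqrt(pmax(second - emp^2, 0) / reps)
  z <- abs(emp - target) / pmax(se, 1e-9)
  expect_gt(mean(z <= 3), 0.985)
  expect_lt(max(z), 6)
})

test_that("phenotype assembly decomposes as specified", {
  # all variances zero: y is exactly the fixed part
  cfg0 <- sim_config(n_founders = 30L, n_generations = 3L,
                     true_vc = list(sigma_s2 = 0, sigma_d2 = 0, sigma_sd = 0,
                                    sigma_e2 = 0))
  ds0 <- simulate_dataset(cfg0, seed = 21L)
  expect_equal(ds0$phenotypes$y, attr(ds0$phenotypes, "truth")$xb)

  # variance decomposition: sample variance of y matches the component sum
  tv <- list(sigma_s2 = 0.3, sigma_d2 = 0.1, sigma_sd = 0.1,
             sigma_c2 = 0.15, sigma_m2 = 0.1, sigma_e2 = 0.6)
  cfg <- sim_config(n_founders = 500L, n_generations = 4L,
                    mean_family_size = 3, true_vc = tv,
                    fixed_effects = list(sex = 0, sei = rep(0, 6),
                                         birth_year_slope = 0,
                                         legendre = c(0, 0, 0)))
  ds <- simulate_dataset(cfg, seed = 22L)
  y <- ds$phenotypes$y
  total <- tv$sigma_s2 + tv$sigma_d2 + tv$sigma_c2 + tv$sigma_m2 + tv$sigma_e2
  # cluster-robust MC standard error of the sample variance (families share
  # maternal and genetic effects, so records are not independent)
  z <- (y - mean(y))^2
  fam <- ds$pedigree$dam[match(ds$phenotypes$id, ds$pedigree$id)]
  cl <- tapply(z - mean(z), fam, sum)
  se <- sqrt(sum(cl^2)) / length(y)
  expect_lt(abs(stats::var(y) - total), 3 * se)
})

test_that("binary modes hit the base rate and logit mode centers at one half", {
  cfg <- sim_config(n_founders = 200L, n_generations = 3L,
                    true_vc = list(sigma_s2 = 0, sigma_d2 = 0, sigma_sd = 0,
                                   sigma_e2 = 1e-12),
                    fixed_effects = list(sex = 0, sei = rep(0, 6),
                                         birth_year_slope = 0,
                                         legendre = c(0, 0, 0)),
                    trait_mode = "logit_binary", base_rate = 0.5)
  ds <- simulate_dataset(cfg, seed = 23L)
  n <- nrow(ds$phenotypes)
  expect_lt(abs(mean(ds$phenotypes$y) - 0.5), 3 * sqrt(0.25 / n))

  cfg2 <- sim_config(n_founders = 200L, n_generations = 3L,
                     trait_mode = "liability_binary", base_rate = 0.38)
  ds2 <- simulate_dataset(cfg2, seed = 24L)
  expect_lt(abs(mean(ds2$phenotypes$y) - 0.38), 0.05)
})

test_that("fixtures round-trip and truth files echo the generating parameters", {
  dir <- withr::local_tempdir()
  ds <- small_dataset(seed = 25L, n_founders = 16L, n_generations = 3L)
  paths <- write_fixtures(ds, dir)
  expect_true(all(file.exists(paths)))
  truth <- yaml::read_yaml(paths["truth"])
  expect_equal(truth$true_vc$sigma_s2, 0.3)
  expect_equal(truth$true_vc$sigma_e2, 0.6)
  ped2 <- read_pedigree(paths["pedigree"])
  expect_identical(ped2$id, ds$pedigree$id)

  # different seeds: same schema, different phenotypes
  dir2 <- withr::local_tempdir()
  ds2 <- small_dataset(seed = 26L, n_founders = 16L, n_generations = 3L)
  paths2 <- write_fixtures(ds2, dir2)
  h1 <- readLines(paths["phenotypes"], n = 1)
  h2 <- readLines(paths2["phenotypes"], n = 1)
  expect_identical(h1, h2)
  expect_false(identical(readLines(paths["phenotypes"]),
                         readLines(paths2["phenotypes"])))
})
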