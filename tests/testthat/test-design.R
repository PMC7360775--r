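test_that("sparse birth-year levels merge forward, trailing remainder merges backward", {
  # 3 + 1 < 5 forces the shift into 1946: one merged level of size 10
  map <- merge_sparse_levels(c(`1944` = 3, `1945` = 1, `1946` = 6), 5)
  expect_equal(unname(map), rep("1944-1946", 3))

  # already large enough: unchanged
  map2 <- merge_sparse_levels(c(`1944` = 5, `1945` = 7), 5)
  expect_equal(unname(map2), c("1944", "1945"))

  # trailing small level merges backward into the previous closed group
  map3 <- merge_sparse_levels(c(`1944` = 9, `1945` = 2), 5)
  expect_equal(unname(map3), rep("1944-1945", 2))

  # all below min_count in total: single level plus warning
  expect_warning(map4 <- merge_sparse_levels(c(a = 1, b = 1), 5),
                 class = "imprintvc_sparse_levels")
  expect_equal(length(unique(map4)), 1L)
})

test_that("merged groups are contiguous, large enough and count-preserving", {
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(3:15, 1)
    counts <- stats::setNames(stats::rpois(k, 4), sprintf("%d", 1990 + seq_len(k)))
    counts[counts == 0] <- 1
    mc <- sample(2:8, 1)
    if (sum(counts) < mc) next
    map <- merge_sparse_levels(counts, mc)
    groups <- split(names(counts), map[names(counts)])
    for (g in groups) {
      idx <- match(g, names(counts))
      expect_equal(idx, seq(min(idx), max(idx)))      # contiguous
    }
    sizes <- tapply(counts, map[names(counts)], sum)
    # every group except possibly one (via backward merge) is >= min_count;
    # the backward-merged group is even larger, so all must pass
    expect_true(all(sizes >= mc))
    expect_equal(sum(sizes), sum(counts))
  }
})

test_that("Legendre covariates hit the endpoint and midpoint values", {
  rng <- c(0, 10)
  expect_equal(unname(legendre_covariates(10, 3, rng)[1, ]), c(1, 1, 1))
  expect_equal(unname(legendre_covariates(5, 3, rng)[1, ]), c(0, -0.5, 0))
  expect_equal(unname(legendre_covariates(0, 3, rng)[1, ]), c(-1, 1, -1))
  expect_error(legendre_covariates(11, 3, rng), class = "imprintvc_range_error")
  expect_error(legendre_covariates(1:3, 3, c(2, 2)), class = "imprintvc_range_error")
})

test_that("design matrices have the documented structure", {
  ds <- small_dataset(seed = 5L, n_founders = 20L, n_generations = 3L)
  ped <- ds$pedigree; phen <- ds$phenotypes

  # no fixed terms: intercept only
  d0 <- build_design(model_spec("y"), ped, phen)
  expect_equal(colnames(d0$X), "(Intercept)")

  # sex factor with full dummies: one column aliased against the intercept
  d1 <- build_design(model_spec("y", fixed = list(term_factor("sex"))),
                     ped, phen)
  expect_equal(ncol(d1$X), 3L)
  expect_equal(attr(d1$X, "rank"), 2L)
  expect_equal(sum(attr(d1$X, "aliased")), 1L)
  expect_true(all(d1$X[, attr(d1$X, "aliased")] == 0))

  # Mendelian: two unit entries per Z_g row, at the record's two slots
  dm <- build_design(model_spec("y", genetic = "mendelian"), ped, phen)
  expect_true(all(Matrix::rowSums(dm$Z_g) == 2))
  # Imprinting: Z_s picks only paternal (odd) slots, Z_d only maternal (even)
  di <- build_design(model_spec("y", genetic = "imprinting"), ped, phen)
  expect_true(all(Matrix::rowSums(di$Z_s) == 1))
  js <- Matrix::summary(di$Z_s)$j
  jd <- Matrix::summary(di$Z_d)$j
  expect_true(all(js %% 2 == 1))
  expect_true(all(jd %% 2 == 0))
  # merging the two imprinting incidences reproduces the Mendelian one
  expect_equal(as.matrix(di$Z_s + di$Z_d), as.matrix(dm$Z_g))

  # maternal incidences: one unit entry per row
  dc <- build_design(model_spec("y", maternal_env = TRUE, maternal_gen = TRUE),
                     ped, phen)
  expect_true(all(Matrix::rowSums(dc$Z_c) == 1))
  expect_true(all(Matrix::rowSums(dc$Z_m) == 1))
})

test_that("term spans partition the non-intercept columns of X", {
  ds <- small_dataset(seed = 6L, n_founders = 24L, n_generations = 3L)
  spec <- model_spec("y", fixed = list(
    term_factor("sex"), term_factor("sei"),
    term_interaction(c("sex", "sei")), term_legendre("years_obs", 3)))
  d <- build_design(spec, ds$pedigree, ds$phenotypes)
  spans <- unlist(d$term_spans)
  expect_equal(sort(unname(spans)), 2:ncol(d$X))
  expect_equal(anyDuplicated(spans), 0L)
})

test_that("spec errors are raised for bad model/data combinations", {
  ds <- small_dataset(seed = 7L, n_founders = 16L, n_generations = 3L)
  expect_error(build_design(model_spec("y", link = "logit"),
                            ds$pedigree, ds$phenotypes),
               class = "imprintvc_spec_error")
  expect_error(build_design(model_spec("nope"), ds$pedigree, ds$phenotypes),
               class = "imprintvc_spec_error")
  # missing covariate values are dropped with a warning
  phen2 <- ds$phenotypes
  phen2$years_obs[1:3] <- NA
  expect_warning(
    d <- build_design(model_spec("y", fixed = list(term_legendre("years_obs"))),
                      ds$pedigree, phen2),
    class = "imprintvc_missing_value"
  )
  expect_equal(d$n, nrow(ds$phenotypes) - 3L)
})

test_that("model specifications round-trip through YAML", {
  spec <- model_spec("y", fixed = list(
    term_factor("birth_year", merge_min_count = 5),
    term_factor("sex"),
    term_interaction(c("sex", "birth_year")),
    term_legendre("years_obs", 3, range = c(0, 60))),
    genetic = "imprinting", maternal_env = TRUE, link = "identity")
  f <- tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  spec2 <- read_model_spec(f)
  expect_equal(spec2, spec)
})
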