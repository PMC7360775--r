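#' Null distributions for one-sided restricted likelihood-ratio tests
#'
#' Describes the reference distribution of an RLRT statistic as a mixture of
#' chi-square laws, `sum_j w_j chi2_{df_j}`, where `df = 0` denotes a point
#' mass at zero (the boundary component). A plain chi-square with `df`
#' degrees of freedom is the one-element mixture.
#'
#' Defaults used by the model ladder: testing a single variance component
#' (maternal environmental or maternal genetic) uses a plain chi-square with
#' one degree of freedom, with the `0.5 chi2_0 + 0.5 chi2_1` boundary
#' mixture available; testing the imprinting variance (two extra
#' parameters, one on the boundary) uses the
#' `0.5 chi2_1 + 0.5 chi2_2` mixture.
#'
#' @param dfs integer vector of degrees of freedom (>= 0).
#' @param weights mixture weights, non-negative, summing to 1; defaults to
#'   equal weights.
#' @return object of class `imp_null_spec`.
#' @export
null_spec <- function(dfs, weights = NULL) {
  dfs <- as.integer(dfs)
  if (any(dfs < 0)) abort_imp("SPEC_ERROR", "degrees of freedom must be >= 0")
  weights <- weights %||% rep(1 / length(dfs), length(dfs))
  if (length(weights) != length(dfs) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort_imp("SPEC_ERROR", "weights must be non-negative and sum to 1")
  }
  structure(list(kind = if (length(dfs) == 1L) "chi2" else "mixture",
                 dfs = dfs, weights = weights),
            class = "imp_null_spec")
}

#' @rdname null_spec
#' @export
null_chi2_1 <- function() null_spec(1L)

#' @rdname null_spec
#' @export
null_boundary_1 <- function() null_spec(c(0L, 1L), c(0.5, 0.5))

#' @rdname null_spec
#' @export
null_imprinting <- function() null_spec(c(1L, 2L), c(0.5, 0.5))

#' Survival function of a chi-square mixture
#'
#' `p = sum_j w_j P(chi2_{df_j} > stat)`; a `df = 0` component contributes
#' 1 when `stat = 0` and 0 otherwise, so `stat = 0` always gives `p = 1`.
#'
#' @param stat non-negative test statistic.
#' @param null an [null_spec()].
#' @return upper-tail probability in `[0, 1]`.
#' @export
mixture_chi2_sf <- function(stat, null) {
  if (stat < 0) abort_imp("DOMAIN_ERROR", "test statistic must be >= 0")
  terms <- vapply(seq_along(null$dfs), function(j) {
    df <- null$dfs[j]
    if (df == 0L) as.numeric(stat <= 0)
    else stats::pchisq(stat, df = df, lower.tail = FALSE)
  }, 0)
  sum(null$weights * terms)
}

#' One-sided restricted likelihood-ratio test
#'
#' Computes `max(0, 2 (ll_alt - ll_null))` for a null model nested in (an
#' equivalent reparameterization of) the alternative and refers it to the
#' given chi-square mixture. A raw statistic below `-1e-6` -- an alternative
#' fit with a *lower* restricted likelihood than its null, which should not
#' happen when both fits converged -- sets `negative_stat_flag`, the
#' indicator of a flat likelihood surface or numerical inaccuracy.
#'
#' @param fit_null,fit_alt `imp_fit` objects or bare log-likelihood values.
#' @param null an [null_spec()]; default the imprinting mixture
#'   `0.5 chi2_1 + 0.5 chi2_2`.
#' @return object of class `imp_test`: `statistic`, `p_value`, `null`,
#'   `negative_stat_flag`, `ll_null`, `ll_alt`.
#' @export
rlrt <- function(fit_null, fit_alt, null = null_imprinting()) {
  ll0 <- if (inherits(fit_null, "imp_fit")) fit_null$loglik else as.numeric(fit_null)
  ll1 <- if (inherits(fit_alt, "imp_fit")) fit_alt$loglik else as.numeric(fit_alt)
  raw <- 2 * (ll1 - ll0)
  flag <- raw < -1e-6
  stat <- max(0, raw)
  structure(list(statistic = stat, p_value = mixture_chi2_sf(stat, null),
                 null = null, negative_stat_flag = flag,
                 ll_null = ll0, ll_alt = ll1),
            class = "imp_test")
}

#' @export
print.imp_test <- function(x, ...) {
  mix <- paste(sprintf("%.2g*chi2_%d", x$null$weights, x$null$dfs),
               collapse = " + ")
  cat(sprintf("RLRT: statistic = %.4f, null = %s, P = %.4g%s\n",
              x$statistic, mix, x$p_value,
              if (x$negative_stat_flag) "  [negative raw statistic: flat likelihood?]" else ""))
  invisible(x)
}

#' Derived population parameters
#'
#' Computes the additive, phenotypic and imprinting variances and the
#' corresponding ratios from fitted variance components.
#'
#' Under the Mendelian models the additive variance is
#' `sigma_a^2 = 2 sigma_g^2`. The `"as_printed"` variant keeps the
#' phenotypic variance as `sigma_p^2 = sigma_g^2 + sigma_e^2` (plus
#' `sigma_c^2` and `sigma_m^2` when present) -- the per-gamete variance
#' enters once, which can push `h^2` above 1 for strongly heritable traits
#' (then flagged). The `"consistent"` variant counts the full additive
#' contribution `2 sigma_g^2` inside `sigma_p^2`, which keeps all ratios in
#' `[0, 1]` and scale-invariant. Under the imprinting models
#' `sigma_a^2 = sigma_s^2 + sigma_d^2` and `sigma_p^2` adds the residual
#' plus any maternal components under both variants. The imprinting
#' variance is `sigma_i^2 = sigma_s^2 + sigma_d^2 - 2 sigma_sd`, zero under
#' pure Mendelian inheritance, and the relative imprinting variance is
#' `sigma_i^2 / sigma_a^2`.
#'
#' Standard errors of all ratios are obtained by the delta method from the
#' fit's variance-component covariance matrix when a fit is supplied.
#'
#' @param fit an `imp_fit`, or a bare named list of variance components (no
#'   SEs in that case).
#' @param model_kind `"mendelian"` or `"imprinting"`; inferred from the
#'   components when omitted.
#' @param variant `"as_printed"` (default) or `"consistent"`.
#' @param logit_residual for threshold (logit-scale) fits: `"none"` uses the
#'   components as they are; `"pi2_3"` adds the logit residual `pi^2 / 3`
#'   to `sigma_p^2` (both conventions are defensible; reports should state
#'   which one was used).
#' @return object of class `imp_derived`: a list with `sigma_a2`,
#'   `sigma_p2`, `sigma_i2` (imprinting only), `h2`, `c2`, `m2`, `i2_rel`
#'   and a data.frame `table` with estimates and standard errors.
#' @export
derived_parameters <- function(fit, model_kind = NULL,
                               variant = c("as_printed", "consistent"),
                               logit_residual = c("none", "pi2_3")) {
  variant <- match.arg(variant)
  logit_residual <- match.arg(logit_residual)
  if (inherits(fit, "imp_fit")) {
    vc <- fit$vc
    vcov <- fit$vcov_sigma
  } else {
    vc <- fit
    vcov <- NULL
  }
  model_kind <- model_kind %||%
    (if (!is.null(vc$sigma_s2)) "imprinting" else "mendelian")

  extra_e <- if (logit_residual == "pi2_3") pi^2 / 3 else 0
  fns <- derived_fns(model_kind, variant, names(vc), extra_e)
  est <- lapply(fns, function(f) f(vc))
  if (est$sigma_p2 <= 0) abort_imp("DOMAIN_ERROR", "phenotypic variance is zero")

  ses <- rep(NA_real_, length(fns))
  names(ses) <- names(fns)
  if (!is.null(vcov)) {
    comp <- rownames(vcov)
    for (nm in names(fns)) {
      g <- num_gradient_vc(fns[[nm]], vc, comp)
      ses[nm] <- sqrt(max(0, as.numeric(t(g) %*% vcov %*% g)))
    }
  }
  flagged <- !is.na(est$h2) && est$h2 > 1
  if (flagged) {
    warn_imp("H2_ABOVE_ONE",
             sprintf("as-printed h2 = %.3f exceeds 1; see the 'consistent' variant", est$h2))
  }
  tab <- data.frame(parameter = names(fns),
                    estimate = unlist(est),
                    se = unname(ses),
                    stringsAsFactors = FALSE)
  structure(c(est, list(table = tab, variant = variant,
                        model_kind = model_kind, h2_above_one = flagged)),
            class = "imp_derived")
}

derived_fns <- function(model_kind, variant, have, extra_e) {
  has_c <- "sigma_c2" %in% have
  has_m <- "sigma_m2" %in% have
  if (model_kind == "mendelian") {
    sigma_a2 <- function(v) 2 * v$sigma_g2
    sigma_p2 <- function(v) {
      g <- if (variant == "consistent") 2 * v$sigma_g2 else v$sigma_g2
      g + v$sigma_e2 + extra_e + (if (has_c) v$sigma_c2 else 0) +
        (if (has_m) v$sigma_m2 else 0)
    }
    fns <- list(sigma_a2 = sigma_a2, sigma_p2 = sigma_p2,
                h2 = function(v) sigma_a2(v) / sigma_p2(v))
  } else {
    sigma_a2 <- function(v) v$sigma_s2 + v$sigma_d2
    sigma_p2 <- function(v) {
      sigma_a2(v) + v$sigma_e2 + extra_e + (if (has_c) v$sigma_c2 else 0) +
        (if (has_m) v$sigma_m2 else 0)
    }
    sigma_i2 <- function(v) v$sigma_s2 + v$sigma_d2 - 2 * v$sigma_sd
    fns <- list(sigma_a2 = sigma_a2, sigma_p2 = sigma_p2,
                sigma_i2 = sigma_i2,
                h2 = function(v) sigma_a2(v) / sigma_p2(v),
                i2_rel = function(v) sigma_i2(v) / sigma_a2(v))
  }
  if (has_c) fns$c2 <- function(v) v$sigma_c2 / sigma_p2(v)
  if (has_m) fns$m2 <- function(v) v$sigma_m2 / sigma_p2(v)
  fns
}

num_gradient_vc <- function(f, vc, comp, h = 1e-6) {
  g <- numeric(length(comp))
  scale <- max(abs(unlist(vc)), 1e-8)
  for (i in seq_along(comp)) {
    vp <- vc; vm <- vc
    step <- h * scale
    vp[[comp[i]]] <- vp[[comp[i]]] + step
    vm[[comp[i]]] <- vm[[comp[i]]] - step
    g[i] <- (f(vp) - f(vm)) / (2 * step)
  }
  g
}

#' @export
print.imp_derived <- function(x, ...) {
  cat(sprintf("<imp_derived> %s model, %s variant%s\n", x$model_kind,
              x$variant, if (isTRUE(x$h2_above_one)) "  [h2 > 1]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Incremental Wald F tests for fixed effects
#'
#' Tests each fixed term by adding terms in the declared order at the fitted
#' variance components (the covariance `V` is held fixed): after whitening
#' by the Cholesky factor of `V`, the F statistic for a term is the drop in
#' residual sum of squares divided by the term's rank increment, over the
#' full model's residual mean square. The rank increment counts only
#' columns not linearly dependent on earlier columns (singular effects are
#' zeroed), so a fully aliased term yields a `DF = 0` row with `P = NA`.
#' The denominator degrees of freedom are `n - rank(X)` of the full fixed
#' design; software-specific numerical denominator-DF approximations are
#' not replicated, so reported `DF_den` (and hence P values) are the
#' residual-DF convention.
#'
#' With no random effects the statistic reduces exactly to the classical
#' sequential ANOVA F.
#'
#' @param fit an `imp_fit`.
#' @param term_order optional character vector re-ordering the terms
#'   (labels as in the design's `term_spans`); reordering changes the
#'   incremental statistics, as it must.
#' @return data.frame with columns `term`, `F`, `DF`, `DF_den`, `P`.
#' @export
wald_incremental <- function(fit, term_order = NULL) {
  design <- fit$design
  spans <- design$term_spans
  if (!length(spans)) return(data.frame(term = character(0), F = numeric(0),
                                        DF = integer(0), DF_den = numeric(0),
                                        P = numeric(0)))
  labels <- term_order %||% names(spans)
  if (!all(labels %in% names(spans))) {
    abort_imp("SPEC_ERROR", "term_order contains unknown term labels")
  }
  sig <- c(kernel_coefs(design, fit$vc), fit$vc$sigma_e2)
  V <- build_V(design, sig)
  U <- chol(V)
  Xw <- backsolve(U, design$X, transpose = TRUE)   # note: uses original (zeroed) X
  yw <- backsolve(U, design$y, transpose = TRUE)

  n <- design$n
  # sequential fit: intercept first, then terms in requested order
  Q <- matrix(0, n, 0L)
  add_cols <- function(cols) {
    r <- 0L
    for (j in cols) {
      v <- Xw[, j]
      nv0 <- sqrt(sum(v^2))
      if (nv0 == 0) next
      for (pass in 1:2) if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
      nv <- sqrt(sum(v^2))
      if (nv >= 1e-8 * nv0) {
        Q <<- cbind(Q, v / nv)
        r <- r + 1L
      }
    }
    r
  }
  yss <- sum(yw^2)
  rss <- function() yss - sum(crossprod(Q, yw)^2)
  add_cols(which(colnames(design$X) == "(Intercept)"))
  rss_prev <- rss()
  rows <- data.frame(term = labels, F = NA_real_, DF = 0L,
                     DF_den = NA_real_, P = NA_real_,
                     stringsAsFactors = FALSE)
  drops <- numeric(length(labels))
  for (i in seq_along(labels)) {
    r <- add_cols(spans[[labels[i]]])
    rss_cur <- rss()
    rows$DF[i] <- r
    drops[i] <- rss_prev - rss_cur
    rss_prev <- rss_cur
  }
  rank_full <- ncol(Q)
  df_den <- n - rank_full
  s2 <- rss_prev / df_den
  for (i in seq_along(labels)) {
    if (rows$DF[i] > 0L) {
      rows$F[i] <- (drops[i] / rows$DF[i]) / s2
      rows$DF_den[i] <- df_den
      rows$P[i] <- stats::pf(rows$F[i], rows$DF[i], df_den, lower.tail = FALSE)
    }
  }
  rows
}

#' Correlation of predicted genetic values between two fits
#'
#' Pearson correlation of the per-individual genetic values (sum of the two
#' gamete BLUPs) of two fits over the same individuals -- the standard
#' concordance check between, e.g., a linear and a threshold fit of the
#' same model.
#'
#' @param fit_a,fit_b `imp_fit` objects carrying genetic BLUPs.
#' @return Pearson correlation coefficient.
#' @export
compare_genetic_predictions <- function(fit_a, fit_b) {
  ga <- genetic_values(fit_a)
  gb <- genetic_values(fit_b)
  common <- intersect(names(ga), names(gb))
  if (!length(common)) abort_imp("SPEC_ERROR", "fits share no individuals")
  ga <- ga[common]; gb <- gb[common]
  if (stats::sd(ga) == 0 || stats::sd(gb) == 0) {
    abort_imp("DOMAIN_ERROR", "zero variance in predicted genetic values")
  }
  stats::cor(ga, gb)
}
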