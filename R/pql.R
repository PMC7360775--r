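#' Fit a logit threshold model by penalized quasi-likelihood
#'
#' Fits the generalized linear mixed (threshold) counterpart of a linear
#' model on a binary 0/1 trait with a logit link, using the penalized
#' quasi-likelihood working-variate scheme: at the current linear predictor
#' `eta` the class probabilities are `mu = exp(eta) / (1 + exp(eta))`, the
#' working response is `z = eta + (y - mu) / [mu (1 - mu)]` with weights
#' `W = mu (1 - mu)`, and the weighted linear mixed model with the
#' specification's random structure is refitted on `z` until `eta` reaches a
#' fixed point. The residual variance on the working scale is fixed at 1
#' (the standard PQL dispersion choice); the logit-scale residual variance
#' `pi^2 / 3` is reported separately for ratio computations.
#'
#' Internally the model is for `P(y = 1)`; the class-zero probability
#' `pi0 = 1 - mu` (the convention in which threshold-model reports are often
#' written) is returned alongside, and fixed-effect signs flip between the
#' two conventions.
#'
#' The quantity reported as `loglik` is the restricted likelihood of the
#' final working model, an approximate criterion that cannot be used for
#' likelihood-ratio testing across models; hypothesis tests in this package
#' are linear-model-only.
#'
#' @param design an `imp_design` built with `link = "logit"` on a binary
#'   trait.
#' @param control an [reml_control()] for the inner linear fits.
#' @param max_iter,tol outer-iteration cap and relative convergence
#'   tolerance on `eta`.
#' @return an `imp_fit` with additional class `imp_pql_fit` and fields
#'   `eta`, `mu`, `pi0`, `pql_iter`, `scale = "logit"`.
#' @export
fit_pql <- function(design, control = reml_control(), max_iter = 50L,
                    tol = 1e-6) {
  if (design$spec$link != "logit" || design$trait_kind != "binary") {
    abort_imp("SPEC_ERROR", "fit_pql requires a binary trait and link = 'logit'")
  }
  y <- design$y
  if (length(unique(y)) < 2L) {
    abort_imp("SEPARATION", "all responses identical; class probabilities are degenerate")
  }
  mu <- (y + mean(y)) / 2
  eta <- stats::qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6))
  start <- NULL
  fit <- NULL
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (min(w) < 1e-10 || max(abs(eta)) > 30) {
      abort_imp("SEPARATION",
                "working weights underflow (quasi-complete separation)")
    }
    z <- eta + (y - mu) / w
    wd <- design
    wd$y <- z
    wd$weights <- w
    fit <- fit_reml(wd, start = start, control = control,
                    fix_sigma_e = 1, blups = TRUE)
    start <- fit$vc
    eta_new <- as.vector(linear_predictor(fit))
    delta <- max(abs(eta_new - eta)) / (1 + max(abs(eta_new)))
    eta <- eta_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    if (control$on_nonconvergence == "error") {
      abort_imp("NO_CONVERGENCE",
                sprintf("PQL did not reach a fixed point in %d iterations", max_iter))
    }
    warn_imp("NO_CONVERGENCE",
             sprintf("PQL did not reach a fixed point in %d iterations", max_iter))
    fit$converged <- FALSE
  }
  mu <- stats::plogis(eta)
  fit$eta <- eta
  fit$mu <- mu
  fit$pi0 <- 1 - mu
  fit$pql_iter <- it
  fit$scale <- "logit"
  class(fit) <- c("imp_pql_fit", class(fit))
  fit
}

# Xb + Zu at the current inner fit
linear_predictor <- function(fit) {
  design <- fit$design
  eta <- as.vector(design$X %*% fit$fixef$estimate)
  b <- fit$blups
  if (!is.null(b$g)) {
    eta <- eta + b$g[design$pat] + b$g[design$mat]
  } else if (!is.null(b$g_s)) {
    eta <- eta + b$g_s[design$pat] + b$g_d[design$mat]
  }
  if (!is.null(b$c)) eta <- eta + as.vector(design$Z_c %*% b$c)
  if (!is.null(b$m)) eta <- eta + as.vector(design$Z_m %*% b$m)
  unname(eta)
}

#' Logit-scale residual variance
#'
#' The implicit residual variance of a logistic threshold model on the
#' liability (logit) scale, `pi^2 / 3`, used when phenotypic-variance ratios
#' are computed from a PQL fit.
#' @return `pi^2 / 3`.
#' @export
logit_residual_variance <- function() pi^2 / 3
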