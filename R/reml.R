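#' Control settings for the REML optimizer
#'
#' @param max_iter maximum Newton iterations per start.
#' @param tol_loglik relative log-likelihood change declaring convergence.
#' @param tol_grad gradient max-norm (unconstrained scale) declaring
#'   convergence.
#' @param n_starts number of starts; the first is a deterministic heuristic
#'   (an equal split of the phenotypic variance), further starts are seeded
#'   random perturbations of it.
#' @param seed seed for the random restarts.
#' @param max_step cap on the max-norm of a Newton step (unconstrained
#'   scale), for stability far from the optimum.
#' @param information `"ai"` uses the average-information matrix at the
#'   optimum as the information matrix; `"numeric"` finite-differences the
#'   analytic gradient for an observed-information estimate.
#' @param on_nonconvergence `"warn"` returns the best state found with
#'   `converged = FALSE`; `"error"` raises a `NO_CONVERGENCE` condition.
#' @param verbose print the iteration trace.
#' @return a list of class `imp_reml_control`.
#' @export
reml_control <- function(max_iter = 100L, tol_loglik = 1e-8, tol_grad = 1e-5,
                         n_starts = 1L, seed = 1L, max_step = 2,
                         information = c("ai", "numeric"),
                         on_nonconvergence = c("warn", "error"),
                         verbose = FALSE) {
  structure(list(max_iter = max_iter, tol_loglik = tol_loglik,
                 tol_grad = tol_grad, n_starts = n_starts, seed = seed,
                 max_step = max_step, information = match.arg(information),
                 on_nonconvergence = match.arg(on_nonconvergence),
                 verbose = verbose),
            class = "imp_reml_control")
}

# ---- variance-component bookkeeping -----------------------------------

VC_FLOOR <- 1e-10

# canonical component names for a design, in the order of design$K
vc_components <- function(design) {
  map <- c(g = "sigma_g2", gss = "sigma_s2", gdd = "sigma_d2",
           gsd = "sigma_sd", c = "sigma_c2", m = "sigma_m2")
  unname(map[names(design$K)])
}

# coefficients of the K kernels (in design$K order) from a vc list
kernel_coefs <- function(design, vc) {
  comp <- vc_components(design)
  miss <- setdiff(comp, names(vc))
  if (length(miss)) {
    abort_imp("SPEC_ERROR",
              sprintf("variance components missing for this model: %s",
                      paste(miss, collapse = ", ")))
  }
  vapply(comp, function(nm) as.numeric(vc[[nm]]), 0)
}

validate_vc <- function(design, vc) {
  comp <- vc_components(design)
  if (all(c("sigma_s2", "sigma_d2", "sigma_sd") %in% comp)) {
    s2 <- vc$sigma_s2; d2 <- vc$sigma_d2; sd <- vc$sigma_sd
    if (s2 < 0 || d2 < 0 || sd^2 > s2 * d2 + 1e-12) {
      abort_imp("DOMAIN_ERROR",
                "gametic covariance [[sigma_s2, sigma_sd], [sigma_sd, sigma_d2]] must be positive semidefinite")
    }
  }
  for (nm in intersect(c("sigma_g2", "sigma_c2", "sigma_m2"), comp)) {
    if (vc[[nm]] < 0) abort_imp("DOMAIN_ERROR", sprintf("%s must be >= 0", nm))
  }
  if (is.null(vc$sigma_e2) || vc$sigma_e2 <= 0) {
    abort_imp("DOMAIN_ERROR", "sigma_e2 must be > 0")
  }
  invisible(TRUE)
}

# Unconstrained parameterization:
#  - imprinting Sigma via log-Cholesky: theta = (log l11, l21, log l22),
#    Sigma = L L' so the PSD boundary (including rank-1, the no-imprinting
#    null) stays reachable;
#  - scalar variances on the log scale with a small floor.
theta_names <- function(design, fix_sigma_e = NULL) {
  comp <- vc_components(design)
  nm <- character(0)
  if ("sigma_g2" %in% comp) nm <- c(nm, "log_sigma_g2")
  if ("sigma_s2" %in% comp) nm <- c(nm, "log_l11", "l21", "log_l22")
  if ("sigma_c2" %in% comp) nm <- c(nm, "log_sigma_c2")
  if ("sigma_m2" %in% comp) nm <- c(nm, "log_sigma_m2")
  if (is.null(fix_sigma_e)) nm <- c(nm, "log_sigma_e2")
  nm
}

# natural coefficients (K order + sigma_e2 last) and Jacobian wrt theta
theta_to_sigma <- function(design, theta, fix_sigma_e = NULL) {
  comp <- vc_components(design)
  nk <- length(comp)
  sig <- numeric(nk + 1L)
  J <- matrix(0, nk + 1L, length(theta))
  ti <- 0L
  for (ci in seq_along(comp)) {
    nm <- comp[ci]
    if (nm == "sigma_g2" || nm == "sigma_c2" || nm == "sigma_m2") {
      ti <- ti + 1L
      v <- exp(theta[ti])
      sig[ci] <- v + VC_FLOOR
      J[ci, ti] <- v
    } else if (nm == "sigma_s2") {
      l11 <- exp(theta[ti + 1L]); l21 <- theta[ti + 2L]; l22 <- exp(theta[ti + 3L])
      i_s <- ci; i_d <- which(comp == "sigma_d2"); i_sd <- which(comp == "sigma_sd")
      sig[i_s] <- l11^2 + VC_FLOOR
      sig[i_d] <- l21^2 + l22^2 + VC_FLOOR
      sig[i_sd] <- l11 * l21
      J[i_s, ti + 1L] <- 2 * l11^2
      J[i_sd, ti + 1L] <- l11 * l21
      J[i_sd, ti + 2L] <- l11
      J[i_d, ti + 2L] <- 2 * l21
      J[i_d, ti + 3L] <- 2 * l22^2
      ti <- ti + 3L
    }
    # sigma_d2 / sigma_sd handled together with sigma_s2
  }
  if (is.null(fix_sigma_e)) {
    ti <- ti + 1L
    v <- exp(theta[ti])
    sig[nk + 1L] <- v + VC_FLOOR
    J[nk + 1L, ti] <- v
  } else {
    sig[nk + 1L] <- fix_sigma_e
  }
  list(sig = sig, J = J)
}

sigma_to_theta <- function(design, vc, fix_sigma_e = NULL) {
  comp <- vc_components(design)
  th <- numeric(0)
  if ("sigma_g2" %in% comp) th <- c(th, log(max(vc$sigma_g2, VC_FLOOR)))
  if ("sigma_s2" %in% comp) {
    l11 <- sqrt(max(vc$sigma_s2, VC_FLOOR))
    l21 <- vc$sigma_sd / l11
    l22sq <- max(vc$sigma_d2 - l21^2, VC_FLOOR)
    th <- c(th, log(l11), l21, 0.5 * log(l22sq))
  }
  if ("sigma_c2" %in% comp) th <- c(th, log(max(vc$sigma_c2, VC_FLOOR)))
  if ("sigma_m2" %in% comp) th <- c(th, log(max(vc$sigma_m2, VC_FLOOR)))
  if (is.null(fix_sigma_e)) th <- c(th, log(max(vc$sigma_e2, VC_FLOOR)))
  th
}

vc_from_sigma <- function(design, sig) {
  comp <- vc_components(design)
  out <- as.list(sig[seq_along(comp)])
  names(out) <- comp
  out$sigma_e2 <- sig[length(comp) + 1L]
  out
}

# ---- likelihood machinery ---------------------------------------------

build_V <- function(design, sig) {
  nk <- length(design$K)
  r0 <- if (is.null(design$weights)) rep(1, design$n) else 1 / design$weights
  V <- diag(sig[nk + 1L] * r0, design$n)
  for (j in seq_len(nk)) V <- V + sig[j] * design$K[[j]]
  V
}

# Core REML evaluation at natural coefficients `sig` (K order + sigma_e2).
# want = "ll" | "grad" (gradient + AI in the natural scale).
reml_core <- function(design, sig, want = "ll") {
  n <- design$n
  Xr <- design$Xr
  p <- ncol(Xr)
  y <- design$y
  r0 <- if (is.null(design$weights)) rep(1, n) else 1 / design$weights
  V <- build_V(design, sig)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% Xr
  XtViX <- crossprod(Xr, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  logdetX <- 2 * sum(log(diag(chX)))
  Viy <- Vi %*% y
  XtViy <- crossprod(Xr, Viy)
  beta <- backsolve(chX, forwardsolve(t(chX), XtViy))
  Py <- as.vector(Viy - ViX %*% beta)
  yPy <- sum(y * Py)
  ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + yPy)
  out <- list(ll = ll, beta = as.vector(beta), XtViX = XtViX, chX = chX,
              Py = Py, Vi = Vi, ViX = ViX)
  if (want == "ll") return(out)

  P <- Vi - ViX %*% backsolve(chX, forwardsolve(t(chX), t(ViX)))
  nk <- length(design$K)
  m <- nk + 1L
  grad <- numeric(m)
  U <- matrix(0, n, m)
  for (j in seq_len(nk)) {
    Kj <- design$K[[j]]
    trPK <- sum(P * Kj)                    # Kj symmetric
    u <- Kj %*% Py
    grad[j] <- -0.5 * (trPK - sum(Py * u))
    U[, j] <- u
  }
  trPR <- sum(diag(P) * r0)
  uR <- r0 * Py
  grad[m] <- -0.5 * (trPR - sum(Py * uR))
  U[, m] <- uR
  AI <- 0.5 * crossprod(U, P %*% U)
  out$grad <- grad
  out$AI <- AI
  out$P <- P
  out
}

#' REML log-likelihood by direct covariance evaluation
#'
#' Evaluates the restricted log-likelihood
#' `-0.5 [ (n - p) log(2 pi) + log|V| + log|X' V^-1 X| + y' P y ]`
#' where `V` is the marginal covariance implied by the variance components:
#' the genetic kernel (Mendelian `sigma_g^2` or the imprinting
#' `Sigma`-weighted gametic blocks of `G (x) Sigma`), plus `sigma_c^2` and
#' `sigma_m^2` kernels when present, plus `sigma_e^2 I`. The additive
#' constant includes the `(n - p) log(2 pi)` term, shared with
#' [reml_loglik_mme()] so the two evaluators are directly comparable.
#'
#' @param design an `imp_design`.
#' @param vc named list of variance components, e.g.
#'   `list(sigma_g2 = 0.2, sigma_e2 = 0.8)` or
#'   `list(sigma_s2 =, sigma_d2 =, sigma_sd =, sigma_e2 =)`.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik_direct <- function(design, vc) {
  validate_vc(design, vc)
  sig <- c(kernel_coefs(design, vc), vc$sigma_e2)
  ev <- reml_core(design, sig, want = "ll")
  if (is.null(ev)) {
    abort_imp("SINGULAR_COVARIANCE", "V or X'V^-1 X is numerically singular")
  }
  ev$ll
}

#' REML log-likelihood via the mixed-model equations
#'
#' Computes the same restricted log-likelihood as [reml_loglik_direct()]
#' through the mixed-model-equations identity
#' `-0.5 [ (n - p) log(2 pi) + log|R| + log|G_u| + log|C| + y' P y ]`,
#' where `C` is the MME coefficient matrix and `G_u` the joint random-effect
#' covariance (for the imprinting structure, `Sigma (x) G` over the stacked
#' `[g_s; g_d]`, an ordering equivalent to the gamete-major `G (x) Sigma`).
#' This route requires the inverses of `G`, `Sigma` and `A` and is used as
#' an independent oracle for the direct evaluator at desk scale.
#'
#' @inheritParams reml_loglik_direct
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik_mme <- function(design, vc) {
  validate_vc(design, vc)
  n <- design$n
  Xr <- design$Xr
  p <- ncol(Xr)
  y <- design$y
  w <- if (is.null(design$weights)) rep(1, n) else design$weights
  se2 <- vc$sigma_e2
  rinv <- w / se2
  logdetR <- sum(log(se2 / w))

  Zblocks <- list()
  Ginv_blocks <- list()
  logdetGu <- 0
  spec <- design$spec
  if (spec$genetic == "mendelian") {
    G <- unclass(design$G)
    chG <- chol(G)
    if (vc$sigma_g2 <= 0) abort_imp("SINGULAR_COVARIANCE", "sigma_g2 must be > 0 for the MME route")
    Zblocks$g <- as.matrix(design$Z_g)
    Ginv_blocks$g <- chol2inv(chG) / vc$sigma_g2
    logdetGu <- logdetGu + nrow(G) * log(vc$sigma_g2) + 2 * sum(log(diag(chG)))
  } else if (spec$genetic == "imprinting") {
    G <- unclass(design$G)
    chG <- chol(G)
    Sig <- matrix(c(vc$sigma_s2, vc$sigma_sd, vc$sigma_sd, vc$sigma_d2), 2, 2)
    detS <- Sig[1, 1] * Sig[2, 2] - Sig[1, 2]^2
    if (detS <= 0 || Sig[1, 1] <= 0) {
      abort_imp("SINGULAR_COVARIANCE",
                "gametic covariance Sigma must be positive definite for the MME route")
    }
    Ginv <- chol2inv(chG)
    Sinv <- solve(Sig)
    Zblocks$g <- cbind(as.matrix(design$Z_s), as.matrix(design$Z_d))
    Ginv_blocks$g <- rbind(cbind(Sinv[1, 1] * Ginv, Sinv[1, 2] * Ginv),
                           cbind(Sinv[2, 1] * Ginv, Sinv[2, 2] * Ginv))
    logdetGu <- logdetGu + nrow(G) * log(detS) + 4 * sum(log(diag(chG)))
  }
  if (spec$maternal_env) {
    Zblocks$c <- as.matrix(design$Z_c)
    Ginv_blocks$c <- diag(1 / vc$sigma_c2, ncol(Zblocks$c))
    logdetGu <- logdetGu + ncol(Zblocks$c) * log(vc$sigma_c2)
  }
  if (spec$maternal_gen) {
    A <- unclass(design$A)
    chA <- chol(A)
    Zblocks$m <- as.matrix(design$Z_m)
    Ginv_blocks$m <- chol2inv(chA) / vc$sigma_m2
    logdetGu <- logdetGu + nrow(A) * log(vc$sigma_m2) + 2 * sum(log(diag(chA)))
  }
  if (!length(Zblocks)) {
    # no random terms: REML of the weighted fixed-effects regression
    XtWX <- crossprod(Xr * rinv, Xr)
    chX <- chol(XtWX)
    b <- backsolve(chX, forwardsolve(t(chX), crossprod(Xr, rinv * y)))
    r <- y - Xr %*% b
    yPy <- sum(rinv * r^2)
    return(-0.5 * ((n - p) * log(2 * pi) + logdetR + 2 * sum(log(diag(chX))) + yPy))
  }

  Z <- do.call(cbind, Zblocks)
  q <- ncol(Z)
  Gu_inv <- matrix(0, q, q)
  off <- 0L
  for (nm in names(Zblocks)) {
    k <- ncol(Zblocks[[nm]])
    Gu_inv[off + seq_len(k), off + seq_len(k)] <- Ginv_blocks[[nm]]
    off <- off + k
  }
  W <- cbind(Xr, Z)
  WtRiW <- crossprod(W * rinv, W)
  C <- WtRiW
  ii <- p + seq_len(q)
  C[ii, ii] <- C[ii, ii] + Gu_inv
  chC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chC)) abort_imp("SINGULAR_COVARIANCE", "MME coefficient matrix is singular")
  rhs <- crossprod(W, rinv * y)
  sol <- backsolve(chC, forwardsolve(t(chC), rhs))
  yPy <- sum(rinv * y^2) - sum(rhs * sol)
  -0.5 * ((n - p) * log(2 * pi) + logdetR + logdetGu + 2 * sum(log(diag(chC))) + yPy)
}

# ---- fitting -----------------------------------------------------------

default_start <- function(design, fix_sigma_e = NULL) {
  comp <- vc_components(design)
  qr0 <- qr(design$Xr)
  rss <- sum(qr.resid(qr0, design$y)^2)
  vtot <- rss / max(design$n - qr0$rank, 1L)
  nscal <- sum(comp %in% c("sigma_c2", "sigma_m2"))
  vc <- list()
  if ("sigma_g2" %in% comp) vc$sigma_g2 <- 0.15 * vtot
  if ("sigma_s2" %in% comp) {
    vc$sigma_s2 <- 0.15 * vtot
    vc$sigma_d2 <- 0.15 * vtot
    vc$sigma_sd <- 0.075 * vtot
  }
  if ("sigma_c2" %in% comp) vc$sigma_c2 <- 0.1 * vtot
  if ("sigma_m2" %in% comp) vc$sigma_m2 <- 0.1 * vtot
  vc$sigma_e2 <- if (is.null(fix_sigma_e)) {
    max(vtot * (1 - 0.3 - 0.1 * nscal), 0.1 * vtot)
  } else fix_sigma_e
  vc
}

#' Fit a pedigree mixed model by REML
#'
#' Maximizes the restricted likelihood over an unconstrained
#' parameterization (log-Cholesky for the 2 x 2 gametic covariance of the
#' imprinting structure, log scale for scalar variances) with a
#' Newton/average-information ascent: analytic gradients, the
#' average-information matrix as the Hessian approximation, step halving,
#' and an optional set of seeded random restarts. Convergence requires both
#' a relative log-likelihood change below `tol_loglik` and a gradient
#' max-norm below `tol_grad`.
#'
#' @param design an `imp_design` from [build_design()].
#' @param start optional named list of starting variance components; by
#'   default a deterministic split of the phenotypic variance.
#' @param control an [reml_control()].
#' @param fix_sigma_e if non-NULL, the residual variance is fixed at this
#'   value instead of being estimated (used by the threshold model, where
#'   the working-scale residual variance is 1).
#' @param blups compute BLUPs of all random effects and fixed-effect
#'   estimates at the optimum (set `FALSE` to save memory/time in large
#'   simulation studies that only need variance components).
#' @return object of class `imp_fit`: list with `vc` (named variance
#'   components), `loglik`, `converged`, `n_iter`, `gradient`,
#'   `info_theta` (information matrix, unconstrained scale), `vcov_sigma`
#'   (delta-method covariance of the natural components), `se` (their
#'   standard errors), `fixef` (data.frame of fixed-effect estimates, NA
#'   rows for aliased columns), `blups` (list `g` or `g_s`/`g_d` per gamete
#'   slot, `c` per mother, `m` per individual), and the `design`.
#' @export
fit_reml <- function(design, start = NULL, control = reml_control(),
                     fix_sigma_e = NULL, blups = TRUE) {
  comp <- vc_components(design)
  tn <- theta_names(design, fix_sigma_e)

  if (!length(tn)) {                      # nothing to estimate: plain (W)GLS
    sig <- c(kernel_coefs(design, list()), fix_sigma_e)
    ev <- reml_core(design, sig, want = "ll")
    return(finalize_fit(design, theta = numeric(0), ev = ev,
                        sigJ = list(sig = sig, J = matrix(0, 1, 0)),
                        converged = TRUE, n_iter = 0L, control = control,
                        fix_sigma_e = fix_sigma_e, blups = blups))
  }
  if (!length(comp) && is.null(fix_sigma_e)) {
    # residual-only REML has a closed form
    qr0 <- qr(design$Xr)
    w <- if (is.null(design$weights)) rep(1, design$n) else design$weights
    sw <- sqrt(w)
    qrw <- qr(design$Xr * sw)
    rssw <- sum(qr.resid(qrw, design$y * sw)^2)
    se2 <- rssw / (design$n - qrw$rank)
    sig <- se2
    ev <- reml_core(design, sig, want = "ll")
    return(finalize_fit(design, theta = log(se2), ev = ev,
                        sigJ = theta_to_sigma(design, log(se2), NULL),
                        converged = TRUE, n_iter = 0L, control = control,
                        fix_sigma_e = NULL, blups = blups))
  }

  vc0 <- start %||% default_start(design, fix_sigma_e)
  starts <- list(sigma_to_theta(design, vc0, fix_sigma_e))
  if (control$n_starts > 1L) {
    rs <- get_rng_state()
    on.exit(restore_rng_state(rs), add = TRUE)
    set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1L)) {
      starts[[s + 1L]] <- starts[[1L]] + stats::rnorm(length(tn), sd = 0.7)
    }
  }

  best <- NULL
  for (th0 in starts) {
    res <- newton_ai(design, th0, control, fix_sigma_e)
    if (is.null(best) || (!is.null(res) && res$ll > best$ll)) best <- res
  }
  if (is.null(best)) {
    abort_imp("NO_CONVERGENCE", "REML likelihood could not be evaluated at any start")
  }
  if (!best$converged) {
    msg <- sprintf("REML did not converge in %d iterations (|grad| = %.2e)",
                   best$n_iter, max(abs(best$ev$grad_theta)))
    if (control$on_nonconvergence == "error") {
      abort_imp("NO_CONVERGENCE", msg, data = best)
    }
    warn_imp("NO_CONVERGENCE", msg)
  }
  finalize_fit(design, theta = best$theta, ev = best$ev, sigJ = best$sigJ,
               converged = best$converged, n_iter = best$n_iter,
               control = control, fix_sigma_e = fix_sigma_e, blups = blups)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# Newton ascent with AI Hessian on the unconstrained scale.
newton_ai <- function(design, theta, control, fix_sigma_e) {
  eval_at <- function(th, want) {
    sigJ <- theta_to_sigma(design, th, fix_sigma_e)
    ev <- reml_core(design, sigJ$sig, want = want)
    if (is.null(ev)) return(NULL)
    if (want == "grad") {
      ev$grad_theta <- as.vector(crossprod(sigJ$J, ev$grad))
      ev$AI_theta <- crossprod(sigJ$J, ev$AI %*% sigJ$J)
    }
    list(ev = ev, sigJ = sigJ)
  }
  cur <- eval_at(theta, "grad")
  if (is.null(cur)) return(NULL)
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    g <- cur$ev$grad_theta
    H <- cur$ev$AI_theta
    # ridge until the AI matrix is safely positive definite
    lam <- 1e-8 * max(1, max(abs(diag(H))))
    step <- NULL
    for (k in 1:30) {
      step <- tryCatch(solve(H + lam * diag(nrow(H)), g),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) break
      lam <- lam * 10
    }
    if (is.null(step) || !all(is.finite(step))) step <- g / max(1, max(abs(g)))
    sm <- max(abs(step))
    if (sm > control$max_step) step <- step * control$max_step / sm

    # full step first, with the gradient evaluated in the same factorization
    # (most iterations accept it); otherwise step-halve on cheap ll-only
    # evaluations and re-evaluate the gradient at the accepted point
    accepted <- NULL
    t_acc <- 1
    cand <- eval_at(theta + step, "grad")
    if (!is.null(cand) && is.finite(cand$ev$ll) &&
        cand$ev$ll >= cur$ev$ll - 1e-12) {
      accepted <- cand
    } else {
      t_ls <- 0.5
      for (h in 1:29) {
        cand <- eval_at(theta + t_ls * step, "ll")
        if (!is.null(cand) && is.finite(cand$ev$ll) &&
            cand$ev$ll >= cur$ev$ll - 1e-12) {
          t_acc <- t_ls
          break
        }
        cand <- NULL
        t_ls <- t_ls / 2
      }
      if (!is.null(cand)) accepted <- eval_at(theta + t_acc * step, "grad")
    }
    if (is.null(accepted)) break          # no improving point found
    theta <- theta + t_acc * step
    dll <- accepted$ev$ll - cur$ev$ll
    cur <- accepted
    if (control$verbose) {
      message(sprintf("iter %3d  ll = %.8f  dll = %.3e  |g| = %.3e",
                      it, cur$ev$ll, dll, max(abs(cur$ev$grad_theta))))
    }
    if (abs(dll) < control$tol_loglik * (1 + abs(cur$ev$ll)) &&
        max(abs(cur$ev$grad_theta)) < control$tol_grad) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, ll = cur$ev$ll, ev = cur$ev, sigJ = cur$sigJ,
       converged = converged, n_iter = it)
}

# eigen-based pseudo-inverse (boundary fits make the information singular)
pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

finalize_fit <- function(design, theta, ev, sigJ, converged, n_iter, control,
                         fix_sigma_e, blups) {
  if (is.null(ev)) abort_imp("SINGULAR_COVARIANCE", "likelihood not evaluable at the optimum")
  comp <- vc_components(design)
  vc <- vc_from_sigma(design, sigJ$sig)
  # information matrix on the unconstrained scale
  info_theta <- NULL
  vcov_sigma <- NULL
  if (length(theta)) {
    if (control$information == "numeric") {
      info_theta <- -num_hessian_grad(design, theta, fix_sigma_e)
    } else if (!is.null(ev$AI)) {
      info_theta <- crossprod(sigJ$J, ev$AI %*% sigJ$J)
    } else {
      ev2 <- reml_core(design, sigJ$sig, want = "grad")
      info_theta <- crossprod(sigJ$J, ev2$AI %*% sigJ$J)
      ev <- ev2
    }
    vcov_sigma <- sigJ$J %*% pinv_sym(info_theta) %*% t(sigJ$J)
    rownames(vcov_sigma) <- colnames(vcov_sigma) <- c(comp, "sigma_e2")
  }
  se <- if (!is.null(vcov_sigma)) sqrt(pmax(diag(vcov_sigma), 0)) else NULL

  fixef <- NULL
  blup_list <- NULL
  if (blups) {
    if (is.null(ev$Py)) {
      ev <- reml_core(design, sigJ$sig, want = "ll")
    }
    aliased <- attr(design$X, "aliased")
    bse <- sqrt(diag(chol2inv(ev$chX)))
    est <- rep(0, ncol(design$X))
    sev <- rep(NA_real_, ncol(design$X))
    est[!aliased] <- ev$beta
    sev[!aliased] <- bse
    fixef <- data.frame(term = colnames(design$X), estimate = est,
                        se = sev, aliased = aliased,
                        stringsAsFactors = FALSE)
    blup_list <- compute_blups(design, vc, ev$Py)
  }
  structure(list(
    vc = vc, loglik = ev$ll, converged = converged, n_iter = n_iter,
    theta = theta, gradient = ev$grad_theta %||% numeric(0),
    info_theta = info_theta, vcov_sigma = vcov_sigma, se = se,
    fixef = fixef, blups = blup_list,
    flat_likelihood_warning = FALSE,
    fix_sigma_e = fix_sigma_e, control = control, design = design
  ), class = "imp_fit")
}

num_hessian_grad <- function(design, theta, fix_sigma_e, h = 1e-4) {
  k <- length(theta)
  gfun <- function(th) {
    sigJ <- theta_to_sigma(design, th, fix_sigma_e)
    ev <- reml_core(design, sigJ$sig, want = "grad")
    if (is.null(ev)) return(rep(NA_real_, k))
    as.vector(crossprod(sigJ$J, ev$grad))
  }
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h
    H[, i] <- (gfun(theta + e) - gfun(theta - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

compute_blups <- function(design, vc, Py) {
  spec <- design$spec
  out <- list()
  if (spec$genetic == "mendelian") {
    tg <- as.vector(Matrix::crossprod(design$Z_g, Py))
    out$g <- as.vector(unclass(design$G) %*% (vc$sigma_g2 * tg))
    names(out$g) <- rownames(design$G)
  } else if (spec$genetic == "imprinting") {
    ts <- as.vector(Matrix::crossprod(design$Z_s, Py))
    td <- as.vector(Matrix::crossprod(design$Z_d, Py))
    G <- unclass(design$G)
    out$g_s <- as.vector(G %*% (vc$sigma_s2 * ts + vc$sigma_sd * td))
    out$g_d <- as.vector(G %*% (vc$sigma_sd * ts + vc$sigma_d2 * td))
    names(out$g_s) <- names(out$g_d) <- rownames(G)
  }
  if (spec$maternal_env) {
    out$c <- vc$sigma_c2 * as.vector(Matrix::crossprod(design$Z_c, Py))
    names(out$c) <- design$pedigree$id[design$mothers]
  }
  if (spec$maternal_gen) {
    tm <- as.vector(Matrix::crossprod(design$Z_m, Py))
    out$m <- as.vector(unclass(design$A) %*% (vc$sigma_m2 * tm))
    names(out$m) <- design$pedigree$id
  }
  out
}

#' Per-individual genetic values from a fit
#'
#' Sums the two gamete BLUPs of each individual: under the Mendelian model
#' `g[paternal slot] + g[maternal slot]`; under the imprinting model the
#' paternally transmitted effect of the paternal gamete plus the maternally
#' transmitted effect of the maternal gamete,
#' `g_s[paternal slot] + g_d[maternal slot]`.
#'
#' @param fit an `imp_fit` with BLUPs.
#' @return named numeric vector over all pedigree individuals.
#' @export
genetic_values <- function(fit) {
  b <- fit$blups
  if (is.null(b)) abort_imp("SPEC_ERROR", "fit carries no BLUPs (refit with blups = TRUE)")
  ped <- fit$design$pedigree
  N <- n_individuals(ped)
  pat <- seq(1L, 2L * N, by = 2L)
  mat <- pat + 1L
  gv <- if (!is.null(b$g)) {
    b$g[pat] + b$g[mat]
  } else if (!is.null(b$g_s)) {
    b$g_s[pat] + b$g_d[mat]
  } else {
    abort_imp("SPEC_ERROR", "fit has no genetic effects")
  }
  stats::setNames(as.vector(gv), ped$id)
}

#' @export
print.imp_fit <- function(x, ...) {
  cat(sprintf("<imp_fit> REML log-likelihood %.4f (%s, %d iterations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  comp <- names(x$vc)
  est <- unlist(x$vc)
  se <- if (!is.null(x$se)) x$se[comp] else rep(NA_real_, length(comp))
  print(data.frame(component = comp, estimate = round(est, 6),
                   se = round(se, 6), row.names = NULL))
  invisible(x)
}
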