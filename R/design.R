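#' Fixed-effect term constructors
#'
#' A model's fixed part is declared as an ordered list of terms. Order
#' matters: incremental Wald F tests add terms in the declared order, and
#' aliased (linearly dependent) columns are zeroed against the columns of
#' earlier terms, mirroring software that sets singular effects to zero.
#'
#' * `term_factor()` -- a categorical effect coded with one full dummy column
#'   per level (no reference level; redundancy is resolved by singular-column
#'   zeroing). `merge_min_count` applies the sparse-level merging rule of
#'   [merge_sparse_levels()] before coding, e.g. so every birth-year level
#'   keeps at least five individuals.
#' * `term_interaction()` -- product dummies of two or more factors, built
#'   after any level merging of the parent factors.
#' * `term_legendre()` -- Legendre polynomial covariates of a continuous
#'   variable up to `order` (1 = linear, 2 = quadratic, 3 = cubic), the
#'   standard way to model a time-under-observation effect smoothly.
#'
#' @param name,names covariate column name(s) in the phenotype table.
#' @param merge_min_count minimum level count before merging kicks in
#'   (NULL = no merging).
#' @param order highest Legendre order, in 1..3.
#' @param range numeric length-2 standardization range for the covariate
#'   (default: observed min/max).
#' @return an object of class `imp_term`.
#' @name fixed_terms
NULL

#' @rdname fixed_terms
#' @export
term_factor <- function(name, merge_min_count = NULL) {
  structure(list(kind = "factor", columns = name,
                 merge_min_count = merge_min_count,
                 label = name),
            class = "imp_term")
}

#' @rdname fixed_terms
#' @export
term_interaction <- function(names) {
  if (length(names) < 2L) {
    abort_imp("SPEC_ERROR", "an interaction needs at least two factors")
  }
  structure(list(kind = "interaction", columns = names,
                 label = paste(names, collapse = ":")),
            class = "imp_term")
}

#' @rdname fixed_terms
#' @export
term_legendre <- function(name, order = 3L, range = NULL) {
  order <- as.integer(order)
  if (!order %in% 1:3) abort_imp("SPEC_ERROR", "legendre order must be 1, 2 or 3")
  structure(list(kind = "legendre", columns = name, order = order,
                 range = range, label = sprintf("leg(%s,%d)", name, order)),
            class = "imp_term")
}

#' Declarative model specification
#'
#' Describes one member of the model ladder: the trait, the ordered fixed
#' terms, the random genetic structure, and optional maternal terms.
#'
#' * `genetic = "mendelian"`: one gametic effect vector `g` (length 2N) with
#'   variance `G sigma_g^2`; each record picks up the sum of its paternal and
#'   maternal gamete effects.
#' * `genetic = "imprinting"`: two gametic effect vectors `g_s` (expression
#'   when paternally transmitted) and `g_d` (maternal transmission), with
#'   joint covariance `G (x) Sigma`, `Sigma = [[sigma_s^2, sigma_sd],
#'   [sigma_sd, sigma_d^2]]` (Kronecker product, effects stored
#'   gamete-major); a record picks up `g_s[paternal slot] + g_d[maternal
#'   slot]`. The imprinting variance is `sigma_i^2 = sigma_s^2 + sigma_d^2 -
#'   2 sigma_sd`, zero when the two expression patterns coincide.
#' * `genetic = "none"` drops the genetic term (used e.g. for plain logistic
#'   fits that serve as oracles for the threshold model).
#'
#' `maternal_env` adds a maternal (shared-household) effect `c` per mother,
#' iid with variance `sigma_c^2`; `maternal_gen` adds a maternal genetic
#' effect `m` with covariance `A sigma_m^2`, the dam's value applying to
#' each of her offspring. `link = "logit"` marks the model for the
#' penalized quasi-likelihood threshold fit and requires a binary trait.
#'
#' @param trait trait column name.
#' @param fixed ordered list of [fixed_terms].
#' @param genetic `"mendelian"`, `"imprinting"` or `"none"`.
#' @param maternal_env,maternal_gen logical flags.
#' @param link `"identity"` or `"logit"`.
#' @return object of class `imp_model_spec`.
#' @export
model_spec <- function(trait, fixed = list(),
                       genetic = c("mendelian", "imprinting", "none"),
                       maternal_env = FALSE, maternal_gen = FALSE,
                       link = c("identity", "logit")) {
  genetic <- match.arg(genetic)
  link <- match.arg(link)
  stopifnot(is.list(fixed))
  for (tm in fixed) {
    if (!inherits(tm, "imp_term")) {
      abort_imp("SPEC_ERROR", "fixed terms must be built with term_*() constructors")
    }
  }
  structure(list(trait = trait, fixed = fixed, genetic = genetic,
                 maternal_env = isTRUE(maternal_env),
                 maternal_gen = isTRUE(maternal_gen), link = link),
            class = "imp_model_spec")
}

#' @export
print.imp_model_spec <- function(x, ...) {
  terms <- vapply(x$fixed, `[[`, "", "label")
  cat(sprintf("<imp_model_spec> trait=%s link=%s genetic=%s%s%s\n  fixed: %s\n",
              x$trait, x$link, x$genetic,
              if (x$maternal_env) " + c" else "",
              if (x$maternal_gen) " + m" else "",
              if (length(terms)) paste(terms, collapse = ", ") else "(intercept only)"))
  invisible(x)
}

#' Serialize / read a model specification
#'
#' Round-trips an `imp_model_spec` through a YAML file losslessly.
#'
#' @param spec an `imp_model_spec`.
#' @param path file path.
#' @return `read_model_spec()` returns the reconstructed `imp_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  fixed <- lapply(spec$fixed, function(tm) {
    out <- list(kind = tm$kind, columns = as.list(tm$columns))
    if (!is.null(tm$merge_min_count)) out$merge_min_count <- tm$merge_min_count
    if (!is.null(tm$order)) out$order <- tm$order
    if (!is.null(tm$range)) out$range <- as.list(tm$range)
    out
  })
  yaml::write_yaml(list(trait = spec$trait, genetic = spec$genetic,
                        maternal_env = spec$maternal_env,
                        maternal_gen = spec$maternal_gen,
                        link = spec$link, fixed = fixed), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  fixed <- lapply(raw$fixed, function(tm) {
    cols <- unlist(tm$columns)
    switch(tm$kind,
      factor = term_factor(cols, merge_min_count = tm$merge_min_count),
      interaction = term_interaction(cols),
      legendre = term_legendre(cols, order = tm$order,
                               range = if (!is.null(tm$range)) unlist(tm$range)),
      abort_imp("SPEC_ERROR", sprintf("unknown term kind '%s'", tm$kind))
    )
  })
  model_spec(trait = raw$trait, fixed = fixed, genetic = raw$genetic,
             maternal_env = raw$maternal_env, maternal_gen = raw$maternal_gen,
             link = raw$link)
}

#' Merge sparse ordered factor levels
#'
#' Implements the birth-year style merging rule: scanning the levels in
#' their natural ascending order, individuals in a level with fewer than
#' `min_count` members are shifted into the next level until every merged
#' level holds at least `min_count`; a trailing remainder below `min_count`
#' is merged backward into the last closed group.
#'
#' @param counts named vector of level counts, names in ascending level
#'   order.
#' @param min_count minimum members per merged level (>= 1).
#' @return named character vector mapping each original level to its merged
#'   level label (`"first-last"` for multi-level groups).
#' @examples
#' merge_sparse_levels(c(`1944` = 3, `1945` = 1, `1946` = 6), 5)
#' @export
merge_sparse_levels <- function(counts, min_count) {
  stopifnot(min_count >= 1)
  lv <- names(counts)
  if (is.null(lv)) abort_imp("SPEC_ERROR", "counts must be named by level")
  if (sum(counts) < min_count) {
    warn_imp("SPARSE_LEVELS",
             "total count below min_count; all levels merged into one")
    lab <- group_label(lv)
    return(stats::setNames(rep(lab, length(lv)), lv))
  }
  groups <- list()
  cur <- character(0)
  acc <- 0
  for (i in seq_along(lv)) {
    cur <- c(cur, lv[i])
    acc <- acc + counts[i]
    if (acc >= min_count) {
      groups[[length(groups) + 1L]] <- cur
      cur <- character(0)
      acc <- 0
    }
  }
  if (length(cur)) {  # trailing remainder: backward merge
    k <- length(groups)
    groups[[k]] <- c(groups[[k]], cur)
  }
  out <- character(0)
  for (g in groups) out[g] <- group_label(g)
  out[lv]
}

group_label <- function(levels) {
  if (length(levels) == 1L) levels else
    paste(levels[1L], levels[length(levels)], sep = "-")
}

#' Legendre polynomial covariates
#'
#' Standardizes `t` to `x = -1 + 2 (t - t_min) / (t_max - t_min)` on
#' `[-1, 1]` and evaluates the Legendre polynomials `P1(x) = x`,
#' `P2(x) = (3x^2 - 1)/2`, `P3(x) = (5x^3 - 3x)/2` up to `order`.
#'
#' @param t numeric vector.
#' @param order highest order, in 1..3.
#' @param range standardization range `c(t_min, t_max)`; values of `t`
#'   outside it are an error.
#' @return n x order matrix with columns `leg1..leg<order>`.
#' @export
legendre_covariates <- function(t, order = 3L, range = base::range(t)) {
  order <- as.integer(order)
  if (!order %in% 1:3) abort_imp("SPEC_ERROR", "legendre order must be 1, 2 or 3")
  t_min <- range[1L]; t_max <- range[2L]
  if (!(t_max > t_min)) abort_imp("RANGE_ERROR", "range must satisfy t_max > t_min")
  if (any(t < t_min - 1e-12) || any(t > t_max + 1e-12)) {
    abort_imp("RANGE_ERROR", "covariate values outside the standardization range")
  }
  x <- -1 + 2 * (t - t_min) / (t_max - t_min)
  cols <- list(x, (3 * x^2 - 1) / 2, (5 * x^3 - 3 * x) / 2)[seq_len(order)]
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("leg", seq_len(order))
  out
}

# level ordering: numeric-looking levels sort numerically, else lexically
ordered_levels <- function(x) {
  ux <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(ux))
  if (!anyNA(num)) ux[order(num)] else sort(ux)
}

factor_dummies <- function(x, term, prefix) {
  x <- as.character(x)
  lv <- ordered_levels(x)
  if (!is.null(term$merge_min_count)) {
    counts <- table(factor(x, levels = lv))
    map <- merge_sparse_levels(stats::setNames(as.numeric(counts), lv),
                               term$merge_min_count)
    x <- unname(map[x])
    lv <- unique(map[lv])
  }
  M <- matrix(0, length(x), length(lv),
              dimnames = list(NULL, paste0(prefix, "_", lv)))
  M[cbind(seq_along(x), match(x, lv))] <- 1
  M
}

#' Compile a model specification into design matrices
#'
#' Builds the response vector `y`, the fixed design `X` (intercept plus
#' full-dummy factor coding, interactions and Legendre covariates, in the
#' declared term order), and the random-effect incidence structures for the
#' requested model. Columns of `X` that are linearly dependent on earlier
#' columns are detected sequentially and zeroed (recorded in the `aliased`
#' attribute), emulating mixed-model software that sets singular effects to
#' zero; the incremental Wald test inherits this order dependence.
#'
#' Records with a missing covariate value are dropped with a warning. A
#' model with maternal terms requires every phenotyped individual to have a
#' known dam.
#'
#' The returned design also carries the dense covariance kernels used by the
#' REML engine, built from the gametic relationship matrix `G` restricted to
#' the phenotyped records' gamete slots: under the imprinting structure the
#' genetic covariance contribution is `sigma_s^2 G[pat, pat] + sigma_d^2
#' G[mat, mat] + sigma_sd (G[pat, mat] + G[mat, pat])`, and the Mendelian
#' kernel is the sum of all four blocks times `sigma_g^2`.
#'
#' @param spec an `imp_model_spec`.
#' @param pedigree an `imp_pedigree`.
#' @param phen an `imp_phenotypes`.
#' @param relmat optional precomputed list with elements `G`
#'   ([gametic_matrix()]) and, when `maternal_gen` is set, `A`
#'   ([additive_matrix()]); computed from the pedigree when omitted. Passing
#'   it avoids recomputation across the ladder of models.
#' @return object of class `imp_design`: a list with `y`, `X` (aliased
#'   columns zeroed; attributes `aliased`, `rank`), `Xr` (reduced full-rank
#'   copy), `term_spans`, sparse incidences `Z_g` or `Z_s`/`Z_d`, `Z_c`,
#'   `Z_m`, kernel list `K`, gamete slot indices `pat`/`mat`, record ids,
#'   and the relationship matrices used.
#' @export
build_design <- function(spec, pedigree, phen, relmat = NULL) {
  trait_kind <- attr(phen, "trait_kind")
  if (spec$link == "logit" && trait_kind != "binary") {
    abort_imp("SPEC_ERROR", "logit link requires a binary (0/1) trait")
  }
  if (!spec$trait %in% names(phen)) {
    abort_imp("SPEC_ERROR", sprintf("trait '%s' not in phenotype table", spec$trait))
  }
  needed <- unique(unlist(lapply(spec$fixed, `[[`, "columns")))
  miss_col <- setdiff(needed, names(phen))
  if (length(miss_col)) {
    abort_imp("SPEC_ERROR",
              sprintf("covariate(s) missing from phenotypes: %s",
                      paste(miss_col, collapse = ", ")))
  }

  df <- as.data.frame(phen)
  if (length(needed)) {
    complete <- stats::complete.cases(df[, needed, drop = FALSE])
    if (!all(complete)) {
      warn_imp("MISSING_VALUE",
               sprintf("dropped %d record(s) with missing covariate values",
                       sum(!complete)))
      df <- df[complete, , drop = FALSE]
    }
  }
  n <- nrow(df)
  if (n == 0L) abort_imp("SPEC_ERROR", "no usable phenotype records")

  idx <- attr(pedigree, "index_of")[df$id]
  dam_idx <- pedigree$dam_idx[idx]
  if ((spec$maternal_env || spec$maternal_gen) && anyNA(dam_idx)) {
    abort_imp("SPEC_ERROR",
              "maternal terms require a known dam for every phenotyped individual")
  }

  y <- as.numeric(df[[spec$trait]])

  # ---- fixed design ----
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  term_spans <- list()
  # factor terms by name, so interactions reuse the parents' merged levels
  factor_terms <- list()
  for (tm in spec$fixed) if (tm$kind == "factor") factor_terms[[tm$columns]] <- tm
  for (tm in spec$fixed) {
    M <- switch(tm$kind,
      factor = factor_dummies(df[[tm$columns]], tm, tm$columns),
      interaction = {
        parts <- lapply(tm$columns, function(cn) {
          factor_dummies(df[[cn]],
                         factor_terms[[cn]] %||% list(merge_min_count = NULL),
                         cn)
        })
        M <- parts[[1L]]
        for (p in parts[-1L]) {
          M <- do.call(cbind, lapply(seq_len(ncol(M)), function(j) {
            out <- M[, j] * p
            colnames(out) <- paste(colnames(M)[j], colnames(p), sep = ":")
            out
          }))
        }
        M
      },
      legendre = {
        rng <- tm$range %||% base::range(as.numeric(df[[tm$columns]]))
        M <- legendre_covariates(as.numeric(df[[tm$columns]]), tm$order, rng)
        colnames(M) <- paste0(tm$columns, "_", colnames(M))
        M
      }
    )
    lbl <- tm$label
    k <- 1L
    while (lbl %in% names(term_spans)) {   # repeated terms keep distinct rows
      k <- k + 1L
      lbl <- sprintf("%s.%d", tm$label, k)
    }
    term_spans[[lbl]] <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
  }

  al <- sequential_alias(X)
  X_zeroed <- X
  X_zeroed[, al$aliased] <- 0
  attr(X_zeroed, "aliased") <- al$aliased
  attr(X_zeroed, "rank") <- al$rank

  # ---- random incidences ----
  gi <- gamete_index(pedigree)[idx, , drop = FALSE]
  pat <- gi[, "paternal"]; mat <- gi[, "maternal"]
  N2 <- 2L * n_individuals(pedigree)

  if (is.null(relmat)) {
    relmat <- list(G = gametic_matrix(pedigree),
                   A = if (spec$maternal_gen) additive_matrix(pedigree))
  }
  G <- relmat$G
  A <- relmat$A

  K <- list()
  Z_s <- Z_d <- Z_g <- Z_c <- Z_m <- NULL
  if (spec$genetic != "none") {
    Z_s <- Matrix::sparseMatrix(i = seq_len(n), j = pat, x = 1, dims = c(n, N2))
    Z_d <- Matrix::sparseMatrix(i = seq_len(n), j = mat, x = 1, dims = c(n, N2))
    Gpp <- G[pat, pat, drop = FALSE]
    Gmm <- G[mat, mat, drop = FALSE]
    Gpm <- G[pat, mat, drop = FALSE]
    if (spec$genetic == "mendelian") {
      Z_g <- Z_s + Z_d
      K$g <- Gpp + Gmm + Gpm + t(Gpm)
    } else {
      K$gss <- Gpp
      K$gdd <- Gmm
      K$gsd <- Gpm + t(Gpm)
    }
  }
  mothers <- NULL
  if (spec$maternal_env) {
    mothers <- sort(unique(dam_idx))
    Z_c <- Matrix::sparseMatrix(i = seq_len(n), j = match(dam_idx, mothers),
                                x = 1, dims = c(n, length(mothers)))
    K$c <- (outer(dam_idx, dam_idx, `==`)) * 1
  }
  if (spec$maternal_gen) {
    if (is.null(A)) A <- additive_matrix(pedigree)
    Z_m <- Matrix::sparseMatrix(i = seq_len(n), j = dam_idx, x = 1,
                                dims = c(n, n_individuals(pedigree)))
    K$m <- A[dam_idx, dam_idx, drop = FALSE]
  }

  structure(list(
    y = y, X = X_zeroed, Xr = X[, !al$aliased, drop = FALSE],
    term_spans = term_spans, n = n, ids = df$id,
    pat = pat, mat = mat, dam_idx = dam_idx, mothers = mothers,
    Z_g = Z_g, Z_s = Z_s, Z_d = Z_d, Z_c = Z_c, Z_m = Z_m,
    K = K, G = G, A = A, weights = NULL,
    trait_kind = trait_kind, spec = spec, pedigree = pedigree
  ), class = "imp_design")
}

# Sequentially detect columns linearly dependent on earlier columns via a
# growing orthonormal basis (modified Gram-Schmidt with reorthogonalization).
sequential_alias <- function(X, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  Q <- matrix(0, n, 0L)
  aliased <- logical(p)
  for (j in seq_len(p)) {
    v <- X[, j]
    nv0 <- sqrt(sum(v^2))
    if (nv0 == 0) { aliased[j] <- TRUE; next }
    for (pass in 1:2) if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv < tol * nv0) {
      aliased[j] <- TRUE
    } else {
      Q <- cbind(Q, v / nv)
    }
  }
  list(aliased = aliased, rank = sum(!aliased))
}

#' @export
print.imp_design <- function(x, ...) {
  cat(sprintf(
    "<imp_design> n=%d records, X: %d columns (rank %d, %d aliased), genetic=%s%s%s\n",
    x$n, ncol(x$X), attr(x$X, "rank"), sum(attr(x$X, "aliased")),
    x$spec$genetic,
    if (x$spec$maternal_env) " + c" else "",
    if (x$spec$maternal_gen) " + m" else ""))
  invisible(x)
}
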