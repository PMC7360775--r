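#' Additive (numerator) relationship matrix
#'
#' Computes the N x N additive genetic relationship matrix `A` by the tabular
#' method: processing individuals in pedigree (topological) order,
#' `a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})` for earlier individuals `j`,
#' and `a_ii = 1 + 0.5 a_{sire(i),dam(i)}`; unknown parents contribute 0.
#' The diagonal is `1 + F_i` where `F_i` is the inbreeding coefficient, which
#' is read off the diagonal (single source of truth) and attached as the
#' `"inbreeding"` attribute.
#'
#' @param pedigree an `imp_pedigree`.
#' @return symmetric numeric matrix with dimnames set to the individual ids,
#'   class `imp_additive`, attribute `inbreeding` (numeric vector `F`).
#' @export
additive_matrix <- function(pedigree) {
  n <- n_individuals(pedigree)
  s <- pedigree$sire_idx
  d <- pedigree$dam_idx
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + A[si, j]
      if (!is.na(di)) row <- row + A[di, j]
      row <- 0.5 * row
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  attr(A, "inbreeding") <- diag(A) - 1
  class(A) <- c("imp_additive", "matrix", "array")
  A
}

#' Inbreeding coefficients
#' @param pedigree an `imp_pedigree`.
#' @return numeric vector `F` named by id (founders have `F = 0`).
#' @export
inbreeding <- function(pedigree) {
  A <- additive_matrix(pedigree)
  stats::setNames(attr(A, "inbreeding"), pedigree$id)
}

#' Gametic relationship matrix
#'
#' Computes the 2N x 2N gametic relationship matrix `G` between all gametes
#' of a pedigree -- twice the size of the number of individuals. Gametes are
#' processed in pedigree order, paternal slot first: the gamete that
#' individual `i` received from parent `p` (with gametes `p1`, `p2`)
#' relates to every earlier gamete `x` as `G(new, x) = 0.5 [G(p1, x) +
#' G(p2, x)]`, with `G(new, new) = 1`; gametes from unknown (or phantom)
#' parents are unrelated to everything. The entry between an individual's
#' two gametes equals its inbreeding coefficient, `G(i_pat, i_mat) = F_i`.
#'
#' @param pedigree an `imp_pedigree`.
#' @return symmetric 2N x 2N matrix with unit diagonal, dimnames
#'   `"<id>.p"` / `"<id>.m"` aligned with [gamete_index()], class
#'   `imp_gametic`.
#' @export
gametic_matrix <- function(pedigree) {
  n <- n_individuals(pedigree)
  s <- pedigree$sire_idx
  d <- pedigree$dam_idx
  m <- 2L * n
  G <- matrix(0, m, m)
  labs <- as.vector(rbind(paste0(pedigree$id, ".p"), paste0(pedigree$id, ".m")))
  dimnames(G) <- list(labs, labs)
  for (i in seq_len(n)) {
    for (k in 1:2) {                       # 1 = paternal slot, 2 = maternal
      g <- 2L * (i - 1L) + k
      p <- if (k == 1L) s[i] else d[i]
      if (!is.na(p) && g > 1L) {
        j <- seq_len(g - 1L)
        p1 <- 2L * p - 1L; p2 <- 2L * p
        row <- 0.5 * (G[p1, j] + G[p2, j])
        G[g, j] <- row
        G[j, g] <- row
      }
      G[g, g] <- 1
    }
  }
  class(G) <- c("imp_gametic", "matrix", "array")
  G
}

#' Collapse a gametic matrix to the additive relationship matrix
#'
#' The additive relationship between individuals i and j is half the sum of
#' the four relationships between their gametes:
#' `a_ij = 0.5 * sum_{u in gametes(i), v in gametes(j)} G(u, v)`.
#' On the diagonal this gives `a_ii = 0.5 [1 + 1 + 2 G(i_pat, i_mat)] =
#' 1 + F_i`. The result equals [additive_matrix()] elementwise and is used
#' as a consistency check between the two constructions.
#'
#' @param G an `imp_gametic` matrix.
#' @param pedigree the `imp_pedigree` it was built from.
#' @return an `imp_additive` matrix.
#' @export
gametic_to_additive <- function(G, pedigree) {
  n <- n_individuals(pedigree)
  pat <- seq(1L, 2L * n, by = 2L)
  mat <- pat + 1L
  A <- 0.5 * (G[pat, pat] + G[pat, mat] + G[mat, pat] + G[mat, mat])
  dimnames(A) <- list(pedigree$id, pedigree$id)
  attr(A, "inbreeding") <- diag(A) - 1
  class(A) <- c("imp_additive", "matrix", "array")
  A
}

#' Export a relationship matrix as coordinate triplets
#'
#' Writes the lower triangle (including diagonal) of a labelled symmetric
#' matrix as tab-separated `row_label`, `col_label`, `value` records, for
#' verification against external pedigree software.
#'
#' @param m labelled symmetric matrix.
#' @param path output file path.
#' @param zero_tol entries with absolute value below this are omitted.
#' @return invisibly, the number of triplets written.
#' @export
export_matrix_triplets <- function(m, path, zero_tol = 0) {
  idx <- which(lower.tri(m, diag = TRUE) & abs(m) > zero_tol, arr.ind = TRUE)
  out <- data.frame(
    row = rownames(m)[idx[, 1L]],
    col = colnames(m)[idx[, 2L]],
    value = m[idx],
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(out))
}
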