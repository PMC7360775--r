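#' Construct a validated, topologically ordered pedigree
#'
#' A pedigree is a set of individual/sire/dam records. The constructor
#' validates identifiers, creates phantom founder records for parents that are
#' referenced but never declared, topologically sorts the records so that
#' every parent precedes its offspring, and assigns each individual a pair of
#' gamete indices: the paternal gamete slot comes first, then the maternal
#' slot, in record order. With `N` individuals the gamete indices are a
#' bijection onto `1..2N`, which is what makes the gametic relationship
#' matrix twice the size of the number of individuals.
#'
#' Unknown parents are encoded as `"0"`, the empty string, or `NA`. Sex is
#' coded 1 = male, 2 = female; an individual used as a sire but recorded as
#' female (or vice versa) triggers a warning, not an error.
#'
#' @param id character vector of unique individual identifiers (opaque
#'   strings; registry-style non-contiguous serials are fine).
#' @param sire,dam character vectors of parent identifiers (`"0"`, `""` or
#'   `NA` for unknown).
#' @param sex optional integer vector (1 = male, 2 = female, NA unknown).
#' @param birth_year optional integer vector.
#' @return An object of class `imp_pedigree`: a `data.frame` with columns
#'   `id`, `sire`, `dam`, `sex`, `birth_year`, `sire_idx`, `dam_idx`,
#'   `founder`, `phantom`, rows in topological order, plus attributes
#'   `index_of` (named integer map id -> row) and `n` (number of
#'   individuals).
#' @examples
#' ped <- pedigree(id = c("C", "S", "D"), sire = c("S", "0", "0"),
#'                 dam = c("D", "0", "0"))
#' gamete_index(ped, "C")
#' @export
pedigree <- function(id, sire, dam, sex = NULL, birth_year = NULL) {
  id <- as.character(id)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  n0 <- length(id)
  stopifnot(length(sire) == n0, length(dam) == n0)
  if (any(!nzchar(id)) || anyNA(id)) {
    abort_imp("PARSE_ERROR", "pedigree ids must be non-empty")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort_imp("DUPLICATE_ID",
              sprintf("duplicated pedigree id(s): %s",
                      paste(utils::head(dup, 5L), collapse = ", ")))
  }
  self_parent <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self_parent)) {
    abort_imp("CYCLE",
              sprintf("individual '%s' is recorded as its own parent",
                      id[self_parent[1L]]))
  }

  sex <- if (is.null(sex)) rep(NA_integer_, n0) else as.integer(sex)
  if (any(!is.na(sex) & !sex %in% c(1L, 2L))) {
    abort_imp("PARSE_ERROR", "sex codes must be 1 (male) or 2 (female)")
  }
  birth_year <- if (is.null(birth_year)) rep(NA_integer_, n0) else as.integer(birth_year)

  # phantom founders for parents referenced but never declared
  referenced <- setdiff(unique(c(sire, dam)), c(id, NA))
  phantom <- c(rep(FALSE, n0), rep(TRUE, length(referenced)))
  if (length(referenced)) {
    warn_imp("PHANTOM_FOUNDER",
             sprintf("%d parent id(s) never declared; added as phantom founders",
                     length(referenced)))
    id <- c(id, referenced)
    sire <- c(sire, rep(NA_character_, length(referenced)))
    dam <- c(dam, rep(NA_character_, length(referenced)))
    sex <- c(sex, rep(NA_integer_, length(referenced)))
    birth_year <- c(birth_year, rep(NA_integer_, length(referenced)))
  }
  n <- length(id)

  ord <- topo_order(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  sex <- sex[ord]; birth_year <- birth_year[ord]; phantom <- phantom[ord]

  index_of <- seq_len(n)
  names(index_of) <- id
  sire_idx <- unname(index_of[sire])
  dam_idx <- unname(index_of[dam])

  # sex-consistency warnings (1 = male, 2 = female)
  bad_sire <- stats::na.omit(sire_idx[!is.na(sire_idx)])
  bad_sire <- unique(bad_sire[!is.na(sex[bad_sire]) & sex[bad_sire] == 2L])
  bad_dam <- stats::na.omit(dam_idx[!is.na(dam_idx)])
  bad_dam <- unique(bad_dam[!is.na(sex[bad_dam]) & sex[bad_dam] == 1L])
  if (length(bad_sire) || length(bad_dam)) {
    warn_imp("SEX_INCONSISTENT",
             sprintf("%d individual(s) used as a parent inconsistently with their sex code",
                     length(bad_sire) + length(bad_dam)))
  }

  out <- data.frame(
    id = id, sire = sire, dam = dam, sex = sex, birth_year = birth_year,
    sire_idx = sire_idx, dam_idx = dam_idx,
    founder = is.na(sire_idx) & is.na(dam_idx), phantom = phantom,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "index_of") <- index_of
  attr(out, "n") <- n
  class(out) <- c("imp_pedigree", "data.frame")
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "0" | x == ""] <- NA_character_
  x
}

# Kahn topological sort; ties broken by original record order so that an
# already-sorted pedigree maps to the identity permutation.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  sire_i <- unname(idx[sire])
  dam_i <- unname(idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  avail <- which(indeg == 0L)
  out <- integer(0)
  while (length(avail)) {
    i <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- sort(c(avail, ch))
    }
  }
  if (length(out) != n) {
    abort_imp("CYCLE", "pedigree contains a parent-offspring cycle")
  }
  out
}

#' @export
print.imp_pedigree <- function(x, ...) {
  cat(sprintf("<imp_pedigree> %d individuals (%d founders, %d phantom)\n",
              nrow(x), sum(x$founder), sum(x$phantom)))
  print(utils::head(as.data.frame(x)[, c("id", "sire", "dam", "sex", "birth_year")], 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param pedigree an `imp_pedigree`.
#' @return integer count `N`.
#' @export
n_individuals <- function(pedigree) attr(pedigree, "n")

#' Gamete indices of individuals
#'
#' Each individual owns two gamete slots among `1..2N`: the paternal slot
#' (odd, `2i - 1` for the individual at row `i`) and the maternal slot
#' (even, `2i`). The paternal slot always precedes the maternal slot.
#'
#' @param pedigree an `imp_pedigree`.
#' @param id character vector of ids (default: all individuals).
#' @return integer matrix with columns `paternal`, `maternal` and one row per
#'   requested id.
#' @export
gamete_index <- function(pedigree, id = pedigree$id) {
  idx <- attr(pedigree, "index_of")[as.character(id)]
  if (anyNA(idx)) {
    missing <- as.character(id)[is.na(idx)]
    abort_imp("MISSING_ID",
              sprintf("id(s) not in pedigree: %s",
                      paste(utils::head(missing, 5L), collapse = ", ")))
  }
  cbind(paternal = 2L * unname(idx) - 1L, maternal = 2L * unname(idx))
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header row and columns resolvable to id/sire/dam;
#' unknown parents are encoded as `0` or empty. Optional `sex` and
#' `birth_year` columns are picked up when present.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param col_map named character vector mapping the roles `id`, `sire`,
#'   `dam` (and optionally `sex`, `birth_year`) to column names in the file.
#' @return an `imp_pedigree`.
#' @export
read_pedigree <- function(path, sep = "\t",
                          col_map = c(id = "id", sire = "sire", dam = "dam",
                                      sex = "sex", birth_year = "birth_year")) {
  if (!file.exists(path)) abort_imp("PARSE_ERROR", sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(col_map)) || !all(col_map[need] %in% names(df))) {
    abort_imp("PARSE_ERROR", "pedigree file must provide id/sire/dam columns")
  }
  getcol <- function(role) {
    nm <- col_map[role]
    if (!is.na(nm) && nm %in% names(df)) df[[nm]] else NULL
  }
  sx <- getcol("sex")
  by <- getcol("birth_year")
  pedigree(
    id = df[[col_map["id"]]],
    sire = df[[col_map["sire"]]],
    dam = df[[col_map["dam"]]],
    sex = if (!is.null(sx)) suppressWarnings(as.integer(sx)),
    birth_year = if (!is.null(by)) suppressWarnings(as.integer(by))
  )
}

#' Build a phenotype table bound to a pedigree
#'
#' @param data data.frame with one row per phenotyped individual.
#' @param trait name of the trait column (numeric; binary traits take values
#'   in 0/1 and are detected automatically).
#' @param covariates character vector of covariate column names kept for
#'   model building; columns of type factor/character are treated as factors,
#'   numeric columns as continuous.
#' @param pedigree the `imp_pedigree` the individuals belong to; every
#'   phenotyped id must be present.
#' @param id name of the id column (default `"id"`).
#' @return object of class `imp_phenotypes`: the data.frame restricted to
#'   id, trait and covariates, with attributes `trait`, `trait_kind`
#'   (`"binary"` or `"continuous"`) and `covariates`.
#' @export
phenotypes <- function(data, trait, covariates = character(), pedigree,
                       id = "id") {
  if (!trait %in% names(data)) {
    abort_imp("PARSE_ERROR", sprintf("trait column '%s' not found", trait))
  }
  if (!id %in% names(data)) abort_imp("PARSE_ERROR", "id column not found")
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov)) {
    abort_imp("PARSE_ERROR",
              sprintf("covariate column(s) not found: %s",
                      paste(miss_cov, collapse = ", ")))
  }
  yv <- data[[trait]]
  if (is.character(yv)) yv <- suppressWarnings(as.numeric(yv))
  if (anyNA(yv) || !is.numeric(yv)) {
    abort_imp("PARSE_ERROR", "trait values must be numeric and non-missing")
  }
  ids <- as.character(data[[id]])
  known <- ids %in% names(attr(pedigree, "index_of"))
  if (!all(known)) {
    abort_imp("MISSING_ID",
              sprintf("phenotyped id(s) absent from pedigree: %s",
                      paste(utils::head(ids[!known], 5L), collapse = ", ")))
  }
  trait_kind <- if (all(yv %in% c(0, 1))) "binary" else "continuous"
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out[[trait]] <- yv
  for (cv in covariates) out[[cv]] <- data[[cv]]
  attr(out, "trait") <- trait
  attr(out, "trait_kind") <- trait_kind
  attr(out, "covariates") <- covariates
  class(out) <- c("imp_phenotypes", "data.frame")
  out
}

#' Read a phenotype table from a delimited text file
#'
#' @inheritParams phenotypes
#' @param path file path (header row required).
#' @param sep field delimiter (default tab).
#' @return an `imp_phenotypes`; see [phenotypes()].
#' @export
read_phenotypes <- function(path, trait, covariates = character(), pedigree,
                            id = "id", sep = "\t") {
  if (!file.exists(path)) abort_imp("PARSE_ERROR", sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  phenotypes(df, trait = trait, covariates = covariates,
             pedigree = pedigree, id = id)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Drops every individual that is neither phenotyped nor an ancestor of a
#' phenotyped individual; ordering and gamete indices are re-assigned in the
#' returned sub-pedigree. The phenotyped set itself is never touched.
#'
#' @param pedigree an `imp_pedigree`.
#' @param phen an `imp_phenotypes` bound to this pedigree.
#' @return an `imp_pedigree` containing the ancestor closure of the
#'   phenotyped individuals.
#' @export
prune_to_informative <- function(pedigree, phen) {
  idx <- attr(pedigree, "index_of")
  keep <- logical(nrow(pedigree))
  keep[idx[unique(phen$id)]] <- TRUE
  # records are topologically ordered, so one reverse sweep closes ancestry
  for (i in rev(seq_len(nrow(pedigree)))) {
    if (keep[i]) {
      s <- pedigree$sire_idx[i]; d <- pedigree$dam_idx[i]
      if (!is.na(s)) keep[s] <- TRUE
      if (!is.na(d)) keep[d] <- TRUE
    }
  }
  sub <- pedigree[keep, , drop = FALSE]
  suppressWarnings(pedigree(sub$id, sub$sire, sub$dam, sub$sex, sub$birth_year))
}
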