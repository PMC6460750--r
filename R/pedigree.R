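# Pedigree handling and the average numerator relationship matrix.

#' Construct a pedigree
#'
#' A pedigree is an ordered table of (id, sire, dam) records. Unknown parents
#' are coded `"0"` (or `NA`); unknown parents are treated as unrelated,
#' non-inbred founders, the standard tabular-method convention. Open-pollinated
#' progeny therefore carry `sire = "0"`. Parents that are referenced but have
#' no record of their own are added as implicit founder records.
#'
#' The constructor validates uniqueness of ids and acyclicity, and stores a
#' topological order internally so input files need not be sorted.
#'
#' @param id,sire,dam vectors of equal length; coerced to character.
#' @return an object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` and an internal topological ordering attribute.
#' @examples
#' ped <- pedigree(id = c("1", "2", "3"), sire = c("0", "0", "1"),
#'                 dam = c("0", "0", "2"))
#' build_A(ped)["1", "3"]  # 0.5
#' @export
pedigree <- function(id, sire, dam) {
  id   <- as.character(id)
  sire <- as.character(sire)
  dam  <- as.character(dam)
  stopifnot(length(id) == length(sire), length(id) == length(dam))
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)]   <- "0"
  if (anyNA(id) || any(id == "0"))
    stop_ogb("pedigree: individual ids must be non-missing and not '0'")
  if (anyDuplicated(id))
    stop_ogb("pedigree: duplicate id(s): ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
  # implicit founders for referenced-but-absent parents
  parents <- setdiff(unique(c(sire, dam)), c(id, "0"))
  if (length(parents)) {
    id   <- c(parents, id)
    sire <- c(rep("0", length(parents)), sire)
    dam  <- c(rep("0", length(parents)), dam)
  }
  ord <- topo_order(id, sire, dam)
  out <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  attr(out, "topo") <- ord
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
as_pedigree <- function(x) {
  if (inherits(x, "pedigree")) return(x)
  nm <- tolower(names(x))
  stopifnot(all(c("id", "sire", "dam") %in% nm))
  pedigree(x[[which(nm == "id")]], x[[which(nm == "sire")]], x[[which(nm == "dam")]])
}

# Kahn topological sort; errors naming a cycle if one exists.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  pidx <- cbind(ifelse(sire == "0", NA_integer_, idx[sire]),
                ifelse(dam  == "0", NA_integer_, idx[dam]))
  indeg <- rowSums(!is.na(pidx))
  children <- vector("list", n)
  for (i in idx) for (p in pidx[i, ]) if (!is.na(p))
    children[[p]] <- c(children[[p]], i)
  queue <- idx[indeg == 0]
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- id[setdiff(idx, ord)]
    stop_ogb("pedigree: cycle detected involving id(s): ",
             paste(cyc, collapse = ", "))
  }
  ord
}

#' Relationship matrix container
#'
#' A labelled symmetric matrix of additive relationships, either the pedigree
#' numerator matrix (`kind = "A"`, diagonal 1 + F) or the trace-scaled genomic
#' matrix (`kind = "G"`, mean diagonal 1).
#'
#' @param values symmetric numeric matrix with row/column names.
#' @param kind `"A"` or `"G"`.
#' @export
relationship_matrix <- function(values, kind = c("A", "G")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    stop_ogb("relationship_matrix: labels (dimnames) are required")
  if (!is_symmetric_tol(values, 1e-8))
    stop_ogb("relationship_matrix: input is not symmetric to tolerance")
  values <- (values + t(values)) / 2
  colnames(values) <- rownames(values)
  structure(values, kind = kind, class = c("relationship_matrix", "matrix", "array"))
}

#' @export
kind <- function(K) attr(K, "kind")

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix kind=%s, %d individuals, mean diag %.4f>\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Average numerator relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix A by the recursive tabular
#' method over the topologically sorted pedigree:
#' `A[i,j] = (A[j,s(i)] + A[j,d(i)])/2` for j preceding i, and
#' `A[i,i] = 1 + A[s(i),d(i)]/2`; unknown parents contribute zero.
#' Rows/columns are returned in the pedigree's input order.
#'
#' @param ped a [pedigree()].
#' @return a [relationship_matrix()] of kind `"A"`.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  ord <- attr(ped, "topo")
  id <- ped$id; sire <- ped$sire; dam <- ped$dam
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id[ord]  # position in topo order
  s_t <- ifelse(sire[ord] == "0", 0L, pos[sire[ord]])
  d_t <- ifelse(dam[ord]  == "0", 0L, pos[dam[ord]])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s_t[i]; di <- d_t[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (si > 0L) A[j, si] else numeric(i - 1L)
      ad_ <- if (di > 0L) A[j, di] else numeric(i - 1L)
      v <- (as_ + ad_) / 2
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) A[si, di] / 2 else 0
  }
  dimnames(A) <- list(id[ord], id[ord])
  A <- A[id, id, drop = FALSE]  # back to input order
  relationship_matrix(A, kind = "A")
}

#' Inbreeding coefficients from a numerator relationship matrix
#'
#' `F_i = A_ii - 1`. For a genomic matrix the analogous quantity is reported
#' but labelled genomic, with a warning, because trace-scaled G diagonals are
#' not pedigree inbreeding coefficients.
#'
#' @param K a [relationship_matrix()].
#' @return named numeric vector of per-individual F.
#' @export
inbreeding <- function(K) {
  stopifnot(inherits(K, "relationship_matrix"))
  if (identical(attr(K, "kind"), "G"))
    warning("inbreeding(): kernel is genomic (G); values are genomic ",
            "diagonal excesses, not pedigree inbreeding", call. = FALSE)
  stats::setNames(diag(K) - 1, rownames(K))
}

#' Group coancestry and status number
#'
#' Group coancestry of an equal-weight group is
#' `theta = sum(K[subset, subset]) / (2 N^2)` (coancestry = numerator
#' relationship / 2), and the status number is `N_S = 1 / (2 theta)`.
#' For N unrelated, non-inbred individuals `N_S = N`.
#'
#' @param K a [relationship_matrix()].
#' @param subset ids over which to compute the summary; default all.
#' @return object of class `coancestry_summary`: list with `theta`,
#'   `status_number`, `n_individuals`.
#' @export
status_number <- function(K, subset = NULL) {
  stopifnot(inherits(K, "relationship_matrix"))
  ids <- rownames(K)
  if (is.null(subset)) subset <- ids
  subset <- as.character(subset)
  if (!length(subset)) stop_ogb("status_number: empty subset")
  missing_ids <- setdiff(subset, ids)
  if (length(missing_ids))
    stop_ogb("status_number: ids not in matrix: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
  Ks <- K[subset, subset, drop = FALSE]
  n <- length(subset)
  theta <- sum(Ks) / (2 * n^2)
  structure(list(theta = theta, status_number = 1 / (2 * theta),
                 n_individuals = n),
            class = "coancestry_summary")
}

#' @export
print.coancestry_summary <- function(x, ...) {
  cat(sprintf("group coancestry theta = %.6f, status number N_S = %.2f (n = %d)\n",
              x$theta, x$status_number, x$n_individuals))
  invisible(x)
}
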