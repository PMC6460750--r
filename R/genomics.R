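# Marker QC, imputation, genomic relationship matrix and LD summaries.

#' Genotype matrix container
#'
#' Dosage matrix (individuals x markers, coded 0/1/2 with `NA` for missing)
#' plus per-marker metadata: chromosome, physical position (1-based bp) and
#' two platform quality scores in [0,1] (`qa`, a genotype-training score
#' analogue, and `qb`, a call-quality analogue).
#'
#' @param dosages numeric matrix, rownames = individual ids, colnames =
#'   marker ids; entries in `{0,1,2,NA}` (real values in `[0,2]` are allowed
#'   after imputation and flagged by `imputed = TRUE`).
#' @param marker_meta data.frame with columns `marker`, `chrom`, `pos`,
#'   `qa`, `qb`; one row per marker, or `NULL`.
#' @param imputed logical; allows non-integer dosages in `[0,2]`.
#' @export
genotype_matrix <- function(dosages, marker_meta = NULL, imputed = FALSE) {
  stopifnot(is.matrix(dosages), is.numeric(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop_ogb("genotype_matrix: dosages must have individual and marker names")
  v <- dosages[!is.na(dosages)]
  if (imputed) {
    if (length(v) && (min(v) < -1e-8 || max(v) > 2 + 1e-8))
      stop_ogb("genotype_matrix: imputed dosages must lie in [0, 2]")
  } else if (length(v) && !all(v %in% c(0, 1, 2))) {
    bad <- which(!(dosages %in% c(0, 1, 2)) & !is.na(dosages), arr.ind = TRUE)[1, ]
    stop_ogb(sprintf("genotype_matrix: invalid dosage %s at individual '%s', marker '%s'",
                     format(dosages[bad[1], bad[2]]),
                     rownames(dosages)[bad[1]], colnames(dosages)[bad[2]]))
  }
  if (!is.null(marker_meta)) {
    stopifnot(all(c("marker", "chrom", "pos", "qa", "qb") %in% names(marker_meta)))
    if (nrow(marker_meta) != ncol(dosages) ||
        !identical(as.character(marker_meta$marker), colnames(dosages)))
      stop_ogb("genotype_matrix: marker_meta must have one row per marker, in order")
    if (any(marker_meta$pos < 0)) stop_ogb("genotype_matrix: negative positions")
  }
  structure(list(dosages = dosages, marker_meta = marker_meta, imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix %d individuals x %d markers, %.1f%% missing%s>\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages)), if (x$imputed) ", imputed" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-marker minor allele frequency and call rate
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `marker`, `maf`, `call_rate`.
#' @export
marker_stats <- function(g) {
  M <- g$dosages
  call_rate <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  data.frame(marker = colnames(M), maf = pmin(p, 1 - p),
             call_rate = call_rate, row.names = NULL)
}

#' Default marker filtering thresholds
#'
#' The five QC rules applied by [filter_markers()]: platform score `qa`
#' (genotype-training analogue) > 0.5, platform score `qb` (call-quality
#' analogue) > 0.15, minor allele frequency > 0.01, SNP call rate > 0.6, and
#' pairwise composite r-squared < 0.9 (greedy sliding-window LD pruning,
#' window 50 markers, step 5, the later-positioned marker of an offending
#' pair removed).
#'
#' @export
filter_thresholds <- function(qa = 0.5, qb = 0.15, maf = 0.01,
                              call_rate = 0.6, ld_r2 = 0.9,
                              ld_window = 50L, ld_step = 5L) {
  th <- list(qa = qa, qb = qb, maf = maf, call_rate = call_rate,
             ld_r2 = ld_r2, ld_window = as.integer(ld_window),
             ld_step = as.integer(ld_step))
  for (nm in c("qa", "qb", "maf", "call_rate", "ld_r2"))
    if (th[[nm]] < 0 || th[[nm]] > 1)
      stop_ogb("filter_thresholds: ", nm, " must lie in [0,1]")
  th
}

#' Marker quality filtering
#'
#' Applies the four per-marker rules (qa, qb, MAF, call rate; strict `>` to
#' keep), then LD pruning on the survivors. Each removed marker is attributed
#' to its first failing rule, in the order qa, qb, maf, call_rate, ld.
#'
#' @param g a [genotype_matrix()] with marker metadata.
#' @param thresholds from [filter_thresholds()].
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (class `filter_report`: n_input, n_pass, per-rule removal counts,
#'   thresholds used).
#' @export
filter_markers <- function(g, thresholds = filter_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$marker_meta))
    stop_ogb("filter_markers: marker metadata (qa/qb/chrom/pos) required")
  meta <- g$marker_meta
  st <- marker_stats(g)
  n_input <- ncol(g$dosages)
  fail <- rep(NA_character_, n_input)
  fail[is.na(fail) & !(meta$qa > thresholds$qa)] <- "qa"
  fail[is.na(fail) & !(meta$qb > thresholds$qb)] <- "qb"
  fail[is.na(fail) & !(!is.na(st$maf) & st$maf > thresholds$maf)] <- "maf"
  fail[is.na(fail) & !(st$call_rate > thresholds$call_rate)] <- "call_rate"
  keep <- which(is.na(fail))
  if (length(keep) >= 2) {
    pruned <- ld_prune(g$dosages[, keep, drop = FALSE],
                       meta$chrom[keep], meta$pos[keep],
                       r2_max = thresholds$ld_r2,
                       window = thresholds$ld_window,
                       step = thresholds$ld_step)
    fail[keep[!pruned]] <- "ld"
    keep <- keep[pruned]
  }
  if (!length(keep))
    stop_ogb("filter_markers: all markers removed; genomic matrix undefined")
  removals <- table(factor(fail, levels = c("qa", "qb", "maf", "call_rate", "ld")))
  report <- structure(list(n_input = n_input, n_pass = length(keep),
                           removed = as.list(removals),
                           thresholds = thresholds,
                           failed_markers = stats::setNames(fail[!is.na(fail)],
                                                            colnames(g$dosages)[!is.na(fail)])),
                      class = "filter_report")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         meta[keep, , drop = FALSE], imputed = g$imputed)
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d markers in, %d pass\n", x$n_input, x$n_pass))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %-9s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

# Greedy sliding-window LD pruning; returns logical keep vector.
# Within each window, markers are scanned in genome order and a marker is
# dropped if its r2 with any retained earlier marker in the window is >= r2_max.
ld_prune <- function(M, chrom, pos, r2_max = 0.9, window = 50L, step = 5L) {
  keep <- rep(TRUE, ncol(M))
  ord <- order(chrom, pos)
  for (ch in unique(chrom)) {
    idx <- ord[chrom[ord] == ch]
    m <- length(idx)
    if (m < 2) next
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, m)]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(stats::cor(M[, win, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        for (a in seq_along(win)[-1]) {
          earlier <- seq_len(a - 1L)
          earlier <- earlier[keep[win[earlier]]]
          if (length(earlier) &&
              any(r2[earlier, a] >= r2_max, na.rm = TRUE))
            keep[win[a]] <- FALSE
        }
      }
      if (start + window - 1L >= m) break
      start <- start + step
    }
  }
  keep
}

#' EM imputation of missing dosages
#'
#' Missing entries are replaced by their conditional expectations under an
#' iterative EM scheme: initialise at marker (column) means, then alternate
#' (i) re-estimating the realized individual-by-individual covariance from the
#' completed matrix and (ii) replacing each missing dosage by its conditional
#' expectation given the observed dosages at that marker and the current
#' covariance, until the largest absolute change is below `tol`. Imputed
#' values are real numbers clamped to `[0, 2]`; observed entries are never
#' modified.
#'
#' @param g a [genotype_matrix()]; every marker needs at least one observed
#'   entry.
#' @param tol convergence tolerance on the max absolute dosage change
#'   (default 1e-4).
#' @param max_iter maximum EM sweeps (default 100). On non-convergence the
#'   column-mean imputation is returned with a warning and
#'   `attr(, "em_converged") = FALSE`.
#' @param ridge relative ridge added to the covariance for stable
#'   conditioning.
#' @return a complete [genotype_matrix()] with `imputed = TRUE`.
#' @export
impute_em <- function(g, tol = 1e-4, max_iter = 100L, ridge = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  M <- g$dosages
  miss <- is.na(M)
  if (!any(miss)) {
    out <- genotype_matrix(M, g$marker_meta, imputed = g$imputed)
    attr(out, "em_converged") <- TRUE
    return(out)
  }
  if (any(colSums(!miss) == 0))
    stop_ogb("impute_em: marker(s) with no observed entries: ",
             paste(utils::head(colnames(M)[colSums(!miss) == 0], 5), collapse = ", "))
  n <- nrow(M)
  mu <- colMeans(M, na.rm = TRUE)
  X <- M
  X[miss] <- matrix(mu, n, ncol(M), byrow = TRUE)[miss]
  mean_fill <- X
  miss_cols <- which(colSums(miss) > 0)
  miss_idx <- lapply(miss_cols, function(j) which(miss[, j]))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    S <- tcrossprod(Xc) / ncol(X)
    diag(S) <- diag(S) + ridge * mean(diag(S))
    B <- chol2inv(chol(S))    # precision over individuals
    R <- B %*% Xc             # residual projections, n x m
    delta <- 0
    for (k in seq_along(miss_cols)) {
      j <- miss_cols[k]; mi <- miss_idx[[k]]
      # conditional mean via the precision matrix:
      # x_m <- x_m - B[m,m]^-1 (B Xc)[m, j]
      upd <- if (length(mi) == 1L) R[mi, j] / B[mi, mi]
             else solve(B[mi, mi, drop = FALSE], R[mi, j])
      newv <- pmin(2, pmax(0, X[mi, j] - upd))
      delta <- max(delta, max(abs(newv - X[mi, j])))
      X[mi, j] <- newv
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("impute_em: EM did not converge in ", max_iter,
            " iterations; returning column-mean imputation", call. = FALSE)
    X <- mean_fill
  }
  out <- genotype_matrix(X, g$marker_meta, imputed = TRUE)
  attr(out, "em_converged") <- converged
  out
}

#' Trace-scaled genomic relationship matrix
#'
#' `G = ZZ' / (tr(ZZ') / n)` with `Z = M - P`, `P` twice the per-marker
#' reference allele frequency (column means of `M`) and `n` the number of
#' individuals, so that `mean(diag(G)) = 1` exactly. Monomorphic markers
#' contribute nothing and are harmless; an input with fewer than two
#' polymorphic markers is an error.
#'
#' @param g a complete [genotype_matrix()] (impute first).
#' @return a [relationship_matrix()] of kind `"G"`.
#' @export
compute_G <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  M <- g$dosages
  if (anyNA(M)) stop_ogb("compute_G: missing dosages; run impute_em() first")
  v <- apply(M, 2, stats::var)
  if (sum(v > 0) < 2)
    stop_ogb("compute_G: fewer than 2 polymorphic markers; G degenerate")
  Z <- sweep(M, 2, colMeans(M))
  ZZt <- tcrossprod(Z)
  G <- ZZt / (sum(diag(ZZt)) / nrow(M))
  relationship_matrix(G, kind = "G")
}

#' Composite r-squared between two markers
#'
#' Squared composite (Burrows-type) correlation of 0/1/2 dosages over
#' individuals observed at both markers, i.e. the squared Pearson correlation
#' of the dosage vectors. Symmetric and invariant to allele-coding swaps
#' (`x -> 2 - x`). Zero variance at either marker gives `NA` (flagged
#' undefined, never 0).
#'
#' @param g a [genotype_matrix()].
#' @param marker_i,marker_j marker ids or column indices.
#' @return r2 in [0,1], or `NA` with attribute `undefined = TRUE`.
#' @export
composite_r2 <- function(g, marker_i, marker_j) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$dosages[, marker_i]
  y <- g$dosages[, marker_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Mean composite r-squared of intra-chromosome marker pairs, binned by
#' physical distance (absolute bp difference). Distances are assigned to
#' half-open bins `(k*w, (k+1)*w]`.
#'
#' @param g a [genotype_matrix()] with chromosome/position metadata.
#' @param max_distance_bp only pairs at most this far apart (default 50 kb).
#' @param bin_width_bp width of distance bins (default 500 bp).
#' @return object of class `ld_decay_curve`: data.frame with `bin_start`,
#'   `bin_end`, `mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, max_distance_bp = 50000, bin_width_bp = 500) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$marker_meta)) stop_ogb("ld_decay: marker metadata required")
  meta <- g$marker_meta
  nb <- ceiling(max_distance_bp / bin_width_bp)
  sums <- numeric(nb); cnts <- numeric(nb)
  for (ch in unique(meta$chrom)) {
    j <- which(meta$chrom == ch)
    if (length(j) < 2) next
    pos <- meta$pos[j]
    r2 <- suppressWarnings(stats::cor(g$dosages[, j, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    dd <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(dd) & dd > 0 & dd <= max_distance_bp & !is.na(r2)
    if (!any(sel)) next
    bin <- ceiling(dd[sel] / bin_width_bp)
    sums <- sums + unname(tapply(r2[sel], factor(bin, levels = seq_len(nb)), sum, default = 0))
    cnts <- cnts + unname(tapply(rep(1, sum(sel)), factor(bin, levels = seq_len(nb)), sum, default = 0))
  }
  if (!sum(cnts))
    stop_ogb("ld_decay: no intra-chromosome pairs within max_distance_bp")
  out <- data.frame(bin_start = (seq_len(nb) - 1) * bin_width_bp,
                    bin_end = seq_len(nb) * bin_width_bp,
                    mid = (seq_len(nb) - 0.5) * bin_width_bp,
                    mean_r2 = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                    n_pairs = cnts)
  class(out) <- c("ld_decay_curve", "data.frame")
  out
}

#' Distance at which mean r-squared decays to a threshold
#'
#' The first bin whose mean r2 is at or below the threshold determines the
#' decay distance, linearly interpolated (on bin midpoints) between that bin
#' and the preceding one. If the threshold is never reached within the curve,
#' `NA` is returned with attribute `not_reached = TRUE`.
#'
#' @param curve an [ld_decay()] result.
#' @param threshold r2 threshold (the conventional reporting value is 0.2).
#' @export
decay_distance <- function(curve, threshold = 0.2) {
  stopifnot(inherits(curve, "ld_decay_curve"))
  ok <- !is.na(curve$mean_r2) & curve$n_pairs > 0
  x <- curve$mid[ok]; y <- curve$mean_r2[ok]
  k <- which(y <= threshold)
  if (!length(k)) return(structure(NA_real_, not_reached = TRUE))
  k <- k[1]
  if (k == 1L) return(x[1])
  x0 <- x[k - 1]; y0 <- y[k - 1]; x1 <- x[k]; y1 <- y[k]
  if (y1 == y0) return(x1)
  x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0)
}

#' Spectral decomposition of a relationship matrix
#'
#' Eigendecomposition in descending eigenvalue order with per-individual
#' component scores `eigenvector * sqrt(max(eigenvalue, 0))`; the eigenvalue
#' sum equals the trace of K. Used to visualise population structure
#' (diverged seed orchards separate on the first components).
#'
#' @param K a [relationship_matrix()] (symmetric to tolerance).
#' @param n_components number of leading components to return (default all).
#' @return list with `values` (all eigenvalues) and `scores`
#'   (individuals x n_components).
#' @export
spectral_decomposition <- function(K, n_components = NULL) {
  if (!is_symmetric_tol(unclass(K), 1e-8))
    stop_ogb("spectral_decomposition: matrix is not symmetric to tolerance")
  e <- eigen((unclass(K) + t(unclass(K))) / 2, symmetric = TRUE)
  nc <- min(n_components %||% nrow(K), nrow(K))
  scores <- e$vectors[, seq_len(nc), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(nc)], 0)), nc)
  rownames(scores) <- rownames(K)
  colnames(scores) <- paste0("PC", seq_len(nc))
  list(values = e$values, scores = scores)
}
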