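# Independent oracles. These deliberately share no code with the package
# implementation: the A-matrix oracle enumerates gene-drop inheritance
# vectors exactly, the mixed-model oracle works by direct dense inversion of
# V, and the LD oracle is a discrete Wright-Fisher forward simulation.

# ---- exact gene-drop A-matrix oracle --------------------------------------
# ped: data.frame id/sire/dam as integer indices, 0 = unknown, parents
# precede offspring. Enumerates every inheritance vector (one bit per
# child-known-parent link); unknown parents are distinct unrelated founders.
# Returns the numerator relationship matrix (exact dyadic rationals).
oracle_A_genedrop <- function(sire, dam) {
  n <- length(sire)
  links <- integer(0)           # (individual, which-parent) with known parent
  for (i in seq_len(n)) {
    if (sire[i] > 0) links <- c(links, 2L * i - 1L)
    if (dam[i] > 0)  links <- c(links, 2L * i)
  }
  L <- length(links)
  nc <- 2^L
  bits <- matrix(0L, nc, max(L, 1))
  if (L > 0)
    for (b in seq_len(L))
      bits[, b] <- rep(rep(0:1, each = 2^(L - b)), length.out = nc)
  # allele labels per individual: list of two integer vectors (length nc)
  al1 <- vector("list", n); al2 <- vector("list", n)
  counter <- 0L
  fresh <- function() { counter <<- counter + 1L; rep(counter, nc) }
  for (i in seq_len(n)) {
    if (sire[i] > 0) {
      b <- bits[, match(2L * i - 1L, links)]
      p <- sire[i]
      al1[[i]] <- ifelse(b == 0L, al1[[p]], al2[[p]])
    } else al1[[i]] <- fresh()
    if (dam[i] > 0) {
      b <- bits[, match(2L * i, links)]
      p <- dam[i]
      al2[[i]] <- ifelse(b == 0L, al1[[p]], al2[[p]])
    } else al2[[i]] <- fresh()
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    f <- mean((al1[[i]] == al1[[j]]) + (al1[[i]] == al2[[j]]) +
                (al2[[i]] == al1[[j]]) + (al2[[i]] == al2[[j]])) / 4
    A[i, j] <- A[j, i] <- 2 * f
  }
  A
}

# ---- dense direct-inversion mixed-model oracle ----------------------------
# theta: c(a, r, s, e). Returns logRL, beta, u (all kernel individuals),
# PEV, by brute-force dense algebra on V = sigma2_a Za K Za' + ... .
oracle_mixed <- function(theta, y, X, ia, K, Fr = NULL, Fs = NULL) {
  n <- length(y); q <- nrow(K)
  Za <- matrix(0, n, q); Za[cbind(seq_len(n), ia)] <- 1
  V <- theta[1] * (Za %*% K %*% t(Za)) + theta[4] * diag(n)
  inc <- function(f) { Z <- matrix(0, length(f), nlevels(f)); Z[cbind(seq_along(f), as.integer(f))] <- 1; Z }
  if (!is.null(Fr)) { Zr <- inc(Fr); V <- V + theta[2] * tcrossprod(Zr) }
  if (!is.null(Fs)) { Zs <- inc(Fs); V <- V + theta[3] * tcrossprod(Zs) }
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% solve(B, t(X) %*% Vi)
  yPy <- drop(t(y) %*% P %*% y)
  logRL <- -0.5 * ((n - ncol(X)) * log(2 * pi) +
                     determinant(V)$modulus + determinant(B)$modulus + yPy)
  u <- drop(theta[1] * K %*% t(Za) %*% P %*% y)
  KZ <- theta[1] * K %*% t(Za)
  pev <- diag(theta[1] * K - KZ %*% P %*% t(KZ))
  list(logRL = as.numeric(logRL), beta = drop(beta), u = u, pev = pev)
}

# ---- Wright-Fisher forward simulation (LD decay oracle) -------------------
# Diploid random mating, m equally spaced markers on one chromosome,
# per-interval recombination rate r_adj. Returns the haplotype matrix.
oracle_wf_sim <- function(n_dip, m, r_adj, generations, p0 = 0.5) {
  H <- matrix(rbinom(2 * n_dip * m, 1, p0), 2 * n_dip, m)
  gamete <- function(h1, h2) {
    sw <- c(rbinom(1, 1, 0.5), rbinom(m - 1, 1, r_adj))
    st <- cumsum(sw) %% 2
    h1 * (st == 0) + h2 * st
  }
  for (g in seq_len(generations)) {
    Hn <- matrix(0L, 2 * n_dip, m)
    for (i in seq_len(n_dip)) {
      pa <- sample.int(n_dip, 2, replace = TRUE)
      Hn[2 * i - 1, ] <- gamete(H[2 * pa[1] - 1, ], H[2 * pa[1], ])
      Hn[2 * i, ]     <- gamete(H[2 * pa[2] - 1, ], H[2 * pa[2], ])
    }
    H <- Hn
    # keep segregating: restart lost markers would bias LD; instead we rely
    # on p0 = 0.5 and short runs, and drop fixed markers at analysis time
  }
  H
}

# Mean r2 by distance bin from a haplotype-derived dosage matrix.
oracle_ld_curve <- function(dosages, pos, max_d, bw) {
  v <- apply(dosages, 2, var)
  keep <- v > 0
  dosages <- dosages[, keep, drop = FALSE]; pos <- pos[keep]
  r2 <- suppressWarnings(cor(dosages))^2
  dd <- abs(outer(pos, pos, "-"))
  sel <- upper.tri(dd) & dd > 0 & dd <= max_d
  bin <- ceiling(dd[sel] / bw)
  tapply(r2[sel], bin, mean, na.rm = TRUE)
}

# Distance at which a binned curve (named by bin index) crosses a threshold,
# linear interpolation on bin midpoints.
oracle_decay_at <- function(means, bw, threshold) {
  mids <- (as.numeric(names(means)) - 0.5) * bw
  k <- which(means <= threshold)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(mids[1])
  x0 <- mids[k - 1]; y0 <- means[k - 1]; x1 <- mids[k]; y1 <- means[k]
  unname(x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0))
}
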