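# Linear mixed model: y = X b + Z1 u + Z2 r + Z3 r(s) + e, with
# u ~ N(0, sigma2_a K), r ~ N(0, sigma2_r I), r(s) ~ N(0, sigma2_rs I),
# e ~ N(0, sigma2_e I). K is the pedigree (A) or genomic (G) kernel; the
# BLUP and GBLUP pipelines differ only in K.

#' Trial data container
#'
#' Phenotype records for one or more traits in long format, with the fixed
#' seed-source factor and the replicate / set-within-replicate design
#' factors. One record per individual per trait.
#'
#' @param df data.frame with columns `id`, `trait`, `value`, `seed_source`,
#'   `replicate`, `set` and optionally `orchard` (seed-orchard label used by
#'   cross-validation scenarios).
#' @export
trial_data <- function(df) {
  need <- c("id", "trait", "value", "seed_source", "replicate", "set")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ogb("trial_data: missing column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  for (nm in c("seed_source", "replicate", "set"))
    df[[nm]] <- factor(df[[nm]])
  if (!"orchard" %in% names(df)) df$orchard <- NA_character_
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Build fixed and random design structures
#'
#' Fixed part: intercept + seed-source contrasts (reference-level coding;
#' levels with no records are dropped with a message). Random incidences map
#' records to individuals (kernel labels), replicates, and sets nested within
#' replicates.
#'
#' @param data a [trial_data()] restricted to one trait.
#' @param K relationship kernel whose labels define the individual effects.
#' @return list with `y`, `X`, `ia` (record -> kernel column index),
#'   `Fr`, `Fs` (replicate and set-within-replicate factors or `NULL` when a
#'   term has fewer than 2 levels and is dropped), and bookkeeping fields.
#' @export
build_design <- function(data, K) {
  stopifnot(inherits(data, "trial_data"))
  if (length(unique(data$trait)) != 1)
    stop_ogb("build_design: restrict data to a single trait first")
  labels <- rownames(K)
  absent <- setdiff(unique(data$id), labels)
  if (length(absent))
    stop_ogb("build_design: record id(s) absent from kernel: ",
             paste(utils::head(absent, 5), collapse = ", "))
  data <- droplevels(data)
  y <- data$value
  ss <- droplevels(data$seed_source)
  X <- if (nlevels(ss) >= 2) stats::model.matrix(~ss) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  # drop rank-deficient fixed columns (e.g. a seed source confounded in subset)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    message("build_design: dropping rank-deficient fixed column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  Fr <- droplevels(data$replicate)
  Fs <- droplevels(interaction(data$replicate, data$set, drop = TRUE, sep = ":"))
  if (nlevels(Fr) < 2) Fr <- NULL
  if (is.null(Fr) || nlevels(Fs) < 2 || nlevels(Fs) == nlevels(Fr)) Fs <- NULL
  list(y = y, X = X, ia = match(data$id, labels), ids = data$id,
       Fr = Fr, Fs = Fs, n = length(y), labels = labels)
}

# 0/1 incidence matrix of a factor.
incidence <- function(f) {
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# --- restricted likelihood machinery -----------------------------------
# Rotated representation: with H = K[ia, ia] = U diag(d) U',
# V = sigma2_a H + sigma2_r Zr Zr' + sigma2_rs Zs Zs' + sigma2_e I
# becomes, after rotation by U', a diagonal Delta = sigma2_a d + sigma2_e
# plus a low-rank part handled by the Woodbury identity. All per-iteration
# work is O(n^2 m) with m = n_reps + n_sets.

.reml_eval <- function(theta, rot, want_derivs = TRUE) {
  n <- length(rot$yt); p <- ncol(rot$Xt); m <- ncol(rot$W)
  Delta <- theta[1] * rot$d + theta[4]
  Dinv <- 1 / Delta
  if (m > 0) {
    sig <- sqrt(c(rep(theta[2], rot$m_r), rep(theta[3], rot$m_s)))
    Aw <- sweep(rot$W, 2, sig, "*")
    Q <- Dinv * Aw
    Mm <- diag(m) + crossprod(Aw, Q)
    cM <- chol(Mm)
    Minv <- chol2inv(cM)
    Vinv <- -Q %*% tcrossprod(Minv, Q)
    diag(Vinv) <- diag(Vinv) + Dinv
    logdetV <- sum(log(Delta)) + 2 * sum(log(diag(cM)))
  } else {
    Vinv <- diag(Dinv, n)
    logdetV <- sum(log(Delta))
  }
  VX <- Vinv %*% rot$Xt
  B <- crossprod(rot$Xt, VX)
  cB <- chol(B)
  Vy <- Vinv %*% rot$yt
  beta <- backsolve(cB, forwardsolve(t(cB), crossprod(rot$Xt, Vy)))
  Py <- Vy - VX %*% beta
  yPy <- sum(rot$yt * Py)
  logRL <- -0.5 * ((n - p) * log(2 * pi) + logdetV +
                     2 * sum(log(diag(cB))) + yPy)
  out <- list(logRL = logRL, beta = drop(beta), Py = drop(Py), Vinv = Vinv,
              VX = VX, B = B)
  if (!want_derivs) return(out)
  P <- Vinv - VX %*% backsolve(cB, forwardsolve(t(cB), t(VX)))
  Py <- drop(Py)
  # dV/dtheta_i applied to Py, for i = a, r, s, e
  Fc <- matrix(0, n, 4)
  Fc[, 1] <- rot$d * Py
  if (rot$m_r > 0) {
    Wr <- rot$W[, seq_len(rot$m_r), drop = FALSE]
    Fc[, 2] <- Wr %*% crossprod(Wr, Py)
  }
  if (rot$m_s > 0) {
    Ws <- rot$W[, rot$m_r + seq_len(rot$m_s), drop = FALSE]
    Fc[, 3] <- Ws %*% crossprod(Ws, Py)
  }
  Fc[, 4] <- Py
  PF <- P %*% Fc
  AI <- 0.5 * crossprod(Fc, PF)
  trPV <- numeric(4)
  trPV[1] <- sum(diag(P) * rot$d)
  if (rot$m_r > 0) trPV[2] <- sum((P %*% Wr) * Wr)
  if (rot$m_s > 0) trPV[3] <- sum((P %*% Ws) * Ws)
  trPV[4] <- sum(diag(P))
  yPVPy <- drop(crossprod(Py, Fc))
  score <- -0.5 * (trPV - yPVPy)
  out$score <- score; out$AI <- AI; out$trPV <- trPV; out$yPVPy <- yPVPy
  out
}

#' REML variance-component estimation
#'
#' Maximises the restricted likelihood of the replicated trial model over
#' `(sigma2_a, sigma2_r, sigma2_rs, sigma2_e)` by average-information updates
#' with expectation-maximisation fallback steps whenever an AI update would
#' leave the parameter space or decrease the restricted likelihood.
#' Convergence requires `|delta logRL| < tol_logl` and a maximum relative
#' parameter change below `tol_par`. Components are constrained non-negative;
#' a component pinned below `1e-8 *` phenotypic variance is reported as 0
#' with a boundary flag. On non-convergence the last iterate is returned with
#' `converged = FALSE` (downstream reports then show the NA convention).
#'
#' @param data a [trial_data()].
#' @param K a [relationship_matrix()] (A for BLUP, G for GBLUP). Eigenvalues
#'   below `-1e-8` are clamped to zero (near-singular G is routine).
#' @param trait trait to fit (default: the single trait present).
#' @param init optional starting values, named `a`, `r`, `s`, `e`.
#' @param max_iter,tol_logl,tol_par iteration controls.
#' @param eigen_H optional precomputed `eigen()` of `K[ia, ia]` (a
#'   performance knob for repeated fits on the same individuals; validated
#'   only for dimension).
#' @return object of class `vc_fit` with components `sigma2_a`, `sigma2_r`,
#'   `sigma2_rs`, `sigma2_e`, their asymptotic standard errors (from the
#'   inverse AI matrix), `log_likelihood`, `converged`, `boundary`,
#'   `iterations`, and the component covariance used by [heritability()].
#' @export
reml_fit <- function(data, K, trait = NULL, init = NULL, max_iter = 100L,
                     tol_logl = 1e-6, tol_par = 1e-6, eigen_H = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(data, "trial_data"), inherits(K, "relationship_matrix"))
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  trait <- unique(data$trait)
  if (length(trait) != 1) stop_ogb("reml_fit: specify a single trait")
  class(data) <- c("trial_data", "data.frame")
  des <- build_design(data, K)
  n <- des$n
  H <- unclass(K)[des$ia, des$ia, drop = FALSE]
  if (is.null(eigen_H)) eigen_H <- eigen(H, symmetric = TRUE)
  if (length(eigen_H$values) != n)
    stop_ogb("reml_fit: eigen_H dimension mismatch")
  d <- pmax(eigen_H$values, 0)
  U <- eigen_H$vectors
  W0 <- cbind(if (!is.null(des$Fr)) incidence(des$Fr),
              if (!is.null(des$Fs)) incidence(des$Fs))
  m_r <- if (!is.null(des$Fr)) nlevels(des$Fr) else 0L
  m_s <- if (!is.null(des$Fs)) nlevels(des$Fs) else 0L
  rot <- list(yt = drop(crossprod(U, des$y)), Xt = crossprod(U, des$X),
              W = if (m_r + m_s > 0) crossprod(U, W0) else matrix(0, n, 0),
              d = d, m_r = m_r, m_s = m_s)
  vy <- stats::var(des$y)
  floor_e <- 1e-8 * vy  # conditioning floor for the residual variance
  active <- c(TRUE, m_r > 0, m_s > 0, TRUE)
  theta <- c(0.4, 0.05, 0.05, 0.5) * vy
  if (!is.null(init)) theta <- c(init["a"], init["r"], init["s"], init["e"])
  theta[!active] <- 0
  qlev <- c(n, max(m_r, 1), max(m_s, 1), n)  # EM denominators
  ev <- .reml_eval(theta, rot)
  pin_tol <- 1e-8 * vy
  pinned <- !active
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # release a pinned component whose gradient points back inside
    pinned[active & pinned & ev$score > 0] <- FALSE
    free <- active & !pinned
    free[4] <- TRUE
    step_ok <- FALSE
    AIf <- ev$AI[free, free, drop = FALSE]
    prop <- theta
    upd <- tryCatch(solve(AIf + diag(1e-10 * max(diag(AIf)), sum(free)),
                          ev$score[free]),
                    error = function(e) NULL)
    if (!is.null(upd)) {
      prop[free] <- theta[free] + upd
      # a negative proposal decays the component geometrically instead of
      # being rejected, so boundary components reach zero in a few steps
      neg <- free & prop < 0
      prop[neg] <- theta[neg] / 100
      prop[4] <- max(prop[4], floor_e)
      ev2 <- tryCatch(.reml_eval(prop, rot), error = function(e) NULL)
      if (!is.null(ev2) && is.finite(ev2$logRL) &&
          ev2$logRL >= ev$logRL - 1e-10) step_ok <- TRUE
    }
    if (!step_ok) {
      # EM fallback: sigma_i^2 <- sigma_i^2 + sigma_i^4/q_i (y'PV_iPy - tr(PV_i)),
      # with geometric overrelaxation along the EM direction (plain EM steps
      # crawl near boundaries) and step-halving as a last resort
      em <- theta + theta^2 / qlev * (ev$yPVPy - ev$trPV)
      em[!free] <- theta[!free]
      em <- pmax(em, 0)
      em[4] <- max(em[4], floor_e)
      dir <- em - theta
      prop <- theta; ev2 <- ev; found <- FALSE
      for (alpha in c(1, 2, 4, 8, 16, 32)) {
        cand <- pmax(theta + alpha * dir, 0)
        cand[4] <- max(cand[4], floor_e)
        evc <- tryCatch(.reml_eval(cand, rot), error = function(e) NULL)
        if (is.null(evc) || !is.finite(evc$logRL) ||
            evc$logRL < ev2$logRL - 1e-12) break
        prop <- cand; ev2 <- evc; found <- TRUE
      }
      if (!found) {
        h <- 0L; alpha <- 0.5
        while (!found && h < 30L) {
          cand <- pmax(theta + alpha * dir, 0)
          cand[4] <- max(cand[4], floor_e)
          evc <- tryCatch(.reml_eval(cand, rot), error = function(e) NULL)
          if (!is.null(evc) && is.finite(evc$logRL) &&
              evc$logRL >= ev$logRL - 1e-10) {
            prop <- cand; ev2 <- evc; found <- TRUE
          }
          alpha <- alpha / 2; h <- h + 1L
        }
        if (!found) break
      }
    }
    # boundary acceleration: a component with negative score that the
    # quadratic step barely moves is shrunk an order of magnitude whenever
    # that does not decrease the restricted likelihood
    shr <- free & seq_len(4) != 4 & ev2$score < 0 & prop > 0
    if (any(shr)) {
      prop3 <- prop; prop3[shr] <- prop[shr] / 10
      ev3 <- tryCatch(.reml_eval(prop3, rot), error = function(e) NULL)
      if (!is.null(ev3) && is.finite(ev3$logRL) &&
          ev3$logRL >= ev2$logRL - 1e-12) { prop <- prop3; ev2 <- ev3 }
    }
    # pin components that collapsed to the boundary and still push outward
    hit <- active & seq_len(4) != 4 & prop < pin_tol & ev2$score < 0
    if (any(hit)) { prop[hit] <- 0; pinned[hit] <- TRUE
                    ev2 <- .reml_eval(prop, rot) }
    dlog <- abs(ev2$logRL - ev$logRL)
    dpar <- max(abs(prop - theta) / pmax(abs(theta), pin_tol))
    if (verbose)
      message(sprintf("iter %2d  logRL %.8f  theta %s", iter, ev2$logRL,
                      paste(signif(prop, 5), collapse = " ")))
    theta <- prop; ev <- ev2
    if (dlog < tol_logl && dpar < tol_par) { converged <- TRUE; break }
  }
  boundary <- active & theta < 1e-8 * vy
  boundary[4] <- FALSE   # residual variance is floored, never zeroed
  theta_rep <- ifelse(boundary, 0, theta)
  se <- rep(NA_real_, 4)
  covmat <- matrix(NA_real_, 4, 4)
  freeF <- active & !boundary
  ci <- tryCatch(solve(ev$AI[freeF, freeF, drop = FALSE]),
                 error = function(e) NULL)
  if (!is.null(ci)) {
    covmat[freeF, freeF] <- ci
    se[freeF] <- sqrt(pmax(diag(ci), 0))
  }
  nms <- c("sigma2_a", "sigma2_r", "sigma2_rs", "sigma2_e")
  structure(list(sigma2_a = theta_rep[1], sigma2_r = theta_rep[2],
                 sigma2_rs = theta_rep[3], sigma2_e = theta_rep[4],
                 se = stats::setNames(se, nms),
                 cov = structure(covmat, dimnames = list(nms, nms)),
                 log_likelihood = ev$logRL, converged = converged,
                 boundary = stats::setNames(boundary, nms),
                 iterations = iter, n = n, trait = trait,
                 kernel = attr(K, "kind"), active = active),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s kernel), trait '%s', n = %d, %s after %d iterations\n",
              x$kernel, x$trait, x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  comp <- c(x$sigma2_a, x$sigma2_r, x$sigma2_rs, x$sigma2_e)
  lab <- c("sigma2_a", "sigma2_r", "sigma2_r(s)", "sigma2_e")
  for (i in seq_along(comp))
    cat(sprintf("  %-12s %10.5f  (se %s)\n", lab[i], comp[i],
                ifelse(is.na(x$se[i]), "-", sprintf("%.5f", x$se[i]))))
  cat(sprintf("  logRL = %.6f\n", x$log_likelihood))
  h <- heritability(x)
  cat(sprintf("  h2 = %.4f (se %s)\n", h$h2,
              ifelse(is.na(h$se), "-", sprintf("%.4f", h$se))))
  invisible(x)
}

#' Narrow-sense heritability from a variance-component fit
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the replicate and
#' set-within-replicate variances are deliberately excluded from the
#' denominator. `full = TRUE` gives the optional full-phenotypic-variance
#' ratio (not the default). Standard error by the first-order delta method
#' on the component covariance.
#'
#' @param vc a `vc_fit` (or list with `sigma2_a`, `sigma2_e`, optional `cov`).
#' @param full include design variances in the denominator.
#' @return list with `h2` and `se`.
#' @export
heritability <- function(vc, full = FALSE) {
  a <- vc$sigma2_a; e <- vc$sigma2_e
  extra <- if (full) (vc$sigma2_r %||% 0) + (vc$sigma2_rs %||% 0) else 0
  den <- a + e + extra
  if (den <= 0) return(list(h2 = NA_real_, se = NA_real_, undefined = TRUE))
  h2 <- a / den
  se <- NA_real_
  if (!is.null(vc$cov) && !full) {
    g <- c(e, 0, 0, -a) / den^2
    C <- vc$cov; C[is.na(C)] <- 0
    se <- sqrt(max(drop(t(g) %*% C %*% g), 0))
  }
  list(h2 = h2, se = se)
}

#' Theoretical accuracy of a breeding value
#'
#' `r = sqrt(1 - PEV / (K_ii sigma2_a))`, the prediction-error-variance based
#' accuracy, with `K_ii` the kernel diagonal (G_ii for GBLUP, A_ii for BLUP).
#' Tiny negative PEV overshoot (>= -1e-10) is clamped to 0; PEV exceeding
#' `K_ii sigma2_a` beyond tolerance is flagged invalid (`NA` with a warning),
#' signalling model/PEV inconsistency rather than being clamped.
#'
#' @param pev prediction error variance(s).
#' @param K_ii kernel diagonal element(s).
#' @param sigma2_a additive genetic variance.
#' @return accuracy in [0, 1] (vectorised).
#' @export
theoretical_accuracy <- function(pev, K_ii, sigma2_a) {
  stopifnot(length(sigma2_a) == 1)
  cap <- K_ii * sigma2_a
  pev <- ifelse(pev < 0 & pev >= -1e-10, 0, pev)
  bad <- pev < 0 | pev > cap * (1 + 1e-8) + 1e-12
  if (any(bad, na.rm = TRUE))
    warning("theoretical_accuracy: PEV outside [0, K_ii * sigma2_a] for ",
            sum(bad, na.rm = TRUE), " individual(s); returned NA", call. = FALSE)
  r2 <- 1 - pev / cap
  out <- sqrt(pmin(pmax(r2, 0), 1))
  out[bad] <- NA_real_
  out[cap == 0] <- 0
  out
}

# Dense mixed-model-equation solve shared by solve_blup() and the
# cross-validation loop. Individual effects cover every kernel label so
# unphenotyped individuals are predicted through the kernel.
.mme_solve <- function(y, X, ia, Fr, Fs, Kinv, vc, pev = TRUE) {
  n <- length(y); q <- nrow(Kinv); p <- ncol(X)
  Zu <- matrix(0, n, q)
  Zu[cbind(seq_len(n), ia)] <- 1
  Z <- cbind(Zu,
             if (!is.null(Fr)) incidence(Fr),
             if (!is.null(Fs)) incidence(Fs))
  lam <- c(rep(0, q),
           if (!is.null(Fr)) rep(vc$sigma2_e / vc$sigma2_r, nlevels(Fr)),
           if (!is.null(Fs)) rep(vc$sigma2_e / vc$sigma2_rs, nlevels(Fs)))
  ZZ <- crossprod(Z)
  diag(ZZ) <- diag(ZZ) + lam
  idx_u <- p + seq_len(q)
  ZZ[seq_len(q), seq_len(q)] <- ZZ[seq_len(q), seq_len(q)] +
    Kinv * (vc$sigma2_e / vc$sigma2_a)
  Cmat <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                cbind(crossprod(Z, X), ZZ))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  cC <- tryCatch(chol(Cmat), error = function(e)
    stop_ogb("mixed-model equations singular; consider bending the kernel ",
             "(near-singular G) or checking the design"))
  csolve <- function(b) backsolve(cC, forwardsolve(t(cC), b))
  sol <- csolve(rhs)
  sol <- sol + csolve(rhs - drop(Cmat %*% sol))  # one refinement step
  out <- list(beta = sol[seq_len(p)], u = sol[idx_u])
  if (pev) {
    Cinv <- chol2inv(cC)
    # one Newton step for the inverse: accurate PEV even when the variance
    # ratios make the coefficient matrix ill-conditioned
    Cinv <- Cinv + Cinv %*% (diag(nrow(Cmat)) - Cmat %*% Cinv)
    out$pev <- vc$sigma2_e * diag(Cinv)[idx_u]
  }
  out
}

#' Solve the mixed-model equations at plugged-in variance components
#'
#' Returns breeding values for every individual in the kernel (including
#' unphenotyped ones, predicted through the kernel), fixed-effect estimates,
#' PEV from the corresponding diagonal block of the inverse coefficient
#' matrix, and the theoretical accuracy. If the kernel has eigenvalues below
#' 1e-8 it is bent by adding 1e-6 to the diagonal (logged).
#'
#' In the `sigma2_a -> 0` limit all breeding values shrink to 0 and fixed
#' effects revert to (generalised) least squares; at `sigma2_a = 0` exactly,
#' breeding values are returned as 0 with zero PEV and accuracy 0.
#'
#' @param data a [trial_data()] for one trait.
#' @param K a [relationship_matrix()].
#' @param vc variance components (a `vc_fit` or a list with `sigma2_a`,
#'   `sigma2_r`, `sigma2_rs`, `sigma2_e`).
#' @param trait optional trait selector.
#' @return object of class `breeding_values`: data.frame `id`, `ebv`, `pev`,
#'   `accuracy`, with attributes `fixed` (named fixed-effect estimates),
#'   `kernel` (kind used) and `vc`.
#' @export
solve_blup <- function(data, K, vc, trait = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(K, "relationship_matrix"))
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  class(data) <- c("trial_data", "data.frame")
  if (vc$sigma2_e <= 0) stop_ogb("solve_blup: sigma2_e must be positive")
  des <- build_design(data, K)
  labels <- rownames(K)
  if (vc$sigma2_a <= 0) {
    # ridge limit: no additive signal; fixed effects by GLS under the
    # remaining design random effects
    n <- length(des$y)
    V <- diag(vc$sigma2_e, n)
    if (!is.null(des$Fr) && (vc$sigma2_r %||% 0) > 0)
      V <- V + vc$sigma2_r * tcrossprod(incidence(des$Fr))
    if (!is.null(des$Fs) && (vc$sigma2_rs %||% 0) > 0)
      V <- V + vc$sigma2_rs * tcrossprod(incidence(des$Fs))
    Vi <- chol2inv(chol(V))
    B <- crossprod(des$X, Vi %*% des$X)
    beta <- solve(B, crossprod(des$X, Vi %*% des$y))
    out <- data.frame(id = labels, ebv = 0, pev = 0, accuracy = 0,
                      row.names = NULL)
    class(out) <- c("breeding_values", "data.frame")
    attr(out, "fixed") <- stats::setNames(drop(beta), colnames(des$X))
    attr(out, "kernel") <- attr(K, "kind"); attr(out, "vc") <- vc
    return(out)
  }
  Kv <- unclass(K)
  emin <- min(eigen(Kv, symmetric = TRUE, only.values = TRUE)$values)
  if (emin < 1e-8) {
    message(sprintf("solve_blup: bending kernel (min eigenvalue %.2e) by 1e-6", emin))
    Kv <- Kv + diag(1e-6, nrow(Kv))
  }
  Kinv <- chol2inv(chol(Kv))
  use_r <- !is.null(des$Fr) && (vc$sigma2_r %||% 0) > 0
  use_s <- !is.null(des$Fs) && (vc$sigma2_rs %||% 0) > 0
  sol <- .mme_solve(des$y, des$X, des$ia,
                    if (use_r) des$Fr else NULL,
                    if (use_s) des$Fs else NULL,
                    Kinv, vc, pev = TRUE)
  pev <- sol$pev
  pev[pev < 0 & pev >= -1e-10] <- 0
  acc <- theoretical_accuracy(pev, diag(Kv), vc$sigma2_a)
  out <- data.frame(id = labels, ebv = sol$u, pev = pev, accuracy = acc,
                    row.names = NULL)
  class(out) <- c("breeding_values", "data.frame")
  attr(out, "fixed") <- stats::setNames(sol$beta, colnames(des$X))
  attr(out, "kernel") <- attr(K, "kind")
  attr(out, "vc") <- vc
  out
}

#' @export
print.breeding_values <- function(x, ...) {
  cat(sprintf("<breeding_values (%s kernel), %d individuals, mean accuracy %.3f>\n",
              attr(x, "kernel"), nrow(x), mean(x$accuracy, na.rm = TRUE)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
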