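# Genomics module: filtering, imputation, G matrix, LD, spectral structure.

test_that("compute_G matches the hand-worked 3x2 oracle and its invariants", {
  M <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  G <- compute_G(genotype_matrix(M))
  # Z = M - colmeans -> [[-1,1],[0,0],[1,-1]]; ZZ' = [[2,0,-2],[0,0,0],[-2,0,2]]
  # tr = 4, n = 3 -> G = ZZ' * 3/4
  expect_equal(unname(unclass(G)),
               matrix(c(1.5, 0, -1.5, 0, 0, 0, -1.5, 0, 1.5), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mean(diag(G)), 1, tolerance = 1e-12)

  # identical genotype rows: G11 = G22 = G12
  M2 <- matrix(c(0, 0, 2, 1, 1, 0, 2, 2, 1, 0, 0, 2), 3, 4,
               dimnames = list(c("a", "b", "c"), paste0("m", 1:4)))
  M2["b", ] <- M2["a", ]
  G2 <- compute_G(genotype_matrix(M2, imputed = TRUE))
  expect_equal(G2["a", "a"], G2["b", "b"], tolerance = 1e-12)
  expect_equal(G2["a", "a"], G2["a", "b"], tolerance = 1e-12)

  # adding a monomorphic marker leaves G unchanged
  M3 <- cbind(M2, m5 = c(2, 2, 2))
  expect_equal(unclass(compute_G(genotype_matrix(M3, imputed = TRUE))),
               unclass(G2), tolerance = 1e-12)
  # monomorphic-only input is degenerate
  expect_error(compute_G(genotype_matrix(
    matrix(2, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))), "polymorphic")
  expect_error(compute_G(genotype_matrix(
    matrix(c(0, 1, NA, 2), 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "missing")
})

test_that("composite_r2: identities, coding swap, null level", {
  set.seed(5)
  M <- matrix(rbinom(40 * 4, 2, 0.5), 40, 4,
              dimnames = list(sprintf("i%02d", 1:40), paste0("m", 1:4)))
  M[, 2] <- M[, 1]
  M[, 3] <- 2 - M[, 1]
  M[, 4] <- 1  # zero variance
  g <- genotype_matrix(M)
  expect_equal(composite_r2(g, "m1", "m2"), 1)
  expect_equal(composite_r2(g, "m1", "m3"), 1)  # negative correlation squares to 1
  r <- composite_r2(g, "m1", "m4")
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_equal(composite_r2(g, "m1", "m2"), composite_r2(g, "m2", "m1"))
  # independent markers, n = 10000: mean r2 at the 1/n scale
  set.seed(6)
  Mi <- matrix(rbinom(10000 * 20, 2, 0.5), 10000, 20,
               dimnames = list(NULL, paste0("s", 1:20)))
  rownames(Mi) <- as.character(seq_len(10000))
  r2 <- cor(Mi)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.001)
})

test_that("filter_markers applies the five rules with first-fail attribution", {
  # MAF 0.005: 1 copy among 100 individuals
  M <- matrix(0, 100, 3, dimnames = list(sprintf("i%03d", 1:100), c("lowmaf", "lowcall", "ok")))
  M[1, "lowmaf"] <- 1
  M[, "ok"] <- rbinom(100, 2, 0.5)
  M[, "lowcall"] <- M[, "ok"]
  M[seq_len(50), "lowcall"] <- NA
  st <- marker_stats(genotype_matrix(M))
  expect_equal(st$maf[st$marker == "lowmaf"], 0.005)
  expect_equal(st$call_rate[st$marker == "lowcall"], 0.5)
  meta <- data.frame(marker = colnames(M), chrom = 1, pos = c(100, 2000, 50000),
                     qa = 0.9, qb = 0.9)
  res <- filter_markers(genotype_matrix(M, meta))
  expect_equal(res$report$failed_markers[["lowmaf"]], "maf")
  expect_equal(res$report$failed_markers[["lowcall"]], "call_rate")
  expect_equal(colnames(res$genotypes$dosages), "ok")

  # hand-enumerated 10-marker toy: m1 qa, m2 call rate, m3 MAF, m10 LD-pruned
  toy <- toy_filter_matrix()
  res <- filter_markers(toy)
  expect_equal(res$report$n_input, 10)
  expect_equal(res$report$n_pass, 6)
  expect_setequal(colnames(res$genotypes$dosages), paste0("m", 4:9))
  expect_equal(res$report$removed$qa, 1)
  expect_equal(res$report$removed$call_rate, 1)
  expect_equal(res$report$removed$maf, 1)
  expect_equal(res$report$removed$ld, 1)
  expect_equal(res$report$removed$qb, 0)
  # removing everything is an explicit error
  expect_error(filter_markers(toy, filter_thresholds(maf = 0.99)), "all markers")
})

test_that("impute_em identities and self-masking benefit", {
  M <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(letters[1:3], c("m1", "m2")))
  g <- genotype_matrix(M)
  expect_identical(impute_em(g)$dosages, M)
  # a missing entry in an all-2 column imputes to 2 (mean-init fixed point)
  M2 <- matrix(c(2, 2, NA, 0, 1, 2, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], paste0("m", 1:3)))
  out <- impute_em(genotype_matrix(M2))
  expect_equal(out$dosages["c", "m1"], 2, tolerance = 1e-3)
  # observed entries are never moved
  obs <- !is.na(M2)
  expect_equal(out$dosages[obs], M2[obs])
  expect_error(impute_em(genotype_matrix(
    matrix(c(NA, NA, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "no observed")

  # EM beats column-mean imputation on related individuals (single seed here;
  # the multi-seed version is an acceptance criterion)
  cfg <- small_config(seed = 9, n_markers = 500, n_chromosomes = 5)
  pop <- simulate_orchard_population(cfg)
  full <- pop$complete_dosages
  set.seed(10)
  mask <- matrix(runif(length(full)) < 0.1, nrow(full))
  obs <- full; obs[mask] <- NA
  gm <- genotype_matrix(obs, pop$genotypes$marker_meta)
  em <- impute_em(gm)$dosages
  mu <- colMeans(obs, na.rm = TRUE)
  meanimp <- obs
  meanimp[mask] <- matrix(mu, nrow(obs), ncol(obs), byrow = TRUE)[mask]
  rmse <- function(x) sqrt(mean((x[mask] - full[mask])^2))
  expect_lt(rmse(em), rmse(meanimp))
})

test_that("ld_decay binning and decay_distance interpolation", {
  curve <- structure(data.frame(bin_start = c(0, 2000), bin_end = c(2000, 4000),
                                mid = c(1000, 3000), mean_r2 = c(0.50, 0.19),
                                n_pairs = c(10, 10)),
                     class = c("ld_decay_curve", "data.frame"))
  d <- decay_distance(curve, 0.2)
  expect_gt(d, 1000); expect_lt(d, 3000)
  expect_equal(d, 1000 + (0.5 - 0.2) / (0.5 - 0.19) * 2000)
  curve$mean_r2 <- c(0.50, 0.20)
  expect_equal(decay_distance(curve, 0.2), 3000)
  # perfect LD genome-wide: constant curve, threshold never reached
  M <- matrix(rbinom(30, 2, 0.5), 30, 1)[, c(1, 1, 1)]
  dimnames(M) <- list(sprintf("i%02d", 1:30), c("a", "b", "c"))
  meta <- data.frame(marker = c("a", "b", "c"), chrom = 1,
                     pos = c(100, 600, 1100), qa = 1, qb = 1)
  cv <- ld_decay(genotype_matrix(M, meta), max_distance_bp = 2000,
                 bin_width_bp = 500)
  expect_true(all(cv$mean_r2[cv$n_pairs > 0] == 1))
  nr <- decay_distance(cv, 0.2)
  expect_true(is.na(nr) && attr(nr, "not_reached"))
  expect_error(ld_decay(genotype_matrix(M, meta), max_distance_bp = 10),
               "no intra-chromosome")
})

test_that("simulated LD decays with distance and tracks ld_decay_bp ordering", {
  d3 <- d5 <- numeric(0)
  for (s in 1:20) {
    cfg <- small_config(seed = 100 + s, n_founders = c(60, 60),
                        n_families = c(15, 15), n_markers = 400,
                        n_chromosomes = 2, chrom_length_bp = 6e4,
                        ld_decay_bp = c(3000, 5000))
    pop <- simulate_orchard_population(cfg)
    for (o in c("W", "T")) {
      ids <- names(pop$orchard)[pop$orchard == o]
      g <- genotype_matrix(pop$complete_dosages[ids, ], pop$genotypes$marker_meta)
      cv <- ld_decay(g, max_distance_bp = 2e4, bin_width_bp = 1000)
      dd <- decay_distance(cv, 0.2)
      if (o == "W") d3 <- c(d3, dd) else d5 <- c(d5, dd)
    }
  }
  expect_gt(mean(d5, na.rm = TRUE), mean(d3, na.rm = TRUE))
})

test_that("spectral decomposition: trace identity, degenerate case, orchard separation", {
  set.seed(31)
  L <- matrix(rnorm(100), 10)
  K <- tcrossprod(L); dimnames(K) <- list(letters[1:10], letters[1:10])
  K <- relationship_matrix(K / mean(diag(K)), "G")
  sp <- spectral_decomposition(K)
  expect_equal(sum(sp$values), sum(diag(K)), tolerance = 1e-8)
  Id <- relationship_matrix(matrix(diag(10), 10, 10,
                                   dimnames = list(letters[1:10], letters[1:10])), "A")
  spI <- spectral_decomposition(Id)
  expect_equal(spI$values, rep(1, 10))
  bad <- matrix(rnorm(16), 4)
  expect_error(spectral_decomposition(bad), "symmetric")

  # two diverged orchards separate on the first two component scores
  cfg <- small_config(seed = 41, n_founders = c(50, 50), n_families = c(12, 12),
                      n_markers = 500, divergence = 0.15)
  pop <- simulate_orchard_population(cfg)
  G <- compute_G(genotype_matrix(pop$complete_dosages, pop$genotypes$marker_meta))
  sp <- spectral_decomposition(G, 2)
  lab <- as.integer(pop$orchard[rownames(sp$scores)] == "W")
  fit <- suppressWarnings(glm(lab ~ sp$scores[, 1] + sp$scores[, 2],
                              family = binomial))
  acc <- mean((fitted(fit) > 0.5) == lab)
  expect_gt(acc, 0.9)
})
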