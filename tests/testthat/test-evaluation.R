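# Evaluation module: folds, predictive accuracy, cross-validation, gain.

test_that("make_folds sizes, determinism and partition", {
  ids <- sprintf("i%03d", 1:100)
  f <- make_folds(ids, 10, 1)
  expect_true(all(table(f) == 10))
  f2 <- make_folds(sprintf("i%03d", 1:101), 10, 1)
  expect_setequal(as.integer(table(f2)), c(10, 11))
  expect_equal(sum(table(f2) == 11), 1)
  expect_identical(make_folds(ids, 10, 7), make_folds(ids, 10, 7))
  expect_false(identical(make_folds(ids, 10, 7), make_folds(ids, 10, 8)))
  expect_setequal(names(f), ids)  # partition: every id exactly once
  expect_error(make_folds(ids, 1, 1), "n_folds")
  expect_error(make_folds(ids[1:5], 10, 1), "more folds")
})

test_that("predictive_accuracy arithmetic and degeneracy", {
  expect_equal(predictive_accuracy(1:5, 1:5), 1)
  expect_equal(predictive_accuracy(1:5, -(1:5)), -1)
  # EBV = (1,2,3), GEBV = (1,2,4): direct arithmetic oracle
  r_oracle <- 3 / sqrt(2 * 42 / 9)
  expect_equal(predictive_accuracy(c(1, 2, 3), c(1, 2, 4)), r_oracle,
               tolerance = 1e-12)
  r <- predictive_accuracy(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(r) && attr(r, "undefined"))
  expect_error(predictive_accuracy(1:2, 1:2), "at least 3")
  # name alignment
  a <- c(x = 1, y = 2, z = 3); b <- c(z = 3, x = 1, y = 2)
  expect_equal(predictive_accuracy(a, b), 1)
})

test_that("genetic gain: selection arithmetic and directions", {
  bv <- stats::setNames(as.numeric(1:10), paste0("i", 1:10))
  expect_equal(genetic_gain(bv, 0.2, "higher_better")$gain, 9.5)
  expect_equal(genetic_gain(bv, 0.2, "lower_better")$gain, 1.5)
  expect_equal(genetic_gain(rep(3, 7), 0.4)$gain, 3)
  expect_equal(genetic_gain(bv, 1)$gain, mean(bv))    # proportion 1 = overall mean
  expect_equal(length(genetic_gain(bv, 0.25)$selected), 3)  # ceiling(2.5)
  # stable tie-break by id
  tied <- stats::setNames(c(1, 2, 2, 0), c("d", "b", "a", "c"))
  expect_equal(genetic_gain(tied, 0.5)$selected, c("a", "b"))
  expect_error(genetic_gain(numeric(0)), "empty")
  expect_error(genetic_gain(bv, 0), "proportion")
})

test_that("gain_comparison_report shape and errors", {
  mk <- function(ids, shift = 0) {
    bvs <- data.frame(id = ids, ebv = seq_along(ids) + shift,
                      pev = 0.1, accuracy = 0.7)
    class(bvs) <- c("breeding_values", "data.frame")
    list(vc = list(sigma2_a = 0.3, sigma2_e = 0.7, converged = TRUE), bvs = bvs)
  }
  ids <- paste0("i", 1:10)
  rep1 <- gain_comparison_report(list(t1 = mk(ids), t2 = mk(ids)),
                                 list(t1 = mk(ids), t2 = mk(ids)))
  expect_equal(nrow(rep1), 2)
  expect_equal(rep1$dG_blup, rep1$dG_gblup)    # identical BV sets
  expect_equal(rep1$h2_blup, rep(0.3, 2))
  expect_error(gain_comparison_report(list(t1 = mk(ids)),
                                      list(t1 = mk(paste0("j", 1:10)))),
               "individual sets differ")
  # non-converged fits report the NA convention
  bad <- mk(ids); bad$vc$converged <- FALSE
  rep2 <- gain_comparison_report(list(t1 = bad), list(t1 = mk(ids)))
  expect_true(is.na(rep2$h2_blup) && is.na(rep2$dG_blup))
  expect_false(is.na(rep2$h2_gblup))
})

test_that("cross-validation structure: solves count and zero-information flag", {
  cfg <- small_config(seed = 61)
  pop <- simulate_orchard_population(cfg)
  A <- build_A(pop$pedigree)
  G <- compute_G(genotype_matrix(pop$complete_dosages, pop$genotypes$marker_meta))
  vcA <- reml_fit(pop$phenotypes, A)
  ref <- local({
    bv <- solve_blup(pop$phenotypes, A, vcA)
    stats::setNames(bv$ebv, bv$id)
  })
  scen <- cv_scenario("W", "W", n_folds = 5, n_replications = 3, seed = 2)
  res <- cross_validate(pop$phenotypes, G, scen, ref)
  expect_equal(res$n_solves, 15)
  expect_equal(length(res$r_p), 3)
  expect_false(res$zero_information)
  expect_true(all(abs(res$r_p) <= 1))
  # pedigree kernel carries no link between orchards: structurally zero info
  scen2 <- cv_scenario("W", "T", n_folds = 5, n_replications = 2, seed = 2)
  res2 <- cross_validate(pop$phenotypes, A, scen2, ref, vc = vcA)
  expect_true(res2$zero_information)
  # within-population marker CV has signal
  expect_gt(res$mean_rp, 0)
})

test_that("within-population r_p increases with heritability", {
  rp <- sapply(1:6, function(s) {
    sapply(c(0.1, 0.5), function(h2) {
      cfg <- small_config(seed = 700 + s, h2_target = h2,
                          n_founders = c(40, 10), n_families = c(14, 2),
                          n_markers = 300)
      pop <- simulate_orchard_population(cfg)
      A <- build_A(pop$pedigree)
      G <- compute_G(genotype_matrix(pop$complete_dosages,
                                     pop$genotypes$marker_meta))
      # reference EBVs at the generating variance components, so the
      # reference stays non-degenerate even when REML pins sigma2_a at low h2
      bv <- solve_blup(pop$phenotypes, A, pop$true_variance_components)
      ref <- stats::setNames(bv$ebv, bv$id)
      scen <- cv_scenario("W", "W", n_folds = 5, n_replications = 2, seed = s)
      cross_validate(pop$phenotypes, G, scen, ref,
                     vc = pop$true_variance_components)$mean_rp
    })
  })
  expect_gt(mean(rp[2, ]), mean(rp[1, ]))
})

test_that("enlarging the training set with relatives does not hurt accuracy", {
  diffs <- sapply(1:8, function(s) {
    cfg <- small_config(seed = 800 + s, n_founders = c(40, 10),
                        n_families = c(16, 2), h2_target = 0.4)
    pop <- simulate_orchard_population(cfg)
    ids_w <- names(pop$orchard)[pop$orchard == "W"]
    G <- compute_G(genotype_matrix(pop$complete_dosages,
                                   pop$genotypes$marker_meta))
    A <- build_A(pop$pedigree)
    # generating variance components keep reference and predictions
    # non-degenerate across seeds (REML can pin sigma2_a at this small n)
    vcG <- pop$true_variance_components
    refbv <- solve_blup(pop$phenotypes, A, vcG)
    ref <- stats::setNames(refbv$ebv, refbv$id)
    val <- withr::with_seed(s, sample(ids_w, 25))
    train_full <- setdiff(ids_w, val)
    train_half <- withr::with_seed(s + 99, sample(train_full,
                                                  length(train_full) %/% 2))
    pred <- function(train) {
      keep <- c(train, val)
      d <- pop$phenotypes[pop$phenotypes$id %in% train, ]
      class(d) <- c("trial_data", "data.frame")
      Ks <- relationship_matrix(unclass(G)[keep, keep], "G")
      bv <- solve_blup(d, Ks, vcG)
      predictive_accuracy(ref[val], stats::setNames(bv$ebv, bv$id)[val])
    }
    pred(train_full) - pred(train_half)
  })
  expect_gt(mean(diffs), -0.02)  # one-sided: no loss beyond sampling noise
})
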