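# Synthetic-data module: determinism, structure, calibration.

test_that("identical configs give bit-identical populations; seeds differ", {
  cfg <- small_config(seed = 5, missing_rate = 0.05)
  p1 <- simulate_orchard_population(cfg)
  p2 <- simulate_orchard_population(small_config(seed = 5, missing_rate = 0.05))
  expect_identical(p1$complete_dosages, p2$complete_dosages)
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$phenotypes$value, p2$phenotypes$value)
  expect_identical(p1$tbv, p2$tbv)
  expect_identical(as.data.frame(p1$pedigree), as.data.frame(p2$pedigree))
  p3 <- simulate_orchard_population(small_config(seed = 6, missing_rate = 0.05))
  expect_false(identical(p1$complete_dosages, p3$complete_dosages))
  expect_false(identical(p1$phenotypes$value, p3$phenotypes$value))
})

test_that("invalid configurations error", {
  expect_error(small_config(n_markers = 2, n_chromosomes = 3), "n_markers")
  expect_error(small_config(offspring_range = c(0, 10)), "offspring")
  expect_error(small_config(h2_target = 1.2), "h2_target")
  expect_error(small_config(selection_intensity = 0), "selection_intensity")
  expect_error(small_config(n_qtl = 1000, n_markers = 300), "n_qtl")
  # h2 = 1 forces sigma2_e = 0 and is allowed
  cfg <- small_config(h2_target = 1)
  expect_equal(simulate_orchard_population(cfg)$true_variance_components$sigma2_e, 0)
  # mothers cannot outnumber the retained founder pool
  expect_error(simulate_orchard_population(
    small_config(n_founders = c(30, 20), n_families = c(20, 5),
                 selection_intensity = c(0.3, 1))), "mothers")
})

test_that("72 families averaging 9.6 offspring give about 691 individuals", {
  totals <- vapply(1:10, function(s) {
    cfg <- small_config(seed = 400 + s, n_founders = c(120, 60),
                        n_families = c(46, 26), n_markers = 60,
                        n_chromosomes = 2, n_qtl = 10)
    nrow(simulate_orchard_population(cfg)$complete_dosages)
  }, numeric(1))
  # sd of a family total is ~sqrt(72 * 8.6) ~ 25
  expect_lt(abs(mean(totals) - 691), 30)
  expect_true(all(abs(totals - 691) < 100))
})

test_that("population structure is internally consistent", {
  cfg <- small_config(seed = 8, missing_rate = 0.05,
                      n_atsc_families = 2, atsc_family_size = 6)
  pop <- simulate_orchard_population(cfg)
  ids <- pop$phenotypes$id
  # every phenotyped individual has a pedigree record and a genotype row
  expect_true(all(ids %in% pop$pedigree$id))
  expect_true(all(ids %in% rownames(pop$genotypes$dosages)))
  expect_setequal(unique(pop$orchard), c("W", "T", "ATSC"))
  # documented pedigree: all offspring sires unknown, dams known
  ped <- as.data.frame(pop$pedigree)
  off <- ped[ped$id %in% ids, ]
  expect_true(all(off$sire == "0"))
  expect_true(all(off$dam != "0"))
  # pedigree is topologically valid: parents precede offspring after sort
  ord <- attr(pop$pedigree, "topo")
  pos <- match(seq_along(ped$id), ord)
  parent_pos <- match(match(ped$dam, ped$id), ord)
  expect_true(all(is.na(parent_pos) | parent_pos < pos |
                    ped$dam == "0"))
  # true breeding values have exactly the generating additive variance
  expect_equal(var(pop$tbv), pop$true_variance_components$sigma2_a,
               tolerance = 1e-10)
  # masked entries at the configured rate
  expect_lt(abs(mean(is.na(pop$genotypes$dosages)) - 0.05), 0.01)
})

test_that("offspring dosages obey Mendelian transmission from realized parents", {
  cfg <- small_config(seed = 12)
  pop <- simulate_orchard_population(cfg)
  fh <- simulate_founder_haplotypes(cfg)   # same substreams -> same founders
  founder_dose <- do.call(rbind, lapply(fh$haplotypes, function(h) {
    d <- h[seq(1, nrow(h), 2), ] + h[seq(2, nrow(h), 2), ]
    rownames(d) <- sub("\\.1$", "", rownames(h)[seq(1, nrow(h), 2)])
    d
  }))
  tp <- as.data.frame(pop$true_pedigree)
  off <- tp[tp$sire != "0" | (tp$dam != "0"), ]
  off <- off[off$id %in% rownames(pop$complete_dosages), ]
  for (i in sample(nrow(off), 30)) {
    kid <- pop$complete_dosages[off$id[i], ]
    mum <- founder_dose[off$dam[i], ]
    dad <- founder_dose[off$sire[i], ]
    lower <- (mum == 2) + (dad == 2)
    upper <- 2 - (mum == 0) - (dad == 0)
    expect_true(all(kid >= lower & kid <= upper))
  }
})

test_that("phenotype model: null heritability and heritability calibration", {
  cfg0 <- small_config(seed = 21, h2_target = 0)
  pop0 <- simulate_orchard_population(cfg0)
  expect_true(all(pop0$tbv == 0))
  expect_true(all(pop0$qtl_effects == 0))
  # mean realized h2 over seeds within +/- 0.05 of target at n >= 500
  h2s <- vapply(1:30, function(s) {
    cfg <- small_config(seed = 500 + s, n_founders = c(80, 80),
                        n_families = c(28, 28), n_markers = 100,
                        n_chromosomes = 2, n_qtl = 30, h2_target = 0.4)
    pop <- simulate_orchard_population(cfg)
    v <- var(pop$tbv)
    v / (v + pop$true_variance_components$sigma2_e)
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.4), 0.05)
})

test_that("founder LD is complete in the no-recombination limit", {
  cfg <- small_config(seed = 31, ld_decay_bp = c(1e12, 1e12), n_markers = 60,
                      n_chromosomes = 2, n_founders = c(40, 40))
  fh <- simulate_founder_haplotypes(cfg)
  h <- fh$haplotypes$W
  chrom1 <- which(fh$map$chrom == 1)
  # identical haplotype columns arise whenever thresholds coincide; any two
  # identical columns must show composite r2 exactly 1
  dose <- h[seq(1, nrow(h), 2), chrom1] + h[seq(2, nrow(h), 2), chrom1]
  dimnames(dose) <- list(sprintf("i%02d", seq_len(nrow(dose))),
                         fh$map$marker[chrom1])
  g <- genotype_matrix(dose, imputed = TRUE)
  cols <- g$dosages
  dup <- which(duplicated(t(cols)))[1]
  if (!is.na(dup)) {
    match_col <- which(apply(cols, 2, identical, cols[, dup]))[1]
    expect_equal(composite_r2(g, match_col, dup), 1)
  }
  # and mean intra-chromosome r2 vastly exceeds the finite-decay case
  r2_inf <- mean(cor(cols[, apply(cols, 2, var) > 0])^2)
  cfg2 <- small_config(seed = 31, ld_decay_bp = c(500, 500), n_markers = 60,
                       n_chromosomes = 2, n_founders = c(40, 40))
  fh2 <- simulate_founder_haplotypes(cfg2)
  h2 <- fh2$haplotypes$W
  cols2 <- h2[seq(1, nrow(h2), 2), chrom1] + h2[seq(2, nrow(h2), 2), chrom1]
  r2_fin <- mean(cor(cols2[, apply(cols2, 2, var) > 0])^2)
  expect_gt(r2_inf, 2 * r2_fin)
})
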