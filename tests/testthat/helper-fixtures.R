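# Shared fixtures built in code at test time.

# Small two-orchard simulation config (fast; ~130 individuals).
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_founders = c(W = 30, T = 20), n_families = c(W = 8, T = 5),
         n_markers = 300, n_chromosomes = 3, chrom_length_bp = 1e5,
         n_qtl = 40, h2_target = 0.4, n_atsc_families = 0,
         missing_rate = 0, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Random small trial instance for mixed-model oracle checks: a random
# well-conditioned PSD kernel, random design, one record per individual.
random_instance <- function(n, seed, n_src = 2, n_rep = 3, n_set = 2) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(n * n, sd = 0.3), n)
    K <- tcrossprod(L) + diag(n)
    K <- K / mean(diag(K))
    ids <- sprintf("id%02d", seq_len(n))
    dimnames(K) <- list(ids, ids)
    df <- data.frame(
      id = ids, trait = "t", value = rnorm(n, 10),
      seed_source = sample(paste0("src", seq_len(n_src)), n, replace = TRUE),
      replicate = sample(paste0("r", seq_len(n_rep)), n, replace = TRUE),
      set = sample(paste0("s", seq_len(n_set)), n, replace = TRUE))
    list(data = trial_data(df), K = relationship_matrix(K, "A"))
  })
}

# Hand-enumerated 10-marker toy matrix: exactly three markers fail one
# per-marker rule each (m1 the qa rule, m2 the call-rate rule, m3 the MAF
# rule), m10 duplicates m9 (r2 = 1, pruned by the LD rule), m4-m9 pass.
# Expected survivors: m4, m5, m6, m7, m8, m9 -> n_pass = 6.
toy_filter_matrix <- function() {
  n <- 40
  withr::with_seed(42, {
    base <- function(p) rbinom(n, 2, p)
    M <- cbind(m1 = base(0.5), m2 = base(0.5), m3 = rep(0, n),
               m4 = base(0.4), m5 = base(0.5), m6 = base(0.6),
               m7 = base(0.3), m8 = base(0.5), m9 = base(0.5))
    M <- cbind(M, m10 = M[, "m9"])        # perfect LD with m9
    M[seq_len(n / 2), "m2"] <- NA         # call rate 0.5 (< 0.6)
    rownames(M) <- sprintf("i%02d", seq_len(n))
    meta <- data.frame(marker = colnames(M), chrom = 1L,
                       pos = seq(1000, by = 1000, length.out = 10),
                       qa = c(0.2, rep(0.9, 9)),  # m1 fails qa > 0.5
                       qb = rep(0.9, 10))
    genotype_matrix(M, meta)
  })
}
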