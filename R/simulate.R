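# Deterministic synthetic-data generator: two diverged seed-orchard founder
# pools, open-pollinated half-sib families with unknown recorded sires, linked
# biallelic markers with controllable LD decay, and phenotypes from the
# replicated trial model. All randomness flows from one master seed through
# named substreams (see substream_seed()), so adding a stochastic feature
# never perturbs existing draws.

#' Simulation configuration
#'
#' Per-orchard fields (`n_founders`, `n_families`, `selection_intensity`,
#' `ld_decay_bp`) take length-2 vectors named `W`/`T` (scalars are recycled).
#' `selection_intensity` is the fraction of founders retained in the orchard's
#' parent pool: smaller fractions mean harsher selection, fewer realized
#' parents, smaller status number and slower measured LD decay.
#' `ld_decay_bp` is the physical distance at which the expected marker
#' r-squared halves. Defaults emulate a two-orchard open-pollinated progeny
#' trial of roughly 70 families averaging ~9.6 offspring (range 1-24), with a
#' small external control seed source, at desk scale.
#'
#' @param n_founders founders per orchard pool.
#' @param n_families open-pollinated families (known mothers) per orchard.
#' @param offspring_range,offspring_mean family-size distribution (truncated
#'   shifted Poisson on `offspring_range` with the given mean).
#' @param n_markers,n_chromosomes,chrom_length_bp marker map (positions are
#'   1-based bp; desk-scale chromosome lengths keep marker pairs within LD
#'   range).
#' @param ld_decay_bp per-orchard distance at which expected r2 halves.
#' @param n_qtl causal loci, drawn among the simulated loci.
#' @param qtl_in_panel if `TRUE` (default) the causal loci are genotyped
#'   markers, so marker-based prediction transfers across populations; if
#'   `FALSE` the QTL columns are withheld from the genotype panel and
#'   prediction works only through marker-QTL linkage disequilibrium, whose
#'   phase does not transfer between independently simulated orchards.
#' @param h2_target narrow-sense heritability sigma2_a/(sigma2_a+sigma2_e).
#' @param selection_intensity fraction of founders retained, in (0, 1].
#' @param n_replicates,n_sets_per_replicate trial design.
#' @param trait_direction `"higher_better"` or `"lower_better"`.
#' @param selfing_rate probability an offspring's pollen parent is its mother.
#' @param missing_rate completely-at-random genotype missingness.
#' @param divergence drift parameter (F_ST-like) separating orchard founder
#'   allele frequencies from the shared ancestral frequencies.
#' @param n_atsc_families,atsc_family_size,n_founders_atsc optional third
#'   small control group ("ATSC-like"); set `n_atsc_families = 0` to disable.
#' @param design_var_frac replicate and set-within-replicate variances, each
#'   as a fraction of total phenotypic variance.
#' @param morgans_per_chrom genetic length used for meiosis.
#' @param trait_name phenotype trait label.
#' @param seed master seed; identical configs give bit-identical populations.
#' @return validated object of class `simulation_config`.
#' @export
simulation_config <- function(n_founders = c(W = 150, T = 80),
                              n_families = c(W = 46, T = 25),
                              offspring_range = c(1, 24),
                              offspring_mean = 9.6,
                              n_markers = 2000,
                              n_chromosomes = 11,
                              chrom_length_bp = 2e5,
                              ld_decay_bp = c(W = 3000, T = 5000),
                              n_qtl = 100,
                              h2_target = 0.3,
                              selection_intensity = c(W = 0.9, T = 0.5),
                              n_replicates = 5,
                              n_sets_per_replicate = 4,
                              trait_direction = c("higher_better", "lower_better"),
                              selfing_rate = 0.04,
                              missing_rate = 0.05,
                              divergence = 0.10,
                              n_atsc_families = 2,
                              atsc_family_size = 12,
                              n_founders_atsc = 20,
                              design_var_frac = 0.10,
                              morgans_per_chrom = 1,
                              qtl_in_panel = TRUE,
                              trait_name = "trait",
                              seed = 1) {
  per_orchard <- function(x, what) {
    if (length(x) == 1) x <- c(W = unname(x), T = unname(x))
    if (length(x) != 2) stop_ogb("simulation_config: ", what, " must have length 1 or 2")
    names(x) <- c("W", "T")
    x
  }
  cfg <- list(n_founders = per_orchard(n_founders, "n_founders"),
              n_families = per_orchard(n_families, "n_families"),
              offspring_range = offspring_range,
              offspring_mean = offspring_mean,
              n_markers = n_markers, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp,
              ld_decay_bp = per_orchard(ld_decay_bp, "ld_decay_bp"),
              n_qtl = n_qtl, h2_target = h2_target,
              selection_intensity = per_orchard(selection_intensity,
                                                "selection_intensity"),
              n_replicates = n_replicates,
              n_sets_per_replicate = n_sets_per_replicate,
              trait_direction = match.arg(trait_direction),
              selfing_rate = selfing_rate, missing_rate = missing_rate,
              divergence = divergence,
              n_atsc_families = n_atsc_families,
              atsc_family_size = atsc_family_size,
              n_founders_atsc = n_founders_atsc,
              design_var_frac = design_var_frac,
              morgans_per_chrom = morgans_per_chrom,
              qtl_in_panel = isTRUE(qtl_in_panel),
              trait_name = trait_name, seed = seed)
  counts <- c(cfg$n_founders, cfg$n_families, n_markers, n_chromosomes,
              chrom_length_bp, n_qtl, n_replicates, n_sets_per_replicate)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop_ogb("simulation_config: counts must be positive integers")
  if (n_markers < n_chromosomes)
    stop_ogb("simulation_config: n_markers < n_chromosomes is invalid")
  if (h2_target < 0 || h2_target > 1)
    stop_ogb("simulation_config: h2_target must lie in [0, 1]")
  if (any(cfg$selection_intensity <= 0 | cfg$selection_intensity > 1))
    stop_ogb("simulation_config: selection_intensity must lie in (0, 1]")
  if (offspring_range[1] < 1 || offspring_range[2] < offspring_range[1])
    stop_ogb("simulation_config: offspring_range invalid (families need >= 1 offspring)")
  if (offspring_mean < offspring_range[1] || offspring_mean > offspring_range[2])
    stop_ogb("simulation_config: offspring_mean outside offspring_range")
  if (n_qtl > n_markers) stop_ogb("simulation_config: n_qtl > n_markers")
  if (selfing_rate < 0 || selfing_rate > 1 || missing_rate < 0 || missing_rate >= 1)
    stop_ogb("simulation_config: rates out of range")
  if (2 * design_var_frac >= 1)
    stop_ogb("simulation_config: design_var_frac too large")
  structure(cfg, class = "simulation_config")
}

# Marker map shared by all groups: markers split near-evenly across
# chromosomes, positions sorted uniform draws.
make_map <- function(config) {
  with_substream(config$seed, "map", {
    cuts <- round(seq(0, config$n_markers, length.out = config$n_chromosomes + 1))
    counts <- diff(cuts)
    chrom <- rep(seq_len(config$n_chromosomes), counts)
    pos <- unlist(lapply(counts, function(m)
      sort(sample.int(config$chrom_length_bp, m))))
    data.frame(marker = sprintf("M%05d", seq_len(config$n_markers)),
               chrom = chrom, pos = pos)
  })
}

# Latent AR(1) haplotypes: allele = indicator(latent < qnorm(p_m)); the
# latent autocorrelation between adjacent markers at distance d is
# 2^(-d / (2 * ld_decay_bp)) so the squared haplotype correlation (hence
# expected r2) halves at ld_decay_bp. `signs` carries a population-specific
# +/-1 per marker interval: it randomises the sign of each adjacent-marker
# association (leaving r2 untouched), so LD phase is independent between
# separately simulated populations, as between long-diverged orchards.
draw_haplotypes <- function(n_hap, map, freqs, ld_decay_bp, signs = NULL) {
  M <- nrow(map)
  Z <- matrix(0, n_hap, M)
  d <- c(0, diff(map$pos))
  newchrom <- c(TRUE, diff(map$chrom) != 0)
  rho <- 2^(-d / (2 * ld_decay_bp))
  rho[newchrom] <- 0
  if (!is.null(signs)) rho <- rho * signs
  z <- stats::rnorm(n_hap)
  for (m in seq_len(M)) {
    z <- rho[m] * z + sqrt(1 - rho[m]^2) * stats::rnorm(n_hap)
    Z[, m] <- z
  }
  (Z < matrix(stats::qnorm(freqs), n_hap, M, byrow = TRUE)) * 1L
}

#' Simulate founder haplotype pools
#'
#' Builds the shared marker map, draws ancestral allele frequencies, diverges
#' them per orchard by a Balding-Nichols beta draw with drift parameter
#' `divergence`, and generates founder haplotypes with distance-dependent LD
#' from a latent autoregressive process whose squared correlation halves at
#' the orchard's `ld_decay_bp`. LD phase (the sign pattern of inter-marker
#' correlations) is independent between orchards because the latent processes
#' are independent.
#'
#' @param config a [simulation_config()].
#' @return list with `map`, per-group `freqs` and `haplotypes`
#'   (2 x n_founders rows per group; groups `W`, `T` and optionally `ATSC`).
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  map <- make_map(config)
  p0 <- with_substream(config$seed, "freq",
                       stats::runif(config$n_markers, 0.1, 0.9))
  Fd <- config$divergence
  groups <- c("W", "T", if (config$n_atsc_families > 0) "ATSC")
  freqs <- list(); haps <- list()
  for (g in groups) {
    pg <- if (g == "ATSC") p0 else
      with_substream(config$seed, paste0("freq_", g),
                     stats::rbeta(config$n_markers,
                                  p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd))
    pg <- pmin(pmax(pg, 0.02), 0.98)
    nf <- if (g == "ATSC") config$n_founders_atsc else config$n_founders[g]
    ld <- if (g == "ATSC") mean(config$ld_decay_bp) else config$ld_decay_bp[g]
    signs <- with_substream(config$seed, paste0("phase_", g),
                            sample(c(-1, 1), config$n_markers, replace = TRUE))
    hp <- with_substream(config$seed, paste0("hap_", g),
                         draw_haplotypes(2 * nf, map, pg, ld, signs))
    rownames(hp) <- paste0(rep(sprintf("F_%s%03d", g, seq_len(nf)), each = 2),
                           c(".1", ".2"))
    freqs[[g]] <- pg
    haps[[g]] <- hp
  }
  list(map = map, freqs = freqs, haplotypes = haps)
}

# Batch meiosis: one gamete per row of parent_idx. Crossovers follow a
# Haldane-type switch process along the map; the first marker of each
# chromosome restarts on a random parental haplotype.
meiosis_batch <- function(hap, parent_idx, map, morgans_per_chrom, chrom_length_bp) {
  G <- length(parent_idx); M <- nrow(map)
  d <- c(0, diff(map$pos))
  newchrom <- c(TRUE, diff(map$chrom) != 0)
  r <- 0.5 * (1 - exp(-2 * d * morgans_per_chrom / chrom_length_bp))
  r[newchrom] <- 0.5
  S <- matrix(stats::rbinom(G * M, 1, rep(r, each = G)), G, M)
  state <- t(apply(S, 1, cumsum)) %% 2
  h1 <- hap[2 * parent_idx - 1, , drop = FALSE]
  h2 <- hap[2 * parent_idx, , drop = FALSE]
  h1 * (state == 0) + h2 * state
}

# Truncated shifted-Poisson family sizes on [lo, hi] with target mean.
draw_family_sizes <- function(n, range, mean_target) {
  lo <- range[1]; hi <- range[2]
  if (lo == hi) return(rep(lo, n))
  lam <- mean_target - lo
  out <- lo + stats::rpois(n, lam)
  while (any(bad <- out > hi)) out[bad] <- lo + stats::rpois(sum(bad), lam)
  out
}

#' Simulate a two-orchard open-pollinated trial population
#'
#' For each orchard, a fraction `selection_intensity` of the founder pool is
#' retained as realized parents; each family shares a known mother drawn from
#' the retained pool, and every offspring's pollen parent is drawn from the
#' same pool (selfing with probability `selfing_rate`). The documented
#' pedigree records sires as unknown (`"0"`), mirroring open pollination; the
#' realized parents are kept in a separate true pedigree for diagnostics.
#' Offspring genotypes arise by meiosis from the founder haplotypes, then a
#' fraction `missing_rate` of dosage entries is masked completely at random
#' and per-marker platform quality scores are drawn uniform(0, 1) so that
#' the filtering thresholds bite. Phenotypes follow the replicated trial
#' model via [simulate_phenotypes()].
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_population`: documented `pedigree`,
#'   `true_pedigree`, `genotypes` (with missing entries), `complete_dosages`,
#'   `phenotypes`, `tbv` (named true breeding values),
#'   `true_variance_components`, `orchard` labels, `qtl`, `qtl_effects`,
#'   `map`, `founders` (ids of realized pollen-pool members per orchard) and
#'   the `config`.
#' @export
simulate_orchard_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fh <- simulate_founder_haplotypes(config)
  groups <- names(fh$haplotypes)
  ped_id <- ped_sire <- ped_dam <- character(0)
  true_sire <- character(0)
  dos_list <- list()
  orchard <- character(0)
  for (g in groups) {
    hap <- fh$haplotypes[[g]]
    nf <- nrow(hap) / 2
    founder_ids <- sprintf("F_%s%03d", g, seq_len(nf))
    si <- if (g == "ATSC") 1 else config$selection_intensity[g]
    n_ret <- max(1L, round(si * nf))
    retained <- with_substream(config$seed, paste0("select_", g),
                               sort(sample.int(nf, n_ret)))
    nfam <- if (g == "ATSC") config$n_atsc_families else config$n_families[g]
    if (nfam > n_ret)
      stop_ogb("simulate_orchard_population: orchard ", g, " retains ", n_ret,
               " founders but needs ", nfam, " mothers")
    mothers <- with_substream(config$seed, paste0("mothers_", g),
                              sample(retained, nfam))
    fam_sizes <- if (g == "ATSC") rep(config$atsc_family_size, nfam) else
      with_substream(config$seed, paste0("famsize_", g),
                     draw_family_sizes(nfam, config$offspring_range,
                                       config$offspring_mean))
    mom_of <- rep(mothers, fam_sizes)
    n_off <- length(mom_of)
    dad_of <- with_substream(config$seed, paste0("fathers_", g), {
      dads <- sample(retained, n_off, replace = TRUE)
      self <- stats::runif(n_off) < config$selfing_rate
      dads[self] <- mom_of[self]
      dads
    })
    gam_m <- with_substream(config$seed, paste0("meiosis_m_", g),
                            meiosis_batch(hap, mom_of, fh$map,
                                          config$morgans_per_chrom,
                                          config$chrom_length_bp))
    gam_f <- with_substream(config$seed, paste0("meiosis_f_", g),
                            meiosis_batch(hap, dad_of, fh$map,
                                          config$morgans_per_chrom,
                                          config$chrom_length_bp))
    dos <- gam_m + gam_f
    fam_idx <- rep(seq_len(nfam), fam_sizes)
    within <- sequence(fam_sizes)
    off_ids <- sprintf("%s%03d_%02d", g, fam_idx, within)
    rownames(dos) <- off_ids
    colnames(dos) <- fh$map$marker
    dos_list[[g]] <- dos
    ped_id <- c(ped_id, founder_ids[mothers], off_ids)
    ped_sire <- c(ped_sire, rep("0", nfam), rep("0", n_off))
    ped_dam <- c(ped_dam, rep("0", nfam), founder_ids[mom_of])
    true_sire <- c(true_sire, rep("0", nfam), founder_ids[dad_of])
    orchard <- c(orchard, stats::setNames(rep(g, n_off), off_ids))
  }
  dosages <- do.call(rbind, dos_list)
  documented <- pedigree(ped_id, ped_sire, ped_dam)
  # true pedigree: realized sires known (sires of founder records stay unknown)
  true_ped <- pedigree(ped_id, true_sire, ped_dam)
  qtl_idx <- with_substream(config$seed, "qtl",
                            sort(sample.int(config$n_markers, config$n_qtl)))
  eff <- with_substream(config$seed, "qtl_effects", stats::rnorm(config$n_qtl))
  sigma2_a <- config$h2_target
  sigma2_e <- 1 - config$h2_target
  if (config$h2_target == 0) eff[] <- 0
  tbv_raw <- drop(dosages[, qtl_idx, drop = FALSE] %*% eff)
  if (config$h2_target > 0) {
    v <- stats::var(tbv_raw)
    if (v <= 0) stop_ogb("simulate_orchard_population: degenerate QTL genotypes")
    eff <- eff * sqrt(sigma2_a / v)
    tbv <- tbv_raw * sqrt(sigma2_a / v)
  } else tbv <- tbv_raw * 0
  tbv <- tbv - mean(tbv)
  names(tbv) <- rownames(dosages)
  sigma_p <- (sigma2_a + sigma2_e) / (1 - 2 * config$design_var_frac)
  true_vc <- list(sigma2_a = sigma2_a,
                  sigma2_r = config$design_var_frac * sigma_p,
                  sigma2_rs = config$design_var_frac * sigma_p,
                  sigma2_e = sigma2_e)
  qual <- with_substream(config$seed, "quality",
                         cbind(qa = stats::runif(config$n_markers),
                               qb = stats::runif(config$n_markers)))
  meta <- data.frame(marker = fh$map$marker, chrom = fh$map$chrom,
                     pos = fh$map$pos, qa = qual[, "qa"], qb = qual[, "qb"])
  panel <- if (config$qtl_in_panel) seq_len(config$n_markers) else
    setdiff(seq_len(config$n_markers), qtl_idx)
  observed <- dosages[, panel, drop = FALSE]
  meta <- meta[panel, , drop = FALSE]
  rownames(meta) <- NULL
  if (config$missing_rate > 0) {
    mask <- with_substream(config$seed, "missing",
                           matrix(stats::runif(length(observed)) < config$missing_rate,
                                  nrow(observed)))
    observed[mask] <- NA
  }
  pop <- structure(list(pedigree = documented, true_pedigree = true_ped,
                        genotypes = genotype_matrix(observed, meta),
                        complete_dosages = dosages,
                        phenotypes = NULL, tbv = tbv,
                        true_variance_components = true_vc,
                        orchard = orchard, qtl = fh$map$marker[qtl_idx],
                        qtl_effects = eff, map = fh$map,
                        founders = lapply(stats::setNames(groups, groups), function(g) {
                          nf <- nrow(fh$haplotypes[[g]]) / 2
                          si <- if (g == "ATSC") 1 else config$selection_intensity[g]
                          sprintf("F_%s%03d", g,
                                  with_substream(config$seed, paste0("select_", g),
                                                 sort(sample.int(nf, max(1L, round(si * nf))))))
                        }),
                        config = config),
                   class = "synthetic_population")
  pop$phenotypes <- simulate_phenotypes(pop, config)
  pop
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population: %d genotyped individuals (%s), %d markers, h2 target %.2f>\n",
              nrow(x$complete_dosages),
              paste(sprintf("%s=%d", names(table(x$orchard)), table(x$orchard)),
                    collapse = ", "),
              ncol(x$complete_dosages), x$config$h2_target))
  invisible(x)
}

#' Simulate trial phenotypes
#'
#' `y = mu + seed-source effect + replicate + set(replicate) + TBV + e`,
#' with replicate and set effects drawn at `design_var_frac` of phenotypic
#' variance each, residuals at `1 - h2_target`, and true breeding values from
#' the population's QTL (scaled so `var(TBV) = sigma2_a = h2_target`, hence
#' realized narrow-sense heritability `var(TBV)/(var(TBV)+sigma2_e)` equals
#' the target up to residual sampling). Individuals are assigned to
#' replicates and sets uniformly at random.
#'
#' @param pop a `synthetic_population`.
#' @param config its [simulation_config()] (defaults to `pop$config`).
#' @return a [trial_data()] with one record per individual.
#' @export
simulate_phenotypes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "synthetic_population"))
  ids <- names(pop$tbv)
  n <- length(ids)
  vc <- pop$true_variance_components
  rep_f <- with_substream(config$seed, "design_rep",
                          sample(config$n_replicates, n, replace = TRUE))
  set_f <- with_substream(config$seed, "design_set",
                          sample(config$n_sets_per_replicate, n, replace = TRUE))
  rep_eff <- with_substream(config$seed, "rep_effects",
                            stats::rnorm(config$n_replicates, 0, sqrt(vc$sigma2_r)))
  set_eff <- with_substream(config$seed, "set_effects",
                            matrix(stats::rnorm(config$n_replicates *
                                                  config$n_sets_per_replicate,
                                                0, sqrt(vc$sigma2_rs)),
                                   config$n_replicates))
  resid <- with_substream(config$seed, "resid",
                          stats::rnorm(n, 0, sqrt(vc$sigma2_e)))
  src_eff <- c(W = 0, T = 0.3, ATSC = -0.3)
  y <- 10 + src_eff[pop$orchard[ids]] + rep_eff[rep_f] +
    set_eff[cbind(rep_f, set_f)] + pop$tbv[ids] + resid
  trial_data(data.frame(id = ids, trait = config$trait_name, value = unname(y),
                        seed_source = pop$orchard[ids],
                        replicate = paste0("rep", rep_f),
                        set = paste0("set", set_f),
                        orchard = unname(pop$orchard[ids])))
}
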