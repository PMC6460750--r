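# Umbrella pipeline: simulate/load -> filter -> impute -> A/G -> REML fits
# -> accuracy -> cross-validation -> genetic gain, with a provenance
# manifest. Re-running an identical config reproduces all outputs
# bit-identically (all randomness flows from the master seed; no
# timestamps enter any output).

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain hierarchical list (or a JSON file): either
#' a `simulation` block (arguments for [simulation_config()]) or an `inputs`
#' block with paths (`pedigree`, `genotypes`, `marker_meta`, `phenotypes`),
#' plus optional `thresholds` ([filter_thresholds()] arguments), `trait`,
#' `cv` (`scenarios`, a list of `c(training, validation)` pairs; `n_folds`;
#' `n_replications`), `selection` (`proportion`, `direction`), `ld`
#' (`max_distance_bp`, `bin_width_bp`), `out_dir` and master `seed`.
#'
#' @param config list or path to a JSON file.
#' @return the validated config list (with defaults filled in).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop_ogb("run_config: out_dir is required")
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$simulation) && is.null(config$inputs))
    stop_ogb("run_config: need a 'simulation' block or an 'inputs' block")
  if (is.null(config$simulation)) {
    need <- c("pedigree", "genotypes", "marker_meta", "phenotypes")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop_ogb("run_config: inputs missing: ", paste(miss, collapse = ", "))
    absent <- !vapply(config$inputs[need], file.exists, logical(1))
    if (any(absent))
      stop_ogb("run_config: input path(s) not found: ",
               paste(unlist(config$inputs[need][absent]), collapse = ", "))
  }
  user_scen <- config$cv$scenarios
  config$cv <- utils::modifyList(
    list(scenarios = list(c("W", "W"), c("T", "T"), c("W", "T"), c("T", "W"),
                          c("WT", "WT")),
         n_folds = 10L, n_replications = 30L),
    config$cv %||% list())
  if (!is.null(user_scen)) config$cv$scenarios <- user_scen
  config$selection <- utils::modifyList(
    list(proportion = 0.2, direction = "higher_better"),
    config$selection %||% list())
  config$ld <- utils::modifyList(list(max_distance_bp = 2e4, bin_width_bp = 500),
                                 config$ld %||% list())
  config
}

#' Run the full evaluation pipeline
#'
#' Executes the stages in order, writing every intermediate artifact under
#' `out_dir` together with a JSON manifest carrying the config hash, master
#' seed and produced files. Any stage failure halts with the stage name;
#' artifacts of completed stages persist.
#'
#' @param config see [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # hash the analysis-defining part of the config (output location excluded)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE)
  hash <- fnv1a(as.character(cfg_json))
  hc <- sprintf("config_hash=%s seed=%d", hash, config$seed)
  manifest <- list(config_hash = hash, seed = config$seed,
                   package = as.character(utils::packageVersion("orchardgblup")),
                   config = config, outputs = character(0))
  note <- function(p) manifest$outputs <<- c(manifest$outputs, p)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop_ogb("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  dat <- stage("load", {
    if (!is.null(config$simulation)) {
      sc <- do.call(simulation_config,
                    utils::modifyList(config$simulation,
                                      list(seed = config$seed)))
      pop <- simulate_orchard_population(sc)
      note(write_population(pop, out))
      list(ped = pop$pedigree, g = pop$genotypes, pheno = pop$phenotypes)
    } else {
      list(ped = read_pedigree(config$inputs$pedigree),
           g = read_genotypes(config$inputs$genotypes, config$inputs$marker_meta),
           pheno = read_phenotypes(config$inputs$phenotypes))
    }
  })
  pheno_ids <- unique(dat$pheno$id)
  recon <- setdiff(pheno_ids, rownames(dat$g$dosages))
  if (length(recon)) {
    message("reconciliation: ", length(recon),
            " phenotyped individual(s) lack genotypes; listed in manifest")
    manifest$unmatched_phenotype_ids <- recon
  }

  filt <- stage("filter", {
    th <- do.call(filter_thresholds, config$thresholds %||% list())
    res <- filter_markers(dat$g, th)
    note(write_filter_report(res$report, file.path(out, "filter_report.json")))
    message(sprintf("  markers: %d -> %d (%s)", res$report$n_input,
                    res$report$n_pass,
                    paste(sprintf("%s=%d", names(res$report$removed),
                                  unlist(res$report$removed)), collapse = ", ")))
    res$genotypes
  })

  gimp <- stage("impute", impute_em(filt))

  A <- stage("amat", {
    A <- build_A(dat$ped)
    note(write_kernel(A, file.path(out, "A.tsv"), hc))
    A
  })
  G <- stage("grm", {
    G <- compute_G(gimp)
    note(write_kernel(G, file.path(out, "G.tsv"), hc))
    G
  })

  stage("lddecay", {
    curve <- ld_decay(gimp, config$ld$max_distance_bp, config$ld$bin_width_bp)
    write_with_header(as.data.frame(curve), file.path(out, "ld_decay.tsv"),
                      "\t", hc)
    note(file.path(out, "ld_decay.tsv"))
  })
  stage("pca", {
    sp <- spectral_decomposition(G, 10)
    write_with_header(data.frame(id = rownames(sp$scores), sp$scores),
                      file.path(out, "pca_scores.tsv"), "\t", hc)
    note(file.path(out, "pca_scores.tsv"))
  })

  traits <- unique(dat$pheno$trait)
  if (!is.null(config$trait)) traits <- intersect(traits, config$trait)
  fits <- stage("fit", {
    fits <- list()
    for (tr in traits) {
      sub <- dat$pheno[dat$pheno$trait == tr, , drop = FALSE]
      class(sub) <- c("trial_data", "data.frame")
      for (kern in list(A, G)) {
        kd <- attr(kern, "kind")
        vc <- reml_fit(sub, kern)
        message(sprintf("  %s/%s: logRL %.3f, %d iterations, %s", tr, kd,
                        vc$log_likelihood, vc$iterations,
                        if (vc$converged) "converged" else "NOT converged"))
        bvs <- solve_blup(sub, kern, vc)
        mdl <- if (kd == "A") "blup" else "gblup"
        jsonlite::write_json(
          list(trait = tr, kernel = kd,
               components = vc[c("sigma2_a", "sigma2_r", "sigma2_rs", "sigma2_e")],
               se = as.list(vc$se), log_likelihood = vc$log_likelihood,
               converged = vc$converged, h2 = heritability(vc)),
          file.path(out, sprintf("varcomp_%s_%s.json", mdl, tr)),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
        write_with_header(as.data.frame(bvs),
                          file.path(out, sprintf("bvs_%s_%s.tsv", mdl, tr)),
                          "\t", hc)
        note(file.path(out, sprintf("bvs_%s_%s.tsv", mdl, tr)))
        # gains are compared on the genotyped/phenotyped subset, so the
        # pedigree-model extra ancestors do not enter selection
        keep <- bvs$id %in% sub$id
        bsub <- bvs[keep, , drop = FALSE]
        class(bsub) <- class(bvs)
        fits[[tr]][[mdl]] <- list(vc = vc, bvs = bsub)
      }
    }
    fits
  })

  cvres <- stage("cv", {
    rows <- list()
    for (tr in traits) {
      sub <- dat$pheno[dat$pheno$trait == tr, , drop = FALSE]
      class(sub) <- c("trial_data", "data.frame")
      ref <- stats::setNames(fits[[tr]]$blup$bvs$ebv, fits[[tr]]$blup$bvs$id)
      for (sc in config$cv$scenarios) {
        scen <- cv_scenario(sc[1], sc[2], config$cv$n_folds,
                            config$cv$n_replications, config$seed)
        for (mdl in c("blup", "gblup")) {
          K <- if (mdl == "blup") A else G
          res <- cross_validate(sub, K, scen, ref, vc = fits[[tr]][[mdl]]$vc)
          message(sprintf("  %s %s %s: mean r_p %.3f", tr, scen$label, mdl,
                          res$mean_rp))
          rows[[length(rows) + 1]] <-
            data.frame(scenario = scen$label, trait = tr, model = mdl,
                       mean_rp = res$mean_rp, sd_rp = res$sd_rp,
                       zero_information = res$zero_information)
        }
      }
    }
    tab <- do.call(rbind, rows)
    write_with_header(tab, file.path(out, "cv_results.tsv"), "\t", hc)
    note(file.path(out, "cv_results.tsv"))
    tab
  })

  gains <- stage("gain", {
    tab <- gain_comparison_report(lapply(fits, `[[`, "blup"),
                                  lapply(fits, `[[`, "gblup"),
                                  config$selection$proportion,
                                  config$selection$direction)
    write_with_header(tab, file.path(out, "gain_report.tsv"), "\t", hc)
    note(file.path(out, "gain_report.tsv"))
    tab
  })

  manifest$outputs <- unname(unlist(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(fits = fits, cv = cvres, gains = gains)))
}

# ---------------------------------------------------------------------------
# Command-line interface: orchard-gblup <subcommand> [--flag value ...]

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_ogb("cli: unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `impute`, `amat`, `grm`, `ne`, `fit`,
#' `cv`, `gain`, `lddecay`, `pca`, `run`; plus `--version` and `--help`.
#' Used by the `inst/cli/orchard-gblup` Rscript wrapper.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @export
ogb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: orchard-gblup <subcommand> [--flag value ...]",
    "  simulate --out <dir> [--seed N] [--config sim.json]",
    "  run      --config run.json",
    "  amat     --pedigree ped.csv --out A.tsv",
    "  grm      --genotypes g.tsv --meta meta.tsv --out G.tsv",
    "  ne       --matrix K.tsv [--kind A|G] [--ids ids.txt]",
    "  filter   --genotypes g.tsv --meta meta.tsv --out dir/",
    "  impute   --genotypes g.tsv --out imputed.tsv",
    "  fit      --phenotypes p.csv --kernel K.tsv --kind A|G [--trait t] --out dir/",
    "  cv       --phenotypes p.csv --kernel K.tsv --kind A|G --reference bvs.tsv",
    "           --scenario W-T [--folds 10] [--reps 30] [--seed N]",
    "  gain     --bvs bvs.tsv [--proportion 0.2] [--direction higher_better|lower_better]",
    "  lddecay  --genotypes g.tsv --meta meta.tsv --out curve.tsv",
    "  pca      --matrix K.tsv [--kind A|G] --out scores.tsv",
    sep = "\n")
  if (!length(args) || args[1] %in% c("--help", "help")) {
    cat(usage, "\n"); return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat("orchard-gblup ", as.character(utils::packageVersion("orchardgblup")), "\n",
        sep = ""); return(invisible(0L))
  }
  cmd <- args[1]
  fl <- parse_flags(args[-1])
  seed <- as.integer(fl$seed %||% 1L)
  switch(cmd,
    simulate = {
      sim_args <- if (!is.null(fl$config))
        jsonlite::read_json(fl$config, simplifyVector = TRUE) else list()
      cfg <- do.call(simulation_config,
                     utils::modifyList(sim_args, list(seed = seed)))
      pop <- simulate_orchard_population(cfg)
      write_population(pop, fl$out %||% ".")
    },
    run = invisible(run_pipeline(fl$config)),
    amat = {
      A <- build_A(read_pedigree(fl$pedigree))
      write_kernel(A, fl$out %||% "A.tsv")
    },
    grm = {
      g <- read_genotypes(fl$genotypes, fl$meta)
      write_kernel(compute_G(impute_em(g)), fl$out %||% "G.tsv")
    },
    ne = {
      K <- read_kernel(fl$matrix, fl$kind %||% "A")
      subset <- if (!is.null(fl$ids)) readLines(fl$ids) else NULL
      print(status_number(K, subset))
    },
    filter = {
      g <- read_genotypes(fl$genotypes, fl$meta)
      res <- filter_markers(g)
      dir.create(fl$out %||% ".", showWarnings = FALSE, recursive = TRUE)
      write_genotypes(res$genotypes, file.path(fl$out %||% ".", "filtered.tsv"))
      write_filter_report(res$report, file.path(fl$out %||% ".", "filter_report.json"))
      print(res$report)
    },
    impute = {
      g <- read_genotypes(fl$genotypes, fl$meta)
      write_genotypes(impute_em(g), fl$out %||% "imputed.tsv")
    },
    fit = {
      data <- read_phenotypes(fl$phenotypes)
      K <- read_kernel(fl$kernel, fl$kind %||% "A")
      vc <- reml_fit(data, K, trait = fl$trait)
      print(vc)
      bvs <- solve_blup(data, K, vc, trait = fl$trait)
      dir.create(fl$out %||% ".", showWarnings = FALSE, recursive = TRUE)
      write_with_header(as.data.frame(bvs),
                        file.path(fl$out %||% ".", "bvs.tsv"), "\t")
    },
    cv = {
      data <- read_phenotypes(fl$phenotypes)
      K <- read_kernel(fl$kernel, fl$kind %||% "G")
      ref_df <- utils::read.delim(fl$reference, comment.char = "#",
                                  colClasses = c(id = "character"))
      ref <- stats::setNames(ref_df$ebv, ref_df$id)
      parts <- strsplit(fl$scenario %||% "WT-WT", "-", fixed = TRUE)[[1]]
      scen <- cv_scenario(parts[1], parts[2], as.integer(fl$folds %||% 10L),
                          as.integer(fl$reps %||% 30L), seed)
      print(cross_validate(data, K, scen, ref))
    },
    gain = {
      df <- utils::read.delim(fl$bvs, comment.char = "#",
                              colClasses = c(id = "character"))
      print(genetic_gain(stats::setNames(df$ebv, df$id),
                         as.numeric(fl$proportion %||% 0.2),
                         fl$direction %||% "higher_better"))
    },
    lddecay = {
      g <- read_genotypes(fl$genotypes, fl$meta)
      curve <- ld_decay(g)
      write_with_header(as.data.frame(curve), fl$out %||% "ld_decay.tsv", "\t")
    },
    pca = {
      K <- read_kernel(fl$matrix, fl$kind %||% "G")
      sp <- spectral_decomposition(K, 10)
      write_with_header(data.frame(id = rownames(sp$scores), sp$scores),
                        fl$out %||% "pca_scores.tsv", "\t")
    },
    stop_ogb("cli: unknown subcommand '", cmd, "'\n", usage)
  )
  invisible(0L)
}
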