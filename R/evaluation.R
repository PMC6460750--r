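# Cross-validation scenarios, predictive accuracy and genetic gain.

#' Random fold assignment at the individual level
#'
#' Individuals are assigned to folds uniformly at random with fold sizes
#' differing by at most 1. The assignment is a pure function of
#' `(ids, n_folds, replication_seed)`.
#'
#' @param ids individual ids.
#' @param n_folds number of folds (>= 2, at most `length(ids)`).
#' @param replication_seed integer seed for this replication.
#' @return named integer vector: fold index per id.
#' @export
make_folds <- function(ids, n_folds, replication_seed) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n_folds < 2) stop_ogb("make_folds: n_folds must be >= 2")
  if (n_folds > n) stop_ogb("make_folds: more folds than individuals")
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- withr::with_seed(as.integer(replication_seed %% 2^31), sample(ids))
  stats::setNames(rep(seq_len(n_folds), sizes)[match(ids, perm)], ids)
}

#' Predictive accuracy of genomic predictions
#'
#' Pearson correlation between the reference breeding values (full-data
#' pedigree-model EBVs) and the cross-validated marker-only predictions of
#' the same individuals.
#'
#' @param ebv_reference,gebv_predicted aligned numeric vectors (matched by
#'   names when both are named), length >= 3.
#' @return correlation in [-1, 1], or `NA` with attribute `undefined = TRUE`
#'   when either vector has zero variance (never silently 0).
#' @export
predictive_accuracy <- function(ebv_reference, gebv_predicted) {
  if (!is.null(names(ebv_reference)) && !is.null(names(gebv_predicted))) {
    if (!setequal(names(ebv_reference), names(gebv_predicted)))
      stop_ogb("predictive_accuracy: vectors cover different individuals")
    gebv_predicted <- gebv_predicted[names(ebv_reference)]
  }
  if (length(ebv_reference) != length(gebv_predicted))
    stop_ogb("predictive_accuracy: length mismatch")
  if (length(ebv_reference) < 3)
    stop_ogb("predictive_accuracy: need at least 3 individuals")
  if (stats::sd(ebv_reference) == 0 || stats::sd(gebv_predicted) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(ebv_reference, gebv_predicted)
}

#' Cross-validation scenario
#'
#' Training and validation populations are named by orchard labels; `"WT"`
#' is shorthand for both orchards. When training equals validation
#' (within / across), folds partition that population and each fold is
#' predicted from the remaining folds. When they differ (between-orchard),
#' folds partition the validation orchard and the full training orchard is
#' used for every fold.
#'
#' @param training,validation `"W"`, `"T"` or `"WT"`.
#' @param n_folds,n_replications the replicated k-fold design (defaults
#'   10-fold, 30 replications).
#' @param seed master seed; replication r uses `seed + r` so any single
#'   replication is re-runnable in isolation.
#' @export
cv_scenario <- function(training, validation, n_folds = 10L,
                        n_replications = 30L, seed = 1L) {
  expand <- function(x) if (identical(x, "WT")) c("W", "T") else x
  tr <- expand(training); va <- expand(validation)
  stopifnot(all(tr %in% c("W", "T", "ATSC")), all(va %in% c("W", "T", "ATSC")))
  structure(list(training = tr, validation = va,
                 label = paste0(paste(training, collapse = ""), "->",
                                paste(validation, collapse = "")),
                 n_folds = as.integer(n_folds),
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed)),
            class = "cv_scenario")
}

#' Replicated k-fold cross-validation of breeding-value prediction
#'
#' For each replication and fold, the model is fit on training records with
#' validation-fold phenotypes withheld, the withheld individuals' breeding
#' values are predicted through the kernel (for GBLUP the kernel must be
#' built over training and validation individuals jointly so marker
#' relationships connect them), and after all folds each validation
#' individual carries exactly one cross-validated prediction. The
#' per-replication predictive accuracy is the correlation of those
#' predictions with the reference EBVs; mean and sd are taken over
#' replications. Variance components are estimated once on the training
#' population and plugged into the per-fold mixed-model solves.
#'
#' @param data a [trial_data()] for one trait with an `orchard` column.
#' @param K the kernel of the model under evaluation (A for BLUP, G for
#'   GBLUP), covering all training and validation individuals.
#' @param scenario a [cv_scenario()].
#' @param reference_ebv named vector of reference breeding values (full-data
#'   pedigree-model EBVs) covering the validation individuals.
#' @param vc optional variance components; estimated on the training
#'   population by [reml_fit()] when `NULL`.
#' @return object of class `cv_result`: per-replication `r_p`, `mean_rp`,
#'   `sd_rp`, number of solves performed, and a `zero_information` flag set
#'   when the kernel carries no relationship between validation and training
#'   individuals (between-orchard pedigree case).
#' @export
cross_validate <- function(data, K, scenario, reference_ebv, vc = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(K, "relationship_matrix"),
            inherits(scenario, "cv_scenario"))
  if (length(unique(data$trait)) != 1)
    stop_ogb("cross_validate: one trait at a time")
  data$orchard <- as.character(data$orchard)
  train_ids <- unique(data$id[data$orchard %in% scenario$training])
  val_ids <- unique(data$id[data$orchard %in% scenario$validation])
  if (!length(train_ids) || !length(val_ids))
    stop_ogb("cross_validate: empty training or validation population")
  within_mode <- setequal(train_ids, val_ids)
  if (!within_mode && length(intersect(train_ids, val_ids)))
    stop_ogb("cross_validate: training and validation must coincide or be disjoint")
  need <- union(train_ids, val_ids)
  absent <- setdiff(need, rownames(K))
  if (length(absent))
    stop_ogb("cross_validate: kernel lacks individual(s): ",
             paste(utils::head(absent, 5), collapse = ", "),
             if (attr(K, "kind") == "G")
               " (build G jointly over training and validation)" else "")
  missing_ref <- setdiff(val_ids, names(reference_ebv))
  if (length(missing_ref))
    stop_ogb("cross_validate: reference EBVs missing for: ",
             paste(utils::head(missing_ref, 5), collapse = ", "))
  tr_data <- data[data$id %in% train_ids, , drop = FALSE]
  class(tr_data) <- c("trial_data", "data.frame")
  if (is.null(vc)) {
    K_tr <- relationship_matrix(unclass(K)[train_ids, train_ids, drop = FALSE],
                                attr(K, "kind"))
    vc <- reml_fit(tr_data, K_tr)
  }
  zero_info <- FALSE
  if (!within_mode) {
    cross_block <- unclass(K)[val_ids, train_ids, drop = FALSE]
    zero_info <- max(abs(cross_block)) < 1e-12
  }
  n_solves <- 0L
  r_p <- numeric(scenario$n_replications)
  pool <- if (within_mode) val_ids else val_ids
  for (r in seq_len(scenario$n_replications)) {
    folds <- make_folds(pool, scenario$n_folds, scenario$seed + r)
    gebv <- stats::setNames(rep(NA_real_, length(val_ids)), val_ids)
    for (f in seq_len(scenario$n_folds)) {
      held <- names(folds)[folds == f]
      if (within_mode) {
        rec <- data[data$id %in% setdiff(train_ids, held), , drop = FALSE]
        ids_k <- train_ids
      } else {
        rec <- tr_data
        ids_k <- c(train_ids, held)
      }
      class(rec) <- c("trial_data", "data.frame")
      Kf <- relationship_matrix(unclass(K)[ids_k, ids_k, drop = FALSE],
                                attr(K, "kind"))
      bv <- if (vc$sigma2_a > 0)
        solve_blup_fast(rec, Kf, vc) else
          stats::setNames(rep(0, length(ids_k)), ids_k)
      gebv[held] <- bv[held]
      n_solves <- n_solves + 1L
    }
    acc <- tryCatch(predictive_accuracy(reference_ebv[val_ids], gebv),
                    error = function(e) NA_real_)
    r_p[r] <- as.numeric(acc)
  }
  structure(list(scenario = scenario$label, trait = unique(data$trait),
                 kernel = attr(K, "kind"),
                 r_p = r_p, mean_rp = mean(r_p, na.rm = TRUE),
                 sd_rp = stats::sd(r_p, na.rm = TRUE),
                 n_solves = n_solves, vc = vc,
                 zero_information = zero_info),
            class = "cv_result")
}

# MME solve without PEV (cross-validation hot path).
solve_blup_fast <- function(data, K, vc) {
  des <- build_design(data, K)
  Kv <- unclass(K)
  Kinv <- tryCatch(chol2inv(chol(Kv)), error = function(e) {
    chol2inv(chol(Kv + diag(1e-6, nrow(Kv))))
  })
  use_r <- !is.null(des$Fr) && (vc$sigma2_r %||% 0) > 0
  use_s <- !is.null(des$Fs) && (vc$sigma2_rs %||% 0) > 0
  sol <- .mme_solve(des$y, des$X, des$ia,
                    if (use_r) des$Fr else NULL,
                    if (use_s) des$Fs else NULL,
                    Kinv, vc, pev = FALSE)
  stats::setNames(sol$u, rownames(K))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV %s (%s, trait '%s'): mean r_p = %.3f (sd %.3f) over %d replications%s\n",
              x$scenario, x$kernel, x$trait, x$mean_rp, x$sd_rp, length(x$r_p),
              if (x$zero_information) " [zero-information kernel link]" else ""))
  invisible(x)
}

#' Genetic gain from truncation selection
#'
#' Ranks individuals by breeding value in the trait's favourable direction,
#' selects the top `ceiling(proportion * n)` (ties broken by stable id
#' order), and returns the mean breeding value of the selected set, the
#' conventional per-generation gain measure at a 20% selection proportion.
#'
#' @param bvs named numeric vector of breeding values, or a
#'   `breeding_values` data.frame.
#' @param proportion selected fraction in (0, 1].
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return object of class `genetic_gain`: `gain`, `selected` ids,
#'   `proportion`, `direction`.
#' @export
genetic_gain <- function(bvs, proportion = 0.2,
                         direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (inherits(bvs, "breeding_values")) bvs <- stats::setNames(bvs$ebv, bvs$id)
  if (!length(bvs)) stop_ogb("genetic_gain: empty breeding-value set")
  if (proportion <= 0 || proportion > 1)
    stop_ogb("genetic_gain: proportion must lie in (0, 1]")
  ids <- names(bvs) %||% as.character(seq_along(bvs))
  k <- ceiling(proportion * length(bvs))
  ord <- if (direction == "higher_better") order(-bvs, ids) else order(bvs, ids)
  sel <- ord[seq_len(k)]
  structure(list(gain = mean(bvs[sel]), selected = ids[sel],
                 proportion = proportion, direction = direction),
            class = "genetic_gain")
}

#' @export
print.genetic_gain <- function(x, ...) {
  cat(sprintf("genetic gain (top %.0f%%, %s): %.4f over %d selected\n",
              100 * x$proportion, x$direction, x$gain, length(x$selected)))
  invisible(x)
}

#' Side-by-side BLUP vs GBLUP gain report
#'
#' One row per trait with heritability, its standard error, mean theoretical
#' accuracy and the truncation-selection gain under each model, mirroring the
#' customary summary-table layout of genomic-selection studies.
#'
#' @param blup_fits,gblup_fits named lists (one element per trait), each
#'   element a list with `vc` (a `vc_fit`) and `bvs` (a `breeding_values`).
#' @param proportion,direction passed to [genetic_gain()]; `direction` may be
#'   a vector named by trait.
#' @return data.frame, one row per trait.
#' @export
gain_comparison_report <- function(blup_fits, gblup_fits, proportion = 0.2,
                                   direction = "higher_better") {
  traits <- names(blup_fits)
  if (!setequal(traits, names(gblup_fits)))
    stop_ogb("gain_comparison_report: trait sets differ")
  if (length(direction) == 1) direction <- stats::setNames(rep(direction, length(traits)), traits)
  rows <- lapply(traits, function(tr) {
    b <- blup_fits[[tr]]; g <- gblup_fits[[tr]]
    if (!setequal(b$bvs$id, g$bvs$id))
      stop_ogb("gain_comparison_report: individual sets differ for trait '", tr,
               "': e.g. ", paste(utils::head(
                 c(setdiff(b$bvs$id, g$bvs$id), setdiff(g$bvs$id, b$bvs$id)), 3),
                 collapse = ", "))
    conv <- function(fit, val) if (isTRUE(fit$vc$converged) || is.null(fit$vc$converged)) val else NA_real_
    hb <- heritability(b$vc); hg <- heritability(g$vc)
    data.frame(trait = tr,
               h2_blup = conv(b, hb$h2), se_blup = conv(b, hb$se),
               r_blup = conv(b, mean(b$bvs$accuracy, na.rm = TRUE)),
               dG_blup = conv(b, genetic_gain(b$bvs, proportion, direction[tr])$gain),
               h2_gblup = conv(g, hg$h2), se_gblup = conv(g, hg$se),
               r_gblup = conv(g, mean(g$bvs$accuracy, na.rm = TRUE)),
               dG_gblup = conv(g, genetic_gain(g$bvs, proportion, direction[tr])$gain))
  })
  do.call(rbind, rows)
}
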