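# Table dialects: comma-separated record tables (pedigree, phenotypes),
# tab-separated matrices (genotypes, kernels, curves), '.' decimal point.
# Lines starting with '#' are provenance header comments and are skipped on
# read.

write_with_header <- function(df, path, sep, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read / write a pedigree CSV (columns id, sire, dam; "0" = unknown parent)
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @param header_comment optional provenance comment.
#' @export
write_pedigree <- function(ped, path, header_comment = NULL) {
  write_with_header(as.data.frame(ped)[c("id", "sire", "dam")], path, ",",
                    header_comment)
  invisible(path)
}

#' Read / write genotype dosage tables
#'
#' Dense TSV dialect: first column `id`, remaining columns one marker each,
#' entries 0/1/2 or NA. An invalid dosage symbol is a parse error naming the
#' individual and marker. Marker metadata travels in a side TSV
#' (`marker`, `chrom`, `pos`, `qa`, `qb`).
#'
#' @param path genotype table path.
#' @param meta_path optional marker metadata TSV.
#' @export
read_genotypes <- function(path, meta_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- ids
  meta <- if (!is.null(meta_path)) read_marker_meta(meta_path) else NULL
  genotype_matrix(M, meta)
}

#' @rdname read_genotypes
#' @param g a [genotype_matrix()].
#' @param header_comment optional provenance comment.
#' @export
write_genotypes <- function(g, path, header_comment = NULL) {
  df <- data.frame(id = rownames(g$dosages), g$dosages, check.names = FALSE)
  write_with_header(df, path, "\t", header_comment)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_marker_meta <- function(path) {
  utils::read.delim(path, comment.char = "#",
                    colClasses = c(marker = "character"))
}

#' @rdname read_genotypes
#' @param meta marker metadata data.frame.
#' @export
write_marker_meta <- function(meta, path, header_comment = NULL) {
  write_with_header(meta, path, "\t", header_comment)
  invisible(path)
}

#' Read a PLINK-RAW style dosage file
#'
#' Whitespace-separated dialect with columns FID IID PAT MAT SEX PHENOTYPE
#' followed by one dosage column per marker; NA preserves missingness. IID
#' becomes the individual id.
#'
#' @param path file path.
#' @param meta optional marker metadata data.frame.
#' @export
read_plink_raw <- function(path, meta = NULL) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          comment.char = "#")
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(lead %in% names(df)[seq_len(6)]))
    stop_ogb("read_plink_raw: expected leading columns ",
             paste(lead, collapse = " "))
  M <- as.matrix(df[, -(1:6), drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- as.character(df$IID)
  genotype_matrix(M, meta)
}

#' Read / write phenotype tables
#' (CSV: id, trait, value, seed_source, replicate, set, orchard)
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  trial_data(utils::read.csv(path, comment.char = "#",
                             colClasses = c(id = "character")))
}

#' @rdname read_phenotypes
#' @param data a [trial_data()].
#' @param header_comment optional provenance comment.
#' @export
write_phenotypes <- function(data, path, header_comment = NULL) {
  write_with_header(as.data.frame(data), path, ",", header_comment)
  invisible(path)
}

#' Read / write relationship matrices
#'
#' Dense labelled TSV (first column `id`, then one column per individual) or
#' long format (`i`, `j`, `value`, upper triangle incl. diagonal) for sparse
#' exchange.
#'
#' @param path file path.
#' @param kind `"A"` or `"G"`; stored in the header comment on write and
#'   required on read.
#' @export
read_kernel <- function(path, kind = c("A", "G")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  relationship_matrix(M, kind)
}

#' @rdname read_kernel
#' @param K a [relationship_matrix()].
#' @param header_comment optional provenance comment.
#' @export
write_kernel <- function(K, path, header_comment = NULL) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  write_with_header(df, path, "\t",
                    paste(c(paste0("kind=", attr(K, "kind")), header_comment),
                          collapse = " "))
  invisible(path)
}

#' @rdname read_kernel
#' @export
write_kernel_long <- function(K, path, header_comment = NULL) {
  ut <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = rownames(K)[ut[, 1]], j = rownames(K)[ut[, 2]],
                   value = K[ut])
  write_with_header(df, path, "\t", header_comment)
  invisible(path)
}

#' Write a filter report as JSON
#' @param report a `filter_report` from [filter_markers()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(n_input = report$n_input, n_pass = report$n_pass,
                            removed = report$removed,
                            thresholds = report$thresholds),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a synthetic population to standard exchange tables
#'
#' Emits pedigree CSV, genotype TSV, marker-metadata TSV, phenotype CSV and
#' a truth file (true breeding values and generating variance components)
#' for test harnesses.
#'
#' @param pop a `synthetic_population`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hc <- sprintf("seed=%d", pop$config$seed)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             marker_meta = file.path(dir, "marker_meta.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.tsv"),
             truth_vc = file.path(dir, "truth_varcomp.json"))
  write_pedigree(pop$pedigree, paths["pedigree"], hc)
  write_genotypes(pop$genotypes, paths["genotypes"], hc)
  write_marker_meta(pop$genotypes$marker_meta, paths["marker_meta"], hc)
  write_phenotypes(pop$phenotypes, paths["phenotypes"], hc)
  write_with_header(data.frame(id = names(pop$tbv), tbv = unname(pop$tbv),
                               orchard = unname(pop$orchard[names(pop$tbv)])),
                    paths["truth"], "\t", hc)
  jsonlite::write_json(pop$true_variance_components, paths["truth_vc"],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
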