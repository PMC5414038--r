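
#' Beta-value matrix container
#'
#' A sample-by-CpG matrix of methylation beta values (fractions in
#' \code{[0,1]}; \code{NA} allowed). Rows are samples, columns CpGs; the IDs
#' live in the dimnames and must be unique.
#'
#' @param values numeric matrix, samples in rows, CpGs in columns
#' @param sample_ids,cpg_ids optional ID vectors overriding the dimnames
#' @return an object of class `beta_matrix`
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        cpg_ids = colnames(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cg%07d", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(cpg_ids)) stop("duplicate CpG IDs")
  rng <- if (all(is.na(values))) c(0, 1) else range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  dimnames(values) <- list(sample_ids, cpg_ids)
  structure(list(values = values), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("beta_matrix: %d samples x %d CpGs; %.2f%% missing\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Standardized residual matrix container
#'
#' The matrix X that ICA decomposes: per-CpG OLS residuals after covariate
#' adjustment, standardized across samples to mean 0 and sd 1. Construction
#' enforces the standardization invariant.
#'
#' @param values numeric matrix, samples x CpGs, no missing values
#' @param adjusted_for character vector of covariate names used
#' @param n_sv number of surrogate variables included in the adjustment
#' @return an object of class `residual_matrix`
#' @export
residual_matrix <- function(values, adjusted_for = character(), n_sv = 0L) {
  stopifnot(is.matrix(values), !anyNA(values))
  mu <- colMeans(values)
  sdv <- apply(values, 2L, sd)
  if (max(abs(mu)) > 1e-8 || max(abs(sdv - 1)) > 1e-8)
    stop("residual matrix must be standardized per CpG (mean 0, sd 1)")
  structure(list(values = values, adjusted_for = adjusted_for,
                 n_sv = as.integer(n_sv)),
            class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf(
    "residual_matrix: %d samples x %d CpGs; adjusted for: %s; %d SVs\n",
    nrow(x$values), ncol(x$values),
    if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = ", ")
    else "(intercept only)", x$n_sv))
  invisible(x)
}

#' @export
dim.residual_matrix <- function(x) dim(x$values)

## ---- TSV I/O -------------------------------------------------------------
## Matrices are serialized with the sample ID as first column ("sample_id")
## and CpG/SNP/feature IDs as the header, values at 10 significant digits.

#' Read / write a sample-by-feature matrix TSV
#'
#' @param path file path
#' @return `read_matrix_tsv`: a numeric matrix with sample IDs as rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @param m matrix with rownames (sample IDs) and colnames (feature IDs)
#' @param id_col name for the leading ID column
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), signif(m, 10), check.names = FALSE)
  names(df) <- c(id_col, colnames(m))
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' Expects the serialization written by [write_matrix_tsv()]: header row of
#' CpG IDs, first column sample IDs.
#' @param path file path
#' @export
read_beta_tsv <- function(path) beta_matrix(read_matrix_tsv(path))

#' Read a gene-set collection in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' @param path file path
#' @return named list of character vectors of gene IDs
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  out
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors
#' @param descriptions optional character vector of set descriptions
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, genes)
    paste(c(nm, ds, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
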