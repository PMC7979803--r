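## Expression preprocessing: I/O, lineage/gene filters, and the three
## normalization schemes compared when choosing the autoencoder input
## representation (rank / per-sample z-score / per-gene z-score mapped
## to [0,1]).

#' Read a gene-by-sample expression matrix
#'
#' Expects a TSV/CSV with gene identifiers in the first column and one
#' column per sample. Values are assumed to be on a log-like scale
#' (e.g. log2(RPKM + 1)); any monotone scale works once rank
#' normalization is applied, which is what makes the method
#' platform-agnostic (RNA-seq or microarray).
#'
#' @param path File path.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), with attribute
#'   `normalization = "raw"`.
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2L) stopf("expression file '%s' has no sample columns", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stopf("non-numeric expression values in column '%s' of '%s'",
          colnames(df)[-1L][bad], path)
  }
  rownames(m) <- genes
  validate_expression(m)
  attr(m, "normalization") <- "raw"
  m
}

#' Write an expression matrix in the format `read_expression()` reads
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (lineage / cancer-type labels)
#'
#' @param path TSV with columns `sample_id`, `lineage` and optionally
#'   `cancer_type`, `subtype`.
#' @return data.frame with those columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("sample_id", "lineage")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in metadata")
  df
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stopf("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stopf("duplicate sample ids in expression matrix")
  if (anyNA(expr)) stopf("expression matrix contains NA values; missing data are not imputed")
  if (any(!is.finite(expr))) stopf("expression matrix contains non-finite values")
  invisible(expr)
}

#' Keep samples whose lineage has enough members
#'
#' Lineages with fewer than `min_per_lineage` samples are dropped
#' (boundary inclusive: a lineage with exactly `min_per_lineage`
#' members is kept). The gene set and the relative sample order are
#' unchanged.
#'
#' @param expr Genes x samples matrix.
#' @param meta Metadata data.frame with `sample_id` and `lineage`.
#' @param min_per_lineage Minimum lineage size (default 20, the
#'   cell-line panel convention).
#' @return Filtered expression matrix.
#' @export
filter_lineages <- function(expr, meta, min_per_lineage = 20L) {
  validate_expression(expr)
  if (min_per_lineage < 1L) stopf("min_per_lineage must be >= 1")
  lin <- meta$lineage[match(colnames(expr), meta$sample_id)]
  if (anyNA(lin)) stopf("samples without lineage labels: %s",
                        paste(utils::head(colnames(expr)[is.na(lin)], 5L), collapse = ", "))
  counts <- table(lin)
  keep_lin <- names(counts)[counts >= min_per_lineage]
  keep <- lin %in% keep_lin
  if (!any(keep)) stopf("no lineage passes the minimum size of %d", min_per_lineage)
  out <- expr[, keep, drop = FALSE]
  attr(out, "normalization") <- attr(expr, "normalization")
  out
}

#' Keep the most variably expressed genes
#'
#' Variance is computed across samples on the matrix as given (i.e. on
#' the raw log-scale values, before any normalization). Ties at the
#' cutoff are broken deterministically in favor of the
#' lexicographically smaller gene id.
#'
#' @param expr Genes x samples matrix.
#' @param n_genes Number of genes to keep.
#' @param statistic Dispersion statistic: `"variance"` (default),
#'   `"mad"`, or `"cv"` (sd/mean).
#' @return Expression matrix restricted to the selected genes, ordered
#'   by decreasing dispersion.
#' @export
select_variable_genes <- function(expr, n_genes,
                                  statistic = c("variance", "mad", "cv")) {
  validate_expression(expr)
  statistic <- match.arg(statistic)
  if (n_genes <= 0L) stopf("n_genes must be positive")
  if (n_genes > nrow(expr)) stopf("n_genes (%d) exceeds available genes (%d)",
                                  n_genes, nrow(expr))
  disp <- switch(statistic,
    variance = apply(expr, 1L, stats::var),
    mad      = apply(expr, 1L, stats::mad),
    cv       = apply(expr, 1L, function(x) stats::sd(x) / mean(x)))
  ord <- order(-disp, rownames(expr))
  out <- expr[ord[seq_len(n_genes)], , drop = FALSE]
  attr(out, "normalization") <- attr(expr, "normalization")
  out
}

#' Normalize an expression matrix
#'
#' Three schemes:
#' \describe{
#'   \item{rank}{Within each sample, genes are ranked (average ranks for
#'     ties) and mapped to the percentile rank/n_genes, so values lie in
#'     (0, 1]. With `direction = "increasing"` (default) larger
#'     expression maps to larger percentiles. Rank output is invariant
#'     under any strictly monotone transform of a sample's values,
#'     which is what allows microarray cohorts to be scored by models
#'     trained on RNA-seq.}
#'   \item{zs}{Per-sample z-score across genes.}
#'   \item{z01}{Per-gene z-score across samples, then an affine map of
#'     each gene's observed range onto [0, 1].}
#' }
#' Zero-variance genes/samples where a z-score is required are mapped to
#' a constant (0 for `zs`, 0.5 for `z01`) with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param scheme `"rank"`, `"zs"`, or `"z01"`.
#' @param direction For `"rank"`: `"increasing"` maps high expression to
#'   percentiles near 1; `"decreasing"` reverses. Training and
#'   prediction must use the same convention.
#' @return Normalized matrix with attribute `normalization` set to the
#'   scheme.
#' @export
normalize_expression <- function(expr, scheme = c("rank", "zs", "z01"),
                                 direction = c("increasing", "decreasing")) {
  validate_expression(expr)
  scheme <- match.arg(scheme)
  direction <- match.arg(direction)
  out <- switch(scheme,
    rank = {
      if (nrow(expr) < 2L) stopf("rank normalization needs >= 2 genes per sample")
      sgn <- if (direction == "increasing") 1 else -1
      apply(expr, 2L, function(x) rank(sgn * x, ties.method = "average") / length(x))
    },
    zs = {
      if (nrow(expr) < 2L) stopf("zs normalization needs >= 2 genes per sample")
      res <- apply(expr, 2L, function(x) {
        s <- stats::sd(x)
        if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
      })
      if (any(apply(expr, 2L, stats::sd) == 0))
        warnf("zero-variance sample(s) mapped to constant 0 under zs normalization")
      res
    },
    z01 = {
      if (ncol(expr) < 2L) stopf("z01 normalization needs >= 2 samples per gene")
      flat <- apply(expr, 1L, stats::sd) == 0
      if (any(flat))
        warnf("%d zero-variance gene(s) mapped to constant 0.5 under z01 normalization",
              sum(flat))
      res <- t(apply(expr, 1L, function(x) {
        s <- stats::sd(x)
        if (s == 0) return(rep(0.5, length(x)))
        z <- (x - mean(x)) / s
        (z - min(z)) / (max(z) - min(z))
      }))
      res
    })
  out <- matrix(out, nrow = nrow(expr), ncol = ncol(expr),
                dimnames = dimnames(expr))
  if (any(!is.finite(out))) stopf("normalization produced non-finite values")
  attr(out, "normalization") <- scheme
  attr(out, "direction") <- if (scheme == "rank") direction else NULL
  out
}
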