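#' Expression set container
#'
#' A minimal container for a log2 gene-by-sample expression matrix with a
#' cancer/normal group label per sample and, for mixed-tissue (macro-dissected)
#' data, a per-sample tumor-purity fraction.
#'
#' @param exprs Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). Values are assumed to be on the log2
#'   scale; values above 30 trigger a not-log-scale warning.
#' @param group Character or factor of length \code{ncol(exprs)} with values
#'   \code{"cancer"} or \code{"normal"}.
#' @param purity Optional numeric vector of length \code{ncol(exprs)} giving
#'   the tumor-cell (epithelial) fraction of each sample; \code{NA} for samples
#'   without a purity estimate (e.g. normals).
#' @return An object of class \code{expr_set}: a list with elements
#'   \code{exprs}, \code{group} and \code{purity}.
#' @export
expr_set <- function(exprs, group, purity = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if (is.null(rownames(exprs)))
    stop("`exprs` must have gene ids as rownames")
  if (is.null(colnames(exprs)))
    stop("`exprs` must have sample ids as colnames")
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]), collapse = ", "))
  group <- as.character(group)
  if (length(group) != ncol(exprs))
    stop("`group` must have one entry per sample")
  if (!all(group %in% c("cancer", "normal")))
    stop("`group` values must be 'cancer' or 'normal'")
  if (!is.null(purity)) {
    purity <- as.numeric(purity)
    if (length(purity) != ncol(exprs))
      stop("`purity` must have one entry per sample")
  }
  fin <- exprs[is.finite(exprs)]
  if (length(fin) && max(fin) > 30)
    warning("expression values above 30: input may not be log2 scale")
  structure(list(exprs = exprs,
                 group = factor(group, levels = c("cancer", "normal")),
                 purity = purity),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d cancer, %d normal)%s\n",
              nrow(x$exprs), ncol(x$exprs),
              sum(x$group == "cancer"), sum(x$group == "normal"),
              if (is.null(x$purity)) "" else ", with purity"))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$exprs)

# Accept either an expr_set or a bare matrix in analysis entry points.
as_expr_matrix <- function(x) {
  if (inherits(x, "expr_set")) x$exprs
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an expr_set or a numeric matrix")
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate sample ids are rejected; duplicate gene ids are allowed and can
#' subsequently be collapsed with \code{\link{collapse_probes}}.
#'
#' @param path Path to a tab-delimited text file.
#' @return Numeric matrix with (possibly duplicated) gene-id rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("malformed expression file (need gene column + samples): ", path)
  ids <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicated sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !(raw[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   raw[[j + 1L]][bad[1]], bad[1], samples[j], path))
    mat[, j] <- v
  }
  rownames(mat) <- ids
  mat
}

#' Write a tab-delimited expression matrix
#'
#' Writes atomically (temporary file in the target directory, then rename), so
#' a partially written table is never left behind.
#'
#' @param mat Numeric matrix with gene-id rownames and sample-id colnames.
#' @param path Output path.
#' @param id_column Name for the gene-id column.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write_table_atomic(df, path)
}

# Atomic table writer shared by all pipeline outputs.
write_table_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Collapse duplicate gene ids to per-gene expression
#'
#' Rows sharing a gene id are replaced by their arithmetic mean in each sample,
#' the usual summarization when several probe-sets map to one gene. Rows whose
#' id is an unmapped sentinel are dropped.
#'
#' @param mat Numeric matrix with gene ids as rownames (duplicates allowed).
#' @param unmapped Character vector of sentinel ids marking probes without a
#'   gene mapping; these rows are removed.
#' @return Numeric matrix with unique gene-id rownames.
#' @export
collapse_probes <- function(mat, unmapped = c("", "NA", "---")) {
  keep <- !(rownames(mat) %in% unmapped) & !is.na(rownames(mat))
  mat <- mat[keep, , drop = FALSE]
  if (!anyDuplicated(rownames(mat))) return(mat)
  ids <- rownames(mat)
  sums <- rowsum(mat, group = ids, reorder = FALSE)
  counts <- as.vector(table(factor(ids, levels = rownames(sums))))
  sums / counts
}
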