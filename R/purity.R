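#' Correlation between gene expression and tumor purity
#'
#' Pearson correlation of every gene's expression with the tumor-cell fraction
#' across macro-dissected cancer samples, with two-sided p-values from the t
#' distribution on n - 2 degrees of freedom. Genes with zero variance cannot
#' be correlated; they are returned flagged \code{excluded} with NA
#' statistics.
#'
#' @param x An \code{\link{expr_set}} (cancer samples with non-missing purity
#'   are used) or an expression matrix.
#' @param purity Purity fractions, one per column of the matrix; taken from
#'   the \code{expr_set} when omitted.
#' @return data.frame gene_id, r, p, significant (p < 0.05), excluded.
#' @export
purity_correlation <- function(x, purity = NULL) {
  X <- as_expr_matrix(x)
  if (is.null(purity) && inherits(x, "expr_set")) {
    keep <- x$group == "cancer" & !is.na(x$purity)
    X <- X[, keep, drop = FALSE]
    purity <- x$purity[keep]
  }
  if (is.null(purity)) stop("`purity` is required when `x` is a matrix")
  if (length(purity) != ncol(X))
    stop("`purity` must have one value per sample")
  n <- ncol(X)
  if (n < 3) stop("need at least 3 samples with purity values")
  if (stats::var(purity) == 0)
    stop("degenerate covariate: purity is constant")
  pc <- purity - mean(purity)
  Xc <- X - rowMeans(X)
  ss_x <- rowSums(Xc^2)
  excluded <- ss_x == 0
  r <- as.vector(Xc %*% pc) / sqrt(ss_x * sum(pc^2))
  r[excluded] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene_id = rownames(X), r = r, p = p,
             significant = !is.na(p) & p < 0.05,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Fraction of a gene set significantly purity-correlated
#'
#' @param associations Output of \code{\link{purity_correlation}}.
#' @param genes Gene subset of interest (DEG list data.frame or character
#'   vector); must be non-empty and overlap the association table.
#' @return Fraction of the subset's testable genes with p < 0.05.
#' @export
fraction_significant <- function(associations, genes) {
  ids <- deg_genes(genes)
  if (length(ids) == 0) stop("undefined fraction: empty gene subset")
  sub <- associations[associations$gene_id %in% ids & !associations$excluded, ,
                      drop = FALSE]
  if (nrow(sub) == 0)
    stop("undefined fraction: no testable genes from the subset are present")
  mean(sub$p < 0.05)
}
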