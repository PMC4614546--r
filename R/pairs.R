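#' Within-sample expression-ordering indicators for gene pairs
#'
#' For each (ordered) gene pair (A, B) and each sample, records whether
#' expr(A) > expr(B) within that sample (1), expr(B) > expr(A) (0), or an
#' exact tie (NA, treated as missing downstream). Because only within-sample
#' comparisons are made, the result is invariant to any strictly increasing
#' per-sample transform of the data.
#'
#' @param x An \code{\link{expr_set}} or expression matrix.
#' @param pairs data.frame with columns gene_a, gene_b.
#' @return Numeric matrix pairs x samples (rownames "A|B") of 0/1/NA.
#' @export
ordering_matrix <- function(x, pairs) {
  X <- as_expr_matrix(x)
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(X))
  if (length(miss))
    stop("missing genes for pairs: ", paste(miss, collapse = ", "))
  A <- X[pairs$gene_a, , drop = FALSE]
  B <- X[pairs$gene_b, , drop = FALSE]
  om <- matrix(NA_real_, nrow(pairs), ncol(X),
               dimnames = list(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                               colnames(X)))
  om[A > B] <- 1
  om[A < B] <- 0
  om
}

#' Fisher's exact screen for reversed gene-pair orderings
#'
#' Per pair, the 2x2 table \[disease: A>B, B>A; normal: A>B, B>A\] (ties
#' excluded) is tested with the two-sided Fisher's exact test; p-values are
#' Benjamini-Hochberg adjusted across the pair universe, and pairs with
#' FDR below the threshold are flagged as significantly reversed. The
#' reversal direction records which group favors A > B more often.
#'
#' @param om Ordering matrix from \code{\link{ordering_matrix}}.
#' @param group "cancer"/"normal" labels for the columns of \code{om}.
#' @param fdr_threshold BH-adjusted significance cutoff.
#' @param pairs Optional data.frame (gene_a, gene_b) matching the rows of
#'   \code{om}; reconstructed from rownames when omitted.
#' @return data.frame per pair: gene_a, gene_b, n_disease_a_gt_b,
#'   n_disease_b_gt_a, n_normal_a_gt_b, n_normal_b_gt_a, fisher_p, fdr,
#'   reversal_direction, significant. Pairs tied in every sample of a group
#'   margin are dropped with a warning.
#' @export
pair_fisher_screen <- function(om, group, fdr_threshold = 0.10, pairs = NULL) {
  group <- as.character(group)
  if (length(group) != ncol(om)) stop("`group` must match the columns of `om`")
  if (sum(group == "cancer") < 2 || sum(group == "normal") < 2)
    stop("need at least 2 samples per group")
  if (is.null(pairs)) {
    sp <- strsplit(rownames(om), "|", fixed = TRUE)
    pairs <- data.frame(gene_a = vapply(sp, `[`, "", 1),
                        gene_b = vapply(sp, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  dis <- om[, group == "cancer", drop = FALSE]
  nor <- om[, group == "normal", drop = FALSE]
  da <- rowSums(dis == 1, na.rm = TRUE); db <- rowSums(dis == 0, na.rm = TRUE)
  na_ <- rowSums(nor == 1, na.rm = TRUE); nb <- rowSums(nor == 0, na.rm = TRUE)
  empty <- (da + db == 0) | (na_ + nb == 0)
  if (any(empty))
    warning(sum(empty), " all-tied pair(s) excluded from the screen")
  p <- rep(NA_real_, nrow(om))
  idx <- which(!empty)
  p[idx] <- vapply(idx, function(i) {
    stats::fisher.test(matrix(c(da[i], db[i], na_[i], nb[i]), 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  fdr <- rep(NA_real_, length(p))
  fdr[idx] <- stats::p.adjust(p[idx], method = "BH")
  prop_dis <- da / pmax(da + db, 1)
  prop_nor <- na_ / pmax(na_ + nb, 1)
  direction <- ifelse(prop_dis > prop_nor, "disease_favors_a",
                      ifelse(prop_dis < prop_nor, "disease_favors_b",
                             NA_character_))
  out <- data.frame(pairs,
                    n_disease_a_gt_b = da, n_disease_b_gt_a = db,
                    n_normal_a_gt_b = na_, n_normal_b_gt_a = nb,
                    fisher_p = p, fdr = fdr,
                    reversal_direction = direction,
                    significant = !is.na(fdr) & fdr < fdr_threshold &
                      !is.na(direction),
                    stringsAsFactors = FALSE)
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical pair key: lexicographically smaller gene first, with the
# direction re-expressed relative to that order.
pair_canonical <- function(df) {
  flip <- df$gene_a > df$gene_b
  key <- ifelse(flip, paste(df$gene_b, df$gene_a, sep = "|"),
                paste(df$gene_a, df$gene_b, sep = "|"))
  dir <- df$reversal_direction
  dir[flip] <- ifelse(dir[flip] == "disease_favors_a",
                      "disease_favors_b", "disease_favors_a")
  data.frame(key = key, canon_direction = dir, stringsAsFactors = FALSE)
}

#' Intersect two pair screens into a consistent pair set
#'
#' Pairs significantly reversed in both screens (matched in canonical order)
#' are split into same-direction pairs (kept: the consistent pair set) and
#' opposite-direction pairs (reported and dropped). The consistency fraction
#' among overlapping pairs is reported with its one-sided binomial tail
#' probability (chance level 1/2).
#'
#' @param screenA,screenB Outputs of \code{\link{pair_fisher_screen}}.
#' @return List of class \code{consistent_pairs}: \code{pairs} (screenA rows
#'   of the kept pairs), \code{n_overlap}, \code{n_same}, \code{consistency},
#'   \code{P2}, \code{dropped}.
#' @export
intersect_pairs <- function(screenA, screenB) {
  sa <- screenA[screenA$significant, , drop = FALSE]
  sb <- screenB[screenB$significant, , drop = FALSE]
  ca <- pair_canonical(sa); cb <- pair_canonical(sb)
  common <- intersect(ca$key, cb$key)
  ia <- match(common, ca$key); ib <- match(common, cb$key)
  same <- ca$canon_direction[ia] == cb$canon_direction[ib]
  kept <- sa[ia[same], , drop = FALSE]
  dropped <- sa[ia[!same], , drop = FALSE]
  rownames(kept) <- rownames(dropped) <- NULL
  n <- length(common); s <- sum(same)
  P2 <- if (n == 0) NA_real_ else stats::pbinom(s - 1, n, 0.5, lower.tail = FALSE)
  structure(list(pairs = kept, n_overlap = n, n_same = s,
                 consistency = if (n == 0) NA_real_ else s / n,
                 P2 = P2, dropped = dropped),
            class = "consistent_pairs")
}

#' @export
print.consistent_pairs <- function(x, ...) {
  cat(sprintf("consistent pairs: %d kept of %d overlapping (%.2f%% same direction; P2 = %s)\n",
              nrow(x$pairs), x$n_overlap,
              100 * ifelse(is.na(x$consistency), 0, x$consistency),
              if (is.na(x$P2)) "NA" else format_p(x$P2)))
  invisible(x)
}

#' Cross-dataset validation of a consistent pair set
#'
#' Checks how a reference pair set behaves in an independent dataset:
#' \code{pair_num} pairs have both genes measured there; \code{pair_05} of
#' those show a reversal tendency (unadjusted Fisher p < 0.05); and
#' \code{direc_con} counts how many of these reverse in the same direction as
#' the reference.
#'
#' @param reference A \code{consistent_pairs} object or a pair data.frame with
#'   gene_a, gene_b, reversal_direction.
#' @param x Validation \code{\link{expr_set}} (or matrix plus \code{group}).
#' @param group Optional labels when \code{x} is a matrix.
#' @return List: pair_num, pair_05, direc_con_n, direc_con_frac, screen (the
#'   per-pair validation table).
#' @export
cross_dataset_consistency <- function(reference, x, group = NULL) {
  ref <- if (inherits(reference, "consistent_pairs")) reference$pairs else reference
  X <- as_expr_matrix(x)
  if (is.null(group) && inherits(x, "expr_set")) group <- x$group
  present <- ref$gene_a %in% rownames(X) & ref$gene_b %in% rownames(X)
  ref <- ref[present, , drop = FALSE]
  pair_num <- nrow(ref)
  if (pair_num == 0)
    return(list(pair_num = 0L, pair_05 = 0L, direc_con_n = 0L,
                direc_con_frac = NA_real_, screen = NULL))
  om <- ordering_matrix(X, ref)
  val <- pair_fisher_screen(om, group, fdr_threshold = 1, pairs = ref[, c("gene_a", "gene_b")])
  m <- match(paste(val$gene_a, val$gene_b), paste(ref$gene_a, ref$gene_b))
  hit <- !is.na(val$fisher_p) & val$fisher_p < 0.05 &
    !is.na(val$reversal_direction)
  agree <- hit & val$reversal_direction == ref$reversal_direction[m]
  list(pair_num = pair_num, pair_05 = sum(hit), direc_con_n = sum(agree),
       direc_con_frac = if (sum(hit) == 0) NA_real_ else sum(agree) / sum(hit),
       screen = val)
}
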