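#' Hypergeometric overlap test between two DEG lists
#'
#' Probability of observing at least k overlapping genes between a list of L1
#' and a list of L2 genes drawn from L background genes:
#' \deqn{P_1 = \sum_{i=k}^{\min(L_1,L_2)} \frac{{L_1 \choose i}{L-L_1 \choose L_2-i}}{{L \choose L_2}}}
#' The overlap is flagged significant at P1 < 0.05.
#'
#' @param list1,list2 DEG lists (data.frames with a \code{gene_id} column, or
#'   character vectors of gene ids).
#' @param background Character vector of the genes commonly detected in the
#'   contributing datasets; both lists must be subsets of it.
#' @return List of class \code{overlap_result}: L, L1, L2, k, P1, significant,
#'   overlap (the gene ids).
#' @export
overlap_test <- function(list1, list2, background) {
  g1 <- unique(deg_genes(list1)); g2 <- unique(deg_genes(list2))
  background <- unique(background)
  out1 <- setdiff(g1, background); out2 <- setdiff(g2, background)
  if (length(out1) || length(out2))
    stop("background mismatch: list genes outside background: ",
         paste(utils::head(c(out1, out2), 5), collapse = ", "))
  L <- length(background); L1 <- length(g1); L2 <- length(g2)
  ov <- intersect(g1, g2); k <- length(ov)
  P1 <- if (k == 0) 1 else stats::phyper(k - 1, L1, L - L1, L2, lower.tail = FALSE)
  structure(list(L = L, L1 = L1, L2 = L2, k = k, P1 = P1,
                 significant = P1 < 0.05, overlap = ov),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of L1 = %d, L2 = %d (background L = %d); P1 = %s%s\n",
              x$k, x$L1, x$L2, x$L, format_p(x$P1),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Dysregulation-direction consistency score between two DEG lists
#'
#' Over the k genes shared by both lists, the score is the fraction s/k with
#' identical up/down direction. The probability of at least s same-direction
#' genes when each matches independently with probability p = 1/2 is the
#' one-sided binomial tail
#' \deqn{P_2 = \sum_{i=s}^{k} {k \choose i} p^i (1-p)^{k-i}}
#' flagged significant at P2 < 0.05.
#'
#' @param list1,list2 DEG lists (data.frames with gene_id and direction).
#' @return List of class \code{consistency_result}: k, s, score, P2,
#'   significant.
#' @export
consistency_score <- function(list1, list2) {
  m <- merge(list1[, c("gene_id", "direction")],
             list2[, c("gene_id", "direction")], by = "gene_id")
  k <- nrow(m)
  if (k == 0)
    stop("undefined score: the two DEG lists share no genes")
  s <- sum(m$direction.x == m$direction.y)
  P2 <- stats::pbinom(s - 1, k, 0.5, lower.tail = FALSE)
  structure(list(k = k, s = s, score = s / k, P2 = P2,
                 significant = P2 < 0.05),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("consistency: s = %d of k = %d (%.1f%%); P2 = %s%s\n",
              x$s, x$k, 100 * x$score, format_p(x$P2),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Merge DEG lists, dropping direction conflicts
#'
#' Union of the genes of two or more DEG lists; any gene reported with
#' opposite directions in different lists is removed (its evidence is
#' self-contradictory); otherwise the direction and the best (smallest pfp)
#' record are retained.
#'
#' @param ... Two or more DEG lists, or a single list() of them.
#' @return A merged DEG list.
#' @export
merge_union_drop_conflicts <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  if (length(lists) < 2) stop("need at least 2 DEG lists to merge")
  all <- do.call(rbind, lists)
  dirs <- tapply(all$direction, all$gene_id, function(d) length(unique(d)))
  conflicted <- names(dirs)[dirs > 1]
  all <- all[!(all$gene_id %in% conflicted), , drop = FALSE]
  all <- all[order(all$pfp), , drop = FALSE]
  out <- all[!duplicated(all$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority-direction DEG call across exactly three lists
#'
#' A gene is kept with direction d iff it appears with direction d in at least
#' two of the three lists (how a macro-dissected DEG consensus is formed from
#' three discovery datasets).
#'
#' @param list1,list2,list3 DEG lists.
#' @return A DEG list of majority genes (best record per gene retained,
#'   origin marked "majority").
#' @export
majority_direction <- function(list1, list2, list3) {
  if (nargs() != 3)
    stop("majority_direction takes exactly 3 DEG lists")
  all <- rbind(list1, list2, list3)
  key <- paste(all$gene_id, all$direction)
  votes <- table(key)
  keep_key <- names(votes)[votes >= 2]
  out <- all[key %in% keep_key, , drop = FALSE]
  out <- out[order(out$pfp), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out$origin <- "majority"
  rownames(out) <- NULL
  out
}

#' Partition shared DEGs into consistent and inconsistent sets
#'
#' Over genes present in both the epithelial and the stromal DEG list: same
#' direction goes to the consistent set, opposite direction to the
#' inconsistent set. The two outputs are disjoint and their union is the
#' intersection of the inputs. Inconsistent genes carry their epithelial
#' direction (the compartment-of-reference convention used when comparing
#' against macro-dissected calls).
#'
#' @param epithelial,stromal DEG lists.
#' @return List with DEG lists \code{consistent} and \code{inconsistent}.
#' @export
partition_consistent <- function(epithelial, stromal) {
  m <- merge(epithelial, stromal[, c("gene_id", "direction")],
             by = "gene_id", suffixes = c("", ".str"))
  same <- m$direction == m$direction.str
  cons <- m[same, setdiff(colnames(m), "direction.str"), drop = FALSE]
  inco <- m[!same, setdiff(colnames(m), "direction.str"), drop = FALSE]
  cons$origin <- rep("consistent", nrow(cons))
  inco$origin <- rep("inconsistent", nrow(inco))
  rownames(cons) <- rownames(inco) <- NULL
  list(consistent = cons, inconsistent = inco)
}

deg_genes <- function(x) {
  if (is.data.frame(x)) as.character(x$gene_id) else as.character(x)
}

format_p <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3)
}
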