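#' Simulate a ground-truth gene universe for a two-compartment tumor study
#'
#' Defines the latent state every simulated cohort of one study shares: per-gene
#' log2 baselines, the differential-expression class of each gene in malignant
#' epithelium and stroma, per-compartment effect sizes, a stromal-vs-epithelial
#' abundance offset, and a set of planted expression-order-reversal gene pairs
#' (a subset of which carries prognostic weight).
#'
#' DEG classes: \code{null}; \code{epi_up}/\code{epi_down} (epithelium only);
#' \code{str_up}/\code{str_down} (stroma only); \code{consistent_up}/
#' \code{consistent_down} (same direction in both compartments);
#' \code{inconsistent_eu_sd} (up in epithelium, down in stroma) and
#' \code{inconsistent_ed_su} (the reverse).
#'
#' Baselines are drawn once here, not per cohort, so that within-sample
#' gene-pair orderings replicate across all cohorts generated from the same
#' truth. Each reversal pair (A, B) is built from one dedicated up- and one
#' dedicated down-gene with a normal-tissue ordering margin of
#' \code{pair_margin} log2 units (B above A) that flips sign in cancer; both
#' members share one stromal offset so the margin holds in both compartments.
#'
#' @param n_genes Total number of genes.
#' @param class_counts Named integer vector of genes per non-null DEG class
#'   (pair genes are extra and drawn from the remaining pool); the rest are null.
#' @param delta Default absolute log2 effect size for DEG classes.
#' @param inconsistent_jitter Half-width of the uniform jitter applied,
#'   independently per compartment, to the effect sizes of inconsistent genes;
#'   their per-compartment magnitudes are drawn from
#'   \code{Uniform(delta - j, delta + j)}.
#' @param offset_sd Standard deviation (log2) of the per-gene stromal-minus-
#'   epithelial baseline abundance offset.
#' @param n_pairs Number of planted reversal pairs.
#' @param n_prognostic Number of those pairs given nonzero hazard weight.
#' @param pair_margin Normal-tissue ordering margin (log2) of each pair; also
#'   the effect size of its member genes, so the margin reverses in cancer.
#' @param prognostic_loghr Total log hazard ratio carried jointly by the
#'   prognostic pairs; each pair gets \code{prognostic_loghr / n_prognostic}.
#' @param baseline_range Range of the Uniform distribution for per-gene log2
#'   baseline means.
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @return Object of class \code{reo_truth}: list with \code{genes} (data.frame
#'   gene_id, deg_class, effect_epi, effect_str, baseline, offset_str,
#'   is_pair_gene) and \code{pairs} (data.frame gene_a, gene_b, beta,
#'   prognostic).
#' @export
simulate_ground_truth <- function(n_genes = 1100,
                                  class_counts = c(consistent_up = 120,
                                                   consistent_down = 120,
                                                   epi_up = 65, epi_down = 65,
                                                   str_up = 65, str_down = 65,
                                                   inconsistent_eu_sd = 60,
                                                   inconsistent_ed_su = 60),
                                  delta = 1.0,
                                  inconsistent_jitter = 0.4,
                                  offset_sd = 5.0,
                                  n_pairs = 40,
                                  n_prognostic = 15,
                                  pair_margin = 3.0,
                                  prognostic_loghr = 1.6,
                                  baseline_range = c(5, 12),
                                  seed = NULL) {
  classes <- c("consistent_up", "consistent_down", "epi_up", "epi_down",
               "str_up", "str_down", "inconsistent_eu_sd", "inconsistent_ed_su")
  if (!all(names(class_counts) %in% classes))
    stop("unknown deg_class in class_counts: ",
         paste(setdiff(names(class_counts), classes), collapse = ", "))
  if (delta <= 0) stop("`delta` must be positive")
  if (n_prognostic > n_pairs) stop("`n_prognostic` cannot exceed `n_pairs`")
  n_deg <- sum(class_counts)
  if (n_deg + 2 * n_pairs > n_genes)
    stop("n_genes too small for the requested classes and pairs")
  if (!is.null(seed)) set.seed(seed)

  gene_id <- sprintf("g%04d", seq_len(n_genes))
  deg_class <- rep("null", n_genes)
  idx <- seq_len(n_deg)
  deg_class[idx] <- rep(names(class_counts), class_counts)
  pair_gene_idx <- n_deg + seq_len(2 * n_pairs)
  is_pair_gene <- seq_len(n_genes) %in% pair_gene_idx

  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  offset_str <- stats::rnorm(n_genes, 0, offset_sd)

  es_epi <- rep(delta, n_genes)
  es_str <- rep(delta, n_genes)
  inc <- deg_class %in% c("inconsistent_eu_sd", "inconsistent_ed_su")
  if (inconsistent_jitter > 0 && any(inc)) {
    lo <- max(delta - inconsistent_jitter, 0.05)
    hi <- delta + inconsistent_jitter
    es_epi[inc] <- stats::runif(sum(inc), lo, hi)
    es_str[inc] <- stats::runif(sum(inc), lo, hi)
  }
  sign_epi <- c(consistent_up = 1, consistent_down = -1, epi_up = 1,
                epi_down = -1, str_up = 0, str_down = 0,
                inconsistent_eu_sd = 1, inconsistent_ed_su = -1, null = 0)
  sign_str <- c(consistent_up = 1, consistent_down = -1, epi_up = 0,
                epi_down = 0, str_up = 1, str_down = -1,
                inconsistent_eu_sd = -1, inconsistent_ed_su = 1, null = 0)
  effect_epi <- sign_epi[deg_class] * es_epi
  effect_str <- sign_str[deg_class] * es_str

  # Pair genes: A (up, former gene of the pair) sits pair_margin below B
  # (down) in normal tissue; cancer effects +/- pair_margin reverse the order.
  pairs <- NULL
  if (n_pairs > 0) {
    a_idx <- pair_gene_idx[seq_len(n_pairs)]
    b_idx <- pair_gene_idx[n_pairs + seq_len(n_pairs)]
    mu_a <- stats::runif(n_pairs, baseline_range[1],
                         max(baseline_range[2] - pair_margin, baseline_range[1] + 1))
    baseline[a_idx] <- mu_a
    baseline[b_idx] <- mu_a + pair_margin
    deg_class[a_idx] <- "consistent_up"
    deg_class[b_idx] <- "consistent_down"
    effect_epi[a_idx] <- pair_margin; effect_str[a_idx] <- pair_margin
    effect_epi[b_idx] <- -pair_margin; effect_str[b_idx] <- -pair_margin
    shared_off <- stats::rnorm(n_pairs, 0, offset_sd)
    offset_str[a_idx] <- shared_off
    offset_str[b_idx] <- shared_off
    beta <- rep(0, n_pairs)
    beta[seq_len(n_prognostic)] <- prognostic_loghr / n_prognostic
    pairs <- data.frame(gene_a = gene_id[a_idx], gene_b = gene_id[b_idx],
                        beta = beta,
                        prognostic = seq_len(n_pairs) <= n_prognostic,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        beta = numeric(), prognostic = logical(),
                        stringsAsFactors = FALSE)
  }
  genes <- data.frame(gene_id = gene_id,
                      deg_class = factor(deg_class, levels = c("null", classes)),
                      effect_epi = unname(effect_epi),
                      effect_str = unname(effect_str),
                      baseline = baseline,
                      offset_str = offset_str,
                      is_pair_gene = is_pair_gene,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, pairs = pairs), class = "reo_truth")
}

#' @export
print.reo_truth <- function(x, ...) {
  tab <- table(x$genes$deg_class)
  cat(sprintf("reo_truth: %d genes, %d reversal pairs (%d prognostic)\n",
              nrow(x$genes), nrow(x$pairs), sum(x$pairs$prognostic)))
  print(tab[tab > 0])
  invisible(x)
}

# Expected per-gene cancer shift matrix for one compartment, given the
# per-sample reversal status of each planted pair (rows = genes, cols = cancer
# samples). Non-pair genes shift uniformly; pair genes shift only in samples
# where their pair is in the reversed state.
cancer_shift_matrix <- function(truth, compartment = c("epi", "str"),
                                n_cancer, pair_reversal = NULL) {
  compartment <- match.arg(compartment)
  eff <- if (compartment == "epi") truth$genes$effect_epi else truth$genes$effect_str
  shift <- matrix(eff, nrow(truth$genes), n_cancer)
  if (nrow(truth$pairs) > 0) {
    if (is.null(pair_reversal))
      pair_reversal <- matrix(1, nrow(truth$pairs), n_cancer)
    if (!is.matrix(pair_reversal) ||
        nrow(pair_reversal) != nrow(truth$pairs) ||
        ncol(pair_reversal) != n_cancer)
      stop("`pair_reversal` must be a pairs x cancer-samples 0/1 matrix")
    ia <- match(truth$pairs$gene_a, truth$genes$gene_id)
    ib <- match(truth$pairs$gene_b, truth$genes$gene_id)
    shift[ia, ] <- shift[ia, , drop = FALSE] * pair_reversal
    shift[ib, ] <- shift[ib, , drop = FALSE] * pair_reversal
  }
  shift
}
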