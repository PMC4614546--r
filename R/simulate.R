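#' Simulate cell-type-specific expression profiles
#'
#' Generates matched malignant-epithelium and stroma profiles (the in-silico
#' analogue of laser-capture-microdissected samples) for one cohort of cancer
#' and normal subjects. Cancer sample \code{i} in the epithelial matrix and
#' cancer sample \code{i} in the stromal matrix are the two compartments of the
#' same patient, which is what makes downstream purity mixtures meaningful.
#'
#' Per gene: epithelial baseline is the truth baseline, stromal baseline adds
#' the gene's stromal abundance offset; cancer samples shift by the signed
#' per-compartment effect of the gene's DEG class; i.i.d. Gaussian noise with
#' sd \code{noise_sd} is added on the log2 scale.
#'
#' @param truth A \code{reo_truth} object.
#' @param n_cancer,n_normal Sample counts (must be positive).
#' @param noise_sd Log2-scale noise standard deviation (must be positive).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param pair_reversal Optional 0/1 matrix (planted pairs x cancer samples)
#'   giving the per-patient reversal state of each planted pair; default all 1
#'   (every cancer sample carries every reversal, the discovery-cohort
#'   contract). Survival cohorts use this to encode patient heterogeneity.
#' @return List with elements \code{epithelial} and \code{stromal}, each an
#'   \code{\link{expr_set}}.
#' @export
simulate_celltype_profiles <- function(truth, n_cancer, n_normal,
                                       noise_sd = 1, seed = NULL,
                                       pair_reversal = NULL) {
  stopifnot(inherits(truth, "reo_truth"))
  if (n_cancer < 1 || n_normal < 1)
    stop("invalid parameter: sample counts must be positive")
  if (noise_sd <= 0)
    stop("invalid parameter: `noise_sd` must be positive")
  if (!is.null(seed)) set.seed(seed)
  g <- truth$genes
  G <- nrow(g)
  samples <- c(sprintf("C%03d", seq_len(n_cancer)),
               sprintf("N%03d", seq_len(n_normal)))
  group <- rep(c("cancer", "normal"), c(n_cancer, n_normal))
  shift_e <- cancer_shift_matrix(truth, "epi", n_cancer, pair_reversal)
  shift_s <- cancer_shift_matrix(truth, "str", n_cancer, pair_reversal)

  epi <- matrix(g$baseline, G, n_cancer + n_normal)
  str <- matrix(g$baseline + g$offset_str, G, n_cancer + n_normal)
  epi[, seq_len(n_cancer)] <- epi[, seq_len(n_cancer)] + shift_e
  str[, seq_len(n_cancer)] <- str[, seq_len(n_cancer)] + shift_s
  epi <- epi + matrix(stats::rnorm(length(epi), 0, noise_sd), G)
  str <- str + matrix(stats::rnorm(length(str), 0, noise_sd), G)
  dimnames(epi) <- dimnames(str) <- list(g$gene_id, samples)
  list(epithelial = suppressWarnings(expr_set(epi, group)),
       stromal = suppressWarnings(expr_set(str, group)))
}

#' Mixture design for macro-dissected samples
#'
#' @param n_cancer,n_normal Sample counts (at least 2 per group).
#' @param purity Numeric vector of tumor-cell fractions, one per cancer
#'   sample, each in \[\code{purity_floor}, 1\]; \code{NULL} draws
#'   Uniform(0.6, 1) at mixing time.
#' @param noise_sd Log2 measurement noise added after mixing (the biological
#'   noise already lives in the compartment profiles).
#' @param normal_epi_fraction Epithelial fraction used for normal-tissue
#'   mixtures (normal breast tissue is itself a mixture).
#' @param purity_floor Lowest admissible purity; 0.6 by default, the usual
#'   clinical sampling threshold for macro-dissected tissue. Set to 0 only
#'   for in-silico checks of the mixture endpoints.
#' @param seed Integer seed used when mixing.
#' @return Object of class \code{mixture_design}.
#' @export
mixture_design <- function(n_cancer, n_normal, purity = NULL,
                           noise_sd = 0.2, normal_epi_fraction = 0.5,
                           purity_floor = 0.6, seed = NULL) {
  if (n_cancer < 2 || n_normal < 2)
    stop("invalid parameter: need at least 2 samples per group")
  if (noise_sd < 0) stop("invalid parameter: `noise_sd` must be non-negative")
  if (!is.null(purity)) {
    if (length(purity) != n_cancer)
      stop("`purity` must have length n_cancer")
    if (any(purity < purity_floor - 1e-12) || any(purity > 1 + 1e-12))
      stop(sprintf("invalid parameter: purity must lie in [%g, 1.0]",
                   purity_floor))
  }
  if (normal_epi_fraction < 0 || normal_epi_fraction > 1)
    stop("invalid parameter: `normal_epi_fraction` must lie in [0, 1]")
  structure(list(n_cancer = n_cancer, n_normal = n_normal, purity = purity,
                 noise_sd = noise_sd,
                 normal_epi_fraction = normal_epi_fraction, seed = seed),
            class = "mixture_design")
}

#' Simulate macro-dissected tissue as purity-weighted mixtures
#'
#' Physical mRNA abundances mix linearly, so compartment profiles are combined
#' on the linear scale and re-logged:
#' \code{macro = log2(purity * 2^epi + (1 - purity) * 2^str) + noise}.
#' Cancer sample \code{i} mixes the two compartments of patient \code{i} at
#' that patient's purity; normal samples mix at the design's fixed normal
#' epithelial fraction.
#'
#' @param epithelial,stromal Matched \code{\link{expr_set}} objects sharing
#'   gene ids and sample layout (as produced by
#'   \code{\link{simulate_celltype_profiles}}).
#' @param design A \code{\link{mixture_design}}.
#' @return An \code{\link{expr_set}} with per-sample purity annotation
#'   (cancer samples carry their purity; normals carry the normal epithelial
#'   fraction).
#' @export
simulate_macro_dissected <- function(epithelial, stromal, design) {
  stopifnot(inherits(design, "mixture_design"))
  E <- as_expr_matrix(epithelial); S <- as_expr_matrix(stromal)
  if (!identical(rownames(E), rownames(S)))
    stop("alignment error: epithelial and stromal gene ids differ")
  if (!identical(colnames(E), colnames(S)))
    stop("alignment error: epithelial and stromal sample ids differ")
  group <- epithelial$group
  nc <- sum(group == "cancer"); nn <- sum(group == "normal")
  if (nc != design$n_cancer || nn != design$n_normal)
    stop("alignment error: sample counts do not match the mixture design")
  if (!is.null(design$seed)) set.seed(design$seed)
  purity <- design$purity
  if (is.null(purity)) purity <- stats::runif(nc, 0.6, 1)
  w <- numeric(ncol(E))
  w[group == "cancer"] <- purity
  w[group == "normal"] <- design$normal_epi_fraction
  M <- log2(sweep(2^E, 2, w, "*") + sweep(2^S, 2, 1 - w, "*"))
  if (design$noise_sd > 0)
    M <- M + matrix(stats::rnorm(length(M), 0, design$noise_sd), nrow(M))
  pur <- ifelse(group == "cancer", w, NA_real_)
  pur[group == "normal"] <- design$normal_epi_fraction
  suppressWarnings(expr_set(M, as.character(group), purity = pur))
}

#' Simulate survival outcomes driven by gene-pair reversal status
#'
#' Per cancer sample, the hazard is
#' \code{baseline_hazard * exp(sum_j beta_j * I[expr(A_j) > expr(B_j)])} over
#' the truth's planted pairs, evaluated on the supplied (macro-dissected)
#' expression. Event times are exponential with that hazard, censoring times
#' exponential with rate \code{censor_rate} (0 = no censoring), and the
#' observed time is the minimum. Age, grade and tumor size covariates are
#' drawn independently of risk.
#'
#' @param macro An \code{\link{expr_set}} (cancer samples are used).
#' @param truth The \code{reo_truth} whose pairs carry the hazard weights.
#' @param baseline_hazard Positive baseline hazard rate.
#' @param censor_rate Non-negative censoring rate.
#' @param seed Integer seed.
#' @return data.frame with columns sample, time, event, age, grade, size.
#' @export
simulate_survival <- function(macro, truth, baseline_hazard = 0.05,
                              censor_rate = 0.15, seed = NULL) {
  stopifnot(inherits(truth, "reo_truth"))
  if (baseline_hazard <= 0)
    stop("invalid parameter: `baseline_hazard` must be positive")
  if (censor_rate < 0)
    stop("invalid parameter: `censor_rate` must be non-negative")
  X <- as_expr_matrix(macro)
  keep <- if (inherits(macro, "expr_set")) macro$group == "cancer" else rep(TRUE, ncol(X))
  X <- X[, keep, drop = FALSE]
  miss <- setdiff(c(truth$pairs$gene_a, truth$pairs$gene_b), rownames(X))
  if (length(miss))
    stop("missing genes for planted pairs: ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(X)
  loghr <- rep(0, n)
  if (nrow(truth$pairs) > 0) {
    om <- X[truth$pairs$gene_a, , drop = FALSE] > X[truth$pairs$gene_b, , drop = FALSE]
    loghr <- as.vector(crossprod(om, truth$pairs$beta))
  }
  hazard <- baseline_hazard * exp(loghr)
  t_event <- stats::rexp(n, hazard)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  data.frame(sample = colnames(X),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             age = round(stats::rnorm(n, 55, 10)),
             grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.5, 0.3)),
             size = round(stats::rlnorm(n, log(2), 0.4), 1),
             stringsAsFactors = FALSE)
}

#' Simulate a survival cohort with patient-level pair heterogeneity
#'
#' Discovery cohorts carry every planted reversal in every cancer sample; a
#' survival cohort instead needs between-patient variation for orderings to be
#' prognostic. Each patient draws a latent aggressive phenotype with
#' probability \code{p_aggressive}; prognostic pairs are reversed exactly in
#' aggressive patients, while zero-weight planted pairs are reversed
#' independently per patient with probability 1/2 (order variation unrelated
#' to outcome, so a univariate screen should discard them).
#'
#' @param truth A \code{reo_truth}.
#' @param n_patients Number of cancer patients.
#' @param p_aggressive Prevalence of the aggressive phenotype.
#' @param noise_sd Compartment-profile noise sd.
#' @param purity Per-patient tumor purity; \code{NULL} draws Uniform(0.6, 1).
#' @param mix_noise_sd Measurement noise added after mixing.
#' @param normal_epi_fraction Epithelial fraction for the cohort's (few)
#'   normal reference samples.
#' @param baseline_hazard,censor_rate Passed to \code{\link{simulate_survival}}.
#' @param n_normal Normal reference samples kept in the matrices (not in the
#'   survival table).
#' @param seed Integer seed.
#' @return List: \code{epithelial}, \code{stromal}, \code{macro} (expr_set),
#'   \code{survival} (data.frame over cancer samples), \code{aggressive}
#'   (0/1 per patient), \code{purity}.
#' @export
simulate_survival_cohort <- function(truth, n_patients, p_aggressive = 0.25,
                                     noise_sd = 1, purity = NULL,
                                     mix_noise_sd = 0.2,
                                     normal_epi_fraction = 0.5,
                                     baseline_hazard = 0.05,
                                     censor_rate = 0.15,
                                     n_normal = 5, seed = NULL) {
  stopifnot(inherits(truth, "reo_truth"))
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(truth$pairs)
  z <- stats::rbinom(n_patients, 1, p_aggressive)
  rev_mat <- matrix(0, np, n_patients)
  if (np > 0) {
    rev_mat[truth$pairs$prognostic, ] <-
      matrix(z, sum(truth$pairs$prognostic), n_patients, byrow = TRUE)
    n_null_pairs <- sum(!truth$pairs$prognostic)
    if (n_null_pairs > 0)
      rev_mat[!truth$pairs$prognostic, ] <-
        matrix(stats::rbinom(n_null_pairs * n_patients, 1, 0.5), n_null_pairs)
  }
  prof <- simulate_celltype_profiles(truth, n_patients, n_normal,
                                     noise_sd = noise_sd,
                                     pair_reversal = rev_mat)
  if (is.null(purity)) purity <- stats::runif(n_patients, 0.6, 1)
  des <- mixture_design(n_patients, n_normal, purity = purity,
                        noise_sd = mix_noise_sd,
                        normal_epi_fraction = normal_epi_fraction)
  macro <- simulate_macro_dissected(prof$epithelial, prof$stromal, des)
  surv <- simulate_survival(macro, truth, baseline_hazard = baseline_hazard,
                            censor_rate = censor_rate)
  list(epithelial = prof$epithelial, stromal = prof$stromal, macro = macro,
       survival = surv, aggressive = z, purity = purity)
}

#' Draw macro-dissection purities concentrated near the sampling threshold
#'
#' Macro-dissected discovery cohorts typically sit just above the 60% tumor
#' content admission threshold; this draws \code{0.6 + 0.4 * Beta(1, shape2)}
#' (mean near 0.61 at the default), staying within \[0.6, 1\].
#'
#' @param n Number of samples.
#' @param shape2 Second Beta shape parameter; larger = closer to 0.6.
#' @return Numeric vector of purities.
#' @export
sample_macro_purity <- function(n, shape2 = 40) {
  0.6 + 0.4 * stats::rbeta(n, 1, shape2)
}
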