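#' Univariate Cox screen over consistent gene pairs
#'
#' Fits, for each candidate pair, a proportional-hazards model with the single
#' binary covariate I\[expr(A) > expr(B)\] (Breslow tie handling), BH-adjusts
#' the Wald p-values across pairs, and keeps pairs with FDR below the
#' threshold. Retained pairs are oriented so that the risk order is positive:
#' gene B above gene A goes with better outcome, i.e. cox_beta > 0 for
#' I\[A > B\]. Pairs with a constant indicator or a non-convergent
#' (monotone-likelihood) fit are skipped with an explicit reason, never
#' silently included.
#'
#' @param pairs data.frame with gene_a, gene_b (e.g. the \code{pairs} element
#'   of \code{\link{intersect_pairs}}).
#' @param om Ordering matrix over those pairs for the training samples
#'   (columns must match \code{survival$sample}).
#' @param survival data.frame with sample, time, event.
#' @param fdr_threshold BH cutoff for retaining pairs.
#' @return data.frame gene_a, gene_b, cox_beta, cox_p, fdr for the retained
#'   pairs, with attribute \code{skipped} (pair, reason) and
#'   \code{all_fits} (every converged fit before thresholding).
#' @export
univariate_cox_screen <- function(pairs, om, survival, fdr_threshold = 0.10) {
  idx <- match(survival$sample, colnames(om))
  if (anyNA(idx))
    stop("ordering matrix lacks columns for samples: ",
         paste(utils::head(survival$sample[is.na(idx)], 5), collapse = ", "))
  om <- om[, idx, drop = FALSE]
  if (sum(survival$event) < 10)
    warning("fewer than 10 events; the Cox screen will be unstable")
  y <- survival::Surv(survival$time, survival$event)
  n_pairs <- nrow(pairs)
  beta <- p <- rep(NA_real_, n_pairs)
  reason <- rep(NA_character_, n_pairs)
  for (j in seq_len(n_pairs)) {
    xj <- om[j, ]
    ok <- !is.na(xj)
    if (length(unique(xj[ok])) < 2) {
      reason[j] <- "degenerate covariate"
      next
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(y[ok] ~ xj[ok], ties = "breslow"),
        warning = function(w) {
          if (grepl("infinite|did not converge|beta may be infinite",
                    conditionMessage(w)))
            invokeRestart("muffleWarning")
          else invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit)) ||
        abs(stats::coef(fit)) > 15) {
      reason[j] <- "non-convergent fit"
      next
    }
    beta[j] <- unname(stats::coef(fit))
    p[j] <- summary(fit)$coefficients[1, "Pr(>|z|)"]
  }
  fitted <- which(is.na(reason))
  fdr <- rep(NA_real_, n_pairs)
  fdr[fitted] <- stats::p.adjust(p[fitted], method = "BH")
  all_fits <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                         cox_beta = beta, cox_p = p, fdr = fdr,
                         stringsAsFactors = FALSE)[fitted, , drop = FALSE]
  keep <- fitted[fdr[fitted] < fdr_threshold]
  out <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                    cox_beta = beta[keep], cox_p = p[keep], fdr = fdr[keep],
                    stringsAsFactors = FALSE)
  # orient: I[A > B] must carry the positive log hazard ratio
  flip <- out$cox_beta < 0
  if (any(flip)) {
    tmp <- out$gene_a[flip]
    out$gene_a[flip] <- out$gene_b[flip]
    out$gene_b[flip] <- tmp
    out$cox_beta[flip] <- -out$cox_beta[flip]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    pair = paste(pairs$gene_a, pairs$gene_b, sep = "|")[!is.na(reason)],
    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  attr(out, "all_fits") <- all_fits
  out
}

#' Classify patients by binomial majority vote over prognostic pairs
#'
#' Each usable pair (both genes measured, not tied) votes low risk iff
#' expr(gene_b) > expr(gene_a) — the ordering associated with better outcome.
#' A patient is called low risk when a one-sided binomial test finds
#' significantly more than half of the usable pairs voting low
#' (P(X >= low votes | n, 1/2) < alpha); otherwise the patient is high risk.
#' Ties abstain, shrinking n. Votes depend only on within-sample orderings,
#' so calls are invariant to per-sample monotone transforms.
#'
#' @param x An \code{\link{expr_set}} or expression matrix (samples are
#'   classified column-wise).
#' @param pairs Prognostic pair data.frame (gene_a, gene_b) oriented as by
#'   \code{\link{univariate_cox_screen}}.
#' @param alpha Vote-test significance level.
#' @return data.frame sample, n_votes, low_votes, p_value, risk_group.
#' @export
classify_patients <- function(x, pairs, alpha = 0.05) {
  X <- as_expr_matrix(x)
  present <- pairs$gene_a %in% rownames(X) & pairs$gene_b %in% rownames(X)
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("unclassifiable: no usable prognostic pairs for this dataset")
  om <- ordering_matrix(X, pairs)   # 1 = A > B (high-risk ordering)
  n_votes <- colSums(!is.na(om))
  low_votes <- colSums(om == 0, na.rm = TRUE)
  if (any(n_votes == 0))
    stop("unclassifiable: zero usable pairs for sample(s) ",
         paste(utils::head(colnames(X)[n_votes == 0], 5), collapse = ", "))
  p <- stats::pbinom(low_votes - 1, n_votes, 0.5, lower.tail = FALSE)
  data.frame(sample = colnames(X), n_votes = n_votes, low_votes = low_votes,
             p_value = p,
             risk_group = ifelse(p < alpha, "low", "high"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname classify_patients
#' @param values Named numeric vector of one patient's expression.
#' @export
classify_patient <- function(values, pairs, alpha = 0.05) {
  X <- matrix(values, ncol = 1, dimnames = list(names(values), "patient"))
  classify_patients(X, pairs, alpha = alpha)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time,event Follow-up times and event indicators (1 = event).
#' @param group Two-level grouping (e.g. risk_group).
#' @return List: chisq, df, p, fit (a \code{survfit} object with the
#'   product-limit curves), n per group.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("grouping error: need two non-empty groups")
  df <- data.frame(time = time, event = event, group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(chisq = chisq, df = 1L, p = p, fit = fit, n = table(group))
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher-risk patient fails
#' first; risk ties count 1/2. Risk may be a numeric score or a
#' \code{"high"}/\code{"low"} group label.
#'
#' @param time,event Survival outcome.
#' @param risk Numeric risk score (higher = worse) or high/low labels.
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(time, event, risk) {
  if (is.character(risk) || is.factor(risk)) {
    risk <- as.character(risk)
    if (!all(risk %in% c("high", "low")))
      stop("`risk` labels must be 'high'/'low'")
    risk <- as.numeric(risk == "high")
  }
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)
  if (fit$count["concordant"] + fit$count["discordant"] +
      fit$count["tied.x"] == 0)
    stop("undefined C-index: no comparable pairs")
  unname(fit$concordance)
}

#' Covariate-adjusted Cox regression of the risk-group signature
#'
#' Reports univariate and multivariate hazard ratios (Wald 95% CI and p) for
#' the risk group and the clinical covariates, the standard independence check
#' of a prognostic signature. Age and tumor size are dichotomized at
#' configurable cutpoints; grade uses the binary contrast I vs II-III.
#'
#' @param survival data.frame with sample, time, event and the clinical
#'   covariates.
#' @param risk_group "high"/"low" per sample (aligned with \code{survival}).
#' @param covariates Which clinical covariates to adjust for.
#' @param age_cut,size_cut Dichotomization cutpoints (years, cm).
#' @return data.frame term, hr, lo, hi, p, hr_adj, lo_adj, hi_adj, p_adj.
#' @export
multivariate_cox <- function(survival, risk_group,
                             covariates = c("age", "grade", "size"),
                             age_cut = 49, size_cut = 2) {
  stopifnot(length(risk_group) == nrow(survival))
  dat <- data.frame(time = survival$time, event = survival$event,
                    risk = as.numeric(risk_group == "high"))
  labels <- c(risk = "risk high vs low")
  if ("age" %in% covariates) {
    dat$age <- as.numeric(survival$age > age_cut)
    labels["age"] <- sprintf("age >%g vs <=%g", age_cut, age_cut)
  }
  if ("grade" %in% covariates) {
    dat$grade <- as.numeric(survival$grade >= 2)
    labels["grade"] <- "grade II-III vs I"
  }
  if ("size" %in% covariates) {
    dat$size <- as.numeric(survival$size > size_cut)
    labels["size"] <- sprintf("size >%g vs <=%g", size_cut, size_cut)
  }
  terms <- setdiff(colnames(dat), c("time", "event"))
  X <- as.matrix(dat[, terms, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    piv <- qr(cbind(1, X))$pivot
    stop("singular fit: collinear covariates among ",
         paste(terms, collapse = ", "))
  }
  wald_row <- function(fit, term) {
    s <- summary(fit)$coefficients
    ci <- summary(fit)$conf.int
    i <- grep(paste0("^", term), rownames(s))[1]
    c(hr = unname(ci[i, "exp(coef)"]), lo = unname(ci[i, "lower .95"]),
      hi = unname(ci[i, "upper .95"]), p = unname(s[i, "Pr(>|z|)"]))
  }
  y <- survival::Surv(dat$time, dat$event)
  uni <- t(vapply(terms, function(tm) {
    wald_row(survival::coxph(y ~ dat[[tm]], ties = "breslow"), "dat")
  }, numeric(4)))
  multi_fit <- survival::coxph(
    stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
    data = dat, ties = "breslow")
  mul <- t(vapply(terms, function(tm) wald_row(multi_fit, tm), numeric(4)))
  data.frame(term = unname(labels[terms]),
             hr = uni[, "hr"], lo = uni[, "lo"], hi = uni[, "hi"],
             p = uni[, "p"],
             hr_adj = mul[, "hr"], lo_adj = mul[, "lo"], hi_adj = mul[, "hi"],
             p_adj = mul[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}
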