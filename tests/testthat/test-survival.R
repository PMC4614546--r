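# Cox pair screen, binomial-vote classifier, Kaplan-Meier/log-rank,
# concordance and covariate adjustment.

test_that("Cox beta matches a grid-search partial-likelihood oracle", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(unname(coef(fit)), oracle_cox_beta(time, event, x),
               tolerance = 1e-6)
  # censored 6-subject case
  t2 <- c(2, 4, 5, 7, 9, 11); e2 <- c(1, 0, 1, 1, 0, 1); x2 <- c(1, 1, 0, 1, 0, 0)
  fit2 <- survival::coxph(survival::Surv(t2, e2) ~ x2, ties = "breslow")
  expect_equal(unname(coef(fit2)), oracle_cox_beta(t2, e2, x2),
               tolerance = 1e-6)
})

test_that("univariate screen skips degenerate pairs and retains planted ones", {
  set.seed(71)
  n <- 120
  z <- rbinom(n, 1, 0.4)
  om <- rbind(good = z,
              flat = rep(1, n),
              noise = rbinom(n, 1, 0.5))
  colnames(om) <- paste0("p", 1:n)
  time <- rexp(n, 0.05 * exp(1.5 * z))
  surv <- data.frame(sample = colnames(om), time = time, event = 1)
  pp <- univariate_cox_screen(
    data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3")),
    om, surv)
  expect_true("a1" %in% pp$gene_a)
  expect_false("a2" %in% c(pp$gene_a, pp$gene_b))
  skipped <- attr(pp, "skipped")
  expect_true(any(grepl("degenerate", skipped$reason)))
  expect_true(all(pp$cox_beta > 0))
})

test_that("null indicators are almost never retained by the FDR screen", {
  set.seed(72)
  n <- 100
  kept <- replicate(10, {
    om <- matrix(rbinom(30 * n, 1, 0.5), 30,
                 dimnames = list(NULL, paste0("p", 1:n)))
    surv <- data.frame(sample = colnames(om), time = rexp(n, 0.1), event = 1)
    prs <- data.frame(gene_a = paste0("a", 1:30), gene_b = paste0("b", 1:30))
    nrow(suppressWarnings(univariate_cox_screen(prs, om, surv)))
  })
  expect_lt(mean(kept), 1)
})

test_that("screen orientation flips negative-beta pairs", {
  set.seed(73)
  n <- 150
  z <- rbinom(n, 1, 0.5)
  om <- rbind(inv = 1 - z)          # indicator is protective as given
  colnames(om) <- paste0("p", 1:n)
  time <- rexp(n, 0.05 * exp(1.5 * z))
  surv <- data.frame(sample = colnames(om), time = time, event = 1)
  pp <- univariate_cox_screen(data.frame(gene_a = "a", gene_b = "b"), om, surv)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$gene_a, "b")     # swapped so that I[A > B] carries risk
  expect_gt(pp$cox_beta, 0)
})

test_that("binomial vote thresholds match exact binomial arithmetic", {
  # 17 pairs: 13 low votes -> low risk; 12 -> high risk
  pairs <- data.frame(gene_a = paste0("a", 1:17), gene_b = paste0("b", 1:17))
  mk_expr <- function(n_low) {
    v <- c(rep(1, 17), rep(0, 17))   # a-genes then b-genes
    names(v) <- c(pairs$gene_a, pairs$gene_b)
    v[pairs$gene_b[seq_len(n_low)]] <- 2   # b > a for the first n_low pairs
    v
  }
  c13 <- classify_patient(mk_expr(13), pairs)
  expect_equal(c13$risk_group, "low")
  expect_equal(c13$p_value, binom.test(13, 17, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(round(c13$p_value, 4), 0.0245)
  c12 <- classify_patient(mk_expr(12), pairs)
  expect_equal(c12$risk_group, "high")
  expect_equal(round(c12$p_value, 4), 0.0717)
  # unanimous low votes win for any n >= 5
  p5 <- pairs[1:5, ]
  v <- c(rep(1, 5), rep(2, 5))
  names(v) <- c(p5$gene_a, p5$gene_b)
  expect_equal(classify_patient(v, p5)$risk_group, "low")
})

test_that("ties abstain and shrink the vote count", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  v <- c(a1 = 1, b1 = 2, a2 = 3, b2 = 3)
  cl <- classify_patient(v, pairs)
  expect_equal(cl$n_votes, 1)
  expect_equal(cl$low_votes, 1)
  # all-tied patient is unclassifiable
  v2 <- c(a1 = 1, b1 = 1, a2 = 3, b2 = 3)
  expect_error(classify_patient(v2, pairs), "unclassifiable")
  expect_error(classify_patients(matrix(1, 1, 1, dimnames = list("zz", "s1")),
                                 pairs), "unclassifiable")
})

test_that("classification is invariant to per-sample monotone transforms", {
  set.seed(74)
  pairs <- data.frame(gene_a = paste0("a", 1:9), gene_b = paste0("b", 1:9))
  X <- matrix(rnorm(18 * 20, 8, 2), 18,
              dimnames = list(c(pairs$gene_a, pairs$gene_b), paste0("s", 1:20)))
  c1 <- classify_patients(X, pairs)
  c2 <- classify_patients(X^3, pairs)
  X3 <- sapply(seq_len(ncol(X)), function(j) 2^(X[, j] / 3) + j)  # per-sample
  dimnames(X3) <- dimnames(X)
  c3 <- classify_patients(X3, pairs)
  expect_identical(c1$risk_group, c2$risk_group)
  expect_identical(c1$risk_group, c3$risk_group)
})

test_that("log-rank matches hand risk-set arithmetic and its edge cases", {
  t6 <- c(3, 5, 7, 2, 6, 9); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("a", "a", "a", "b", "b", "b")
  lr <- km_logrank(t6, e6, g6)
  expect_equal(lr$chisq, oracle_logrank(t6, e6, g6), tolerance = 1e-10)
  # identical groups: statistic exactly 0
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(1, 6); g2 <- rep(c("a", "b"), each = 3)
  lr2 <- km_logrank(t2, e2, g2)
  expect_lt(lr2$chisq, 1e-12)
  expect_equal(lr2$p, 1, tolerance = 1e-10)
  expect_error(km_logrank(t6, e6, rep("a", 6)), "grouping error")
})

test_that("concordance matches exhaustive pair enumeration", {
  time <- c(2, 5, 7, 9, 12); event <- c(1, 1, 0, 1, 0)
  risk <- c(5, 4, 3, 2, 1)
  expect_equal(concordance_index(time, event, risk),
               oracle_cindex(time, event, risk), tolerance = 1e-12)
  expect_equal(concordance_index(time, event, risk), 1)   # perfectly ordered
  expect_equal(concordance_index(time, event, rep(1, 5)), 0.5)
  set.seed(75)
  for (i in 1:5) {
    tt <- rexp(8); ee <- rbinom(8, 1, 0.7); rr <- rnorm(8)
    if (sum(ee) == 0) next
    expect_equal(concordance_index(tt, ee, rr), oracle_cindex(tt, ee, rr),
                 tolerance = 1e-12)
  }
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)), "undefined C")
})

test_that("risk-group C-index accepts high/low labels", {
  time <- c(1, 2, 8, 9); event <- rep(1, 4)
  # 4 concordant cross-group pairs, 2 within-group risk ties at 1/2
  expect_equal(concordance_index(time, event, c("high", "high", "low", "low")),
               5 / 6, tolerance = 1e-12)
})

test_that("multivariate adjustment reduces to the univariate fit and flags collinearity", {
  set.seed(76)
  n <- 80
  risk <- sample(c("high", "low"), n, TRUE)
  sv <- data.frame(sample = paste0("p", 1:n),
                   time = rexp(n, 0.1 * ifelse(risk == "high", 3, 1)),
                   event = rbinom(n, 1, 0.8),
                   age = round(rnorm(n, 55, 8)),
                   grade = sample(1:3, n, TRUE),
                   size = round(rlnorm(n, log(2), 0.3), 1))
  tab <- multivariate_cox(sv, risk, covariates = character(0))
  uni <- survival::coxph(survival::Surv(sv$time, sv$event) ~ I(risk == "high"),
                         ties = "breslow")
  expect_equal(log(tab$hr[1]), unname(coef(uni)), tolerance = 1e-8)
  expect_equal(log(tab$hr_adj[1]), unname(coef(uni)), tolerance = 1e-8)
  # full table has one row per term, univariate + adjusted columns
  tab4 <- multivariate_cox(sv, risk)
  expect_equal(nrow(tab4), 4)
  expect_true(all(is.finite(tab4$hr)))
  # collinear design: age cut makes the age term identical to risk
  sv2 <- sv; sv2$age <- ifelse(risk == "high", 70, 40)
  expect_error(multivariate_cox(sv2, risk, covariates = "age", age_cut = 55),
               "singular fit")
})

test_that("independent covariates leave the adjusted risk HR near the crude HR", {
  set.seed(77)
  ratios <- replicate(5, {
    n <- 150
    z <- rbinom(n, 1, 0.4)
    sv <- data.frame(sample = paste0("p", 1:n),
                     time = rexp(n, 0.05 * exp(1.2 * z)),
                     event = 1,
                     age = round(rnorm(n, 55, 8)),
                     grade = sample(1:3, n, TRUE),
                     size = round(rlnorm(n, log(2), 0.3), 1))
    tab <- multivariate_cox(sv, ifelse(z == 1, "high", "low"))
    tab$hr_adj[1] / tab$hr[1]
  })
  expect_lt(abs(mean(log(ratios))), 0.15)
})
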