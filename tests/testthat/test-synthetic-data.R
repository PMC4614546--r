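# The simulation layer: cell-type profiles, purity mixtures, survival.

small_truth <- function(seed = 7, n_pairs = 4, ...) {
  simulate_ground_truth(
    n_genes = 60,
    class_counts = c(consistent_up = 6, consistent_down = 6,
                     epi_up = 4, epi_down = 4, str_up = 4, str_down = 4,
                     inconsistent_eu_sd = 5, inconsistent_ed_su = 5),
    n_pairs = n_pairs, n_prognostic = 2, seed = seed, ...)
}

test_that("ground truth partitions genes and builds valid pairs", {
  tr <- small_truth()
  g <- tr$genes
  expect_equal(nrow(g), 60)
  expect_true(all(!is.na(g$deg_class)))
  expect_true(all(abs(g$effect_epi[g$deg_class != "null"]) > 0 |
                    abs(g$effect_str[g$deg_class != "null"]) > 0))
  expect_true(all(g$effect_epi[g$deg_class == "null"] == 0))
  expect_true(all(tr$pairs$gene_a != tr$pairs$gene_b))
  # pair members exist and normal baseline orders B above A by the margin
  ia <- match(tr$pairs$gene_a, g$gene_id); ib <- match(tr$pairs$gene_b, g$gene_id)
  expect_equal(g$baseline[ib] - g$baseline[ia], rep(3, 4))
})

test_that("noise-free limit reproduces planted shifts in both compartments", {
  tr <- small_truth()
  prof <- simulate_celltype_profiles(tr, 4, 4, noise_sd = 1e-9, seed = 1)
  g <- tr$genes
  for (cls in c("consistent_up", "inconsistent_eu_sd")) {
    gi <- which(g$deg_class == cls & !g$is_pair_gene)[1]
    de <- mean(prof$epithelial$exprs[gi, 1:4]) - mean(prof$epithelial$exprs[gi, 5:8])
    ds <- mean(prof$stromal$exprs[gi, 1:4]) - mean(prof$stromal$exprs[gi, 5:8])
    expect_equal(de, g$effect_epi[gi], tolerance = 1e-6)
    expect_equal(ds, g$effect_str[gi], tolerance = 1e-6)
  }
})

test_that("null-gene sample mean obeys the law of large numbers", {
  tr <- small_truth()
  prof <- simulate_celltype_profiles(tr, 500, 500, noise_sd = 1, seed = 3)
  g <- tr$genes
  nulls <- which(g$deg_class == "null")[1:5]
  for (gi in nulls) {
    expect_lt(abs(mean(prof$epithelial$exprs[gi, ]) - g$baseline[gi]),
              4 * 1 / sqrt(1000))
  }
})

test_that("profile simulation validates its parameters and is reproducible", {
  tr <- small_truth()
  expect_error(simulate_celltype_profiles(tr, 0, 4), "invalid parameter")
  expect_error(simulate_celltype_profiles(tr, 4, 4, noise_sd = 0), "invalid parameter")
  a <- simulate_celltype_profiles(tr, 5, 5, seed = 42)
  b <- simulate_celltype_profiles(tr, 5, 5, seed = 42)
  expect_identical(a$epithelial$exprs, b$epithelial$exprs)
  expect_identical(a$stromal$exprs, b$stromal$exprs)
})

test_that("mixture endpoints recover the pure compartments", {
  tr <- small_truth()
  prof <- simulate_celltype_profiles(tr, 3, 3, noise_sd = 1, seed = 2)
  d1 <- mixture_design(3, 3, purity = rep(1, 3), noise_sd = 0,
                       normal_epi_fraction = 1, purity_floor = 0)
  m1 <- simulate_macro_dissected(prof$epithelial, prof$stromal, d1)
  expect_equal(m1$exprs, prof$epithelial$exprs, tolerance = 1e-12)
  d0 <- mixture_design(3, 3, purity = rep(0, 3), noise_sd = 0,
                       normal_epi_fraction = 0, purity_floor = 0)
  m0 <- simulate_macro_dissected(prof$epithelial, prof$stromal, d0)
  expect_equal(m0$exprs, prof$stromal$exprs, tolerance = 1e-12)
})

test_that("mixture formula matches the hand-computed linear-scale value", {
  E <- matrix(6, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  S <- matrix(8, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  grp <- rep(c("cancer", "normal"), each = 2)
  es <- suppressWarnings(expr_set(E, grp)); ss <- suppressWarnings(expr_set(S, grp))
  des <- mixture_design(2, 2, purity = c(0.5, 0.5), noise_sd = 0,
                        normal_epi_fraction = 0.5, purity_floor = 0)
  m <- simulate_macro_dissected(es, ss, des)
  expect_equal(unname(m$exprs[1, 1]), log2(0.5 * 64 + 0.5 * 256), tolerance = 1e-12)
  expect_equal(unname(m$exprs[1, 1]), 7.321928, tolerance = 1e-6)
})

test_that("macro expression is monotone in purity when epithelium exceeds stroma", {
  E <- matrix(9, 1, 2, dimnames = list("g1", c("s1", "s2")))
  S <- matrix(5, 1, 2, dimnames = list("g1", c("s1", "s2")))
  vals <- sapply(seq(0, 1, by = 0.1), function(p) log2(p * 2^9 + (1 - p) * 2^5))
  expect_true(all(diff(vals) > 0))
})

test_that("mixture validates alignment and the purity range", {
  tr <- small_truth()
  prof <- simulate_celltype_profiles(tr, 3, 3, seed = 2)
  bad <- prof$stromal
  bad$exprs <- bad$exprs[rev(seq_len(nrow(bad$exprs))), ]
  des <- mixture_design(3, 3, purity = rep(0.8, 3))
  expect_error(simulate_macro_dissected(prof$epithelial, bad, des), "alignment")
  expect_error(mixture_design(3, 3, purity = rep(0.5, 3)), "purity")
  expect_error(mixture_design(1, 3), "at least 2")
})

test_that("survival generator: censoring flag, hazard linkage, errors", {
  tr <- small_truth()
  prof <- simulate_celltype_profiles(tr, 30, 4, seed = 5)
  des <- mixture_design(30, 4, purity = rep(0.8, 30), noise_sd = 0.1)
  mx <- simulate_macro_dissected(prof$epithelial, prof$stromal, des)
  sv <- simulate_survival(mx, tr, baseline_hazard = 0.1, censor_rate = 0, seed = 6)
  expect_true(all(sv$event == 1))
  expect_true(all(sv$time > 0))
  expect_error(simulate_survival(mx, tr, baseline_hazard = 0), "invalid parameter")
})

test_that("planted pair hazard is recovered within 30% at moderate n", {
  tr <- simulate_ground_truth(
    n_genes = 12, class_counts = c(consistent_up = 1, consistent_down = 1),
    n_pairs = 1, n_prognostic = 1, prognostic_loghr = 1.5, seed = 11)
  hrs <- sapply(1:20, function(s) {
    co <- simulate_survival_cohort(tr, 400, p_aggressive = 0.5,
                                   censor_rate = 0, seed = 100 + s)
    om <- ordering_matrix(co$macro$exprs[, co$macro$group == "cancer"], tr$pairs)
    x <- om[1, ]
    fit <- survival::coxph(survival::Surv(co$survival$time, co$survival$event) ~ x,
                           ties = "breslow")
    exp(unname(coef(fit)))
  })
  expect_lt(abs(mean(hrs) - exp(1.5)) / exp(1.5), 0.30)
})

test_that("null pair weights leave log-rank at its nominal type-I level", {
  tr <- simulate_ground_truth(
    n_genes = 12, class_counts = c(consistent_up = 1, consistent_down = 1),
    n_pairs = 1, n_prognostic = 1, prognostic_loghr = 0, seed = 12)
  pvals <- sapply(1:60, function(s) {
    co <- simulate_survival_cohort(tr, 60, p_aggressive = 0.5,
                                   censor_rate = 0.1, seed = 300 + s)
    grp <- rep(c("a", "b"), length.out = 60)
    km_logrank(co$survival$time, co$survival$event, grp)$p
  })
  expect_gt(mean(pvals < 0.05), 0.0 - 1e-9)
  expect_lt(mean(pvals < 0.05), 0.18)   # ~5% expected, binomial slack at n=60
})

test_that("survival cohorts are deterministic and heterogeneous", {
  tr <- small_truth()
  a <- simulate_survival_cohort(tr, 40, seed = 9)
  b <- simulate_survival_cohort(tr, 40, seed = 9)
  expect_identical(a$macro$exprs, b$macro$exprs)
  expect_identical(a$survival, b$survival)
  expect_true(length(unique(a$aggressive)) == 2)
})
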