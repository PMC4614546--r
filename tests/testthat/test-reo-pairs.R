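# Within-sample ordering matrices, the Fisher reversal screen, pair-set
# intersection and cross-dataset checks.

pair_df <- function(a, b) data.frame(gene_a = a, gene_b = b,
                                     stringsAsFactors = FALSE)

test_that("ordering matrix encodes within-sample comparisons with NA ties", {
  X <- rbind(A = c(5, 7, 6), Ap = c(6, 8, 7), B = c(5, 9, 6))
  colnames(X) <- paste0("s", 1:3)
  om <- ordering_matrix(X, pair_df(c("A", "A"), c("Ap", "B")))
  expect_equal(unname(om[1, ]), c(0, 0, 0))        # dominated pair: A' = A + 1
  expect_equal(unname(om[2, ]), c(NA, 0, NA))      # exact ties recorded NA
  expect_error(ordering_matrix(X, pair_df("A", "zz")), "missing genes")
})

test_that("ordering matrix is invariant to per-sample monotone transforms", {
  set.seed(14)
  X <- matrix(rnorm(60, 8), 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  prs <- pair_df(c("g1", "g2", "g5"), c("g3", "g4", "g6"))
  om1 <- ordering_matrix(X, prs)
  om2 <- ordering_matrix(X^3, prs)                 # strictly increasing (X > 0)
  om3 <- ordering_matrix(apply(X, 2, function(c) exp(c / 2) + 1), prs)
  expect_identical(om1, om2)
  expect_identical(om1, om3)
})

test_that("3x3 toy ordering matches hand enumeration", {
  X <- rbind(a = c(1, 5, 3), b = c(2, 4, 3.5), c = c(0, 6, 1))
  colnames(X) <- paste0("s", 1:3)
  om <- ordering_matrix(X, pair_df(c("a", "a", "b"), c("b", "c", "c")))
  expect_equal(unname(om["a|b", ]), c(0, 1, 0))
  expect_equal(unname(om["a|c", ]), c(1, 0, 1))
  expect_equal(unname(om["b|c", ]), c(1, 0, 1))
})

test_that("Fisher screen p-values match the exact-table value and oracle", {
  # disease: 10 of 10 with a>b; normal: 0 of 8 -> p = 1/choose(18,10)
  om <- matrix(c(rep(1, 10), rep(0, 8)), 1,
               dimnames = list("A|B", paste0("s", 1:18)))
  grp <- rep(c("cancer", "normal"), c(10, 8))
  sc <- pair_fisher_screen(om, grp, pairs = pair_df("A", "B"))
  expect_equal(sc$fisher_p, 1 / choose(18, 10), tolerance = 1e-12)
  expect_equal(sc$fisher_p, oracle_fisher_2x2(10, 0, 0, 8), tolerance = 1e-12)
  expect_equal(sc$reversal_direction, "disease_favors_a")
  # identical frequencies in both groups: p = 1
  om2 <- matrix(c(rep(c(1, 0), 5), rep(c(1, 0), 4)), 1,
                dimnames = list("A|B", paste0("s", 1:18)))
  sc2 <- pair_fisher_screen(om2, grp, pairs = pair_df("A", "B"))
  expect_equal(sc2$fisher_p, 1, tolerance = 1e-12)
  expect_false(sc2$significant)
})

test_that("Fisher p agrees with the enumeration oracle on fuzzed tables", {
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    p_pkg <- stats::fisher.test(tab)$p.value
    p_orc <- oracle_fisher_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, p_orc, tolerance = 1e-10)
  }
})

test_that("all-tied pairs are excluded with a warning", {
  om <- matrix(NA_real_, 2, 10,
               dimnames = list(c("A|B", "C|D"), paste0("s", 1:10)))
  om[2, ] <- rep(c(1, 0), 5)
  grp <- rep(c("cancer", "normal"), each = 5)
  expect_warning(sc <- pair_fisher_screen(om, grp,
                                          pairs = pair_df(c("A", "C"), c("B", "D"))),
                 "all-tied")
  expect_equal(nrow(sc), 1)
  expect_equal(sc$gene_a, "C")
})

test_that("BH adjustment in the screen matches a step-up oracle", {
  set.seed(10)
  p <- runif(40)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
})

test_that("swapping the pair order flips the direction, not the p-value", {
  set.seed(11)
  X <- matrix(rnorm(200, 8), 2,
              dimnames = list(c("A", "B"), paste0("s", 1:100)))
  X[1, 1:50] <- X[1, 1:50] + 2
  grp <- rep(c("cancer", "normal"), each = 50)
  s1 <- pair_fisher_screen(ordering_matrix(X, pair_df("A", "B")), grp,
                           pairs = pair_df("A", "B"))
  s2 <- pair_fisher_screen(ordering_matrix(X, pair_df("B", "A")), grp,
                           pairs = pair_df("B", "A"))
  expect_equal(s1$fisher_p, s2$fisher_p, tolerance = 1e-12)
  expect_equal(s1$reversal_direction, "disease_favors_a")
  expect_equal(s2$reversal_direction, "disease_favors_b")
})

test_that("intersect_pairs keeps same-direction pairs and reports consistency", {
  sA <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                   fisher_p = 1e-4, fdr = 1e-3,
                   reversal_direction = c("disease_favors_a", "disease_favors_a",
                                          "disease_favors_b"),
                   significant = TRUE, stringsAsFactors = FALSE)
  sB <- sA
  got <- intersect_pairs(sA, sB)
  expect_equal(nrow(got$pairs), 3)
  expect_equal(got$consistency, 1)
  # opposite direction in screen B drops the pair but reports it
  sB2 <- sA; sB2$reversal_direction[1] <- "disease_favors_b"
  got2 <- intersect_pairs(sA, sB2)
  expect_equal(nrow(got2$pairs), 2)
  expect_equal(nrow(got2$dropped), 1)
  expect_equal(got2$consistency, 2 / 3)
  # disjoint screens give an empty set
  sB3 <- sA; sB3$gene_a <- c("x", "y", "z"); sB3$gene_b <- c("q", "r", "t")
  got3 <- intersect_pairs(sA, sB3)
  expect_equal(nrow(got3$pairs), 0)
  expect_equal(got3$n_overlap, 0)
})

test_that("intersect_pairs matches pairs written in either gene order", {
  sA <- data.frame(gene_a = "a", gene_b = "b", fisher_p = 1e-4, fdr = 1e-3,
                   reversal_direction = "disease_favors_a",
                   significant = TRUE, stringsAsFactors = FALSE)
  sB <- data.frame(gene_a = "b", gene_b = "a", fisher_p = 1e-4, fdr = 1e-3,
                   reversal_direction = "disease_favors_b",
                   significant = TRUE, stringsAsFactors = FALSE)
  got <- intersect_pairs(sA, sB)   # same reversal expressed both ways
  expect_equal(nrow(got$pairs), 1)
  expect_equal(got$consistency, 1)
})

test_that("planted reversal pairs are recovered with correct direction", {
  tr <- simulate_ground_truth(
    n_genes = 120,
    class_counts = c(consistent_up = 10, consistent_down = 10),
    n_pairs = 10, n_prognostic = 2, seed = 51)
  prof <- simulate_celltype_profiles(tr, 15, 15, noise_sd = 1, seed = 52)
  set.seed(53)
  decoys <- pair_df(sample(tr$genes$gene_id, 60, TRUE),
                    sample(tr$genes$gene_id, 60, TRUE))
  decoys <- decoys[decoys$gene_a != decoys$gene_b, ]
  uni <- unique(rbind(tr$pairs[, 1:2], decoys))
  scr_e <- pair_fisher_screen(ordering_matrix(prof$epithelial, uni),
                              prof$epithelial$group, pairs = uni)
  scr_s <- pair_fisher_screen(ordering_matrix(prof$stromal, uni),
                              prof$stromal$group, pairs = uni)
  cps <- intersect_pairs(scr_e, scr_s)
  key <- paste(cps$pairs$gene_a, cps$pairs$gene_b)
  planted <- paste(tr$pairs$gene_a, tr$pairs$gene_b)
  expect_gte(sum(planted %in% key), 9)
  # planted pairs reverse toward gene A in disease
  dir_ok <- cps$pairs$reversal_direction[match(planted, key)]
  expect_true(all(dir_ok == "disease_favors_a", na.rm = TRUE))
})

test_that("cross-dataset consistency is perfect against its own data", {
  tr <- simulate_ground_truth(
    n_genes = 80, class_counts = c(consistent_up = 5, consistent_down = 5),
    n_pairs = 8, n_prognostic = 2, seed = 61)
  prof <- simulate_celltype_profiles(tr, 15, 15, noise_sd = 1, seed = 62)
  uni <- tr$pairs[, 1:2]
  scr <- pair_fisher_screen(ordering_matrix(prof$epithelial, uni),
                            prof$epithelial$group, pairs = uni)
  ref <- scr[scr$significant, , drop = FALSE]
  cc <- cross_dataset_consistency(ref, prof$epithelial)
  expect_equal(cc$pair_num, nrow(ref))
  expect_equal(cc$direc_con_frac, 1)
})
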