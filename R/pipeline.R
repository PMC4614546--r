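#' Configuration for the full synthetic tissue-sampling study
#'
#' Bundles every parameter of the end-to-end pipeline: the ground-truth
#' generator, the cohort layout (two cell-type-specific discovery cohorts,
#' three macro-dissected discovery cohorts, one purity-annotated cohort, two
#' pooled training and two validation survival cohorts), and the stage
#' thresholds. Defaults are the study conditions used throughout the package:
#' cohort sizes mirror the original datasets, macro-dissected discovery
#' cohorts draw purity just above the 60% sampling threshold, the
#' purity-association cohort draws Uniform(0.6, 1), and normal breast tissue
#' is mixed stroma-rich (epithelial fraction 0.25).
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_genes,class_counts,delta,inconsistent_jitter,offset_sd,n_pairs,n_prognostic,pair_margin,prognostic_loghr
#'   Passed to \code{\link{simulate_ground_truth}} (\code{class_counts =
#'   NULL} uses that function's defaults).
#' @param noise_sd Compartment-profile noise sd (log2).
#' @param mix_noise_sd Post-mixing measurement noise sd (log2).
#' @param normal_epi_fraction Epithelial fraction of normal macro-dissected
#'   tissue.
#' @param lcm_sizes,macro_sizes Named list of c(n_cancer, n_normal) per
#'   discovery cohort.
#' @param purity_shape2 Beta shape for macro-cohort purity (see
#'   \code{\link{sample_macro_purity}}).
#' @param purity_cohort c(n_cancer, n_normal) of the purity-association
#'   cohort (purity Uniform(0.6, 1)).
#' @param surv_train_sizes,surv_val_sizes Patient counts of the two pooled
#'   training cohorts and the two validation cohorts.
#' @param p_aggressive,baseline_hazard,censor_rate Survival generator
#'   parameters.
#' @param n_decoy_pairs Random non-reversed pairs added to the screening
#'   universe.
#' @param fdr_deg,fdr_pair,fdr_cox Stage FDR thresholds.
#' @param vote_alpha Binomial vote significance level.
#' @param n_permutations Rank-products permutation count.
#' @param age_cut,size_cut,age_cut_val,size_cut_val Covariate cutpoints for
#'   the training and validation Cox adjustment tables.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1,
                            n_genes = 1100,
                            class_counts = NULL,
                            delta = 1.0,
                            inconsistent_jitter = 0.4,
                            offset_sd = 5.0,
                            n_pairs = 40,
                            n_prognostic = 15,
                            pair_margin = 3.0,
                            prognostic_loghr = 1.6,
                            noise_sd = 1.0,
                            mix_noise_sd = 0.2,
                            normal_epi_fraction = 0.25,
                            lcm_sizes = list(lcm1 = c(30, 22), lcm2 = c(15, 5)),
                            macro_sizes = list(m1 = c(28, 34), m2 = c(19, 27),
                                               m3 = c(67, 17)),
                            purity_shape2 = 40,
                            purity_cohort = c(376, 55),
                            surv_train_sizes = c(134, 85),
                            surv_val_sizes = c(209, 119),
                            p_aggressive = 0.30,
                            baseline_hazard = 0.05,
                            censor_rate = 0.12,
                            n_decoy_pairs = 1500,
                            fdr_deg = 0.10,
                            fdr_pair = 0.10,
                            fdr_cox = 0.10,
                            vote_alpha = 0.05,
                            n_permutations = 100,
                            age_cut = 49, size_cut = 2,
                            age_cut_val = 66, size_cut_val = 1.8) {
  cfg <- as.list(environment())
  stopifnot(fdr_deg > 0, fdr_deg < 1, fdr_pair > 0, fdr_pair <= 1,
            fdr_cox > 0, fdr_cox < 1, vote_alpha > 0, vote_alpha < 1)
  structure(cfg, class = "pipeline_config")
}

# Deterministic stage seeds below 2^31, derived from the master seed.
stage_seed <- function(cfg, k) (as.integer(cfg$seed) %% 1000000L) * 1000L + k

#' Run the full synthetic tissue-sampling study
#'
#' Executes, from one master seed: ground truth; cell-type-specific (LCM-like)
#' and macro-dissected discovery cohorts; rank-products DEG lists per cohort;
#' merged epithelial/stromal lists and the majority-vote macro-dissected list;
#' the consistent/inconsistent partition and its consistency scores against
#' the macro list; purity correlation fractions on a purity-annotated cohort;
#' the gene-pair reversal screens, consistent pair set and cross-dataset
#' validation; and the survival stage (univariate Cox pair selection,
#' binomial-vote risk groups, Kaplan-Meier/log-rank, concordance,
#' covariate-adjusted Cox, purity re-mixing stability).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param outdir Optional directory; when given, per-stage tables and a run
#'   manifest are written there (atomically).
#' @param quiet Suppress per-stage progress messages.
#' @return A nested list with elements \code{truth}, \code{config},
#'   \code{cohorts}, \code{deg}, \code{overlap}, \code{partition},
#'   \code{purity}, \code{pairs}, \code{prognosis}.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  cfg <- config
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("[%s] done in %.1fs", name, proc.time()[3] - t0)
    val
  }

  truth_args <- list(
    n_genes = cfg$n_genes, delta = cfg$delta,
    inconsistent_jitter = cfg$inconsistent_jitter, offset_sd = cfg$offset_sd,
    n_pairs = cfg$n_pairs, n_prognostic = cfg$n_prognostic,
    pair_margin = cfg$pair_margin, prognostic_loghr = cfg$prognostic_loghr,
    seed = stage_seed(cfg, 1))
  if (!is.null(cfg$class_counts)) truth_args$class_counts <- cfg$class_counts
  truth <- stage("truth", do.call(simulate_ground_truth, truth_args))

  lcm <- stage("lcm cohorts", {
    out <- list()
    for (i in seq_along(cfg$lcm_sizes)) {
      nn <- cfg$lcm_sizes[[i]]
      out[[names(cfg$lcm_sizes)[i]]] <- simulate_celltype_profiles(
        truth, nn[1], nn[2], noise_sd = cfg$noise_sd,
        seed = stage_seed(cfg, 10 + i))
    }
    out
  })

  macro <- stage("macro cohorts", {
    out <- list()
    for (i in seq_along(cfg$macro_sizes)) {
      nn <- cfg$macro_sizes[[i]]
      sd_i <- stage_seed(cfg, 20 + i)
      prof <- simulate_celltype_profiles(truth, nn[1], nn[2],
                                         noise_sd = cfg$noise_sd, seed = sd_i)
      pur <- sample_macro_purity(nn[1], cfg$purity_shape2)
      des <- mixture_design(nn[1], nn[2], purity = pur,
                            noise_sd = cfg$mix_noise_sd,
                            normal_epi_fraction = cfg$normal_epi_fraction)
      out[[names(cfg$macro_sizes)[i]]] <- simulate_macro_dissected(
        prof$epithelial, prof$stromal, des)
    }
    out
  })

  deg <- stage("DEG lists (rank products)", {
    d <- list()
    k <- 0
    for (nm in names(lcm)) {
      k <- k + 1
      d[[paste0("epi_", nm)]] <- deg_analysis(
        lcm[[nm]]$epithelial, fdr_threshold = cfg$fdr_deg,
        n_permutations = cfg$n_permutations,
        seed = stage_seed(cfg, 30 + k), origin = paste0("epi_", nm))
      k <- k + 1
      d[[paste0("str_", nm)]] <- deg_analysis(
        lcm[[nm]]$stromal, fdr_threshold = cfg$fdr_deg,
        n_permutations = cfg$n_permutations,
        seed = stage_seed(cfg, 30 + k), origin = paste0("str_", nm))
    }
    for (nm in names(macro)) {
      k <- k + 1
      d[[nm]] <- deg_analysis(macro[[nm]], fdr_threshold = cfg$fdr_deg,
                              n_permutations = cfg$n_permutations,
                              seed = stage_seed(cfg, 30 + k), origin = nm)
    }
    d
  })

  background <- truth$genes$gene_id   # all cohorts share one platform here

  lists <- stage("merge + majority + partition", {
    epi_names <- grep("^epi_", names(deg), value = TRUE)
    str_names <- grep("^str_", names(deg), value = TRUE)
    epithelial <- merge_union_drop_conflicts(deg[epi_names])
    stromal <- merge_union_drop_conflicts(deg[str_names])
    mnames <- names(cfg$macro_sizes)
    macro_degs <- majority_direction(deg[[mnames[1]]], deg[[mnames[2]]],
                                     deg[[mnames[3]]])
    part <- partition_consistent(epithelial, stromal)
    list(epithelial = epithelial, stromal = stromal, macro = macro_degs,
         consistent = part$consistent, inconsistent = part$inconsistent)
  })

  overlap <- stage("overlap/consistency statistics", {
    res <- list()
    epi_names <- grep("^epi_", names(deg), value = TRUE)
    str_names <- grep("^str_", names(deg), value = TRUE)
    res$epi_rep <- list(
      overlap = overlap_test(deg[[epi_names[1]]], deg[[epi_names[2]]], background),
      consistency = consistency_score(deg[[epi_names[1]]], deg[[epi_names[2]]]))
    res$str_rep <- list(
      overlap = overlap_test(deg[[str_names[1]]], deg[[str_names[2]]], background),
      consistency = consistency_score(deg[[str_names[1]]], deg[[str_names[2]]]))
    res$epi_vs_str <- overlap_test(lists$epithelial, lists$stromal, background)
    res$macro_vs_consistent <- list(
      overlap = overlap_test(lists$macro, lists$consistent, background),
      consistency = consistency_score(lists$macro, lists$consistent))
    res$macro_vs_inconsistent <- list(
      overlap = overlap_test(lists$macro, lists$inconsistent, background),
      consistency = consistency_score(lists$macro, lists$inconsistent))
    res
  })

  purity <- stage("purity association", {
    nn <- cfg$purity_cohort
    sd_p <- stage_seed(cfg, 40)
    prof <- simulate_celltype_profiles(truth, nn[1], nn[2],
                                       noise_sd = cfg$noise_sd, seed = sd_p)
    pur <- stats::runif(nn[1], 0.6, 1)
    des <- mixture_design(nn[1], nn[2], purity = pur,
                          noise_sd = cfg$mix_noise_sd,
                          normal_epi_fraction = cfg$normal_epi_fraction)
    mx <- simulate_macro_dissected(prof$epithelial, prof$stromal, des)
    assoc <- purity_correlation(mx)
    null_genes <- truth$genes$gene_id[truth$genes$deg_class == "null"]
    list(assoc = assoc,
         frac_consistent = fraction_significant(assoc, lists$consistent),
         frac_inconsistent = fraction_significant(assoc, lists$inconsistent),
         frac_null = fraction_significant(assoc, null_genes))
  })

  pairs <- stage("gene-pair reversal screens", {
    set.seed(stage_seed(cfg, 50))
    ids <- truth$genes$gene_id
    decoy_a <- sample(ids, cfg$n_decoy_pairs, replace = TRUE)
    decoy_b <- sample(ids, cfg$n_decoy_pairs, replace = TRUE)
    ok <- decoy_a != decoy_b
    universe <- unique(rbind(
      truth$pairs[, c("gene_a", "gene_b")],
      data.frame(gene_a = decoy_a[ok], gene_b = decoy_b[ok],
                 stringsAsFactors = FALSE)))
    lcm1 <- lcm[[1]]
    om_e <- ordering_matrix(lcm1$epithelial, universe)
    om_s <- ordering_matrix(lcm1$stromal, universe)
    screen_epi <- pair_fisher_screen(om_e, lcm1$epithelial$group,
                                     fdr_threshold = cfg$fdr_pair,
                                     pairs = universe)
    screen_str <- pair_fisher_screen(om_s, lcm1$stromal$group,
                                     fdr_threshold = cfg$fdr_pair,
                                     pairs = universe)
    cps <- intersect_pairs(screen_epi, screen_str)
    cross <- list(
      lcm2_epi = cross_dataset_consistency(cps, lcm[[2]]$epithelial),
      lcm2_str = cross_dataset_consistency(cps, lcm[[2]]$stromal))
    for (nm in names(macro))
      cross[[nm]] <- cross_dataset_consistency(cps, macro[[nm]])
    list(universe = universe, screen_epi = screen_epi,
         screen_str = screen_str, consistent_pairs = cps, cross = cross)
  })

  prognosis <- stage("prognostic signature", {
    tr <- list()
    for (i in seq_along(cfg$surv_train_sizes))
      tr[[i]] <- simulate_survival_cohort(
        truth, cfg$surv_train_sizes[i], p_aggressive = cfg$p_aggressive,
        noise_sd = cfg$noise_sd, mix_noise_sd = cfg$mix_noise_sd,
        normal_epi_fraction = cfg$normal_epi_fraction,
        baseline_hazard = cfg$baseline_hazard,
        censor_rate = cfg$censor_rate, seed = stage_seed(cfg, 60 + i))
    # pool training cohorts sample-wise; REO needs no cross-dataset scaling
    pool_expr <- NULL; pool_surv <- NULL
    for (i in seq_along(tr)) {
      Xi <- tr[[i]]$macro$exprs[, tr[[i]]$macro$group == "cancer", drop = FALSE]
      colnames(Xi) <- paste0("T", i, "_", colnames(Xi))
      si <- tr[[i]]$survival
      si$sample <- paste0("T", i, "_", si$sample)
      pool_expr <- cbind(pool_expr, Xi)
      pool_surv <- rbind(pool_surv, si)
    }
    om_tr <- ordering_matrix(pool_expr, pairs$consistent_pairs$pairs)
    prog_pairs <- univariate_cox_screen(pairs$consistent_pairs$pairs, om_tr,
                                        pool_surv,
                                        fdr_threshold = cfg$fdr_cox)
    evaluate <- function(expr_mat, surv, age_cut, size_cut) {
      cls <- classify_patients(expr_mat, prog_pairs, alpha = cfg$vote_alpha)
      stopifnot(identical(cls$sample, surv$sample))
      lr <- km_logrank(surv$time, surv$event, cls$risk_group)
      ci <- concordance_index(surv$time, surv$event, cls$risk_group)
      cox_tab <- tryCatch(
        multivariate_cox(surv, cls$risk_group, age_cut = age_cut,
                         size_cut = size_cut),
        error = function(e) NULL)
      list(classification = cls, logrank = lr, cindex = ci,
           cox_table = cox_tab,
           n_high = sum(cls$risk_group == "high"),
           n_low = sum(cls$risk_group == "low"))
    }
    train_eval <- evaluate(pool_expr, pool_surv, cfg$age_cut, cfg$size_cut)
    vals <- list()
    val_cohorts <- list()
    for (i in seq_along(cfg$surv_val_sizes)) {
      vc <- simulate_survival_cohort(
        truth, cfg$surv_val_sizes[i], p_aggressive = cfg$p_aggressive,
        noise_sd = cfg$noise_sd, mix_noise_sd = cfg$mix_noise_sd,
        normal_epi_fraction = cfg$normal_epi_fraction,
        baseline_hazard = cfg$baseline_hazard,
        censor_rate = cfg$censor_rate, seed = stage_seed(cfg, 70 + i))
      val_cohorts[[i]] <- vc
      Xi <- vc$macro$exprs[, vc$macro$group == "cancer", drop = FALSE]
      vals[[paste0("val", i)]] <- evaluate(
        Xi, vc$survival,
        if (i == 2) cfg$age_cut_val else cfg$age_cut,
        if (i == 2) cfg$size_cut_val else cfg$size_cut)
    }
    stability <- risk_call_stability(val_cohorts[[1]], prog_pairs,
                                     purities = c(0.6, 1.0),
                                     mix_noise_sd = cfg$mix_noise_sd,
                                     normal_epi_fraction = cfg$normal_epi_fraction,
                                     alpha = cfg$vote_alpha,
                                     seed = stage_seed(cfg, 80))
    list(pairs = prog_pairs, train = train_eval, val1 = vals$val1,
         val2 = vals$val2, stability = stability,
         train_survival = pool_surv)
  })

  res <- list(truth = truth, config = cfg,
              cohorts = list(lcm = lcm, macro = macro),
              deg = deg, overlap = overlap, partition = lists,
              purity = purity, pairs = pairs, prognosis = prognosis)
  if (!is.null(outdir)) write_pipeline_tables(res, outdir)
  say("pipeline complete in %.1fs", proc.time()[3] - t_all)
  invisible(res)
}

#' Risk-call stability under purity re-mixing
#'
#' Re-mixes a survival cohort's compartment profiles at two fixed purities
#' (fresh measurement noise each time), classifies both versions with the same
#' signature, and reports the fraction of patients whose risk call changes —
#' the operational test of the signature's insensitivity to tissue
#' composition.
#'
#' @param cohort A list with \code{epithelial}, \code{stromal} expr_sets
#'   (as from \code{\link{simulate_survival_cohort}}).
#' @param pairs Prognostic pair data.frame.
#' @param purities Two purity levels to compare.
#' @param mix_noise_sd,normal_epi_fraction Mixing parameters.
#' @param alpha Vote-test level.
#' @param seed Integer seed.
#' @return List: changed_fraction, n, calls (data.frame of both calls).
#' @export
risk_call_stability <- function(cohort, pairs, purities = c(0.6, 1.0),
                                mix_noise_sd = 0.2,
                                normal_epi_fraction = 0.5,
                                alpha = 0.05, seed = NULL) {
  stopifnot(length(purities) == 2)
  if (!is.null(seed)) set.seed(seed)
  grp <- cohort$epithelial$group
  nc <- sum(grp == "cancer"); nn <- sum(grp == "normal")
  classify_at <- function(p) {
    des <- mixture_design(nc, nn, purity = rep(p, nc),
                          noise_sd = mix_noise_sd,
                          normal_epi_fraction = normal_epi_fraction)
    mx <- simulate_macro_dissected(cohort$epithelial, cohort$stromal, des)
    X <- mx$exprs[, grp == "cancer", drop = FALSE]
    classify_patients(X, pairs, alpha = alpha)$risk_group
  }
  call1 <- classify_at(purities[1])
  call2 <- classify_at(purities[2])
  list(changed_fraction = mean(call1 != call2), n = nc,
       calls = data.frame(purity_lo = call1, purity_hi = call2,
                          stringsAsFactors = FALSE))
}

# Write the pipeline's main tables plus a manifest; all writes are atomic.
write_pipeline_tables <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_table_atomic(df, file.path(outdir, name))
  for (nm in names(res$deg)) w(res$deg[[nm]], paste0("degs_", nm, ".tsv"))
  w(res$partition$epithelial, "degs_epithelial_merged.tsv")
  w(res$partition$stromal, "degs_stromal_merged.tsv")
  w(res$partition$macro, "degs_macro_majority.tsv")
  w(res$partition$consistent, "degs_consistent.tsv")
  w(res$partition$inconsistent, "degs_inconsistent.tsv")
  w(res$purity$assoc, "purity_association.tsv")
  w(res$pairs$screen_epi, "pair_screen_epithelial.tsv")
  w(res$pairs$screen_str, "pair_screen_stromal.tsv")
  w(res$pairs$consistent_pairs$pairs, "consistent_gene_pairs.tsv")
  cross <- do.call(rbind, lapply(names(res$pairs$cross), function(nm) {
    cc <- res$pairs$cross[[nm]]
    data.frame(dataset = nm, pair_num = cc$pair_num, pair_05 = cc$pair_05,
               direc_con = cc$direc_con_n,
               direc_con_frac = cc$direc_con_frac)
  }))
  w(cross, "cross_dataset_consistency.tsv")
  w(res$prognosis$pairs, "prognostic_pairs.tsv")
  w(res$prognosis$train$classification, "risk_groups_training.tsv")
  if (!is.null(res$prognosis$train$cox_table))
    w(res$prognosis$train$cox_table, "cox_adjustment_training.tsv")
  summary_df <- data.frame(
    quantity = c("macro_vs_consistent_score", "macro_vs_inconsistent_score",
                 "frac_purity_sig_consistent", "frac_purity_sig_inconsistent",
                 "pair_consistency", "n_prognostic_pairs",
                 "train_logrank_p", "train_cindex",
                 "val1_logrank_p", "val1_cindex",
                 "val2_logrank_p", "val2_cindex",
                 "risk_call_change_fraction"),
    value = c(res$overlap$macro_vs_consistent$consistency$score,
              res$overlap$macro_vs_inconsistent$consistency$score,
              res$purity$frac_consistent, res$purity$frac_inconsistent,
              res$pairs$consistent_pairs$consistency,
              nrow(res$prognosis$pairs),
              res$prognosis$train$logrank$p, res$prognosis$train$cindex,
              res$prognosis$val1$logrank$p, res$prognosis$val1$cindex,
              res$prognosis$val2$logrank$p, res$prognosis$val2$cindex,
              res$prognosis$stability$changed_fraction))
  w(summary_df, "summary.tsv")
  cfg <- res$config
  manifest <- data.frame(parameter = names(cfg),
                         value = vapply(cfg, function(v)
                           paste(format(unlist(v)), collapse = ","), ""))
  w(manifest, "manifest.tsv")
  invisible(outdir)
}
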