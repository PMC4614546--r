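#!/usr/bin/env Rscript
# Stage 1: simulate the full synthetic study — one shared ground truth, two
# cell-type-specific (LCM-like) discovery cohorts, three macro-dissected
# discovery cohorts with purity near the 60% sampling threshold, one
# purity-annotated cohort, and four survival cohorts — and write everything
# as tab-delimited tables under results/study/ for the later stages.
#
#   Rscript analysis/01_simulate_cohorts.R [seed]

suppressPackageStartupMessages(library(reopair))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
cfg <- pipeline_config(seed = seed)
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ss <- function(k) (seed %% 1000000L) * 1000L + k
w <- function(df, name) {
  path <- file.path(out, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
w_es <- function(es, stem) {
  write_expression(es$exprs, file.path(out, paste0(stem, ".tsv")))
  ann <- data.frame(sample = colnames(es$exprs), group = as.character(es$group))
  if (!is.null(es$purity)) ann$purity <- es$purity
  w(ann, paste0(stem, "_samples.tsv"))
}

message("== ground truth (seed ", seed, ") ==")
truth <- simulate_ground_truth(
  n_genes = cfg$n_genes, delta = cfg$delta,
  inconsistent_jitter = cfg$inconsistent_jitter, offset_sd = cfg$offset_sd,
  n_pairs = cfg$n_pairs, n_prognostic = cfg$n_prognostic,
  pair_margin = cfg$pair_margin, prognostic_loghr = cfg$prognostic_loghr,
  seed = ss(1))
print(truth)
w(truth$genes, "truth_genes.tsv")
w(truth$pairs, "truth_pairs.tsv")

message("== cell-type-specific discovery cohorts ==")
for (i in seq_along(cfg$lcm_sizes)) {
  nm <- names(cfg$lcm_sizes)[i]; nn <- cfg$lcm_sizes[[i]]
  prof <- simulate_celltype_profiles(truth, nn[1], nn[2],
                                     noise_sd = cfg$noise_sd, seed = ss(10 + i))
  w_es(prof$epithelial, paste0(nm, "_epithelial"))
  w_es(prof$stromal, paste0(nm, "_stromal"))
  message(sprintf("  %s: %d cancer vs %d normal (matched compartments)",
                  nm, nn[1], nn[2]))
}

message("== macro-dissected discovery cohorts (purity near 0.6) ==")
for (i in seq_along(cfg$macro_sizes)) {
  nm <- names(cfg$macro_sizes)[i]; nn <- cfg$macro_sizes[[i]]
  prof <- simulate_celltype_profiles(truth, nn[1], nn[2],
                                     noise_sd = cfg$noise_sd, seed = ss(20 + i))
  pur <- sample_macro_purity(nn[1], cfg$purity_shape2)
  des <- mixture_design(nn[1], nn[2], purity = pur, noise_sd = cfg$mix_noise_sd,
                        normal_epi_fraction = cfg$normal_epi_fraction)
  mx <- simulate_macro_dissected(prof$epithelial, prof$stromal, des)
  w_es(mx, paste0(nm, "_macro"))
  message(sprintf("  %s: %d cancer (mean purity %.2f) vs %d normal",
                  nm, nn[1], mean(pur), nn[2]))
}

message("== purity-annotated cohort (purity Uniform[0.6, 1]) ==")
set.seed(ss(40))
nn <- cfg$purity_cohort
prof <- simulate_celltype_profiles(truth, nn[1], nn[2], noise_sd = cfg$noise_sd)
des <- mixture_design(nn[1], nn[2], purity = runif(nn[1], 0.6, 1),
                      noise_sd = cfg$mix_noise_sd,
                      normal_epi_fraction = cfg$normal_epi_fraction)
w_es(simulate_macro_dissected(prof$epithelial, prof$stromal, des),
     "purity_cohort_macro")

message("== survival cohorts ==")
sv_sizes <- c(train1 = cfg$surv_train_sizes[1], train2 = cfg$surv_train_sizes[2],
              val1 = cfg$surv_val_sizes[1], val2 = cfg$surv_val_sizes[2])
for (i in seq_along(sv_sizes)) {
  nm <- names(sv_sizes)[i]
  co <- simulate_survival_cohort(
    truth, sv_sizes[i], p_aggressive = cfg$p_aggressive,
    noise_sd = cfg$noise_sd, mix_noise_sd = cfg$mix_noise_sd,
    normal_epi_fraction = cfg$normal_epi_fraction,
    baseline_hazard = cfg$baseline_hazard, censor_rate = cfg$censor_rate,
    seed = ss(if (nm %in% c("train1", "train2")) 60 + i else 68 + i))
  w_es(co$macro, paste0(nm, "_macro"))
  w_es(co$epithelial, paste0(nm, "_epithelial"))
  w_es(co$stromal, paste0(nm, "_stromal"))
  w(co$survival, paste0(nm, "_survival.tsv"))
  message(sprintf("  %s: %d patients, %.0f%% events", nm, sv_sizes[i],
                  100 * mean(co$survival$event)))
}
w(data.frame(parameter = "seed", value = seed), "manifest.tsv")
message("cohort tables written under ", out)
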