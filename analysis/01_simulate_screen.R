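#!/usr/bin/env Rscript
# Simulate the full screening campaign with known ground truth:
#  - a 44-sample cohort profiled against a 30-drug panel (6-point titrations,
#    0.1-10000 nM, 5% CV noise, 2% outlier wells),
#  - IC20-primed double-combination plates for 13 samples,
#  - 4x4 + fixed-background triple-combination plates for the same samples.
# Writes canonical plate tables and ground-truth sidecars under
# results/plates/.

suppressPackageStartupMessages(library(exscreen))
seed <- 20260923
out <- "results/plates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
panel <- random_drug_panel(30)
panel$drug <- sprintf("drug%02d", 1:30)

noise <- noise_model(cv = 0.05, outlier_rate = 0.02, outlier_scale = 3,
                     seed = seed)
cohort <- simulate_cohort(44, panel, noise = noise)
write_plate_table(cohort$wells, file.path(out, "cohort_plates.csv"))
write_results(cohort$truth, file.path(out, "cohort_ground_truth.csv"))
message(sprintf("cohort: %d plates, %d wells, %d drugs",
                length(unique(cohort$wells$plate_id)), nrow(cohort$wells),
                nrow(panel)))

# Combination designs: the most potent drug primes, a weak partner titrates;
# triples add a mid-potency background at a fixed near-IC20 dose.
primer <- gt_profile("drug_primer", ic50 = 8, slope = 1)
partner <- gt_profile("drug_partner", ic50 = 500, slope = 1)
bgdrug <- gt_profile("drug_bg", ic50 = 20, slope = 1)

set.seed(seed + 1)
deltas <- runif(13, 0, 0.15)  # per-sample interaction strength
dbl <- list(); trp <- list(); truth_rows <- list()
for (i in 1:13) {
  inter <- interaction_model("bliss_shifted", delta = deltas[i])
  dbl[[i]] <- simulate_double_primed(
    primer, 2, partner, interaction = inter,
    noise = noise_model(cv = 0.05, seed = seed + 100 + i),
    plate_id = sprintf("PD%02d", i), sample_id = sprintf("S%02d", i))$wells
  trp[[i]] <- simulate_triple_matrix(
    gt_profile("drug_a", 50), gt_profile("drug_b", 200),
    background = bgdrug, background_conc = 4, interaction = inter,
    noise = noise_model(cv = 0.05, seed = seed + 200 + i),
    plate_id = sprintf("PT%02d", i), sample_id = sprintf("S%02d", i))$wells
  truth_rows[[i]] <- tibble::tibble(sample_id = sprintf("S%02d", i),
                                    true_delta = deltas[i])
}
write_plate_table(dplyr::bind_rows(dbl), file.path(out, "double_plates.csv"))
write_plate_table(dplyr::bind_rows(trp), file.path(out, "triple_plates.csv"))
write_results(dplyr::bind_rows(truth_rows),
              file.path(out, "combination_ground_truth.csv"))
message("combination plates written for 13 samples (double + triple designs)")
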