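#!/usr/bin/env Rscript
# Synthetic participants and task structure: each participant gets a
# private slice orientation (identical reference geometry, physically
# distinct stimuli), 24 mirror-paired stimulus images, counterbalanced
# 156-trial run sequences with homogenized viewpoint randomization, and a
# full pair-of-pairs judgment dataset aggregated to a percent-choice RDM.

suppressPackageStartupMessages(library(facersa))
dir.create("results", showWarnings = FALSE)

participants <- lapply(1:10, generate_participant)
write_participant(participants[[1]], "results/participant01")
cat("participant 1 written to results/participant01 (grid, 24 PNGs, manifest)\n")

ts <- generate_trial_sequence(12, extra_diagonal = 1, seed = 2)
rv <- randomize_viewpoints(ts, seed = 3)
cat(sprintf(
  "run sequence: %d trials; 12-cond transfer off-diag all 1, diag all 2: %s\n",
  length(ts$sequence),
  all(ts$transfer[!diag(12)] == 1) && all(diag(ts$transfer) == 2)))
cat(sprintf(
  "24-cond off-diagonal transfers in {0,1}: %s (accepted after %d tries)\n",
  all(rv$transfer24[!diag(24)] <= 1), rv$tries))
utils::write.table(
  data.frame(trial = seq_along(ts$sequence), face = ts$sequence,
             viewpoint = rv$viewpoints),
  "results/trial_sequence.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# perceptual data: judgments generated from the reference distances
ref12 <- reference_rdm(participants[[1]]$grid, viewpoints = FALSE)
jd <- simulate_pair_of_pairs(ref12, n_repeats = 1, tau = 0.3, seed = 4)
write_rdm(jd$rdm, "results/percent_choice_rdm.tsv")
cat(sprintf("pair-of-pairs: %d trials; percent-choice vs truth r = %.3f\n",
            jd$n_trials,
            rdm_correlation(jd$rdm, ref12)$r))
des12 <- build_rsa_predictors(participants[[1]]$grid, viewpoints = FALSE)
est <- fit_rsa_regression(jd$rdm, des12)$estimates
cat("percent-choice regression RSA estimates (ecc/dir/const):\n")
print(round(est, 3))
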