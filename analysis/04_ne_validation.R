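#!/usr/bin/env Rscript
# Calibration of the two LD-based effective-population-size estimators
# against forward Wright-Fisher simulations with a known truth (Ne = 100).
# The contemporary estimator sees 20 chromosomes x 50 unlinked-pair-rich
# markers; the historical estimator sees one 50 Mb / 0.5 Morgan chromosome
# whose binned LD decay carries the trajectory. Writes a summary TSV under
# results/ne_validation/.

suppressPackageStartupMessages(library(flockdiv))
dir.create("results/ne_validation", recursive = TRUE, showWarnings = FALSE)
seed <- 20240531
n_rep <- 5

message("Contemporary estimator (Waples-Do, random mating) ...")
cont <- vapply(seq_len(n_rep), function(k) {
  wf <- sim_wright_fisher(true_ne = 100, n_generations = 100, n_chrom = 20,
                          chrom_morgans = 0.5, chrom_length_bp = 50e6,
                          n_loci = 1000, sample_n = 50, seed = seed + k)
  contemporary_ne(wf)$ne
}, numeric(1))
message(sprintf("  estimates: %s  (median %.1f, truth 100)",
                paste(round(cont, 1), collapse = ", "), stats::median(cont)))

message("Historical estimator (Sved inversion, alpha = 1: no mutation) ...")
traj <- NULL
hist_med <- vapply(seq_len(n_rep), function(k) {
  wf <- sim_wright_fisher(true_ne = 100, n_generations = 200, n_chrom = 1,
                          chrom_morgans = 0.5, chrom_length_bp = 50e6,
                          n_loci = 500, sample_n = 50, seed = seed + 100 + k)
  tr <- suppressWarnings(historical_ne(wf, alpha = 1))
  if (k == 1) traj <<- tr
  stats::median(tr$ne[tr$t_generations <= 50])
}, numeric(1))
message(sprintf("  recent-bin medians: %s  (median %.1f, truth 100)",
                paste(round(hist_med, 1), collapse = ", "),
                stats::median(hist_med)))
message("  (a mild upward bias is expected: simulated r^2 sits 10-15% below")
message("   Sved's approximate curve, which the inversion translates into a")
message("   correspondingly high Ne; see the methods vignette)")

utils::write.table(
  data.frame(replicate = seq_len(n_rep), contemporary_ne = cont,
             historical_recent_ne = hist_med),
  "results/ne_validation/ne_recovery.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(traj, "results/ne_validation/trajectory_rep1.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Summary written under results/ne_validation/")
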