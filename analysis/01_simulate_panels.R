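#!/usr/bin/env Rscript
# Build the synthetic study panels used by the downstream analyses and
# write them as PLINK files with JSON truth sidecars under results/data/.
#
#  - barb_panel: one population of 24 individuals typed at chip density
#    (43,000 markers over 26 autosomes of 92 Mb, ~2.39 Gb total, ~55 kb
#    spacing), with a planted ~2.4 Mb homozygosity hotspot on chromosome
#    13 carried by 23/24 individuals. Chip density matters here because
#    the ROH criteria (250 kb max gap, 1 Mb min length, 15 SNPs) only
#    bind at realistic marker spacing.
#  - med_panel / barb_in_med: a six-population Balding-Nichols simulation
#    on one shared scaled-down map (2,100 markers; marker density is
#    irrelevant for F_ST/MDS/NJ). Populations 1-5 form the reference
#    panel (F = 0.02, 0.02, 0.05, 0.10, 0.15; 36 individuals each); the
#    sixth (F = 0.02, 24 individuals, relabelled BARB) is written
#    separately so the structure track exercises the merge path.

suppressPackageStartupMessages(library(flockdiv))
seed <- 20240531
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating single-population chip-density panel ...")
barb <- sim_structured(n_pops = 1, n_per_pop = 24, n_loci = 43000,
                       fst = 1e-6, anc_range = c(0.15, 0.85),
                       n_autosomes = 26, chrom_length_bp = 9.2e7,
                       missing_rate = 0.003, seed = seed)
# plant a ~2.4 Mb hotspot on chromosome 13: first gap-free 45-marker window
pos13 <- barb$markers$position_bp[barb$markers$chromosome == "13"]
region <- NULL
for (i in seq_len(length(pos13) - 44)) {
  w <- pos13[i:(i + 44)]
  if (max(diff(w)) <= 250000 && (w[45] - w[1]) >= 2e6) { region <- c(w[1], w[45]); break }
}
stopifnot(!is.null(region))
barb <- plant_roh(barb, chromosome = 13, start_bp = region[1],
                  end_bp = region[2], carrier_fraction = 23 / 24,
                  seed = seed + 1)
write_bed(barb, file.path(out, "barb_panel"))
truth <- attr(barb, "truth")
jsonlite::write_json(list(model = "structured+planted_roh",
                          hotspot = list(chromosome = "13",
                                         start_bp = region[1],
                                         end_bp = region[2],
                                         carriers = length(truth$carriers)),
                          seed = seed),
                     file.path(out, "barb_panel_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf("  24 individuals x %d markers; hotspot 13:%d-%d (%d carriers)",
                nrow(barb$markers), region[1], region[2], length(truth$carriers)))

message("Simulating multi-population structure panels on a shared map ...")
fst_levels <- c(0.02, 0.02, 0.05, 0.10, 0.15, 0.02)
six <- sim_structured(n_pops = 6, n_per_pop = c(rep(36, 5), 24),
                      n_loci = 2100, fst = fst_levels,
                      anc_range = c(0.1, 0.9), n_autosomes = 26,
                      chrom_length_bp = 9.2e7, missing_rate = 0.003,
                      seed = seed + 2)
is_ref <- six$samples$group %in% sprintf("POP%d", 1:5)
med <- subset_dataset(six, samples = which(is_ref))
barb_in_med <- subset_dataset(six, samples = which(!is_ref))
barb_in_med$samples$group <- "BARB"
barb_in_med$samples$family_id <- "BARB"
write_bed(med, file.path(out, "med_panel"))
write_bed(barb_in_med, file.path(out, "barb_in_med"))
jsonlite::write_json(list(model = "balding_nichols", fst = fst_levels,
                          groups = c(sprintf("POP%d", 1:5), "BARB"),
                          seed = seed + 2),
                     file.path(out, "med_panel_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf("  reference: %d individuals; merge target: %d individuals; %d markers",
                nrow(med$samples), nrow(barb_in_med$samples), nrow(med$markers)))
message("Done: panels under ", out)
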