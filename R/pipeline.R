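# One-call orchestration of the two analysis tracks: single-population
# characterization (QC -> diversity -> ROH -> length classes / F_ROH ->
# islands -> Ne) and multi-population structure (merge/subsample -> QC
# with pruning -> IBS/MDS -> F_ST/Reynolds -> NJ). Each returns a report
# bundle and optionally writes TSV/JSON/Newick outputs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Single-population genomic characterization
#'
#' @param ds genotype_dataset (one population).
#' @param qc `qc_config()`; pruning is off by default for this track.
#' @param roh `roh_params()`.
#' @param island_top_fraction top incidence fraction flagged as islands.
#' @param island_merge_gap_bp gap merging flagged SNPs into one island.
#' @param genome_length_bp F_ROH denominator.
#' @param ne_alpha,ne_bins,ne_dist_range historical-Ne settings.
#' @param ne_maf MAF screen for both Ne estimators.
#' @param features optional annotation intervals for island annotation.
#' @param out_dir optional directory; when given, per-stage TSV/JSON
#'   outputs are written there.
#' @return list: `qc_report`, `dataset`, `diversity`, `locus_stats`,
#'   `individual_f`, `segments`, `roh_summary`, `incidence`, `islands`,
#'   `island_annotation` (if features given), `ne_historical`,
#'   `ne_contemporary`.
#' @export
run_characterization <- function(ds, qc = qc_config(prune_enabled = FALSE),
                                 roh = roh_params(),
                                 island_top_fraction = 0.001,
                                 island_merge_gap_bp = 1e6,
                                 genome_length_bp = 2.4e9,
                                 ne_alpha = 2.2, ne_bins = 50,
                                 ne_dist_range = c(25e3, 25e6),
                                 ne_maf = 0.05,
                                 features = NULL, out_dir = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  qcres <- run_qc(ds, qc)
  d <- qcres$dataset
  div <- diversity_summary(d)
  ls <- locus_stats(d)
  fi <- individual_fis(d)
  segments <- detect_roh(d, roh)
  chroms <- unique(d$markers$chromosome)
  rs <- summarize_roh(segments, d$samples$individual_id, chroms,
                      genome_length_bp)
  inc <- snp_incidence(segments, d$markers, nrow(d$samples))
  isl <- island_scan(inc, island_top_fraction, island_merge_gap_bp)
  ann <- if (!is.null(features)) annotate_intervals(isl, features) else NULL
  ne_hist <- tryCatch(
    historical_ne(d, n_bins = ne_bins, dist_range = ne_dist_range,
                  alpha = ne_alpha, maf_min = ne_maf),
    error = function(e) { warning("historical Ne: ", conditionMessage(e)); NULL })
  ne_cont <- tryCatch(contemporary_ne(d, maf_crit = ne_maf),
    error = function(e) { warning("contemporary Ne: ", conditionMessage(e)); NULL })
  bundle <- list(qc_report = qcres$report, dataset = d, diversity = div,
                 locus_stats = ls, individual_f = fi, segments = segments,
                 roh_summary = rs, incidence = inc, islands = isl,
                 island_annotation = ann, ne_historical = ne_hist,
                 ne_contemporary = ne_cont)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(qcres$report, file.path(out_dir, "qc_report.tsv"))
    write_tsv(ls, file.path(out_dir, "locus_stats.tsv"))
    write_tsv(fi, file.path(out_dir, "individual_f.tsv"))
    write_tsv(segments, file.path(out_dir, "roh_segments.tsv"))
    write_tsv(rs$per_individual, file.path(out_dir, "roh_per_individual.tsv"))
    write_tsv(rs$per_chromosome, file.path(out_dir, "roh_per_chromosome.tsv"))
    write_tsv(rs$classes, file.path(out_dir, "roh_length_classes.tsv"))
    write_tsv(inc, file.path(out_dir, "snp_incidence.tsv"))
    write_tsv(isl, file.path(out_dir, "roh_islands.tsv"))
    if (!is.null(ne_hist)) write_tsv(ne_hist, file.path(out_dir, "ne_trajectory.tsv"))
    summary_json <- list(
      diversity = div,
      n_roh = rs$n_roh, l_roh_mb = rs$l_roh_mb, nc_roh = rs$nc_roh,
      lc_roh_mb = rs$lc_roh_mb, n_roh_total = rs$n_total,
      froh_mean = mean(rs$per_individual$froh),
      froh_sd = stats::sd(rs$per_individual$froh),
      ne_contemporary = if (!is.null(ne_cont)) ne_cont$ne else NA)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Multi-population structure analysis
#'
#' @param ds_list genotype_dataset, or list of them (merged on the common
#'   marker panel in order).
#' @param max_per_group per-group subsampling cap (NULL disables).
#' @param seed RNG seed for subsampling.
#' @param qc `qc_config()`; LD pruning is on by default for this track.
#' @param groups optional per-sample group labels overriding
#'   `samples$group` (evaluated after merge/subsample/QC).
#' @param mds_k MDS dimensions.
#' @param out_dir optional output directory.
#' @return list: `qc_report`, `dataset`, `ibs` (distance matrix), `mds`,
#'   `fst` (long table), `reynolds` (matrix), `tree` (phylo),
#'   `dropped_groups`.
#' @export
run_structure <- function(ds_list, max_per_group = 30, seed = 1,
                          qc = qc_config(prune_enabled = TRUE),
                          groups = NULL, mds_k = 2, out_dir = NULL) {
  if (inherits(ds_list, "genotype_dataset")) {
    ds <- ds_list
  } else {
    ds <- Reduce(merge_datasets, ds_list)
  }
  if (!is.null(max_per_group))
    ds <- subsample_per_group(ds, max_per_group, seed)
  qcres <- run_qc(ds, qc)
  d <- qcres$dataset
  glab <- if (is.null(groups)) d$samples$group
          else groups[match(d$samples$individual_id, ds$samples$individual_id)]
  tab <- table(glab)
  dropped <- names(tab)[tab < 2]
  if (length(dropped) > 0) {
    warning("group(s) reduced below 2 individuals dropped: ",
            paste(dropped, collapse = ", "))
    keep <- which(!(glab %in% dropped))
    d <- subset_dataset(d, samples = keep)
    glab <- glab[keep]
  }
  D <- ibs_distance(d)
  mds <- classical_mds(D, k = mds_k)
  if (length(unique(glab)) >= 2) {
    fst <- pairwise_fst(d, glab)
    RD <- fst_matrix(fst, "reynolds_d")
    tree <- if (nrow(RD) >= 3) neighbor_joining(RD) else NULL
  } else {
    warning("fewer than 2 groups remain; F_ST/Reynolds/NJ skipped")
    fst <- NULL; RD <- NULL; tree <- NULL
  }
  bundle <- list(qc_report = qcres$report, dataset = d, ibs = D, mds = mds,
                 fst = fst, reynolds = RD, tree = tree,
                 dropped_groups = dropped, groups = glab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(qcres$report, file.path(out_dir, "qc_report.tsv"))
    utils::write.table(D, file.path(out_dir, "ibs_distance.tsv"),
                       sep = "\t", quote = FALSE)
    coords <- data.frame(individual_id = rownames(mds$coords),
                         group = glab, mds$coords)
    write_tsv(coords, file.path(out_dir, "mds_coordinates.tsv"))
    if (!is.null(fst)) {
      write_tsv(fst, file.path(out_dir, "fst_pairs.tsv"))
      utils::write.table(RD, file.path(out_dir, "reynolds_distance.tsv"),
                         sep = "\t", quote = FALSE)
    }
    if (!is.null(tree))
      ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  }
  bundle
}
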