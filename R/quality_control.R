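# Quality-control cascade for SNP-array panels. Stage order mirrors
# PLINK 1.9: autosomes -> individual call rate (--mind) -> SNP call rate
# (--geno) -> MAF (--maf) -> optional windowed LD pruning
# (--indep-pairwise). Every stage logs removed/retained counts so the
# cascade telescopes.

#' QC configuration
#'
#' Defaults are the thresholds routinely applied to OvineSNP50-class panels:
#' MAF >= 0.05, SNP call rate >= 0.95, individual call rate >= 0.99,
#' 26 autosomes, and 50-SNP/10-step windows at r^2 > 0.2 for pruning.
#'
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param snp_call_min minimum per-SNP call rate (inclusive).
#' @param ind_call_min minimum per-individual call rate (inclusive).
#' @param autosome_count autosome labels retained are "1"..autosome_count.
#' @param prune_r2 r^2 above which one marker of a window pair is removed.
#' @param prune_window,prune_step window size and slide, in SNPs.
#' @param prune_enabled logical; run the LD-pruning stage?
#' @return list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, snp_call_min = 0.95,
                      ind_call_min = 0.99, autosome_count = 26,
                      prune_r2 = 0.2, prune_window = 50, prune_step = 10,
                      prune_enabled = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_call_min >= 0, snp_call_min <= 1,
            ind_call_min >= 0, ind_call_min <= 1,
            prune_r2 >= 0, prune_r2 <= 1,
            prune_window >= prune_step, prune_step >= 1)
  structure(list(maf_min = maf_min, snp_call_min = snp_call_min,
                 ind_call_min = ind_call_min, autosome_count = autosome_count,
                 prune_r2 = prune_r2, prune_window = prune_window,
                 prune_step = prune_step, prune_enabled = prune_enabled),
            class = "qc_config")
}

#' Keep markers on the first n autosomes
#'
#' Markers on chromosome "0", sex chromosomes or any label outside
#' `"1".."n_autosomes"` are removed.
#'
#' @param ds genotype_dataset.
#' @param n_autosomes number of autosomes (sheep: 26).
#' @return genotype_dataset.
#' @export
filter_autosomes <- function(ds, n_autosomes = 26) {
  keep <- ds$markers$chromosome %in% as.character(seq_len(n_autosomes))
  if (!any(keep)) warning("no autosomal markers remain")
  subset_dataset(ds, markers = which(keep))
}

#' Remove individuals with low call rate
#'
#' @param ds genotype_dataset.
#' @param threshold individual retained iff non-missing fraction >= threshold.
#' @return genotype_dataset.
#' @export
filter_individual_callrate <- function(ds, threshold = 0.99) {
  cr <- rowMeans(!is.na(ds$calls))
  subset_dataset(ds, samples = which(cr >= threshold))
}

#' Remove markers with low call rate
#'
#' @param ds genotype_dataset.
#' @param threshold marker retained iff non-missing fraction >= threshold.
#' @return genotype_dataset.
#' @export
filter_snp_callrate <- function(ds, threshold = 0.95) {
  cr <- colMeans(!is.na(ds$calls))
  subset_dataset(ds, markers = which(cr >= threshold))
}

#' Remove markers below a minor-allele-frequency threshold
#'
#' Frequencies are computed from non-missing calls of the current sample
#' set; the boundary is inclusive (maf == threshold is retained).
#'
#' @param ds genotype_dataset.
#' @param threshold minimum MAF.
#' @return genotype_dataset.
#' @export
filter_maf <- function(ds, threshold = 0.05) {
  af <- allele_freq(ds)
  keep <- !is.na(af$maf) & af$maf >= threshold
  subset_dataset(ds, markers = which(keep))
}

# r^2 between dosage columns of a call matrix; zero-variance pairs -> 0
dosage_r2_matrix <- function(calls) {
  suppressWarnings(r <- stats::cor(calls, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r * r
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window over the retained, position-sorted markers of
#' a chromosome, pairs with dosage-correlation r^2 above `r2_max` are broken
#' by removing the lower-MAF member (tie: the later-positioned marker).
#' Windows slide by `step`; passes repeat until no within-window pair
#' exceeds the threshold.
#'
#' @param ds genotype_dataset with position-sorted markers.
#' @param r2_max r^2 threshold (pairs with r^2 > r2_max are broken).
#' @param window,step window size and slide in SNPs.
#' @return character vector of retained marker ids.
#' @export
ld_prune <- function(ds, r2_max = 0.2, window = 50, step = 10) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!markers_sorted(ds$markers))
    stop("markers must be position-sorted within chromosomes before pruning")
  maf <- allele_freq(ds)$maf
  maf[is.na(maf)] <- 0
  retained <- rep(TRUE, nrow(ds$markers))
  for (ch in unique(ds$markers$chromosome)) {
    chr_idx <- which(ds$markers$chromosome == ch)
    repeat {
      removed_any <- FALSE
      cur <- chr_idx[retained[chr_idx]]
      if (length(cur) < 2) break
      starts <- seq(1, length(cur), by = step)
      for (s in starts) {
        w <- cur[s:min(s + window - 1, length(cur))]
        w <- w[retained[w]]            # earlier windows of this pass may have pruned
        if (length(w) < 2) next
        r2 <- dosage_r2_matrix(ds$calls[, w, drop = FALSE])
        repeat {
          r2[lower.tri(r2, diag = TRUE)] <- 0
          viol <- which(r2 > r2_max, arr.ind = TRUE)
          if (nrow(viol) == 0) break
          i <- viol[1, 1]; j <- viol[1, 2]
          drop_local <- if (maf[w[i]] < maf[w[j]]) i
                        else if (maf[w[j]] < maf[w[i]]) j
                        else j          # tie: later-positioned marker
          retained[w[drop_local]] <- FALSE
          removed_any <- TRUE
          r2 <- r2[-drop_local, -drop_local, drop = FALSE]
          w <- w[-drop_local]
          if (length(w) < 2) break
        }
      }
      if (!removed_any) break
    }
  }
  ds$markers$id[retained]
}

#' Run the full QC cascade
#'
#' Stages, in order: autosome filter, individual call rate, SNP call rate,
#' MAF (recomputed on the retained individuals), optional LD pruning.
#'
#' @param ds genotype_dataset.
#' @param config `qc_config()`.
#' @return list with `dataset` (filtered genotype_dataset) and `report`
#'   (data.frame, one row per stage, with marker/individual counts in and
#'   out; removed + retained telescope across stages).
#' @export
run_qc <- function(ds, config = qc_config()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(config, "qc_config"))
  stages <- list()
  log_stage <- function(name, before, after) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name,
      markers_in = nrow(before$markers), markers_out = nrow(after$markers),
      markers_removed = nrow(before$markers) - nrow(after$markers),
      individuals_in = nrow(before$samples), individuals_out = nrow(after$samples),
      individuals_removed = nrow(before$samples) - nrow(after$samples),
      stringsAsFactors = FALSE)
  }
  cur <- ds
  nxt <- filter_autosomes(cur, config$autosome_count)
  log_stage("autosomes", cur, nxt); cur <- nxt
  nxt <- filter_individual_callrate(cur, config$ind_call_min)
  log_stage("individual_call_rate", cur, nxt); cur <- nxt
  nxt <- filter_snp_callrate(cur, config$snp_call_min)
  log_stage("snp_call_rate", cur, nxt); cur <- nxt
  nxt <- filter_maf(cur, config$maf_min)
  log_stage("maf", cur, nxt); cur <- nxt
  if (isTRUE(config$prune_enabled)) {
    keep_ids <- ld_prune(cur, config$prune_r2, config$prune_window,
                         config$prune_step)
    nxt <- subset_dataset(cur, markers = match(keep_ids, cur$markers$id))
    log_stage("ld_prune", cur, nxt); cur <- nxt
  }
  list(dataset = cur, report = do.call(rbind, stages))
}
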