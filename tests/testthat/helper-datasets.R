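# Fixture builders used across the suite. All randomness is seeded by the
# caller so every test is reproducible.

# random dataset with arbitrary (non-HWE) genotype codes, for IO and
# bookkeeping tests
rand_ds <- function(n_ind, n_mark, n_chrom = 2, missing_rate = 0, seed = 1,
                    chrom_length_bp = 5e7) {
  set.seed(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), n_mark))
  pos <- numeric(n_mark)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(chrom_length_bp, k))
  }
  markers <- data.frame(id = sprintf("m%04d", seq_len(n_mark)),
                        chromosome = as.character(chrom), position_bp = pos,
                        allele_a = sample(c("A", "C"), n_mark, TRUE),
                        allele_b = sample(c("G", "T"), n_mark, TRUE),
                        stringsAsFactors = FALSE)
  calls <- matrix(sample(0:2, n_ind * n_mark, TRUE), n_ind, n_mark)
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  samples <- data.frame(family_id = "F1",
                        individual_id = sprintf("I%03d", seq_len(n_ind)),
                        group = "F1", stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls)
}

# dataset from an explicit call matrix and marker positions (one chromosome
# unless chrom given)
ds_from_calls <- function(calls, pos = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1e5
  if (is.null(chrom)) chrom <- rep("1", m)
  markers <- data.frame(id = sprintf("m%04d", seq_len(m)),
                        chromosome = as.character(chrom), position_bp = pos,
                        allele_a = "A", allele_b = "G",
                        stringsAsFactors = FALSE)
  samples <- data.frame(family_id = "F1",
                        individual_id = sprintf("I%03d", seq_len(nrow(calls))),
                        group = "F1", stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls)
}

# choose a plantable window on one chromosome: n_snp consecutive markers
# with every inter-marker gap within max_gap and span >= min_span, so the
# planted run cannot be split by the gap rule
pick_plant_region <- function(ds, chrom, n_snp = 40, max_gap = 250000,
                              min_span = 1.2e6) {
  pos <- ds$markers$position_bp[ds$markers$chromosome == as.character(chrom)]
  for (i in seq_len(length(pos) - n_snp + 1)) {
    w <- pos[i:(i + n_snp - 1)]
    if (max(diff(w)) <= max_gap && (w[n_snp] - w[1]) >= min_span)
      return(c(start_bp = w[1], end_bp = w[n_snp]))
  }
  stop("no plantable window on chromosome ", chrom)
}

# canonical comparable form of a segment table (row order independent)
seg_key <- function(seg) {
  if (nrow(seg) == 0) return(character(0))
  sort(sprintf("%s:%s:%d-%d:%d", seg$individual_id, seg$chromosome,
               seg$start_bp, seg$end_bp, seg$n_snp))
}
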