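# Independent ROH oracle: vectorized run enumeration via rle/split, used to
# cross-check the detector's state-machine scan. Supports the zero-tolerance
# setting (no opposite genotypes, no missing calls inside a run).
oracle_roh <- function(ds, params = roh_params()) {
  stopifnot(params$max_opposite == 0, params$max_missing == 0)
  out <- list()
  for (s in seq_len(nrow(ds$samples))) {
    for (ch in unique(ds$markers$chromosome)) {
      mi <- which(ds$markers$chromosome == ch)
      pos <- ds$markers$position_bp[mi]
      g <- ds$calls[s, mi]
      ok <- !is.na(g) & g != 1L
      if (isTRUE(params$strict_same_allele)) {
        # a 0<->2 transition also breaks a run
        brk_allele <- c(FALSE, ok[-1] & ok[-length(ok)] &
                          g[-1] != g[-length(g)])
      } else {
        brk_allele <- rep(FALSE, length(g))
      }
      brk_gap <- c(FALSE, diff(pos) > params$max_gap_bp)
      run_id <- cumsum((!ok) | brk_gap | brk_allele)
      for (r in split(which(ok), run_id[ok])) {
        n_snp <- length(r)
        len <- pos[max(r)] - pos[min(r)]
        if (n_snp >= params$min_snp && len >= params$min_length_bp)
          out[[length(out) + 1]] <- data.frame(
            individual_id = ds$samples$individual_id[s], chromosome = ch,
            start_bp = pos[min(r)], end_bp = pos[max(r)], n_snp = n_snp,
            length_bp = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(individual_id = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snp = integer(), length_bp = numeric()))
  do.call(rbind, out)
}

# independent re-check that one segment satisfies every criterion
segment_valid <- function(seg_row, ds, params) {
  mi <- which(ds$markers$chromosome == seg_row$chromosome &
              ds$markers$position_bp >= seg_row$start_bp &
              ds$markers$position_bp <= seg_row$end_bp)
  s <- match(seg_row$individual_id, ds$samples$individual_id)
  g <- ds$calls[s, mi]
  pos <- ds$markers$position_bp[mi]
  all(!is.na(g)) && all(g != 1L) &&
    all(diff(pos) <= params$max_gap_bp) &&
    length(g) >= params$min_snp &&
    (seg_row$end_bp - seg_row$start_bp) >= params$min_length_bp &&
    seg_row$n_snp == length(g)
}
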