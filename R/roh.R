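# Runs of homozygosity: consecutive-runs detection, length classes,
# per-individual / per-chromosome summaries, and the genomic inbreeding
# coefficient F_ROH. Segment length is end_bp - start_bp throughout.

#' ROH detection parameters
#'
#' Defaults are the consecutive-runs criteria used for OvineSNP50-class
#' panels: at least 15 SNPs, no heterozygous and no missing call inside a
#' run, inter-SNP gaps of at most 250 kb, minimum run length 1 Mb.
#'
#' @param min_snp minimum SNPs in a run.
#' @param max_opposite heterozygous calls tolerated inside a run.
#' @param max_missing missing calls tolerated inside a run.
#' @param max_gap_bp maximum gap between consecutive run SNPs.
#' @param min_length_bp minimum run length (end - start).
#' @param strict_same_allele if TRUE a run must consist of a single
#'   homozygous genotype (a 0 <-> 2 transition ends it); default FALSE
#'   treats both homozygotes as run members and only heterozygotes as
#'   opposite genotypes.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_snp = 15, max_opposite = 0, max_missing = 0,
                       max_gap_bp = 250000, min_length_bp = 1e6,
                       strict_same_allele = FALSE) {
  stopifnot(min_snp >= 1, max_opposite >= 0, max_missing >= 0,
            max_gap_bp >= 0, min_length_bp >= 1)
  structure(list(min_snp = min_snp, max_opposite = max_opposite,
                 max_missing = max_missing, max_gap_bp = max_gap_bp,
                 min_length_bp = min_length_bp,
                 strict_same_allele = strict_same_allele),
            class = "roh_params")
}

# runs for one individual on one chromosome; returns data.frame rows
scan_chromosome <- function(g, pos, params) {
  n <- length(g)
  hom <- !is.na(g) & g != 1L
  out <- list()
  emit <- function(i, j, n_hom) {
    len <- pos[j] - pos[i]
    if (n_hom >= params$min_snp && len >= params$min_length_bp)
      out[[length(out) + 1]] <<- c(start_bp = pos[i], end_bp = pos[j],
                                   n_snp = n_hom)
  }
  i <- 1L
  while (i <= n) {
    if (!hom[i]) { i <- i + 1L; next }
    # grow a run from i, tolerating up to max_opposite/max_missing breaks
    j <- i
    last_hom <- i
    n_hom <- 1L
    n_opp <- 0L
    n_mis <- 0L
    while (j < n) {
      nxt <- j + 1L
      if (pos[nxt] - pos[j] > params$max_gap_bp) break
      if (is.na(g[nxt])) {
        if (n_mis + 1L > params$max_missing) break
        n_mis <- n_mis + 1L
      } else if (g[nxt] == 1L) {
        if (n_opp + 1L > params$max_opposite) break
        n_opp <- n_opp + 1L
      } else if (params$strict_same_allele && g[nxt] != g[last_hom]) {
        break
      } else {
        n_hom <- n_hom + 1L
        last_hom <- nxt
      }
      j <- nxt
    }
    emit(i, last_hom, n_hom)
    i <- last_hom + 1L
  }
  if (length(out) == 0) return(NULL)
  as.data.frame(do.call(rbind, out))
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Per individual and chromosome, maximal stretches of homozygous
#' non-missing calls with inter-marker gaps at most `max_gap_bp` are
#' located; a heterozygote, a missing call or an oversized gap ends a run
#' (unless within the configured tolerances). Runs with at least `min_snp`
#' SNPs and length (end - start) at least `min_length_bp` are reported.
#'
#' @param ds genotype_dataset, autosomal, position-sorted.
#' @param params `roh_params()`.
#' @return data.frame with columns `individual_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snp`, `length_bp`.
#' @export
detect_roh <- function(ds, params = roh_params()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(params, "roh_params"))
  if (!markers_sorted(ds$markers))
    stop("markers must be position-sorted within chromosomes")
  res <- list()
  chrs <- unique(ds$markers$chromosome)
  for (ch in chrs) {
    mi <- which(ds$markers$chromosome == ch)
    pos <- ds$markers$position_bp[mi]
    for (s in seq_len(nrow(ds$samples))) {
      runs <- scan_chromosome(ds$calls[s, mi], pos, params)
      if (!is.null(runs)) {
        runs$individual_id <- ds$samples$individual_id[s]
        runs$chromosome <- ch
        res[[length(res) + 1]] <- runs
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(individual_id = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snp = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  seg <- do.call(rbind, res)
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg[, c("individual_id", "chromosome", "start_bp", "end_bp", "n_snp",
          "length_bp")]
}

#' Bin ROH segments into the standard length classes
#'
#' Classes are left-closed, right-open: \[1,2), \[2,4), \[4,8), \[8,16) and
#' \[16, Inf) Mb.
#'
#' @param segments data.frame from [detect_roh()].
#' @return data.frame with `class`, `count`, `percent`.
#' @export
classify_lengths <- function(segments) {
  breaks <- c(1, 2, 4, 8, 16, Inf)
  labels <- c("1-2", "2-4", "4-8", "8-16", ">16")
  mb <- segments$length_bp / 1e6
  cl <- cut(mb, breaks = breaks, labels = labels, right = FALSE)
  counts <- as.integer(table(cl))
  total <- sum(counts)
  data.frame(class = labels, count = counts,
             percent = if (total > 0) 100 * counts / total else rep(0, 5),
             stringsAsFactors = FALSE)
}

#' Summarize ROH segments
#'
#' @param segments data.frame from [detect_roh()].
#' @param individuals character vector of all individual ids (so that
#'   zero-ROH individuals contribute 0 to the N_ROH mean).
#' @param chromosomes character vector of all chromosome labels analysed
#'   (zero-ROH chromosomes contribute 0 to NC_ROH).
#' @param genome_length_bp total autosomal genome length for F_ROH.
#' @return list with `n_roh` (`c(mean, sd)` of per-individual counts),
#'   `l_roh_mb` (mean, sd of segment lengths, Mb), `nc_roh` (mean, sd of
#'   per-chromosome counts), `lc_roh_mb` (mean, sd of per-chromosome mean
#'   lengths, over chromosomes carrying at least one segment), `n_total`,
#'   `classes` (from [classify_lengths()]), `per_individual` (count, total
#'   length, F_ROH per individual), `per_chromosome`.
#' @export
summarize_roh <- function(segments, individuals, chromosomes,
                          genome_length_bp = 2.4e9) {
  cnt <- table(factor(segments$individual_id, levels = individuals))
  len_per_ind <- tapply(segments$length_bp,
                        factor(segments$individual_id, levels = individuals),
                        sum, default = 0)
  per_ind <- data.frame(individual_id = individuals,
                        n_roh = as.integer(cnt),
                        total_length_bp = as.numeric(len_per_ind),
                        froh = as.numeric(len_per_ind) / genome_length_bp,
                        row.names = NULL, stringsAsFactors = FALSE)
  chr_f <- factor(segments$chromosome, levels = chromosomes)
  chr_cnt <- table(chr_f)
  chr_mean_len <- tapply(segments$length_bp / 1e6, chr_f, mean)
  per_chr <- data.frame(chromosome = chromosomes,
                        n_roh = as.integer(chr_cnt),
                        mean_length_mb = as.numeric(chr_mean_len),
                        row.names = NULL, stringsAsFactors = FALSE)
  ms <- function(x) c(mean = mean(x), sd = stats::sd(x))
  list(n_roh = ms(per_ind$n_roh),
       l_roh_mb = if (nrow(segments) > 0) ms(segments$length_bp / 1e6)
                  else c(mean = NA_real_, sd = NA_real_),
       nc_roh = ms(per_chr$n_roh),
       lc_roh_mb = ms(stats::na.omit(per_chr$mean_length_mb)),
       n_total = nrow(segments),
       classes = classify_lengths(segments),
       per_individual = per_ind,
       per_chromosome = per_chr)
}

#' Genomic inbreeding coefficient F_ROH for one individual
#'
#' Total ROH length of the individual divided by the autosomal genome
#' length (~2.4 Gb in sheep).
#'
#' @param segments data.frame from [detect_roh()].
#' @param individual individual id.
#' @param genome_length_bp denominator, default 2.4e9.
#' @return numeric fraction in \[0, 1\].
#' @export
froh <- function(segments, individual, genome_length_bp = 2.4e9) {
  seg <- segments[segments$individual_id == individual, , drop = FALSE]
  if (nrow(seg) > 1) {
    o <- order(seg$chromosome, seg$start_bp)
    seg <- seg[o, , drop = FALSE]
    same <- seg$chromosome[-1] == seg$chromosome[-nrow(seg)]
    if (any(same & seg$start_bp[-1] < seg$end_bp[-nrow(seg)]))
      stop("overlapping ROH segments for individual ", individual)
  }
  sum(seg$length_bp) / genome_length_bp
}
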