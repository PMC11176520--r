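# Effective population size from linkage disequilibrium.
#
# Historical trajectory: intrachromosomal pairs are binned by physical
# distance, mean r^2 per bin is corrected for finite sample size
# (r2_adj = mean r^2 - 1/n) and inverted through the Sved-type drift
# expectation E[r^2] ~ 1/(alpha + 4 Ne c), giving
# Ne(c) = (1/(4c)) (1/r2_adj - alpha) at time t = 1/(2c) generations ago.
# alpha = 1 is the no-mutation form, alpha = 2 Sved's original, alpha = 2.2
# the mutation-adjusted constant.
#
# Contemporary Ne: unlinked pairs (markers on different chromosomes),
# Waples & Do's bias-corrected LD method under random mating, with the
# sample-size regimes split at harmonic-mean S = 30:
#   S >= 30: E[r^2_sample] = 1/S + 3.19/S^2
#            Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')
#   S <  30: E[r^2_sample] = 0.0018 + 0.907/S + 4.44/S^2
#            Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')
# where r2' = mean r^2 - E[r^2_sample]; r2' <= 0 or a negative discriminant
# yields an infinite estimate (no detectable drift signal).

#' Pairwise dosage r^2
#'
#' Squared Pearson correlation of 0/1/2 genotype dosages over the samples
#' non-missing at both markers (the unphased Burrows-composite equivalent).
#' Pairs involving a zero-variance marker are skipped.
#'
#' @param ds genotype_dataset.
#' @param pairs two-column integer matrix of marker indices; default all
#'   distinct pairs.
#' @return data.frame `i`, `j`, `r2`, `n` (shared sample count),
#'   `distance_bp` (NA for interchromosomal pairs).
#' @export
pairwise_r2 <- function(ds, pairs = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  m <- nrow(ds$markers)
  if (m < 2) stop("need at least 2 markers")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(m, 2))
  }
  r2 <- numeric(nrow(pairs))
  n <- integer(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- ds$calls[, pairs[k, 1]]
    y <- ds$calls[, pairs[k, 2]]
    ok <- !is.na(x) & !is.na(y)
    n[k] <- sum(ok)
    if (n[k] < 2) next
    vx <- stats::var(x[ok]); vy <- stats::var(y[ok])
    if (vx == 0 || vy == 0) next
    r2[k] <- stats::cor(x[ok], y[ok])^2
    keep[k] <- TRUE
  }
  same_chr <- ds$markers$chromosome[pairs[, 1]] == ds$markers$chromosome[pairs[, 2]]
  dist <- ifelse(same_chr,
                 abs(ds$markers$position_bp[pairs[, 1]] -
                     ds$markers$position_bp[pairs[, 2]]), NA_real_)
  data.frame(i = pairs[, 1], j = pairs[, 2], r2 = r2, n = n,
             distance_bp = dist)[keep, , drop = FALSE]
}

# all intrachromosomal (distance, r2, n) pairs within a distance range,
# computed chromosome by chromosome with matrix correlation
intra_chrom_r2 <- function(ds, min_dist, max_dist) {
  out_d <- list(); out_r <- list(); out_n <- list()
  for (ch in unique(ds$markers$chromosome)) {
    mi <- which(ds$markers$chromosome == ch)
    if (length(mi) < 2) next
    calls <- ds$calls[, mi, drop = FALSE]
    v <- apply(calls, 2, stats::var, na.rm = TRUE)
    usable <- !is.na(v) & v > 0
    mi <- mi[usable]
    if (length(mi) < 2) next
    calls <- ds$calls[, mi, drop = FALSE]
    suppressWarnings(r <- stats::cor(calls, use = "pairwise.complete.obs"))
    nmat <- crossprod(!is.na(calls))
    pos <- ds$markers$position_bp[mi]
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    sel <- ut & d >= min_dist & d <= max_dist & is.finite(r)
    out_d[[length(out_d) + 1]] <- d[sel]
    out_r[[length(out_r) + 1]] <- (r * r)[sel]
    out_n[[length(out_n) + 1]] <- nmat[sel]
  }
  list(distance_bp = unlist(out_d), r2 = unlist(out_r), n = unlist(out_n))
}

#' Historical effective population size from binned LD decay
#'
#' @param ds genotype_dataset (autosomal, QC'd).
#' @param n_bins number of equal-width distance bins.
#' @param dist_range physical distance range (bp) over which pairs enter.
#' @param alpha Sved constant: 1 (no mutation), 2, or 2.2 (mutation).
#' @param min_pairs bins with fewer pairs are dropped.
#' @param cm_per_mb linear map scaling; recombination fraction
#'   `c = distance_bp * cm_per_mb * 1e-8`.
#' @param maf_min markers below this MAF are excluded first.
#' @return data.frame (one row per retained bin): `dist_lo_bp`,
#'   `dist_hi_bp`, `c`, `t_generations`, `n_pairs`, `r2_mean`, `r2_adj`,
#'   `ne`. Bins with `r2_adj <= 0` are dropped with a warning.
#' @export
historical_ne <- function(ds, n_bins = 50, dist_range = c(25e3, 25e6),
                          alpha = 2.2, min_pairs = 50, cm_per_mb = 1,
                          maf_min = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (maf_min > 0) {
    af <- allele_freq(ds)
    ds <- subset_dataset(ds, markers = which(!is.na(af$maf) & af$maf >= maf_min))
  }
  pr <- intra_chrom_r2(ds, dist_range[1], dist_range[2])
  if (length(pr$r2) == 0) stop("no usable intrachromosomal pairs in range")
  edges <- seq(dist_range[1], dist_range[2], length.out = n_bins + 1)
  bin <- cut(pr$distance_bp, breaks = edges, include.lowest = TRUE)
  n_samples <- nrow(ds$samples)
  rows <- list()
  dropped <- 0
  for (b in seq_len(n_bins)) {
    sel <- as.integer(bin) == b
    np <- sum(sel, na.rm = TRUE)
    if (np < min_pairs) next
    r2m <- mean(pr$r2[sel], na.rm = TRUE)
    r2_adj <- r2m - 1 / n_samples
    mid <- (edges[b] + edges[b + 1]) / 2
    cc <- mid * cm_per_mb * 1e-8
    if (r2_adj <= 0) { dropped <- dropped + 1; next }
    rows[[length(rows) + 1]] <- data.frame(
      dist_lo_bp = edges[b], dist_hi_bp = edges[b + 1], c = cc,
      t_generations = 1 / (2 * cc), n_pairs = np, r2_mean = r2m,
      r2_adj = r2_adj, ne = (1 / (4 * cc)) * (1 / r2_adj - alpha))
  }
  if (dropped > 0)
    warning(dropped, " bin(s) dropped: adjusted r^2 <= 0")
  if (length(rows) == 0) stop("no bins with enough pairs and positive signal")
  do.call(rbind, rows)
}

# Waples & Do random-mating closed forms; exported mostly for testing
# against hand-evaluated arithmetic.
#' Contemporary Ne from a drift r^2 signal (random mating coefficients)
#'
#' @param r2_drift mean r^2 minus the expected sampling contribution.
#' @param S harmonic-mean sample size (selects the regime at S = 30).
#' @return Ne point estimate; `Inf` when `r2_drift <= 0` or the
#'   discriminant is negative.
#' @export
waples_ne <- function(r2_drift, S) {
  if (is.na(r2_drift) || r2_drift <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2_drift
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- 0.308^2 - 2.08 * r2_drift
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

# expected sampling r^2 under random mating (Waples 2006 empirical fits)
expected_sample_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

#' Contemporary effective population size (bias-corrected LD method)
#'
#' Uses unlinked marker pairs (different chromosomes) only.
#'
#' @param ds genotype_dataset with at least two chromosomes.
#' @param mating only `"random"` is implemented.
#' @param maf_crit markers below this MAF are excluded (screening out rare
#'   alleles that bias r^2 upward).
#' @param max_pairs optional cap on the number of unlinked pairs (taken
#'   deterministically as a stride over the ordered pair list) to bound
#'   memory on dense panels; `Inf` uses all.
#' @param max_markers dense panels are thinned to at most this many markers
#'   (a deterministic stride across the map) before the pair correlation
#'   matrix is formed; the estimate is unbiased under thinning because
#'   unlinked pairs are exchangeable.
#' @return list with `S` (harmonic mean sample size), `n_pairs`,
#'   `r2_mean`, `r2_sample_expected`, `r2_drift` and `ne`.
#' @export
contemporary_ne <- function(ds, mating = "random", maf_crit = 0.05,
                            max_pairs = Inf, max_markers = 3000) {
  stopifnot(inherits(ds, "genotype_dataset"))
  mating <- match.arg(mating, "random")
  af <- allele_freq(ds)
  ds <- subset_dataset(ds, markers = which(!is.na(af$maf) & af$maf >= maf_crit))
  if (nrow(ds$markers) > max_markers) {
    stride <- seq(1, nrow(ds$markers), length.out = max_markers)
    ds <- subset_dataset(ds, markers = unique(round(stride)))
  }
  chrs <- unique(ds$markers$chromosome)
  if (length(chrs) < 2)
    stop("contemporary Ne needs markers on at least 2 chromosomes")
  calls <- ds$calls
  v <- apply(calls, 2, stats::var, na.rm = TRUE)
  usable <- which(!is.na(v) & v > 0)
  calls <- calls[, usable, drop = FALSE]
  chr <- ds$markers$chromosome[usable]
  suppressWarnings(r <- stats::cor(calls, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(calls))
  cross <- outer(chr, chr, "!=") & upper.tri(r) & is.finite(r) & nmat >= 2
  idx <- which(cross)
  if (is.finite(max_pairs) && length(idx) > max_pairs)
    idx <- idx[seq(1, length(idx), length.out = max_pairs)]
  np <- nmat[idx]
  # Scale Pearson r^2 to the Burrows-composite convention the Waples bias
  # formulas were fitted for: that estimator weights by n/(n-1), so its
  # expectation for independent loci is (S/(S-1))^2/(S-1) ~ 1/S + 3.19/S^2,
  # whereas plain Pearson r^2 has expectation 1/(S-1).
  r2 <- (r * r)[idx] * (np / (np - 1))^2
  S <- length(np) / sum(1 / np)           # harmonic mean of per-pair sizes
  r2_mean <- mean(r2)
  e_r2 <- expected_sample_r2(S)
  r2_drift <- r2_mean - e_r2
  list(S = S, n_pairs = length(idx), r2_mean = r2_mean,
       r2_sample_expected = e_r2, r2_drift = r2_drift,
       ne = waples_ne(r2_drift, S))
}
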