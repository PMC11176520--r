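# Per-locus and summary diversity indices: observed/expected heterozygosity,
# minor allele frequency, and per-individual method-of-moments inbreeding
# coefficients (excess homozygosity relative to Hardy-Weinberg).

#' Per-locus diversity statistics
#'
#' Expected heterozygosity uses the small-sample unbiased estimator
#' `2p(1-p) * 2n/(2n-1)` by default (n = called individuals at the locus);
#' set `unbiased = FALSE` for the plain `2p(1-p)`.
#'
#' @param ds genotype_dataset.
#' @param unbiased logical; apply the `2n/(2n-1)` correction to h_exp.
#' @return data.frame with one row per marker retaining at least one call:
#'   `id`, `chromosome`, `n_called`, `p` (allele-B frequency), `maf`,
#'   `h_obs`, `h_exp`. Zero-call markers are excluded with a warning.
#' @export
locus_stats <- function(ds, unbiased = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_called <- colSums(!is.na(ds$calls))
  if (any(n_called == 0)) {
    warning(sum(n_called == 0), " marker(s) with zero calls excluded")
  }
  keep <- n_called > 0
  calls <- ds$calls[, keep, drop = FALSE]
  n <- n_called[keep]
  p <- colSums(calls, na.rm = TRUE) / (2 * n)
  h_obs <- colSums(calls == 1L, na.rm = TRUE) / n
  corr <- if (unbiased) 2 * n / (2 * n - 1) else 1
  h_exp <- 2 * p * (1 - p) * corr
  data.frame(id = ds$markers$id[keep], chromosome = ds$markers$chromosome[keep],
             n_called = n, p = p, maf = pmin(p, 1 - p),
             h_obs = h_obs, h_exp = h_exp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-individual inbreeding coefficients from excess homozygosity
#'
#' Method-of-moments coefficient in the PLINK `--het` convention:
#' `F_i = (O_hom_i - E_hom_i) / (L_i - E_hom_i)` where, over the `L_i`
#' markers called in individual i, `O_hom_i` counts observed homozygotes
#' and `E_hom_i = sum_l (1 - 2 p_l (1-p_l) * 2n_l/(2n_l - 1))` is the
#' Hardy-Weinberg expectation from the sample allele frequencies.
#'
#' @param ds genotype_dataset.
#' @param unbiased logical; use the corrected h_exp in E_hom (PLINK does).
#' @return data.frame with `individual_id`, `n_called`, `o_hom`, `e_hom`,
#'   `f` (NA where the denominator degenerates).
#' @export
individual_fis <- function(ds, unbiased = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_called_locus <- colSums(!is.na(ds$calls))
  usable <- n_called_locus > 0
  calls <- ds$calls[, usable, drop = FALSE]
  n <- n_called_locus[usable]
  p <- colSums(calls, na.rm = TRUE) / (2 * n)
  corr <- if (unbiased) 2 * n / (2 * n - 1) else 1
  e_het <- 2 * p * (1 - p) * corr
  called <- !is.na(calls)
  L <- rowSums(called)
  o_hom <- rowSums(calls != 1L, na.rm = TRUE)
  e_hom <- as.numeric(called %*% (1 - e_het))
  f <- ifelse(abs(L - e_hom) < .Machine$double.eps^0.5, NA_real_,
              (o_hom - e_hom) / (L - e_hom))
  data.frame(individual_id = ds$samples$individual_id, n_called = L,
             o_hom = o_hom, e_hom = e_hom, f = f,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary of diversity indices
#'
#' Means and sample standard deviations of h_obs, h_exp and MAF are taken
#' across loci; of F_IS across individuals.
#'
#' @param ds genotype_dataset.
#' @param unbiased passed to [locus_stats()] and [individual_fis()].
#' @return list with components `h_obs`, `h_exp`, `maf`, `f_is`, each a
#'   `c(mean, sd)` vector, plus `n_loci` and `n_individuals`.
#' @export
diversity_summary <- function(ds, unbiased = TRUE) {
  ls <- locus_stats(ds, unbiased = unbiased)
  if (nrow(ls) < 2) stop("need at least 2 loci with calls")
  fi <- individual_fis(ds, unbiased = unbiased)
  ms <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  list(h_obs = ms(ls$h_obs), h_exp = ms(ls$h_exp), maf = ms(ls$maf),
       f_is = ms(fi$f), n_loci = nrow(ls), n_individuals = nrow(fi))
}
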