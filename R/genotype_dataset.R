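#' In-memory SNP-array genotype dataset
#'
#' The central container of the package: a set of diploid individuals typed
#' at biallelic markers with known map positions. Genotypes are stored as an
#' integer matrix of allele-B dosages: `0` = homozygous for `allele_a`,
#' `1` = heterozygous, `2` = homozygous for `allele_b`, `NA` = missing call.
#' Which physical allele is `allele_a` is an artifact of file order (the
#' first allele encountered when reading a PED file, or A1 of a BIM file);
#' every statistic in the package is invariant under swapping the two codes.
#'
#' @param samples data.frame with columns `family_id`, `individual_id`,
#'   `group` (population/breed label) and optionally `sex`, `phenotype`.
#' @param markers data.frame with columns `id`, `chromosome` (character),
#'   `position_bp` (integer), `allele_a`, `allele_b`. Markers must be sorted
#'   by position within each chromosome block.
#' @param calls integer matrix, one row per sample, one column per marker,
#'   values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, markers, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(samples$family_id)) samples$family_id <- samples$individual_id
  if (is.null(samples$group)) samples$group <- samples$family_id
  needed <- c("id", "chromosome", "position_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(needed, names(markers))
  if (length(missing_cols) > 0)
    stop("markers is missing columns: ", paste(missing_cols, collapse = ", "))
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.numeric(markers$position_bp)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("calls matrix is ", nrow(calls), "x", ncol(calls),
         " but there are ", nrow(samples), " samples and ",
         nrow(markers), " markers")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0)
    stop("genotype codes must be 0, 1, 2 or NA; found ", bad[1])
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids in dataset")
  key <- paste(samples$family_id, samples$individual_id)
  if (anyDuplicated(key))
    stop("duplicate (family_id, individual_id) pairs in dataset")
  rownames(calls) <- samples$individual_id
  colnames(calls) <- markers$id
  structure(list(samples = samples, markers = markers, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "individuals x",
      nrow(x$markers), "markers\n")
  cat("  chromosomes:", length(unique(x$markers$chromosome)),
      " groups:", length(unique(x$samples$group)), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$samples), nrow(x$markers))

#' Subset a genotype dataset
#'
#' @param ds genotype_dataset.
#' @param samples,markers logical or integer index into samples/markers;
#'   `NULL` keeps all.
#' @return genotype_dataset restricted to the selected rows/columns.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  mi <- if (is.null(markers)) seq_len(nrow(ds$markers)) else markers
  genotype_dataset(ds$samples[si, , drop = FALSE],
                   ds$markers[mi, , drop = FALSE],
                   ds$calls[si, mi, drop = FALSE])
}

#' Allele-B frequency and minor allele frequency per marker
#'
#' Frequencies are computed from non-missing calls only.
#'
#' @param ds genotype_dataset.
#' @return data.frame with columns `id`, `n_called`, `p` (allele-B
#'   frequency) and `maf`.
#' @export
allele_freq <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_called <- colSums(!is.na(ds$calls))
  p <- colSums(ds$calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p[n_called == 0] <- NA_real_
  data.frame(id = ds$markers$id, n_called = n_called, p = p,
             maf = pmin(p, 1 - p), row.names = NULL,
             stringsAsFactors = FALSE)
}

# TRUE when marker positions are non-decreasing within every chromosome block
markers_sorted <- function(markers) {
  ok <- TRUE
  for (ch in unique(markers$chromosome)) {
    pos <- markers$position_bp[markers$chromosome == ch]
    if (is.unsorted(pos)) { ok <- FALSE; break }
  }
  ok
}

#' Sort markers by (chromosome, position)
#'
#' Chromosome blocks are ordered numerically where the labels are numeric,
#' alphabetically otherwise; positions ascend within each block.
#'
#' @param ds genotype_dataset.
#' @return genotype_dataset with reordered markers.
#' @export
sort_markers <- function(ds) {
  chr <- ds$markers$chromosome
  chr_num <- suppressWarnings(as.numeric(chr))
  key <- order(is.na(chr_num), chr_num, chr, ds$markers$position_bp)
  subset_dataset(ds, markers = key)
}
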