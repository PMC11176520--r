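# PLINK 1.x text (PED/MAP) and binary (BED/BIM/FAM) input/output.
# Genotype codes follow the package convention: 0 = hom allele_a,
# 1 = het, 2 = hom allele_b, NA = missing. allele_a of a PED file is the
# first allele encountered in file order (PLINK 1.x behaviour); in a BIM
# file it is the A1 column. Code orientation is arbitrary and all
# downstream statistics are orientation-invariant.

#' Read a PLINK PED/MAP pair
#'
#' @param ped_path path to the .ped file (6 leading columns, then two
#'   allele columns per marker; "0" is the missing allele code).
#' @param map_path path to the .map file (chromosome, id, cM, position).
#' @return genotype_dataset.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  if (ncol(map) != 4) stop("MAP file must have 4 columns, found ", ncol(map))
  n_mark <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_ind <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6 + 2 * n_mark
  for (i in seq_len(n_ind)) {
    if (length(fields[[i]]) != expected)
      stop("PED line ", i, " has ", length(fields[[i]]),
           " fields, expected ", expected,
           " (6 + 2 x ", n_mark, " markers)")
  }
  ped <- do.call(rbind, fields)
  samples <- data.frame(family_id = ped[, 1], individual_id = ped[, 2],
                        paternal_id = ped[, 3], maternal_id = ped[, 4],
                        sex = ped[, 5], phenotype = ped[, 6],
                        group = ped[, 1], stringsAsFactors = FALSE)
  calls <- matrix(NA_integer_, n_ind, n_mark)
  allele_a <- character(n_mark)
  allele_b <- character(n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- ped[, 5 + 2 * j]
    a2 <- ped[, 6 + 2 * j]
    obs <- c(rbind(a1, a2))           # file order: row by row, first then second
    obs <- obs[obs != "0"]
    alleles <- unique(obs)
    if (length(alleles) > 2)
      stop("marker ", map[j, 2], " has more than two alleles: ",
           paste(alleles, collapse = ","))
    aa <- if (length(alleles) >= 1) alleles[1] else "0"
    ab <- if (length(alleles) == 2) alleles[2] else "0"
    allele_a[j] <- aa
    allele_b[j] <- ab
    miss <- a1 == "0" | a2 == "0"
    dose <- (a1 == ab) + (a2 == ab)
    dose[miss] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  markers <- data.frame(id = map[, 2], chromosome = map[, 1],
                        position_bp = map[, 4], allele_a = allele_a,
                        allele_b = allele_b, stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls)
}

#' Write a genotype dataset as PLINK PED/MAP
#'
#' Missing calls are written as the "0 0" allele pair. Markers with an
#' undefined `allele_b` (monomorphic) reuse `allele_a` for code 2, which
#' cannot occur for such markers.
#'
#' @param ds genotype_dataset.
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written.
#' @return prefix, invisibly.
#' @export
write_ped_map <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  mk <- ds$markers
  map <- data.frame(mk$chromosome, mk$id, rep(0, nrow(mk)),
                    format(mk$position_bp, scientific = FALSE, trim = TRUE))
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  sm <- ds$samples
  pat <- if (!is.null(sm$paternal_id)) sm$paternal_id else rep("0", nrow(sm))
  mat <- if (!is.null(sm$maternal_id)) sm$maternal_id else rep("0", nrow(sm))
  sex <- if (!is.null(sm$sex)) sm$sex else rep("0", nrow(sm))
  phe <- if (!is.null(sm$phenotype)) sm$phenotype else rep("-9", nrow(sm))
  n_mark <- nrow(mk)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  aa <- mk$allele_a
  ab <- ifelse(mk$allele_b == "0" | is.na(mk$allele_b), mk$allele_a, mk$allele_b)
  for (i in seq_len(nrow(sm))) {
    g <- ds$calls[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g == 2, ab, aa))
    second <- ifelse(is.na(g), "0", ifelse(g == 0, aa, ab))
    pair <- character(2 * n_mark)
    if (n_mark > 0) {
      pair[c(TRUE, FALSE)] <- first
      pair[c(FALSE, TRUE)] <- second
    }
    writeLines(paste(c(sm$family_id[i], sm$individual_id[i], pat[i],
                       mat[i], sex[i], phe[i], pair), collapse = " "), con)
  }
  invisible(prefix)
}

#' Read a PLINK binary BED/BIM/FAM triple
#'
#' Only the SNP-major layout (third magic byte `0x01`) of PLINK 1.9 is
#' supported. Two-bit codes are mapped as 00 -> 0 (hom A1), 10 -> 1 (het),
#' 11 -> 2 (hom A2), 01 -> NA (missing).
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @return genotype_dataset (allele_a = BIM column A1).
#' @export
read_bed <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  n_mark <- nrow(bim)
  n_ind <- nrow(fam)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", paths[1])
  if (raw[3] == as.raw(0x00))
    stop("individual-major BED files are not supported; re-export in SNP-major mode")
  if (raw[3] != as.raw(0x01))
    stop("unknown BED mode byte: ", as.integer(raw[3]))
  bpm <- ceiling(n_ind / 4)              # bytes per marker
  if (length(raw) - 3 != bpm * n_mark)
    stop("truncated or oversized BED payload: ", length(raw) - 3,
         " bytes for ", n_mark, " markers x ", n_ind, " individuals")
  bits <- matrix(as.integer(rawToBits(raw[-(1:3)])), nrow = 8 * bpm)
  lo <- bits[seq(1, 2 * n_ind, by = 2), , drop = FALSE]
  hi <- bits[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  v <- lo + 2L * hi                      # 2-bit genotype value per (ind, marker)
  calls <- matrix(NA_integer_, n_ind, n_mark)
  calls[v == 0] <- 0L
  calls[v == 2] <- 1L
  calls[v == 3] <- 2L
  samples <- data.frame(family_id = fam[, 1], individual_id = fam[, 2],
                        paternal_id = fam[, 3], maternal_id = fam[, 4],
                        sex = fam[, 5], phenotype = fam[, 6],
                        group = fam[, 1], stringsAsFactors = FALSE)
  markers <- data.frame(id = bim[, 2], chromosome = bim[, 1],
                        position_bp = bim[, 4], allele_a = bim[, 5],
                        allele_b = bim[, 6], stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls)
}

#' Write a genotype dataset as PLINK BED/BIM/FAM (SNP-major)
#'
#' @param ds genotype_dataset.
#' @param prefix output path prefix.
#' @return prefix, invisibly.
#' @export
write_bed <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  mk <- ds$markers
  bim <- data.frame(mk$chromosome, mk$id, rep(0, nrow(mk)),
                    format(mk$position_bp, scientific = FALSE, trim = TRUE),
                    mk$allele_a, mk$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  sm <- ds$samples
  fam <- data.frame(sm$family_id, sm$individual_id,
                    if (!is.null(sm$paternal_id)) sm$paternal_id else "0",
                    if (!is.null(sm$maternal_id)) sm$maternal_id else "0",
                    if (!is.null(sm$sex)) sm$sex else "0",
                    if (!is.null(sm$phenotype)) sm$phenotype else "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n_ind <- nrow(sm)
  n_mark <- nrow(mk)
  pad <- 4 * ceiling(n_ind / 4) - n_ind
  # genotype code -> (low bit, high bit): 0->00, 1->10(lo 0,hi 1), 2->11, NA->01
  lo_of <- function(g) ifelse(is.na(g), 1L, ifelse(g == 2, 1L, 0L))
  hi_of <- function(g) ifelse(is.na(g), 0L, ifelse(g >= 1, 1L, 0L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(n_mark)) {
    g <- c(ds$calls[, j], rep(0L, pad))
    bits <- rbind(lo_of(g), hi_of(g))
    writeBin(packBits(as.integer(bits) > 0, "raw"), con)
  }
  invisible(prefix)
}

#' Align the allele-code orientation of one dataset to a reference
#'
#' The 0/2 code orientation of a dataset read from a PED file depends on
#' file order (first allele encountered becomes `allele_a`), so a written
#' and re-read dataset can carry flipped codes at markers whose first
#' non-missing genotype is the opposite homozygote. This flips the codes
#' (and allele labels) of `ds` wherever its allele pair is the reverse of
#' `ref`'s, restoring a common orientation; genotype content is unchanged.
#'
#' @param ds genotype_dataset to reorient.
#' @param ref genotype_dataset with the same marker ids.
#' @return genotype_dataset.
#' @export
align_coding <- function(ds, ref) {
  idx <- match(ds$markers$id, ref$markers$id)
  if (anyNA(idx)) stop("marker ids of ds are not all present in ref")
  ra <- ref$markers$allele_a[idx]; rb <- ref$markers$allele_b[idx]
  flip <- !is.na(ds$markers$allele_a) & ds$markers$allele_a != "0" &
          ds$markers$allele_a == rb & (ds$markers$allele_b == ra |
                                       ds$markers$allele_b == "0" | ra == "0")
  if (any(flip)) {
    ds$calls[, flip] <- 2L - ds$calls[, flip, drop = FALSE]
    tmp <- ds$markers$allele_a[flip]
    ds$markers$allele_a[flip] <- ds$markers$allele_b[flip]
    ds$markers$allele_b[flip] <- tmp
  }
  ds
}

#' Merge two genotype datasets on their common markers
#'
#' Markers are matched by id (intersection). When the second dataset codes a
#' marker with the alleles swapped, its genotype codes are flipped (0 <-> 2)
#' so both datasets share one orientation. Markers whose allele pairs cannot
#' be reconciled by a swap (e.g. A/C vs A/G, or inconsistent strand-ambiguous
#' A/T and C/G markers) are dropped with a warning reporting the count.
#' Monomorphic markers (one observed allele) are reconciled whenever the
#' observed alleles are compatible.
#'
#' @param a,b genotype_dataset objects with disjoint sample ids.
#' @return genotype_dataset containing all samples of `a` then `b` on the
#'   reconciled marker intersection (map taken from `a`).
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  ka <- paste(a$samples$family_id, a$samples$individual_id)
  kb <- paste(b$samples$family_id, b$samples$individual_id)
  if (length(intersect(ka, kb)) > 0)
    stop("duplicate (family_id, individual_id) across datasets: ",
         intersect(ka, kb)[1])
  common <- intersect(a$markers$id, b$markers$id)
  if (length(common) == 0) {
    warning("no common markers between datasets; merged panel is empty")
  }
  ia <- match(common, a$markers$id)
  ib <- match(common, b$markers$id)
  ma <- a$markers[ia, , drop = FALSE]
  mb <- b$markers[ib, , drop = FALSE]
  norm <- function(x) ifelse(is.na(x) | x == "0", NA_character_, x)
  aa1 <- norm(ma$allele_a); aa2 <- norm(ma$allele_b)
  ba1 <- norm(mb$allele_a); ba2 <- norm(mb$allele_b)
  same <- (is.na(ba1) | ba1 == aa1 | (is.na(aa1))) &
          (is.na(ba2) | ba2 == aa2 | (is.na(aa2)))
  swap <- (is.na(ba1) | ba1 == aa2 | is.na(aa2)) &
          (is.na(ba2) | ba2 == aa1 | is.na(aa1))
  keep <- same | swap
  flip <- swap & !same
  if (any(!keep))
    warning(sum(!keep), " marker(s) dropped in merge: irreconcilable allele pairs")
  # fill allele slots a left undefined from b's (oriented) alleles
  fa <- ifelse(!is.na(aa1), aa1, ifelse(flip, ba2, ba1))
  fb <- ifelse(!is.na(aa2), aa2, ifelse(flip, ba1, ba2))
  mk <- a$markers[ia, , drop = FALSE]
  mk$allele_a <- ifelse(is.na(fa), "0", fa)
  mk$allele_b <- ifelse(is.na(fb), "0", fb)
  ia <- ia[keep]; ib <- ib[keep]; flip <- flip[keep]
  mk <- mk[keep, , drop = FALSE]
  cb <- b$calls[, ib, drop = FALSE]
  if (any(flip)) cb[, flip] <- 2L - cb[, flip, drop = FALSE]
  cols <- intersect(names(a$samples), names(b$samples))
  samples <- rbind(a$samples[, cols, drop = FALSE], b$samples[, cols, drop = FALSE])
  genotype_dataset(samples, mk, rbind(a$calls[, ia, drop = FALSE], cb))
}

#' Random subsample of each group to a maximum size
#'
#' Groups at or below `max_n` are kept whole; larger groups are reduced to
#' `max_n` individuals drawn uniformly at random. Selection is deterministic
#' given `seed`; marker content never changes.
#'
#' @param ds genotype_dataset.
#' @param max_n maximum individuals retained per group (>= 1).
#' @param seed integer RNG seed.
#' @return genotype_dataset.
#' @export
subsample_per_group <- function(ds, max_n, seed) {
  stopifnot(inherits(ds, "genotype_dataset"), max_n >= 1)
  set.seed(seed)
  keep <- logical(nrow(ds$samples))
  for (g in unique(ds$samples$group)) {
    idx <- which(ds$samples$group == g)
    if (length(idx) > max_n) idx <- sort(sample(idx, max_n))
    keep[idx] <- TRUE
  }
  subset_dataset(ds, samples = which(keep))
}
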