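# ROH islands: per-SNP incidence of run membership across individuals,
# standard-normal z-scores, selection of the top incidence fraction and
# merging of flagged SNPs into genomic intervals, plus annotation of
# islands against user-supplied gene/QTL intervals.

#' Per-SNP incidence of ROH membership
#'
#' A marker is counted for an individual when one of that individual's
#' segments on the same chromosome covers its position (closed interval).
#' z-scores standardize the counts over all markers; upper-tail normal
#' p-values are descriptive.
#'
#' @param segments data.frame from [detect_roh()].
#' @param markers marker table (`id`, `chromosome`, `position_bp`), sorted.
#' @param n_individuals number of individuals the segments came from.
#' @return data.frame `id`, `chromosome`, `position_bp`, `count`,
#'   `proportion`, `z`, `p`, with attribute `degenerate = TRUE` when the
#'   count standard deviation is zero (z and p then NA).
#' @export
snp_incidence <- function(segments, markers, n_individuals) {
  count <- integer(nrow(markers))
  if (nrow(segments) > 0) {
    for (ch in unique(segments$chromosome)) {
      mi <- which(markers$chromosome == ch)
      if (length(mi) == 0) next
      pos <- markers$position_bp[mi]
      seg <- segments[segments$chromosome == ch, , drop = FALSE]
      for (k in seq_len(nrow(seg))) {
        hit <- pos >= seg$start_bp[k] & pos <= seg$end_bp[k]
        count[mi[hit]] <- count[mi[hit]] + 1L
      }
    }
  }
  s <- stats::sd(count)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(NA_real_, length(count)) else (count - mean(count)) / s
  tab <- data.frame(id = markers$id, chromosome = markers$chromosome,
                    position_bp = markers$position_bp, count = count,
                    proportion = count / n_individuals, z = z,
                    p = if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "degenerate") <- degenerate
  tab
}

#' Scan an incidence table for ROH islands
#'
#' The `ceiling(top_fraction * n_markers)` markers with the highest
#' incidence are flagged (rank rule; ties at the boundary are all included,
#' so the flagged set can slightly exceed the nominal count). Flagged
#' markers on one chromosome are merged into islands whenever consecutive
#' flagged markers are at most `merge_gap_bp` apart; an island spans its
#' first to last flagged member.
#'
#' @param table data.frame from [snp_incidence()].
#' @param top_fraction fraction of markers to flag (default 0.001).
#' @param merge_gap_bp maximum gap between flagged markers of one island.
#' @return data.frame `chromosome`, `start_bp`, `end_bp`, `length_bp`,
#'   `n_snp`, `marker_ids` (comma-joined); empty when the table is
#'   degenerate.
#' @export
island_scan <- function(table, top_fraction = 0.001, merge_gap_bp = 1e6) {
  empty <- data.frame(chromosome = character(), start_bp = numeric(),
                      end_bp = numeric(), length_bp = numeric(),
                      n_snp = integer(), marker_ids = character(),
                      stringsAsFactors = FALSE)
  if (isTRUE(attr(table, "degenerate")) || nrow(table) == 0) return(empty)
  k <- ceiling(top_fraction * nrow(table))
  kth <- sort(table$count, decreasing = TRUE)[k]
  flagged <- table$count >= kth & table$count > 0
  if (!any(flagged)) return(empty)
  out <- list()
  for (ch in unique(table$chromosome[flagged])) {
    f <- table[flagged & table$chromosome == ch, , drop = FALSE]
    f <- f[order(f$position_bp), , drop = FALSE]
    brk <- c(FALSE, diff(f$position_bp) > merge_gap_bp)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      m <- f[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch, start_bp = min(m$position_bp),
        end_bp = max(m$position_bp),
        length_bp = max(m$position_bp) - min(m$position_bp),
        n_snp = nrow(m), marker_ids = paste(m$id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(suppressWarnings(as.numeric(res$chromosome)), res$start_bp), ,
      drop = FALSE]
}

#' Overlap islands with annotation intervals
#'
#' Closed-interval intersection on matching chromosomes: a feature is
#' reported for an island iff `feature$start <= island$end` and
#' `feature$end >= island$start` (touching endpoints overlap).
#'
#' @param islands data.frame from [island_scan()].
#' @param features data.frame with columns `chromosome`, `start_bp`,
#'   `end_bp`, `name`, and optionally `type` (see [read_features()]).
#' @return data.frame pairing each island with its overlapping features;
#'   attribute `n_skipped` counts malformed feature rows.
#' @export
annotate_intervals <- function(islands, features) {
  needed <- c("chromosome", "start_bp", "end_bp", "name")
  if (!all(needed %in% names(features)))
    stop("features must have columns: ", paste(needed, collapse = ", "))
  ok <- !is.na(features$chromosome) & !is.na(features$start_bp) &
        !is.na(features$end_bp) & features$start_bp <= features$end_bp
  n_skipped <- sum(!ok)
  features <- features[ok, , drop = FALSE]
  if (is.null(features$type)) features$type <- NA_character_
  out <- list()
  for (i in seq_len(nrow(islands))) {
    hit <- features$chromosome == islands$chromosome[i] &
           features$start_bp <= islands$end_bp[i] &
           features$end_bp >= islands$start_bp[i]
    if (any(hit)) {
      f <- features[hit, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chromosome = islands$chromosome[i],
        island_start_bp = islands$start_bp[i],
        island_end_bp = islands$end_bp[i],
        feature = f$name, feature_type = f$type,
        feature_start_bp = f$start_bp, feature_end_bp = f$end_bp,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chromosome = character(), island_start_bp = numeric(),
               island_end_bp = numeric(), feature = character(),
               feature_type = character(), feature_start_bp = numeric(),
               feature_end_bp = numeric(), stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Read annotation intervals from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()`; BED's 0-based half-open
#' coordinates are returned 1-based closed (rtracklayer converts).
#'
#' @param path file path (.bed, .gff, .gff3).
#' @param format forwarded to rtracklayer; guessed from the extension by
#'   default.
#' @return data.frame `chromosome`, `start_bp`, `end_bp`, `name`, `type`.
#' @export
read_features <- function(path, format = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_features() requires the rtracklayer package")
  gr <- if (is.null(format)) rtracklayer::import(path)
        else rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  name <- if (!is.null(df$Name)) df$Name
          else if (!is.null(df$name)) df$name
          else if (!is.null(df$ID)) df$ID
          else paste0("feature_", seq_len(nrow(df)))
  type <- if (!is.null(df$type)) as.character(df$type) else NA_character_
  data.frame(chromosome = as.character(df$seqnames), start_bp = df$start,
             end_bp = df$end, name = as.character(name), type = type,
             stringsAsFactors = FALSE)
}
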