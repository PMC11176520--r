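test_that("incidence counts individuals whose runs cover each marker", {
  markers <- data.frame(id = sprintf("m%02d", 1:10), chromosome = "1",
                        position_bp = (1:10) * 1e6, stringsAsFactors = FALSE)
  # no segments: all zero
  none <- snp_incidence(data.frame(individual_id = character(),
                                   chromosome = character(),
                                   start_bp = numeric(), end_bp = numeric()),
                        markers, 24)
  expect_equal(none$proportion, rep(0, 10))
  # one of 24 individuals, one covering segment (closed interval ends count)
  seg <- data.frame(individual_id = "I1", chromosome = "1",
                    start_bp = 3e6, end_bp = 6e6)
  tab <- snp_incidence(seg, markers, 24)
  expect_equal(tab$count, c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(tab$proportion[3], 1 / 24)
  expect_equal(tab$z, (tab$count - mean(tab$count)) / sd(tab$count))
  expect_equal(tab$p, 1 - pnorm(tab$z))
})

test_that("incidence equals a per-marker brute-force membership recount", {
  set.seed(14)
  markers <- data.frame(id = sprintf("m%03d", 1:120),
                        chromosome = rep(c("1", "2"), each = 60),
                        position_bp = c(sort(sample.int(5e7, 60)),
                                        sort(sample.int(5e7, 60))),
                        stringsAsFactors = FALSE)
  inds <- sprintf("I%02d", 1:12)
  segs <- do.call(rbind, lapply(inds, function(id) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    chr <- sample(c("1", "2"), k, TRUE)
    st <- sample.int(4e7, k)
    data.frame(individual_id = id, chromosome = chr, start_bp = st,
               end_bp = st + sample.int(8e6, k), stringsAsFactors = FALSE)
  }))
  tab <- snp_incidence(segs, markers, 12)
  brute <- sapply(seq_len(nrow(markers)), function(j) {
    covered <- vapply(inds, function(id) {
      s <- segs[segs$individual_id == id & segs$chromosome == markers$chromosome[j], ,
                drop = FALSE]
      any(s$start_bp <= markers$position_bp[j] &
          s$end_bp >= markers$position_bp[j])
    }, logical(1))
    sum(covered)
  })
  expect_equal(tab$count, unname(brute))
})

test_that("the top-fraction flag count matches the ceiling rule", {
  markers <- data.frame(id = sprintf("m%04d", 1:1000), chromosome = "1",
                        position_bp = (1:1000) * 5e4, stringsAsFactors = FALSE)
  tab <- data.frame(id = markers$id, chromosome = "1",
                    position_bp = markers$position_bp,
                    count = c(1000:1), proportion = (1000:1) / 1000,
                    z = 0, p = 0.5)
  attr(tab, "degenerate") <- FALSE
  isl <- island_scan(tab, top_fraction = 0.001, merge_gap_bp = 1e6)
  expect_equal(sum(isl$n_snp), 1)          # ceiling(0.001 * 1000) = 1
  isl5 <- island_scan(tab, top_fraction = 0.005, merge_gap_bp = 1e6)
  expect_equal(sum(isl5$n_snp), 5)
})

test_that("flagged markers further apart than the merge gap form separate islands", {
  tab <- data.frame(id = sprintf("m%02d", 1:20), chromosome = "1",
                    position_bp = (1:20) * 1e6,
                    count = c(rep(1, 20)), proportion = 0.1, z = 0, p = 0.5)
  tab$count[c(3, 8)] <- 20                 # two spikes 5 Mb apart
  attr(tab, "degenerate") <- FALSE
  isl <- island_scan(tab, top_fraction = 0.1, merge_gap_bp = 1e6)
  expect_equal(nrow(isl), 2)
  expect_equal(isl$start_bp, c(3e6, 8e6))
  expect_equal(isl$end_bp, c(3e6, 8e6))
  # with a permissive gap they merge into one island spanning both
  isl2 <- island_scan(tab, top_fraction = 0.1, merge_gap_bp = 6e6)
  expect_equal(nrow(isl2), 1)
  expect_equal(isl2$length_bp, 5e6)
  expect_equal(isl2$n_snp, 2)
})

test_that("every island member outranks every unflagged marker", {
  set.seed(21)
  tab <- data.frame(id = sprintf("m%03d", 1:500), chromosome = "1",
                    position_bp = sort(sample.int(6e7, 500)),
                    count = rpois(500, 2), proportion = 0, z = 0, p = 0.5)
  attr(tab, "degenerate") <- FALSE
  isl <- island_scan(tab, top_fraction = 0.01, merge_gap_bp = 1e6)
  flagged_ids <- unlist(strsplit(isl$marker_ids, ","))
  minflag <- min(tab$count[tab$id %in% flagged_ids])
  expect_gte(minflag, max(tab$count[!(tab$id %in% flagged_ids)]))
})

test_that("a degenerate incidence table yields no islands", {
  markers <- data.frame(id = c("a", "b"), chromosome = "1",
                        position_bp = c(1e6, 2e6), stringsAsFactors = FALSE)
  tab <- snp_incidence(data.frame(individual_id = character(),
                                  chromosome = character(),
                                  start_bp = numeric(), end_bp = numeric()),
                       markers, 10)
  expect_true(attr(tab, "degenerate"))
  expect_equal(nrow(island_scan(tab)), 0)
})

test_that("the scan recovers a planted hotspot over background noise", {
  set.seed(31)
  base <- sim_structured(n_pops = 1, n_per_pop = 24, n_loci = 1000,
                         fst = 1e-6, n_autosomes = 2, chrom_length_bp = 2.5e7,
                         seed = 131)
  region <- pick_plant_region(base, chrom = 1, n_snp = 45)
  planted <- plant_roh(base, chromosome = 1, start_bp = region["start_bp"],
                       end_bp = region["end_bp"],
                       carrier_fraction = 23 / 24, seed = 132)
  seg <- detect_roh(planted, roh_params())
  tab <- snp_incidence(seg, planted$markers, 24)
  isl <- island_scan(tab, top_fraction = 0.001, merge_gap_bp = 1e6)
  expect_equal(nrow(isl), 1)
  truth <- attr(planted, "truth")$planted
  expect_equal(isl$chromosome, "1")
  expect_equal(isl$start_bp, truth$start_bp[1])
  expect_equal(isl$end_bp, truth$end_bp[1])
})

test_that("island annotation intersects closed intervals per chromosome", {
  islands <- data.frame(chromosome = "13", start_bp = 47169096,
                        end_bp = 49619573, length_bp = 2450477,
                        n_snp = 36L, marker_ids = "x")
  feats <- data.frame(chromosome = c("13", "12", "13", "13"),
                      start_bp = c(48000000, 48000000, 46000000, 50000000),
                      end_bp = c(48010000, 48010000, 47169096, 50100000),
                      name = c("in_island", "wrong_chr", "touches_start", "beyond_end"))
  ann <- annotate_intervals(islands, feats)
  expect_setequal(ann$feature, c("in_island", "touches_start"))
  # malformed rows (reversed interval, NA) are skipped and counted
  feats_bad <- rbind(feats,
                     data.frame(chromosome = "13", start_bp = 5e7, end_bp = 4e7,
                                name = "reversed"),
                     data.frame(chromosome = NA, start_bp = 1, end_bp = 2,
                                name = "nochrom"))
  ann2 <- annotate_intervals(islands, feats_bad)
  expect_equal(attr(ann2, "n_skipped"), 2)
  expect_setequal(ann2$feature, c("in_island", "touches_start"))
})

test_that("BED and GFF3 annotation files load into the feature frame", {
  skip_if_not_installed("rtracklayer")
  bed <- tempfile(fileext = ".bed")
  writeLines("13\t47999999\t48010000\tqtl_tailfat", bed)
  fb <- read_features(bed)
  expect_equal(fb$chromosome, "13")
  expect_equal(fb$start_bp, 48000000)    # BED 0-based start converts to 1-based
  expect_equal(fb$end_bp, 48010000)
  expect_equal(fb$name, "qtl_tailfat")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "13\ttest\tgene\t48000000\t48010000\t.\t+\t.\tID=BMP2;Name=BMP2"),
             gff)
  fg <- read_features(gff)
  expect_equal(fg$name, "BMP2")
  expect_equal(fg$start_bp, 48000000)
  expect_equal(fg$type, "gene")
})
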