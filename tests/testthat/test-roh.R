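test_that("detector honours the five consecutive-run criteria", {
  # 20 homozygous SNPs spanning 1.5 Mb, gaps < 250 kb -> one run of 20
  pos <- seq(1e6, 2.5e6, length.out = 20)
  ds <- ds_from_calls(matrix(0L, 1, 20), pos = pos)
  seg <- detect_roh(ds, roh_params())
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snp, 20)
  expect_equal(seg$start_bp, 1e6)
  expect_equal(seg$end_bp, 2.5e6)
  expect_equal(seg$length_bp, 1.5e6)
  # 14 homozygous SNPs spanning 2 Mb -> fails the 15-SNP minimum
  ds14 <- ds_from_calls(matrix(2L, 1, 14), pos = seq(1e6, 3e6, length.out = 14))
  expect_equal(nrow(detect_roh(ds14, roh_params())), 0)
  # heterozygote in the middle splits the run
  g <- rep(0L, 41); g[21] <- 1L
  ds_het <- ds_from_calls(matrix(g, 1), pos = seq(1e6, 4e6, length.out = 41))
  seg <- detect_roh(ds_het, roh_params())
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_snp, c(20, 20))
  # missing call splits too
  g[21] <- NA
  ds_na <- ds_from_calls(matrix(g, 1), pos = seq(1e6, 4e6, length.out = 41))
  expect_equal(nrow(detect_roh(ds_na, roh_params())), 2)
})

test_that("an oversized gap splits a stretch into independently judged halves", {
  # 40 homozygous SNPs; a 300-kb gap after SNP 20; each half spans 1.14 Mb
  pos <- c(seq(1e6, 2.14e6, length.out = 20),
           seq(2.44e6, 3.58e6, length.out = 20))
  ds <- ds_from_calls(matrix(0L, 1, 40), pos = pos)
  seg <- detect_roh(ds, roh_params())
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_snp, c(20, 20))
  # shrink one half below 1 Mb: only the other survives
  pos2 <- c(seq(1e6, 1.9e6, length.out = 20),
            seq(2.25e6, 3.58e6, length.out = 20))
  seg2 <- detect_roh(ds_from_calls(matrix(0L, 1, 40), pos = pos2), roh_params())
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$start_bp, 2.25e6)
})

test_that("runs may mix the two homozygotes unless strict mode is on", {
  g <- rep(c(0L, 2L), 10)
  ds <- ds_from_calls(matrix(g, 1), pos = seq(1e6, 2.5e6, length.out = 20))
  expect_equal(nrow(detect_roh(ds, roh_params())), 1)
  strict <- roh_params(strict_same_allele = TRUE)
  expect_equal(nrow(detect_roh(ds, strict)), 0)
  # strict mode agrees with the oracle too
  set.seed(77)
  rds <- ds_from_calls(matrix(sample(c(0L, 0L, 2L, 2L, 1L), 300, TRUE), 2, 150),
                       pos = sort(sample.int(2e7, 150)))
  p <- roh_params(min_snp = 5, min_length_bp = 2e5, strict_same_allele = TRUE)
  expect_equal(seg_key(detect_roh(rds, p)), seg_key(oracle_roh(rds, p)))
})

test_that("detected segments equal the brute-force maximal-run enumeration", {
  params <- roh_params(min_snp = 10, min_length_bp = 8e5)
  for (trial in 1:30) {
    set.seed(1000 + trial)
    n <- 6; m <- 300
    calls <- matrix(sample(c(0L, 0L, 0L, 2L, 2L, 2L, 1L, NA),
                           n * m, TRUE), n, m)
    chrom <- rep(c("1", "2"), each = m / 2)
    pos <- c(sort(sample.int(3e7, m / 2)), sort(sample.int(3e7, m / 2)))
    ds <- ds_from_calls(calls, pos = pos, chrom = chrom)
    expect_equal(seg_key(detect_roh(ds, params)), seg_key(oracle_roh(ds, params)))
  }
})

test_that("every emitted segment passes an independent criterion re-check", {
  set.seed(55)
  calls <- matrix(sample(c(0L, 0L, 0L, 2L, 2L, 1L, NA), 4 * 400, TRUE), 4, 400)
  ds <- ds_from_calls(calls, pos = sort(sample.int(6e7, 400)))
  params <- roh_params(min_snp = 8, min_length_bp = 5e5)
  seg <- detect_roh(ds, params)
  expect_gt(nrow(seg), 0)
  for (k in seq_len(nrow(seg)))
    expect_true(segment_valid(seg[k, ], ds, params))
})

test_that("tightening criteria is monotone in segment count", {
  set.seed(91)
  calls <- matrix(sample(c(0L, 0L, 0L, 0L, 2L, 2L, 1L), 5 * 400, TRUE), 5, 400)
  ds <- ds_from_calls(calls, pos = sort(sample.int(4e7, 400)))
  base <- nrow(detect_roh(ds, roh_params(min_snp = 8, min_length_bp = 4e5)))
  expect_lte(nrow(detect_roh(ds, roh_params(min_snp = 12, min_length_bp = 4e5))), base)
  expect_lte(nrow(detect_roh(ds, roh_params(min_snp = 8, min_length_bp = 9e5))), base)
  fewer_gap <- nrow(detect_roh(ds, roh_params(min_snp = 8, min_length_bp = 4e5,
                                              max_gap_bp = 1e5)))
  expect_gte(base, fewer_gap)
})

test_that("unsorted markers raise a structural error", {
  ds <- ds_from_calls(matrix(0L, 1, 10), pos = c(5:1, 6:10) * 1e5)
  expect_error(detect_roh(ds), "sorted")
})

test_that("length classes are left-closed right-open with fixed bins", {
  seg <- data.frame(length_bp = c(2.0e6, 1.5e6, 3e6, 20e6))
  cl <- classify_lengths(seg)
  expect_equal(cl$class, c("1-2", "2-4", "4-8", "8-16", ">16"))
  expect_equal(cl$count, c(1L, 2L, 0L, 0L, 1L))   # 2.0 Mb lands in 2-4
  expect_equal(sum(cl$count), 4)
  expect_equal(cl$percent, c(25, 50, 0, 0, 25))
  empty <- classify_lengths(data.frame(length_bp = numeric(0)))
  expect_equal(empty$count, rep(0L, 5))
})

test_that("ROH summaries average over individuals, segments and chromosomes", {
  seg <- data.frame(
    individual_id = c("a", "a", "b", "b", "b", "b"),
    chromosome = c("1", "2", "1", "1", "2", "3"),
    start_bp = rep(1e6, 6),
    end_bp = 1e6 + c(1831000, 2e6, 1.2e6, 1.4e6, 3e6, 9e6),
    n_snp = rep(20L, 6))
  seg$length_bp <- seg$end_bp - seg$start_bp
  s <- summarize_roh(seg, individuals = c("a", "b", "c"),
                     chromosomes = c("1", "2", "3", "4"))
  expect_equal(unname(s$n_roh["mean"]), mean(c(2, 4, 0)))   # zero-ROH counts
  expect_equal(unname(s$l_roh_mb["mean"]), mean(seg$length_bp) / 1e6)
  expect_equal(s$l_roh_mb[["mean"]], 3.071833, tolerance = 1e-6)
  expect_equal(unname(s$nc_roh["mean"]), mean(c(3, 2, 1, 0)))
  # LC_ROH averages per-chromosome means over occupied chromosomes
  per_chr_means <- c(mean(c(1.831, 1.2, 1.4)), mean(c(2, 3)), 9)
  expect_equal(unname(s$lc_roh_mb["mean"]), mean(per_chr_means))
  expect_equal(s$n_total, 6)
  expect_equal(s$per_individual$froh[1], (1831000 + 2e6) / 2.4e9)
})

test_that("F_ROH is total run length over genome length", {
  seg <- data.frame(individual_id = "x", chromosome = c("1", "2"),
                    start_bp = c(1e6, 2e6), end_bp = c(21.4e6, 22.4e6),
                    n_snp = c(100L, 100L),
                    length_bp = c(20.4e6, 20.4e6))
  expect_equal(froh(seg, "x"), 40.8e6 / 2.4e9)
  expect_equal(froh(seg, "x"), 0.017)
  expect_equal(froh(seg[0, ], "x"), 0)
  # overlapping segments are rejected
  bad <- data.frame(individual_id = "x", chromosome = "1",
                    start_bp = c(1e6, 2e6), end_bp = c(3e6, 4e6),
                    n_snp = c(20L, 20L), length_bp = c(2e6, 2e6))
  expect_error(froh(bad, "x"), "overlap")
})

test_that("detector output is invariant under a global allele-code swap", {
  set.seed(66)
  calls <- matrix(sample(c(0L, 0L, 2L, 2L, 1L, NA), 3 * 200, TRUE), 3, 200)
  ds <- ds_from_calls(calls, pos = sort(sample.int(3e7, 200)))
  swapped <- ds; swapped$calls <- 2L - swapped$calls
  p <- roh_params(min_snp = 6, min_length_bp = 3e5)
  expect_equal(seg_key(detect_roh(ds, p)), seg_key(detect_roh(swapped, p)))
})
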