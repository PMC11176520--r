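test_that("IBS distance matches allele-sharing arithmetic", {
  # identical individuals -> 0; opposite homozygotes everywhere -> 1
  calls <- rbind(c(0L, 2L, 1L), c(1L, 2L, 1L), c(2L, 0L, 1L))
  ds <- ds_from_calls(calls)
  D <- ibs_distance(ds)
  # hand fixture: pair (I1, I2): codes (0,1), (2,2), (1,1) -> shared 1,2,2
  expect_equal(D["I001", "I002"], 1 - 5 / 6)
  dup <- ds_from_calls(rbind(calls, calls[1, ]))
  expect_equal(ibs_distance(dup)["I001", "I004"], 0)
  opp <- ds_from_calls(rbind(rep(0L, 5), rep(2L, 5)))
  expect_equal(ibs_distance(opp)["I001", "I002"], 1)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(D)))
})

test_that("IBS handles missing data and rejects pairs with no shared marker", {
  calls <- rbind(c(0L, NA, 2L), c(NA, 1L, 2L))
  D <- ibs_distance(ds_from_calls(calls))
  expect_equal(D[1, 2], 0)              # only marker 3 shared, identical there
  disjoint <- rbind(c(0L, NA), c(NA, 2L))
  expect_error(ibs_distance(ds_from_calls(disjoint)), "no called marker")
  D2 <- ibs_distance(ds_from_calls(disjoint), allow_missing_pairs = TRUE)
  expect_true(is.na(D2[1, 2]))
})

test_that("IBS distance satisfies the triangle inequality on complete data", {
  ds <- rand_ds(8, 100, seed = 12)
  D <- ibs_distance(ds)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("classical MDS reproduces planted Euclidean geometry", {
  set.seed(13)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  fit <- classical_mds(D, k = 2)
  expect_lt(max(abs(as.matrix(dist(fit$coords)) - D)), 1e-8)
  expect_equal(sum(fit$explained), 1, tolerance = 1e-8)
  # collinear points are one-dimensional
  line <- matrix(c(0, 1, 2, 3.5), 4, 1)
  expect_warning(fit1 <- classical_mds(as.matrix(dist(line)), k = 2), "reduced")
  expect_equal(ncol(fit1$coords), 1)    # k reduced: only 1 positive dimension
  # a duplicated individual lands on identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  fit2 <- classical_mds(as.matrix(dist(pts2)), k = 2)
  expect_equal(unname(fit2$coords[11, ]), unname(fit2$coords[1, ]), tolerance = 1e-8)
})

test_that("Weir-Cockerham theta matches a longhand variance-component computation", {
  # two populations, two loci, textbook-style counts
  ga <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 0L), c(1L, 2L))
  gb <- rbind(c(2L, 2L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  ds <- ds_from_calls(rbind(ga, gb), pos = c(1e6, 2e6))
  theta <- wc_theta(ds, 1:5, 6:9)
  # independent longhand computation of a, b, c per locus (r = 2)
  hand <- local({
    num <- 0; den <- 0
    for (l in 1:2) {
      n <- c(5, 4)
      p <- c(sum(ga[, l]) / 10, sum(gb[, l]) / 8)
      h <- c(mean(ga[, l] == 1), mean(gb[, l] == 1))
      r <- 2; nbar <- mean(n)
      nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n * p) / (r * nbar)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
    num / den
  })
  expect_equal(theta, hand)
})

test_that("theta vanishes under the null and saturates at fixed differences", {
  ds0 <- sim_structured(n_pops = 2, n_per_pop = 100, n_loci = 2000,
                        fst = 1e-6, seed = 41)
  th0 <- wc_theta(ds0, 1:100, 101:200)
  expect_lt(abs(th0), 0.01)
  # opposite fixation: theta ~ 1
  fixed <- ds_from_calls(rbind(matrix(0L, 30, 50), matrix(2L, 30, 50)),
                         pos = sort(sample.int(5e7, 50)))
  expect_gt(wc_theta(fixed, 1:30, 31:60), 0.98)
})

test_that("theta is symmetric in group order and allele-swap invariant", {
  ds <- sim_structured(n_pops = 2, n_per_pop = 25, n_loci = 500,
                       fst = 0.08, seed = 43)
  a <- wc_theta(ds, 1:25, 26:50)
  expect_equal(a, wc_theta(ds, 26:50, 1:25))
  sw <- ds; sw$calls <- 2L - sw$calls
  expect_equal(a, wc_theta(sw, 1:25, 26:50))
  fst <- pairwise_fst(ds)
  expect_equal(fst$theta, a)
  expect_equal(fst$reynolds_d, -log(1 - max(a, 0)))
})

test_that("groups below two individuals are rejected for F_ST", {
  ds <- sim_structured(n_pops = 2, n_per_pop = c(5, 1), n_loci = 50,
                       fst = 0.05, seed = 44)
  expect_error(pairwise_fst(ds), "fewer than 2")
})

test_that("Reynolds distance transforms theta monotonically with clamping", {
  expect_equal(reynolds_distance(0), 0)
  expect_equal(reynolds_distance(0.1), 0.1053605, tolerance = 1e-6)
  expect_equal(reynolds_distance(-0.02), 0)       # negative theta clamped
  expect_equal(reynolds_distance(1), Inf)
  th <- c(0.05, 0.1, 0.4)
  expect_true(all(diff(reynolds_distance(th)) > 0))
})

test_that("neighbor-joining solves three taxa exactly and recovers additive trees", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # the three branch lengths solve the pairwise equations exactly
  cp <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(cp), unname(D), tolerance = 1e-12)
  # random additive matrices from 4-8 taxon trees are recovered exactly
  for (n_tip in 4:8) {
    set.seed(50 + n_tip)
    true_tree <- ape::rtree(n_tip, br = function(n) runif(n, 0.05, 1))
    Dt <- ape::cophenetic.phylo(true_tree)
    rec <- neighbor_joining(Dt)
    cpr <- ape::cophenetic.phylo(rec)
    expect_equal(cpr[rownames(Dt), colnames(Dt)], Dt, tolerance = 1e-8)
  }
})

test_that("neighbor-joining is invariant to label order and clamps negatives", {
  set.seed(59)
  true_tree <- ape::rtree(6, br = function(n) runif(n, 0.05, 1))
  D <- ape::cophenetic.phylo(true_tree)
  perm <- sample(6)
  tr1 <- neighbor_joining(D)
  tr2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(D), colnames(D)],
               ape::cophenetic.phylo(tr1)[rownames(D), colnames(D)],
               tolerance = 1e-8)
  expect_true(all(tr1$edge.length >= 0))
  # fewer than 3 taxa: trivial tree with a warning
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(tr <- neighbor_joining(D2), "fewer than 3")
  expect_equal(sum(tr$edge.length), 0.4)
})
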