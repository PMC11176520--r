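# Between-individual and between-population structure: identity-by-state
# distances, classical (Torgerson) MDS, Weir-Cockerham theta, Reynolds
# distances, neighbor-joining trees.

#' Pairwise identity-by-state distance matrix
#'
#' For each pair of individuals, similarity is the mean over mutually
#' non-missing markers of (shared allele count)/2, where the shared count
#' is 2 for identical genotypes, 1 for genotypes one dosage step apart and
#' 0 for opposite homozygotes. Distance = 1 - similarity.
#'
#' @param ds genotype_dataset with >= 2 individuals.
#' @param allow_missing_pairs if FALSE (default), a pair with no mutually
#'   called marker raises an error; if TRUE its entry is NA.
#' @return symmetric numeric matrix with individual ids as dimnames.
#' @export
ibs_distance <- function(ds, allow_missing_pairs = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples)
  if (n < 2) stop("need at least 2 individuals")
  X <- ds$calls
  I0 <- (!is.na(X) & X == 0L) + 0
  I1 <- (!is.na(X) & X == 1L) + 0
  I2 <- (!is.na(X) & X == 2L) + 0
  same <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  one <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
         tcrossprod(I1, I2) + tcrossprod(I2, I1)
  shared <- tcrossprod(I0 + I1 + I2)     # markers called in both
  if (any(shared[upper.tri(shared)] == 0)) {
    if (!allow_missing_pairs)
      stop("some individual pairs share no called marker")
  }
  sim <- (2 * same + one) / (2 * shared)
  D <- 1 - sim
  D[shared == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(ds$samples$individual_id, ds$samples$individual_id)
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of -D^2/2 followed by eigendecomposition; coordinates
#' are the top-k eigenvectors scaled by the square root of their
#' eigenvalues, and each dimension's explained proportion is its
#' eigenvalue's share of the positive spectrum.
#'
#' @param D symmetric distance matrix.
#' @param k number of dimensions requested.
#' @return list with `coords` (n x k' matrix), `eig` (all eigenvalues) and
#'   `explained` (proportion per returned dimension). If fewer than `k`
#'   positive eigenvalues exist, k is reduced with a warning.
#' @export
classical_mds <- function(D, k = 2) {
  fit <- stats::cmdscale(stats::as.dist(D), k = min(k, nrow(D) - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  k_eff <- min(k, length(pos))
  if (k_eff < k)
    warning("only ", k_eff, " positive dimensions available; k reduced")
  coords <- fit$points[, seq_len(k_eff), drop = FALSE]
  list(coords = coords, eig = eig,
       explained = eig[seq_len(k_eff)] / sum(pos))
}

# Weir-Cockerham variance components for one locus across r populations.
# n: called individuals per pop, p: allele-B freq per pop, h: het fraction
# per pop. Returns c(a, b, c) or NULL when undefined.
wc_components <- function(n, p, h) {
  r <- length(n)
  if (any(n < 2)) return(NULL)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(NULL)   # monomorphic overall
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham theta between two groups of a dataset
#'
#' Per-locus variance components are combined as a ratio of sums across
#' loci. Loci monomorphic across both groups, or with fewer than two
#' called individuals in either group, are skipped.
#'
#' @param ds genotype_dataset.
#' @param idx_a,idx_b row indices (samples) of the two groups.
#' @return theta (can be slightly negative in undifferentiated samples).
#' @export
wc_theta <- function(ds, idx_a, idx_b) {
  ga <- ds$calls[idx_a, , drop = FALSE]
  gb <- ds$calls[idx_b, , drop = FALSE]
  na <- colSums(!is.na(ga)); nb <- colSums(!is.na(gb))
  pa <- colSums(ga, na.rm = TRUE) / (2 * pmax(na, 1L))
  pb <- colSums(gb, na.rm = TRUE) / (2 * pmax(nb, 1L))
  ha <- colSums(ga == 1L, na.rm = TRUE) / pmax(na, 1L)
  hb <- colSums(gb == 1L, na.rm = TRUE) / pmax(nb, 1L)
  num <- 0; den <- 0
  for (l in seq_len(ncol(ga))) {
    comp <- wc_components(c(na[l], nb[l]), c(pa[l], pb[l]), c(ha[l], hb[l]))
    if (is.null(comp)) next
    num <- num + comp[1]
    den <- den + sum(comp)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise Weir-Cockerham F_ST and Reynolds distances between groups
#'
#' @param ds genotype_dataset.
#' @param groups character/factor of group labels per sample; defaults to
#'   `ds$samples$group`. Every group must have >= 2 individuals.
#' @return data.frame `pop_a`, `pop_b`, `theta`, `reynolds_d`
#'   (`-ln(1 - max(theta, 0))`).
#' @export
pairwise_fst <- function(ds, groups = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(groups)) groups <- ds$samples$group
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2))
    stop("groups with fewer than 2 individuals: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  gs <- names(tab)
  out <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    th <- wc_theta(ds, which(groups == gs[i]), which(groups == gs[j]))
    out[[length(out) + 1]] <- data.frame(
      pop_a = gs[i], pop_b = gs[j], theta = th,
      reynolds_d = reynolds_distance(th), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reynolds genetic distance from theta
#'
#' `d = -ln(1 - theta)`, with negative theta clamped to 0 first; theta >= 1
#' yields `Inf`.
#'
#' @param theta F_ST estimate(s).
#' @return numeric distance(s).
#' @export
reynolds_distance <- function(theta) {
  ifelse(is.na(theta), NA_real_,
         ifelse(theta >= 1, Inf, -log(1 - pmax(theta, 0))))
}

#' Square distance matrix from a pairwise table
#'
#' @param fst data.frame from [pairwise_fst()].
#' @param value column to place in the matrix (`"reynolds_d"` or `"theta"`).
#' @return labeled symmetric matrix with zero diagonal.
#' @export
fst_matrix <- function(fst, value = "reynolds_d") {
  labs <- sort(unique(c(fst$pop_a, fst$pop_b)))
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (k in seq_len(nrow(fst))) {
    D[fst$pop_a[k], fst$pop_b[k]] <- fst[[value]][k]
    D[fst$pop_b[k], fst$pop_a[k]] <- fst[[value]][k]
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape for >= 4 taxa; the unique 3-taxon
#' solution in closed form). Negative branch lengths are clamped to zero
#' with a warning; labels are taken from the matrix dimnames.
#'
#' @param D symmetric distance matrix with labeled rows.
#' @return `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 3) {
    warning("fewer than 3 taxa: returning trivial 2-taxon tree")
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(D[1, 2] / 2, D[1, 2] / 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  if (n == 3) {
    x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3, 2, byrow = TRUE),
               edge.length = c(x, y, z), tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
  } else {
    tr <- ape::nj(stats::as.dist(D))
  }
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0), " negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
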