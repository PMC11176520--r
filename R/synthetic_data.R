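# Seeded genotype generators with ground-truth records:
#  - sim_structured: multi-population Balding-Nichols panels (known F_ST)
#  - sim_wright_fisher: forward Wright-Fisher with recombination (known Ne)
#  - plant_roh: homozygous segments of known span planted into a dataset
# Each is a pure function of its seed; the truth record attached as
# attr(ds, "truth") suffices to compute expected downstream results.

# uniform marker map over n_autosomes chromosomes of equal length
uniform_map <- function(n_loci, n_autosomes, chrom_length_bp) {
  chrom <- sort(rep_len(seq_len(n_autosomes), n_loci))
  pos <- numeric(n_loci)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(round(stats::runif(k, 1, chrom_length_bp)))
  }
  data.frame(id = sprintf("snp%05d", seq_len(n_loci)),
             chromosome = as.character(chrom), position_bp = pos,
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

#' Simulate a structured multi-population panel (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn uniformly from `anc_range`; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p, so F is that population's expected divergence (and the
#' expected Weir-Cockerham theta between two populations simulated at the
#' same F). Genotypes are Binomial(2, p_pop); missing calls are dropped
#' uniformly at `missing_rate`.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled to `n_pops`).
#' @param n_loci number of biallelic markers.
#' @param fst Balding-Nichols F per population (recycled); use a tiny
#'   value (e.g. 1e-6) for an effectively panmictic panel.
#' @param anc_range range of ancestral allele frequencies.
#' @param n_autosomes,chrom_length_bp map layout (equal-length autosomes).
#' @param missing_rate probability a call is set missing.
#' @param seed integer seed (mandatory; the generator is deterministic).
#' @return genotype_dataset with `attr(, "truth")`: a list holding the
#'   ancestral and per-population allele frequencies and the parameters.
#' @export
sim_structured <- function(n_pops = 2, n_per_pop = 30, n_loci = 1000,
                           fst = 0.05, anc_range = c(0.1, 0.9),
                           n_autosomes = 26, chrom_length_bp = 1e8,
                           missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(fst > 0), all(fst < 1), n_pops >= 1)
  set.seed(seed)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  markers <- uniform_map(n_loci, n_autosomes, chrom_length_bp)
  p_anc <- stats::runif(n_loci, anc_range[1], anc_range[2])
  p_pop <- matrix(NA_real_, n_pops, n_loci)
  calls <- matrix(NA_integer_, sum(n_per_pop), n_loci)
  pop_label <- character(0)
  row0 <- 0
  for (k in seq_len(n_pops)) {
    F <- fst[k]
    p_pop[k, ] <- stats::rbeta(n_loci, p_anc * (1 - F) / F,
                               (1 - p_anc) * (1 - F) / F)
    g <- matrix(stats::rbinom(n_per_pop[k] * n_loci, 2,
                              rep(p_pop[k, ], each = n_per_pop[k])),
                n_per_pop[k], n_loci)
    calls[row0 + seq_len(n_per_pop[k]), ] <- g
    pop_label <- c(pop_label, rep(sprintf("POP%d", k), n_per_pop[k]))
    row0 <- row0 + n_per_pop[k]
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(calls)) < missing_rate
    calls[drop] <- NA_integer_
  }
  samples <- data.frame(family_id = pop_label,
                        individual_id = sprintf("%s_I%03d", pop_label,
                                                unlist(lapply(n_per_pop, seq_len))),
                        group = pop_label, stringsAsFactors = FALSE)
  ds <- genotype_dataset(samples, markers, calls)
  attr(ds, "truth") <- list(model = "balding_nichols", fst = fst,
                            p_anc = p_anc, p_pop = p_pop, seed = seed,
                            missing_rate = missing_rate)
  ds
}

# one recombinant gamete from parent haplotypes hapA/hapB (0/1 vectors)
# over chromosomes described by chrom_index list and morgan lengths
make_gamete <- function(hapA, hapB, chrom_loci, pos_morgan, morgans) {
  gam <- integer(length(hapA))
  for (c_i in seq_along(chrom_loci)) {
    idx <- chrom_loci[[c_i]]
    nx <- stats::rpois(1, morgans[c_i])
    start <- stats::rbinom(1, 1, 0.5)
    if (nx == 0) {
      gam[idx] <- if (start == 0) hapA[idx] else hapB[idx]
    } else {
      bp <- sort(stats::runif(nx, 0, morgans[c_i]))
      phase <- (findInterval(pos_morgan[idx], bp) + start) %% 2
      gam[idx] <- ifelse(phase == 0, hapA[idx], hapB[idx])
    }
  }
  gam
}

#' Forward Wright-Fisher simulation with recombination
#'
#' A monoecious population of `true_ne` diploids (2 Ne haplotypes) evolves
#' `n_generations` under random mating (selfing allowed). Gametes
#' recombine with Poisson-distributed crossovers per chromosome (rate =
#' map length in Morgans). Initial haplotypes are independent Bernoulli
#' draws at frequencies uniform in `init_freq_range` (linkage
#' equilibrium), so simulated LD is the product of drift at `true_ne`.
#'
#' @param true_ne diploid population size (>= 2).
#' @param n_generations generations to evolve (>= 1).
#' @param n_chrom number of chromosomes.
#' @param chrom_morgans genetic length per chromosome (Morgans).
#' @param chrom_length_bp physical length per chromosome.
#' @param n_loci total loci across chromosomes.
#' @param sample_n diploid individuals sampled at the end (<= true_ne).
#' @param init_freq_range range of initial allele frequencies.
#' @param seed integer seed (mandatory).
#' @param max_retries resimulations attempted (advancing the seed, with a
#'   warning) if every locus fixes.
#' @return genotype_dataset; `attr(, "truth")` records `true_ne` and the
#'   configuration.
#' @export
sim_wright_fisher <- function(true_ne = 100, n_generations = 200,
                              n_chrom = 1, chrom_morgans = 0.5,
                              chrom_length_bp = 50e6, n_loci = 500,
                              sample_n = 50, init_freq_range = c(0.1, 0.9),
                              seed, max_retries = 3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(true_ne >= 2, n_generations >= 1, sample_n <= true_ne)
  set.seed(seed)
  chrom_morgans <- rep_len(chrom_morgans, n_chrom)
  markers <- uniform_map(n_loci, n_chrom, chrom_length_bp)
  chrom_loci <- lapply(as.character(seq_len(n_chrom)),
                       function(ch) which(markers$chromosome == ch))
  pos_morgan <- numeric(n_loci)
  for (c_i in seq_len(n_chrom)) {
    idx <- chrom_loci[[c_i]]
    pos_morgan[idx] <- markers$position_bp[idx] / chrom_length_bp *
      chrom_morgans[c_i]
  }
  for (attempt in seq_len(max_retries)) {
    p0 <- stats::runif(n_loci, init_freq_range[1], init_freq_range[2])
    H <- matrix(stats::rbinom(2 * true_ne * n_loci, 1, rep(p0, each = 2 * true_ne)),
                2 * true_ne, n_loci)
    for (gen in seq_len(n_generations)) {
      newH <- matrix(0L, 2 * true_ne, n_loci)
      parents <- matrix(sample.int(true_ne, 2 * true_ne, replace = TRUE),
                        ncol = 2)
      for (ind in seq_len(true_ne)) {
        m <- parents[ind, 1]; f <- parents[ind, 2]
        newH[2 * ind - 1, ] <- make_gamete(H[2 * m - 1, ], H[2 * m, ],
                                           chrom_loci, pos_morgan, chrom_morgans)
        newH[2 * ind, ] <- make_gamete(H[2 * f - 1, ], H[2 * f, ],
                                       chrom_loci, pos_morgan, chrom_morgans)
      }
      H <- newH
    }
    freq <- colMeans(H)
    if (any(freq > 0 & freq < 1)) break
    warning("all loci fixed; resimulating with advanced seed")
    set.seed(seed + attempt)
  }
  picked <- sort(sample.int(true_ne, sample_n))
  calls <- H[2 * picked - 1, , drop = FALSE] + H[2 * picked, , drop = FALSE]
  samples <- data.frame(family_id = "WF",
                        individual_id = sprintf("WF_I%03d", seq_len(sample_n)),
                        group = "WF", stringsAsFactors = FALSE)
  ds <- genotype_dataset(samples, markers, calls)
  attr(ds, "truth") <- list(model = "wright_fisher", true_ne = true_ne,
                            n_generations = n_generations,
                            chrom_morgans = chrom_morgans,
                            chrom_length_bp = chrom_length_bp, seed = seed)
  ds
}

#' Plant homozygous segments into a dataset
#'
#' In a random subset of carrier individuals, every genotype inside the
#' region is set to one homozygote (a per-individual coin flip between the
#' two), producing runs that satisfy the ROH criteria by construction.
#'
#' @param ds genotype_dataset.
#' @param chromosome,start_bp,end_bp the region (closed interval).
#' @param carrier_fraction fraction of individuals that receive the run.
#' @param seed integer seed (mandatory).
#' @param min_snp,min_length_bp detection criteria used to validate that
#'   the region can ever qualify as a ROH; violations raise an error
#'   naming the failed criterion.
#' @return genotype_dataset; `attr(, "truth")` lists the planted segments
#'   (`individual_id`, `chromosome`, `start_bp`, `end_bp`, `n_snp`, the
#'   first/last covered marker positions).
#' @export
plant_roh <- function(ds, chromosome, start_bp, end_bp,
                      carrier_fraction = 1, seed, min_snp = 15,
                      min_length_bp = 1e6) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(ds, "genotype_dataset"),
            carrier_fraction >= 0, carrier_fraction <= 1)
  set.seed(seed)
  mi <- which(ds$markers$chromosome == as.character(chromosome) &
              ds$markers$position_bp >= start_bp &
              ds$markers$position_bp <= end_bp)
  if (length(mi) < min_snp)
    stop("region holds ", length(mi), " markers; minimum SNP criterion (",
         min_snp, ") can never be met")
  span <- max(ds$markers$position_bp[mi]) - min(ds$markers$position_bp[mi])
  if (span < min_length_bp)
    stop("region marker span is ", span, " bp; minimum length criterion (",
         min_length_bp, " bp) can never be met")
  n <- nrow(ds$samples)
  n_carrier <- round(carrier_fraction * n)
  carriers <- if (n_carrier > 0) sort(sample.int(n, n_carrier)) else integer(0)
  truth <- NULL
  for (s in carriers) {
    hom <- sample(c(0L, 2L), 1)
    ds$calls[s, mi] <- hom
    truth <- rbind(truth, data.frame(
      individual_id = ds$samples$individual_id[s],
      chromosome = as.character(chromosome),
      start_bp = min(ds$markers$position_bp[mi]),
      end_bp = max(ds$markers$position_bp[mi]),
      n_snp = length(mi), allele_code = hom, stringsAsFactors = FALSE))
  }
  prior <- attr(ds, "truth")
  attr(ds, "truth") <- list(model = "planted_roh", planted = truth,
                            carriers = carriers, base_truth = prior,
                            seed = seed)
  ds
}
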