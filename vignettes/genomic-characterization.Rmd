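---
title: "Genomic characterization of small livestock populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic characterization of small livestock populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockdiv)
```

flockdiv implements the standard genome-wide characterization workflow
applied to local livestock breeds typed on medium-density SNP arrays
(OvineSNP50-class chips): quality control, within-population diversity,
runs of homozygosity (ROH) and the genomic inbreeding coefficient F~ROH~,
homozygosity islands, LD-based effective population size, and
between-population structure. This vignette documents the statistical
choices, the tunable parameters, what the synthetic-data generators do and
do not emulate, and the known limitations.

## Data model

A `genotype_dataset` holds diploid biallelic genotypes as allele-B dosage
codes (0/1/2, `NA` = missing). The 0/2 orientation is a file-order artifact
(the first allele encountered in a PED file becomes `allele_a`); every
statistic in the package depends only on allele frequencies and
heterozygosity and is therefore orientation-invariant, which the test suite
checks by global code swaps. Coordinates are 1-based marker positions as in
MAP/BIM files, and all interval logic (ROH spans, islands, annotation
overlap) treats intervals as closed `[start_bp, end_bp]`.

## Quality control

`run_qc()` applies, in order: autosome filter (labels `"1".."26"` by
default — chromosome `"0"`, sex and contig labels are removed), individual
call rate (default ≥ 0.99), SNP call rate (default ≥ 0.95), minor allele
frequency (default ≥ 0.05, recomputed on the retained individuals), and
optionally windowed LD pruning (50-SNP windows, 10-SNP step, r² > 0.2).
All thresholds are inclusive at the boundary. The stage order mirrors
PLINK's `--mind`/`--geno`/`--maf` precedence; because order matters when
missingness is structured, the per-stage report telescopes so any
deviation is visible.

Pruning slides windows over the currently retained markers of each
chromosome and, within a violating pair, removes the lower-MAF member
(tie: the later-positioned marker), repeating passes until no surviving
within-window pair exceeds the threshold. r² is the squared Pearson
correlation of genotype dosages over pairwise-complete samples — the
unphased (composite) measure; zero-variance markers have r² defined as 0.
The exact removal choice differs between PLINK versions, so ours is simply
documented and deterministic; pruned marker sets are therefore not
expected to be bit-identical to PLINK's, while the post-condition (no
retained pair above threshold) is identical and brute-force verified.

## Diversity indices

Per locus, with `n` called individuals and allele-B frequency `p`:
observed heterozygosity `h_obs` is the heterozygote fraction; expected
heterozygosity uses the small-sample unbiased estimator
`h_exp = 2p(1-p) · 2n/(2n-1)` (the plain `2p(1-p)` is available behind a
flag, since reports rarely name their convention). Per individual, the
method-of-moments inbreeding coefficient follows the PLINK `--het`
convention, `F_i = (O_hom − E_hom)/(L − E_hom)`, with `E_hom` summing
`1 − h_exp` over the markers called in that individual. With the unbiased
`h_exp`, `E[O_hom] = E[E_hom]` under Hardy–Weinberg, so mean F is centred
on zero in panmictic simulations — a property test. Summary dispersions
are sample standard deviations across loci (H~O~, H~E~, MAF) and across
individuals (F~IS~); published tables rarely state the axis, so the
per-locus and per-individual tables are exposed for recomputation under
either convention.

## Runs of homozygosity

`detect_roh()` implements the consecutive-runs method: per individual and
chromosome, maximal stretches of homozygous, non-missing calls in which
consecutive markers are at most `max_gap_bp` apart. The defaults are the
criteria used for OvineSNP50-class data: ≥ 15 SNPs, no heterozygous and no
missing call inside a run (`max_opposite = max_missing = 0`; positive
tolerances use a greedy counter-based scan), gap ≤ 250 kb, length ≥ 1 Mb.
Three conventions needed fixing:

* **Length is `end_bp − start_bp`** (not `+1`). This is forced by the
  island arithmetic in published tables of this workflow, where
  `49,619,573 − 47,169,096 = 2,450,477` is printed as the interval length.
* **"Opposite genotypes" means heterozygotes**: a run may mix the two
  homozygous codes, matching the consecutive-runs implementations in use.
  A strict same-allele mode (`strict_same_allele = TRUE`) breaks runs at
  0↔2 transitions for sensitivity analysis.
* **Length classes are left-closed**: `[1,2), [2,4), [4,8), [8,16),
  [16,∞)` Mb; a run of exactly 2.0 Mb falls in 2–4.

Zero-ROH individuals count in the N~ROH~ denominator (this changes means
and is deliberate); L~ROH~ averages over segments; NC~ROH~ averages
per-chromosome counts including empty chromosomes, while LC~ROH~ averages
per-chromosome mean lengths over occupied chromosomes only. F~ROH~ divides
an individual's total run length by the autosomal genome length, default
exactly 2.4 Gb (sheep's ~2.4 Gb; configurable). The detector is validated
segment-for-segment against an independent brute-force enumeration on
random genotype matrices.

Marker density matters: the gap and SNP-count criteria only behave
realistically near chip density (~55 kb spacing). The bundled
characterization analysis therefore simulates at full density (43,000
markers over 26 × 92 Mb), while structure analyses, which are
density-insensitive, run on a 20×-reduced map.

## Homozygosity islands

`snp_incidence()` counts, per marker, the individuals whose ROH covers it
(closed interval), and standardizes the counts into z-scores with
descriptive upper-tail normal p-values — no multiple-testing correction,
matching the workflow this reproduces. `island_scan()` flags the top
`ceiling(0.001 · n_markers)` markers by incidence — a rank rule, not a z
cut-off; ranking by count, proportion, z or p is equivalent. Ties at the
boundary are all included (logged), so the flagged set can slightly exceed
the nominal count. Flagged markers within `merge_gap_bp` (default 1 Mb —
published analyses do not state their merge rule, so it is explicit and
configurable) on one chromosome merge into an island spanning first to
last member. Island–annotation overlap is closed-interval intersection per
chromosome; features touching an island endpoint overlap it.

## Effective population size

Both estimators consume dosage-correlation r², appropriate for unphased
chip data.

**Historical trajectory.** Intrachromosomal pairs are binned by physical
distance (default 50 equal-width bins over 0.025–25 Mb, ≥ 50 pairs/bin);
the bin's mean r² is corrected for sample size (`r²_adj = r̄² − 1/n`) and
inverted through the Sved-type drift expectation
`E[r²] ≈ 1/(α + 4·Ne·c)`, giving `Ne(c) = (1/(4c))(1/r²_adj − α)` at
`t = 1/(2c)` generations ago, with `c = distance · 1e-8` under the default
1 cM/Mb linear map. `α` is 1 without mutation, 2 for Sved's original form,
2.2 with mutation (the default for real data). Validation against forward
Wright–Fisher simulations uses `α = 1` because the simulator has no
mutation. Sved's curve is itself a first-order approximation: simulated
equilibrium r² sits 10–15% below it at moderate `4Nec`, which the
inversion translates into a comparable upward bias in Ne — recovery of a
true Ne = 100 lands within ±30%, not exactly on 100, and tests assert
exactly that.

**Contemporary Ne.** Unlinked pairs (markers on different chromosomes;
MAF ≥ 0.05 by default) enter the bias-corrected LD method under random
mating, with the empirical sampling expectations
`E[r²_sample] = 1/S + 3.19/S²` for harmonic-mean sample size S ≥ 30 and
`0.0018 + 0.907/S + 4.44/S²` below, and the corresponding quadratic
inversions for Ne from `r²' = r̄² − E[r²_sample]`; `r²' ≤ 0` or a negative
discriminant yields an infinite estimate (no detectable drift signal).
Those expectations describe the Burrows-composite estimator with n/(n−1)
weighting, whose independence expectation is `(S/(S−1))²/(S−1)` —
numerically `1/S + 3.19/S²` — so pair r² is scaled by `(S/(S−1))²` before
the correction; plain Pearson r² (expectation `1/(S−1)`) would
over-subtract and inflate Ne by roughly a third. The two sample-size
regimes meet at S = 30 with a small inherent discontinuity (≈ 8% in the
small-signal limit, from 1/3 vs 0.308 in the numerators); the package
keeps the published constants rather than smoothing them. Dense panels are
thinned to 3,000 markers by a deterministic stride before the pair matrix
is formed; unlinked pairs are exchangeable, so thinning costs precision,
not accuracy. No jackknife confidence intervals are produced in this
version — point estimates only.

## Population structure

Pairwise identity-by-state distance is one minus the mean shared-allele
fraction over mutually called markers (shared count 2 for identical
genotypes, 1 for one dosage step, 0 for opposite homozygotes). Classical
(Torgerson) MDS double-centres −D²/2; explained variance is reported per
dimension as its eigenvalue's share of the **positive** spectrum (negative
eigenvalues from non-Euclidean distances are discarded and logged).

Differentiation is the Weir–Cockerham θ, computed per locus from the
variance components a, b, c and combined across loci as a ratio of sums
(a ratio-of-averages, not an average of ratios). Loci monomorphic across
the pair or with fewer than two called individuals in either group are
skipped. On two-population Balding–Nichols simulations at F = 0.05, θ is
recovered within ±0.01; under the null it is within ±0.01 of zero. Note
that AMOVA-based pairwise F~ST~ implementations differ numerically from θ
at the margins, so published F~ST~ ranges from such tools are indicative
rather than bit-exact targets. Reynolds distance is `−ln(1 − θ)` with
negative θ clamped to zero before the transform (raw θ is retained);
θ ≥ 1 maps to infinity. Neighbor-joining uses Saitou–Nei agglomeration
(ape's implementation for ≥ 4 taxa; the unique closed-form solution for
3), recovers additive matrices exactly, clamps negative branch lengths to
zero with a warning, and serializes to Newick. Whether trees are built on
breed-level or country-pooled distances is the caller's choice via the
grouping labels.

## Synthetic data: what it does and does not emulate

Three seeded generators provide ground truth for every stage; each is a
pure function of its seed and records a truth object sufficient to compute
expected downstream results.

* `sim_structured()` — Balding–Nichols: ancestral frequencies uniform on a
  range, population frequencies Beta-distributed around them with
  parameter F, genotypes Binomial(2, p). Chosen because it makes expected
  F~ST~ analytic, so structure-stage validation is quantitative. It
  produces **linkage-equilibrium** genotypes: ROH arise only where
  planted, and LD-based Ne on such panels is essentially unbounded — which
  the characterization analysis prints as a caveat.
* `sim_wright_fisher()` — a forward-in-time monoecious Wright–Fisher
  population (selfing allowed) with Poisson crossovers per Morgan, chosen
  over a coalescent so the LD–Ne link stays mechanically transparent at
  desk scale (Ne ≤ a few hundred, loci ≤ ~1,000). Initial haplotypes are
  in linkage equilibrium, so runs must be long enough (~100–200
  generations at Ne = 100) for drift LD to equilibrate.
* `plant_roh()` — sets a region homozygous in a carrier subset
  (per-individual coin-flip allele), erroring if the region can never meet
  the SNP-count or length criteria. Planted runs can legitimately extend
  into homozygous flanking markers, so recovery tests assert coverage of
  the planted span, not exact endpoints.

None of the generators emulate realistic site-frequency spectra,
selection, mutation, genotyping-batch artifacts, or family structure.
Passing tests therefore demonstrate correctness of the estimators under
their model assumptions, not robustness to every property of real chip
data.

## Problem sizes and numerical choices

The bundled analyses use 24 individuals × 43,000 markers for the
single-population track (chip density, where ROH criteria bind), a
six-population, 204-individual, 2,100-marker panel for the structure
track, and Wright–Fisher populations of Ne = 100 with 500–1,000 loci for
Ne calibration — sizes chosen so the full workflow and its validation
suite run in minutes on a laptop. Degenerate inputs are handled
explicitly: zero-call markers are excluded with a warning; a zero-variance
incidence table returns no islands; `r²' ≤ 0` gives an infinite Ne; pairs
with no shared called marker are an error unless explicitly allowed;
groups reduced below two individuals are dropped from structure analyses
with a warning.

## Limitations

* PED/MAP, BED/BIM/FAM (SNP-major) only; no VCF, PLINK 2, or phased data.
* Sliding-window ROH detection (PLINK `--homozyg`) is out of scope; only
  the consecutive-runs method is implemented.
* F_ST is the Weir–Cockerham two-population θ; AMOVA-style estimates from
  other tools will differ slightly.
* The recombination map is linear (configurable cM/Mb); no map files.
* Ne point estimates carry the approximation biases discussed above and
  no confidence intervals.
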