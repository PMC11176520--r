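# flockdiv

Genome-wide characterization of livestock populations from medium-density
SNP-array genotypes, written for conservation-genetics studies of local
breeds (the motivating case is a small fat-tailed sheep population typed
on an OvineSNP50-class chip). The package covers the full workflow such
studies run:

* **PLINK I/O** — PED/MAP and binary BED/BIM/FAM (SNP-major), dataset
  merging with allele-coding reconciliation, per-breed subsampling.
* **Quality control** — autosome / call-rate / MAF filters and windowed
  LD pruning (`--indep-pairwise`-style), with a telescoping per-stage
  report.
* **Diversity** — per-locus H<sub>O</sub>, H<sub>E</sub> (unbiased
  2p(1−p)·2n/(2n−1)), MAF, and per-individual F<sub>IS</sub> =
  (O<sub>hom</sub> − E<sub>hom</sub>)/(L − E<sub>hom</sub>).
* **Runs of homozygosity** — consecutive-runs detection (≥ 15 SNPs, no
  heterozygous/missing call, gap ≤ 250 kb, length ≥ 1 Mb by default),
  length classes 1–2 / 2–4 / 4–8 / 8–16 / > 16 Mb, N<sub>ROH</sub> /
  L<sub>ROH</sub> / per-chromosome summaries, and F<sub>ROH</sub> =
  Σ length / 2.4 Gb.
* **ROH islands** — per-SNP incidence of run membership, z-scores, the
  top-0.1% rank rule, island merging, and gene/QTL interval annotation.
* **Effective population size** — historical trajectory from binned LD
  decay via Ne(c) = (1/(4c))(1/r²<sub>adj</sub> − α) at t = 1/(2c), and
  contemporary Ne by the bias-corrected LD method (random mating,
  Waples–Do corrections with the S = 30 regime split).
* **Structure** — identity-by-state distances, classical MDS with
  explained variance, pairwise Weir–Cockerham θ, Reynolds distances
  −ln(1 − θ), and neighbor-joining trees with Newick export.
* **Synthetic data** — seeded Balding–Nichols panels (analytic F_ST),
  forward Wright–Fisher simulation with recombination (known Ne), and
  planted homozygous segments, each with a ground-truth record.

All estimators the workflow depends on (consecutive-runs detector, island
scan, Weir–Cockerham θ, both Ne estimators, IBS) are implemented here and
validated against independent oracles — brute-force enumeration,
closed-form arithmetic, and simulations with known truth.

## Worked example

The repository is organised as an analysis workflow; the numbered scripts
under `analysis/` run the two study tracks end to end on synthetic panels
with known truth:

```sh
Rscript analysis/01_simulate_panels.R    # build panels + truth sidecars
Rscript analysis/02_characterization.R   # QC, diversity, ROH, islands, Ne
Rscript analysis/03_structure.R          # merge, F_ST, MDS, NJ
Rscript analysis/04_ne_validation.R      # Ne estimators vs known truth
```

`02_characterization.R` characterizes a 24-individual population typed at
chip density (43,000 markers over 26 autosomes ≈ 2.4 Gb) with a planted
homozygosity hotspot on chromosome 13 carried by 23/24 individuals; it
prints:

```
QC: 43000 -> 42819 markers, 24 -> 24 individuals
H_O = 0.417 +/- 0.124   H_E = 0.418 +/- 0.089   MAF = 0.317 +/- 0.109
F_IS = 0.003 +/- 0.007
ROH: 41 segments; N_ROH = 1.71 +/- 0.95; L_ROH = 1.84 +/- 0.65 Mb
F_ROH = 0.0013 +/- 0.0005
ROH islands (top 0.1% incidence):
  chromosome start_bp  end_bp length_bp n_snp
1         13  3215368 5486366   2270998    45
planted hotspot 13:3215368-5486366 recovered: TRUE
```

Reading the numbers: H<sub>O</sub> ≈ H<sub>E</sub> and F<sub>IS</sub> ≈ 0
because the panel is simulated panmictic; the 41 detected runs are
dominated by the planted hotspot (23 carriers) plus chance background
runs, and the island scan recovers the planted span exactly — the point
of the synthetic truth. On real data the same call produces the
Table-1-style diversity/ROH summary and Table-2-style island list for the
population under study.

`04_ne_validation.R` calibrates both Ne estimators against Wright–Fisher
populations of true Ne = 100 (its run printed contemporary estimates with
median 97.1 and recent-bin historical medians with median 136.7 — the
historical inversion inherits a mild upward bias from Sved's
approximation; see the methods vignette).

Each programmatic entry point does the same work in-session, e.g.

```r
library(flockdiv)
ds  <- read_bed("mypanel")                    # BED/BIM/FAM triple
res <- run_characterization(ds, out_dir = "out")
res$diversity; res$roh_summary$classes; res$islands
```

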