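# panhe

Gene presence/absence variation (PAV) and homoeologous exchange (HE)
detection for allopolyploid pangenomes, with pangenome/core-genome growth
modelling — built for the *Brassica napus* A/C-subgenome setting and
exercised end-to-end on a synthetic allotetraploid data generator, so no
sequencing data is needed to run or test any of it.

## What it does

Allotetraploid genomes carry pairs of homoeologous chromosomes (A01/C01,
...) with largely collinear gene content. `panhe` implements the
computational core of a pangenome survey of such a species:

* **PAV calling** — a gene is absent in an accession when fewer than
  `lostCutoff` (5%) of its exon-union bases are covered at depth ≥
  `minCov` (2); the calls assemble into a binary genes × accessions
  matrix (`1` present / `0` absent).
* **HE detection** — runs of ≥3 consecutive absent genes are HE-related
  when their best homology hits lie collinearly (Spearman |ρ| ≥ 0.8) on
  the homoeologous partner chromosome (pid > 90, alignment length ± 10 bp)
  over genes called present there, and binned (1000 bp) coverage shows the
  recipient near 0× with the donor above 1.5× the accession mean — i.e.
  segmental loss with copy-number doubling on the partner. Direction is
  donor → recipient subgenome.
* **Core/variable partitioning** — core genes are present in all retained
  accessions; a gene family is core if any member is, variable only when
  some accession lacks the whole family. Plus per-accession uniquely
  present/absent counts and a 1000-bootstrap Hamming/average-linkage
  dendrogram of accessions.
* **Growth modelling** — up to 100,000 seeded genome combinations per
  size; pangenome fitted as `y = A·x^B + C` and core genome as
  `y = A·e^(Bx) + C` by Levenberg–Marquardt least squares; negative `B`
  with finite `C` means a closed pangenome with asymptotic size `C ± se(C)`.
* **Synthetic generator** — paired A/C chromosomes, one-to-one homoeologs
  (91–99% identity), HEs biased to chromosome ends and C→A, more frequent
  in resynthesised accessions, independent single-gene deletions, Poisson
  ~12× depth (0× over losses, 2× over duplications), all seeded.

File formats go through the usual suspects: GFF3 annotations, `samtools
depth`/bedGraph depth tracks, BLAST 12-column tabular homology, TSV
matrices and assignments, Newick trees, YAML configs.

## Worked example

The `analysis/` scripts run the whole pipeline on the default simulated
study (3 chromosome pairs × 60 genes, 20 accessions of which 8 synthetic,
12× depth). Running them in order prints, for seed 1:

```
$ Rscript analysis/01_simulate.R
reference: 6 chromosomes, 360 genes, 180 homoeolog pairs
accessions: 20 (8 synthetic)
true HE events: 12 (67% C->A); single-gene deletions: 71

$ Rscript analysis/02_call_pav.R
PAV matrix: 360 genes x 20 accessions (excluded: 0)
agreement with truth: 1.0000 (0 discordant cells)
absent calls per accession: mean 10.2 (synthetic 19.9, nonsynthetic 3.8)

$ Rscript analysis/03_detect_hes.R
HE calls: 12 (true events: 12)
event-level precision 1.000, recall 1.000, direction accuracy 1.000

$ Rscript analysis/04_classify.R
synthetic study: 201/360 core genes (55.8%), 180/180 core families (100.0%)
reference B. napus pangenome: 65.2%/34.8% core/variable clusters, 62%/38% genes

$ Rscript analysis/05_model_growth.R
power-law fit (converged): A=-10.2 B=-5.21 C=360; predicted asymptotic size 360.0 +/- 0.0
pan:  C = 95996.0 +/- 7.6 (truth 96000)
core: C = 55999.2 +/- 2.8 (truth 56000)
```

Reading: the caller reproduces the simulated truth exactly at 12×; all 12
simulated exchanges are found with correct direction; every synthetic
accession loses markedly more genes than the natural ones (HEs, not single
deletions, drive the difference); homoeolog families stay core because an
HE deletes one copy while doubling the other; and the fitted pangenome
asymptote pins the closed-pangenome size, with survey-scale coefficient
recovery within a fraction of a percent. Tables land under `results/`
(`pav_matrix.tsv`, `he_calls.tsv` + BED intervals, label tables,
`pav_dendrogram.nwk`, `growth_points_genes.tsv`).

The same machinery is available programmatically:

```r
library(panhe)
sim   <- simulate_study(sim_config(seed = 1))
calls <- lapply(sim$tracks, call_pav, annotation = sim$truth$annotation)
m     <- build_pav_matrix(calls, sapply(sim$tracks, track_mean_depth))
hes   <- detect_hes_all(calls, sim$truth$annotation, sim$tracks,
                        sim$truth$homology)
fits  <- fit_growth_models(growth_curves(m, "genes", cap = 500, seed = 1))
```

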