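---
title: "Methods: PAV calling, homoeologous exchange detection and pangenome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAV calling, homoeologous exchange detection and pangenome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panhe)
```

## The problem

*Brassica napus* (oilseed rape) is an allotetraploid: each nucleus carries
two related subgenomes, A (from *B. rapa*) and C (from *B. oleracea*),
organised as pairs of homoeologous chromosomes (A01 with C01, and so on)
whose gene content is largely collinear at >90% sequence identity. Across
accessions, individual genes come and go — presence/absence variation
(PAV) — and whole chromosome segments are overwritten by their homoeologous
counterpart in nonreciprocal **homoeologous exchanges** (HEs): the
recipient segment's genes are lost while the donor segment's copy number
doubles. Resynthesised ("synthetic") accessions, produced by crossing the
progenitor species, show more and larger HEs, concentrated near chromosome
ends and biased from C to A.

`panhe` implements the computational core of a pangenome survey of this
system: calling gene PAV from per-base read depth, separating HE-related
from independent gene loss, partitioning genes and gene families into core
and variable sets, clustering accessions by their PAV profiles, and
modelling how pangenome and core-genome size grow as accessions are added.
Read mapping, assembly, annotation and homology search are upstream of this
package; it consumes their standard outputs (GFF3, depth TSV/bedGraph,
BLAST tabular, two-column family tables).

## PAV calling

For gene $g$ with exon-union $E_g$ and accession depth track $d(\cdot)$,
the covered fraction at depth threshold $m$ is

$$f_g = \frac{\left|\{b \in E_g : d(b) \ge m\}\right|}{|E_g|},$$

and $g$ is called **absent** iff $f_g < c$. Defaults are $m =$ `min_cov`
$= 2$ and $c =$ `lost_cutoff` $= 0.05$, the standard setting for ~12×
skim data; for very deep libraries the conventional preset is
$m = 300$, $c = 0.70$ with identical semantics. Two conventions are fixed
here because the rule itself does not pin them down:

* **Strict inequality** at the boundary: $f_g$ exactly equal to the cutoff
  is *present*. The boundary case is measure-zero for real data but must be
  deterministic.
* Coverage is computed over the **exon union** (overlapping exons merged);
  a `gene-span` mode exists for annotations without usable exon models.

Both choices are exposed in `pav_params()`. Raising `min_cov` can only
lower $f_g$, and raising `lost_cutoff` can only convert present calls to
absent; these monotonicities are asserted as property tests.

Accessions whose genome-wide mean depth falls below `min_mean_depth`
(default 5×) are excluded before the matrix is assembled, since absence
calls from shallow libraries are dominated by sampling zeros; the cutoff is
a parameter because published analyses name excluded accessions rather
than a threshold.

## HE detection

Candidate events are maximal runs of $\ge$ `min_run_genes` (default 3)
rank-consecutive absent genes on one chromosome. Three tests follow, all
parameterised in `he_params()`:

1. **Homology.** Each run gene's best hit (ties broken by bitscore, then
   percent identity, then subject start) must land on the homoeologous
   partner chromosome with `pid > 90` and alignment length within
   $\pm 10$ bp of the query's exon-union length, and the annotated gene
   overlapping the hit must itself be called *present*. At least
   `support_frac_min` (default 0.8) of the run must pass: real
   annotations drop the occasional gene inside a true HE, and demanding
   unanimity would shatter long events, while 0.8 still rejects chance
   runs.
2. **Order.** Supported hits must be collinear: Spearman $|\rho| \ge 0.8$
   between query gene ranks and subject hit positions. "Roughly
   consecutive" needs an operational form; rank correlation is invariant
   to the (unknown) strand and spacing.
3. **Coverage.** In 1000-bp bins, the recipient interval mean must fall
   below `zero_factor` (0.1) × baseline, and the donor interval (the span
   of the supported hits) must exceed `dup_factor` (1.5) × baseline.

The **baseline** is the accession's genome-wide mean depth by default.
A donor-chromosome baseline sounds natural but is self-defeating: if the
duplicated segment covers fraction $f$ of the donor chromosome, the
chromosome mean is inflated to $\lambda(1+f)$ and the doubling test
$2\lambda > 1.5\lambda(1+f)$ fails for every $f \ge 1/3$ — exactly the
large terminal events the synthetics carry. The genome-wide mean is
invariant to the exchange itself (recipient loss offsets donor gain), so it
is the default; `baseline = "chromosome-mean"` remains available for
comparison.

Direction is read off the chromosome labels (donor subgenome →
recipient subgenome). Every absent gene ends up in exactly one of: an HE
call's recipient list, or the non-HE PAV list — an invariant the tests
assert.

## Core/variable classification

A **gene** is core iff present in every retained accession. A **family**
is core if at least one member is core (clause 1) and variable if some
accession lacks every member (clause 2). The clauses are neither exclusive
nor exhaustive; precedence is fixed as: clause 1 wins when both hold, and
families matching neither (no always-present member, never wholly lost)
default to core, because "variable" should certify a demonstrable
whole-family loss. Both raw clause outcomes are reported alongside the
label so other precedences can be reconstructed.

Uniquely present/absent counts per accession use the obvious definitions
(present only here / absent only here).

The accession dendrogram uses Hamming distance between binary PAV columns
with average linkage; support values are plain bootstrap proportions over
1000 gene resamplings (rows with replacement, seeded). The upstream
clustering tool this mirrors does not print its distance or linkage, so a
deterministic, parameter-free choice is made and both are configurable;
multiscale (approximately unbiased) p-values are out of scope. Columns are
sorted by accession id before clustering so zero-distance ties break
deterministically.

## Growth modelling

For each combination size $k = 1..N$, genome combinations are enumerated
exhaustively when $\binom{N}{k} \le$ `cap` and otherwise sampled uniformly
without replacement down to `cap` (default 100,000, seeded, via rejection
on a key set — collision rates are negligible at the scales involved).
Every sampled combination contributes one point: the pangenome size (genes
or families present in ≥1 member) and the core size (present in all
members; for families, ≥1 member gene present in every member accession).
All points are used for fitting, not per-$k$ means.

The pangenome is fitted as a power law and the core genome as an
exponential decay,

$$y_{pan} = A x^{B} + C, \qquad y_{core} = A e^{Bx} + C,$$

by Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`).
Starts are derived from the data (pan: $C_0 = 1.01\,\max y$,
$A_0 = \bar{y}_{x=1} - C_0$, $B_0 = -1$; core: $C_0 = 0.99\,\min y$,
$B_0 = -0.5$), with up to five seeded jittered restarts; a flat input
short-circuits to $A = 0$, $C = \bar y$. When $B < 0$ the curve is closed
and the asymptotic size is $C$, reported as $C \pm \mathrm{se}(C)$ from
the coefficient covariance — the "±" convention is interpreted here as the
standard error of $C$, the alternative readings (CI half-width, restart
spread) being indistinguishable from published summaries.

## The synthetic data generator

`sim_config()` fixes the study conditions the tests run under: 3
chromosome pairs × 60 genes (1500 bp, two exons, 1000 bp intergenic), 20
accessions of which 40% are synthetic, mean depth 12×, HE probability per
accession per chromosome pair 0.5 (synthetic) / 0.1 (nonsynthetic), spans
uniform over 5–20 genes, terminal anchoring with probability 0.9, C→A
direction with probability 0.8, and a 1% independent single-gene deletion
rate. The depth/coverage geometry (0× over losses, 2× over duplications,
~12× elsewhere) and the qualitative HE biases come from the target
biology; the HE rate and span numbers are order-of-magnitude choices —
published surveys do not quantify them — made once and exposed as
parameters rather than tuned.

Design points worth noting:

* Depth tracks are generated directly (Poisson per base, or exact rates in
  `depth_noise = "exact"` mode) rather than via read simulation and
  alignment: the detectors consume depth and homology tables, so this
  preserves exactly the statistical structure the rules test while keeping
  the suite aligner-free.
* HE segments are rank-aligned between homoeologs, mirroring ancestral
  collinearity; homoeolog identity is drawn per pair, uniform in 91–99%.
* Single-gene deletions are excluded from HE *donor* segments as well as
  recipient segments: a deleted donor copy would leave the segment's depth
  state (0× deleted vs 2× duplicated) undefined and the truth PAV
  ambiguous.
* Boundaries of lost/duplicated regions snap to intergenic midpoints
  (chromosome termini for terminal events) so coverage transitions align
  with gene/intergenic edges.

What the generator does **not** emulate: mappability and repeat artefacts,
GC-dependent coverage, annotation errors, paralogous cross-mapping,
partial-gene loss, reciprocal exchanges, and unplaced contigs. Passing
tests therefore demonstrate that the rules are implemented correctly and
recover truth under the assumed depth model, not that the thresholds are
optimal for any particular real data set.

## Problem sizes and numerical choices

The shipped tests and the acceptance analysis run the default conditions
(360 genes × 20 accessions; ~0.9 Mb per depth track), aggregate four
seeded replicates when ≥50 HE events are needed, cap growth-curve sampling
at a few hundred combinations per $k$ on synthetic matrices, and use 30
points per $n$ over $n = 1..20$ for survey-scale fit recovery — sizes at
which every step completes in seconds while leaving the estimators'
behaviour visible. Exhaustive subset enumeration (the growth-curve oracle)
is used up to 10 accessions. Spearman correlations on supported runs need
≥2 points; runs losing more than `1 - support_frac_min` of their genes are
rejected before the correlation is computed. All randomness flows from
explicit integer seeds; identical configuration and seed give bit-identical
simulations, sampled combinations and bootstrap trees.

## Known limitations

* The detector calls one event per absent run; adjacent independent
  deletions merge into the run and can stretch a call by a gene at either
  edge (event-matching in the tests allows ±1 gene).
* Family-level growth restricted to a combination re-applies only the
  core-member clause; whole-family-loss information outside the
  combination is ignored by construction.
* On small synthetic matrices the core-genome exponential fit extrapolates
  poorly (the observed core decays almost linearly over 20 accessions), so
  its asymptote can undershoot zero; asymptotes are reported as computed,
  with standard errors that make the uncertainty explicit.
* pid thresholds compare BLAST-style percent identities as given; no
  attempt is made to re-align or to model alignment-length inflation from
  gaps beyond the ±10 bp tolerance.
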