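---
title: "Models and conventions behind clonalniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind clonalniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalniche)
```

clonalniche implements the computational work-up for a recurring clinical
puzzle: a clonal, phenotypically aberrant T-cell expansion appears after
CAR-T therapy, and one must decide between a product-derived malignancy, a
de novo T-cell lymphoma, and a reactive (possibly infection-driven)
lymphoproliferation. Each module answers one piece of that question; this
vignette records the underlying models, the conventions chosen where a
convention had to be fixed, and what the synthetic-data tests do and do not
establish.

## Poisson power for transgene detection

If whole-genome sequencing of the lesion shows no reads on the CAR
construct, how much does that absence mean? Reads landing in the
construct's uniquely mappable region of length $L$ bases arrive
approximately as a Poisson process. With $\lambda_{autosomal}$ read pairs
per base on autosomes, a single integration event per cell (copy ratio
$r_{CAR} = 1/2$ relative to diploid autosomes), and a fraction $\rho$ of
cells carrying the construct,

$$\lambda_{CAR} = \lambda_{autosomal} \, L \, r_{CAR} \, \rho, \qquad
\mathrm{power} = P(n_{read} > 0) = 1 - e^{-\lambda_{CAR}}.$$

```{r}
detection_power(lambda_autosomal = 0.3, construct_length = 743,
                copy_ratio = 0.5, cell_fraction = 0.034)
min_detectable_fraction(0.3, 743, 0.5, target_power = 0.95)
```

At a 60x-genome autosomal rate of 0.3 read pairs per base and a 743-base
mappable region, power exceeds 0.95 for any construct-bearing fraction
above about 2.7%, so it certainly does at 3.4%. Note the asymmetry: 3.4%
is a fraction at which 95% power is comfortably available, not the exact
inverse of 0.95.

Two unit conventions coexist in this area: depth models count read *pairs*
per base, while alignment filters count individual records.
`count_construct_reads()` therefore reports both a record count and a
distinct-query-name (pair) count, and the simulation-consistency tests
compare the model against the pair count. The counter includes only
primary, mapped records (secondary 0x100 and supplementary 0x800 flags are
excluded) at or above the MAPQ threshold (default 30): the question is how
many reads received a confident primary placement on the construct.
Fractions above 1 are rejected rather than clamped.

## Neighborhood enrichment with a permutation null

The spatial statistic asks, for each ordered pair of cell types (A, B):
among the neighbors of type-A cells, what fraction are type B, and is that
fraction higher or lower than expected if labels were exchangeable over the
observed positions? Conventions, each of which had to be fixed one way:

* **Neighborhood**: Euclidean distance $0 < d \le r$ with $r = 200$ µm by
  default. The center is never its own neighbor (self-inclusion would
  manufacture self-enrichment), and the boundary is inclusive, matching
  common radius-graph builders.
* **Isolated centers** (no neighbor within $r$) are excluded from the
  type-A average rather than counted as zero: their neighbor composition
  is undefined, not empty. Rows of the observed matrix over types with
  eligible centers consequently sum to 1.
* **Null**: the single global label vector is permuted without replacement
  (no stratification), 1000 times by default, and the observed matrix is
  recomputed each time. The Z score is the observed value standardized by
  the permutation mean and the *population* (n-denominator) standard
  deviation; the choice of denominator is recorded in the result object.
* **Degenerate nulls**: when the permutation sd is exactly 0 (for example
  a single cell type, where every relabeling reproduces the observed
  matrix), Z is defined as 0 — the observation equals a degenerate null,
  which is no evidence of enrichment in either direction.
* **No multiple-testing correction** is applied; the matrix reports raw Z
  scores. Capping to ±9 (`cap_z()`) is a display convention only; analysis
  code receives uncapped values.

The neighbor search is exact (blockwise distance evaluation, no
approximate index), and a brute-force $O(n^2)$ oracle in the test suite
confirms equality on small inputs. Permutation cost is kept low by
building the neighbor adjacency once and reusing it for every relabeling.

## UMI-consensus genotyping

For a single somatic variant, read-level allele calls
(variant/reference/other) are collapsed within each (cell barcode, UMI)
molecule by strict majority. An exact tie for the top allele discards the
UMI: the molecule carries no usable evidence, and discarding inflates
neither class. Cell classification then follows the UMI counts: any
variant-consensus UMI makes the cell mutant; otherwise any covering UMI
(reference or other consensus — both span the queried position) makes it
wild-type; cells with no covering UMI stay unassigned. No minimum
reads-per-UMI is imposed — a single-read UMI is accepted as its own
consensus — which trades some error robustness for coverage; the
simulation tests quantify the trade (mutant-call precision stays above
0.95 at a 1% per-read error rate once UMIs carry three or more reads).

A thin adapter (`read_allele_calls_sam()`) extracts the allele table from
alignments given a `CONTIG:POS:REF>ALT` site (1-based, forward strand),
walking each read's CIGAR to the queried column; a deletion spanning the
site counts as covering, non-variant ("other").

## Clonotypes and biallelic rearrangement

Clones are keyed on beta-chain CDR3 amino-acid sets; alpha chains are
aggregated descriptively. The default `exact_set` keying groups cells with
identical beta sets. Under per-chain capture dropout, a biallelic clone
fragments under exact-set keying (cells that captured only one of the two
beta chains key separately), so a second rule, `shared_chain`, merges
cells whose beta sets intersect (connected components of the cell–chain
graph). The end-to-end pipeline uses `shared_chain` because the planted
biallelic clone is then recovered exactly at any dropout below 1;
`exact_set` remains the default for the function, being the stricter and
more common convention. Random singleton CDR3s collide with vanishing
probability, so the merge does not chain unrelated cells in practice —
but a shared public beta chain between genuinely distinct clones would be
merged; with real data the keying choice deserves a look at the chain
frequency table first.

A chain is *clone-defining* when present in at least half (configurable)
of the member cells bearing that locus, and a locus is biallelic when
exactly two chains are defining. Cells with more than two chains at one
locus (doublets, chimeras) are kept but flagged with a warning.

Public-TCR matching is exact string equality on (locus, CDR3 amino acid)
after uppercasing, the convention for querying VDJdb-style references. No
edit-distance matching is offered; V/J columns are ignored when present.
Counts of matched chains against a live public database are inherently
database-version dependent, so tests run only against packaged synthetic
references.

## Program usage and signature scoring

Program usage solves, per cell, $\min_{u \ge 0} \lVert e - W u \rVert^2$
over the genes shared between the data and a fixed nonnegative spectra
matrix $W$. The solver is Lawson–Hanson active-set NNLS, which terminates
at the exact KKT point — important because usage values at the boundary
(exact zeros) are interpreted. The decomposition operates on *linear*
depth-scaled expression (counts scaled to 10,000 per cell): the mixture
model is additive on that scale, and fitting on log-transformed values
would distort the spectra weights. Signature scoring, by contrast, uses
the conventional log1p scale. Both normalizations are provided by
`normalize_expression(log = ...)`; cells with zero total counts cannot be
scaled and are dropped with a warning. Usage is homogeneous (scaling a
cell scales its usage), so comparisons across cells assume a common
normalization; only relative usages are interpretable.

Signature scores are the mean expression of the signature genes minus the
mean of a pooled control set: genes are ranked by mean expression across
cells and cut into 25 equal-frequency bins, and each signature gene draws
100 controls from its bin (excluding signature genes; with replacement
when the bin is smaller than requested). Matching controls on expression
level removes the depth/abundance component of the score. Signature genes
are put in canonical order before drawing, so the score is invariant to
input gene order at a fixed seed; different seeds change the controls but
leave population-level rankings stable in the tested regimes. Bin count
and control count follow the widely used module-scoring convention and
are exposed as parameters.

## The synthetic lymph node

`simulation_config()` fixes the emulated study conditions:

* **Field and composition**: a 5500 µm square field; 51% double-positive
  (DP) T cells, 20% macrophages, 10% regulatory T cells, 5% fibroblasts,
  5% CD4 T cells, with the remaining 9% split 4% CD8 T cells, 3% NK, 1%
  endothelial, 1% dendritic cells (the smaller populations are stated only
  as "smaller proportions" in the motivating setting; this split is the
  package's fixed choice). Counts per type come from largest-remainder
  rounding, so realized compositions are deterministic and sum exactly.
* **Spatial structure**: DP cells form `dp_cluster_count = 4` Gaussian
  clusters of sd 150 µm — a niche scale chosen as clearly sub-field
  (clusters occupy a few hundred µm on a 5.5 mm field), since the
  motivating data show clustering but publish no cluster scale; all other
  types are uniform. Cluster positions keep 2 sd of padding from the
  border and coordinates are clamped to the field.
* **TCR**: every DP cell carries one expanded clonotype with two alpha and
  two beta chains (biallelic), each chain independently dropped with
  probability 0.1 — a typical single-cell capture inefficiency; other T
  cells carry singleton random CDR3s. The sidecar records the DP
  beta-bearing barcodes as the true clone membership.
* **Expression**: each gene has a home program with concentrated gamma
  weight plus diffuse background; per-cell nonnegative program weights are
  gamma draws, with DP cells boosted 6x on a TFH-like program and damped
  10x on a viral-reactivity program. Counts are negative binomial with
  dispersion 0.5 (variance $\mu + 0.5\mu^2$), a standard overdispersion
  level for droplet snRNA-seq; the sidecar stores the effective weights
  after per-cell depth scaling, which are the quantities a usage
  regression can recover.
* **UMI table**: DP cells are the planted mutant population; per-read
  allele errors occur at rate 0.01, flipping to a uniformly random other
  allele; UMIs per cell are Poisson(4) and reads per UMI
  Poisson-distributed around 3.
* **Alignments**: construct read pairs are drawn Poisson with exactly the
  $\lambda_{CAR}$ of the power model, so simulation and closed form can
  be compared head-on; the default construct fraction is 0, producing the
  construct-free case.

All randomness flows from one master seed through per-product sub-streams,
so adding or reconfiguring one product never perturbs the draws of the
others, and identical configurations produce byte-identical bundles.

What the synthetic data does *not* emulate: doublets and ambient RNA,
segmentation or spatial-decoding error, realistic genome sequence or base
qualities, batch effects, and continuous (non-discrete) cell states.
Passing the planted-structure tests therefore shows the estimators are
correct under their own assumptions — clean labels, Gaussian niches,
additive program mixtures — not that they are robust to every artifact of
real tissue profiles.

## Problem sizes and numerical choices

The shipped test suite exercises the default 2000-cell node with 1000
permutations for the planted-niche checks, 20 x 200 permutations for null
calibration, 500 replicates for the power-simulation comparison, and
1000 cells for genotyping precision — sizes at which the Monte-Carlo
bands in the assertions are meaningful while a full run stays in the tens
of seconds. Distance comparisons use squared distances (no square roots);
ties in largest-remainder rounding break deterministically by vector
order; report percentages round half away from zero (so 6.85 prints as
6.9, matching clinical reporting style, rather than banker's rounding).

## Limitations

The niche test assumes exchangeability of labels over positions under the
null; strong density gradients can inflate enrichment for abundant types.
Genotyping treats the variant as a biallelic site summary and does not
phase or handle multi-site haplotypes. Clone keying by beta set cannot
separate two clones sharing both beta chains. NNLS usage depends on the
supplied spectra being on a scale commensurate with the normalized data;
only relative comparisons between cells and populations are supported.
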