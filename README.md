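# clonalniche

Tools for working up a suspected T-cell malignancy after CAR-T therapy from
molecular data: was a clonally expanded nodal T-cell population derived from
the engineered CAR-T product, and does its phenotype and spatial behavior
look neoplastic or reactive? The package is aimed at computational biologists
analyzing whole-genome sequencing plus spatially resolved single-nucleus
RNA/TCR profiles of such lesions, and at anyone who wants to stress-test
those analyses on synthetic data with known ground truth.

## What it computes

**Transgene detection power (WGS).** Whether "zero construct reads" is
informative depends on depth. Under Poisson sampling the expected number of
read pairs mapping to the construct's uniquely mappable region is

λ_CAR = λ_autosomal · L · r_CAR · ρ

with λ_autosomal the autosomal read-pair rate per base, L the mappable
construct length in bases, r_CAR the copy ratio of a single heterozygous-
equivalent integration (1/2), and ρ the fraction of construct-bearing cells.
Detection power is P(n_read > 0) = 1 − exp(−λ_CAR). `detection_power()`
evaluates it, `min_detectable_fraction()` inverts it, and
`count_construct_reads()` provides the empirical counterpart: a
MAPQ-filtered count of primary alignments on construct contigs in a SAM/BAM
file.

**Spatial niche enrichment.** For each (center type A, neighbor type B)
pair, `niche_enrichment()` computes the mean proportion of type-B cells
among the neighbors (0 < d ≤ 200 µm by default) of type-A cells, compares
it against a null built by permuting the cell-type labels over the fixed
positions (1000 permutations by default), and reports
Z = (observed − null mean)/null sd. `cap_z()` clamps Z to ±9 for display.

**UMI-consensus genotyping.** `genotype_cells()` classifies cells for one
somatic variant from read-level allele calls: reads sharing a (barcode, UMI)
are collapsed by strict-majority consensus (ties discarded); cells with ≥ 1
variant UMI are mutant, cells with covering but no variant UMIs are
wild-type, the rest unassigned.

**Clonotype structure.** `group_clonotypes()` groups cells by beta-chain
CDR3 amino-acid sets, sizes clones per population, and
`flag_biallelic()` marks loci with exactly two clone-defining chains — the
signature of biallelic TCR rearrangement. `match_public_tcrs()` does exact
CDR3 matching against public references (VDJdb-style tables).

**Program usage and signatures.** `score_program_usage()` quantifies each
cell's usage of predefined gene-expression programs by nonnegative least
squares against a fixed spectra matrix; `score_signature()` scores gene sets
against expression-matched control genes drawn from mean-expression bins.

**Synthetic lymph node.** `simulate_lymph_node()` generates every input —
positions, counts, chains, UMI reads, alignments — for a tissue dominated
(51%) by a spatially clustered, clonally expanded CD4+CD8+ double-positive
population carrying one biallelic clonotype, with a ground-truth sidecar.

## Worked example

```r
library(clonalniche)

detection_power(0.3, 743, 0.5, 0.034)
#> [1] 0.9773886

sim <- simulate_lymph_node(simulation_config(n_cells = 1000, seed = 7))
res <- niche_enrichment(sim$cells, radius = 200, n_permutations = 1000, seed = 7)
round(cap_z(res$z)[c("DP_T", "Macrophage", "CD8_T"), c("DP_T", "Macrophage", "CD8_T")], 2)
#>            DP_T Macrophage CD8_T
#> DP_T          9      -9.00 -8.67
#> Macrophage   -9       7.16  5.72
#> CD8_T        -9       7.86  5.08

group_clonotypes(sim$chains, sim$cells, key = "shared_chain")
#> Clonotype table: 171 clones, 674 beta-bearing cells (keying: shared_chain )
#>   clone_id                      beta_chains                       alpha_chains size biallelic_alpha biallelic_beta
#> 1        1 CASSLVVWGRGLNEQFF;CASSQQDSRNTIYF CALSHPFRNSGNTPLVF;CASPGGLTGGGNKLTF  504            TRUE           TRUE
#> ...

table(genotype_cells(sim$umi_reads)$genotype)
#>    mutant wild_type
#>       498       478

proportion_percent(43, 626)
#> [1] 6.9
```

A depth giving 0.977 power at a 3.4% cell fraction means zero confident
construct reads argues strongly against a CAR-derived origin. The Z matrix
shows the planted double-positive population strongly self-enriched
(Z capped at 9) and depleted of other populations — the immune-excluded
niche pattern. The dominant clone holds all 504 beta-bearing DP cells and
carries exactly two alpha and two beta defining chains (biallelic), and
UMI-consensus genotyping recovers the planted mutant population. The 6.9 is
the secondary-malignancy incidence for a 43-of-626 cohort.

`run_pipeline()` chains all stages on one dataset (simulated or read from a
bundle on disk) and writes a single JSON report.

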