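# synologr

Detection and quantification of highly similar intra-genome homologs
(*synologs*) in prokaryotic proteomes.

## The problem

Within a single bacterial or archaeal genome, groups of near-identical
protein-coding genes arise through gene duplication and through horizontal
transfer. From one genome alone the two origins cannot be told apart, so such
genes are collectively called **synologs**. Whether a genome carries an
unusual load of highly similar synologs — say, among its carbohydrate
metabolism genes — is a cohort question: it requires detecting synolog groups
in every genome of a large collection and asking which genomes sit far above
the cohort's typical values.

`synologr` implements that pipeline for computational microbiologists:

* **Detection.** Two modes, mirroring the two ways intra-genome homology is
  established in practice:
  * *de novo*: every intra-genome protein pair is aligned (optimal
    Smith–Waterman local alignment, BLOSUM62, affine gaps 11/1, implemented
    in C++); a pair is a synolog pair iff

    `identity >= 0.90` along `>= 90%` of the **full length of both
    sequences**,

    where identity = matches / alignment columns and coverage is the aligned
    fraction of each sequence. The coverage rule excludes spurious hits
    against severely truncated sequences.
  * *family-constrained*: genes sharing a protein-family label (e.g. a
    FIGfam-style assignment provided in the annotation table) are synolog
    pairs with no length requirement; pairs are aligned globally
    (Needleman–Wunsch/Gotoh) to record identities, and an optional identity
    cutoff (`>= 0.90`) re-partitions families into high-identity groups.
    Family members shorter than half the family median length are flagged as
    truncated and excluded first.
* **Grouping.** A *synolog group* is a set of two or more synologs: a
  connected component of the graph of passing pairs (single linkage).
* **Statistics.** Per genome: the number of synologs S, groups G, genes in
  scope N and the *synolog fraction* F = 100·S/N. Per cohort: median,
  unscaled MAD (median absolute deviation, no 1.4826 factor), min/max, and
  the outlier threshold **median + 2×MAD** for every metric; simple-regression
  R² between S, G and N; the share of genomes with no synologs; the share
  carrying high-identity groups; percentile ranks per genome.
* **Genomic context.** Tandem / dispersed / mixed arrangement calls (by
  intervening-gene count) and category profiles of the genes neighbouring
  each group.
* **Simulation.** A generator for synthetic proteomes with planted synolog
  groups at controlled identity, tandem or dispersed placement, truncated
  decoys and random background genes — every pipeline stage is testable
  against known ground truth without downloading anything.

## Worked example

```r
library(synologr)

# a synthetic genome: 300 background genes + 12 planted groups + 3 decoys
design <- standard_fixture_design(rng_seed = 42)
gen <- generate_genome(design)

scan <- detect_synologs(gen$records,
                        detection_config("denovo", prescreen = TRUE))
scan
#> Synolog scan of genome 'synthetic' (denovo mode)
#>   genes in scope : 339
#>   synologs       : 36 in 12 groups
#>   synolog fraction: 10.6%
#>   mean pair identity: 94.2%
```

All 12 planted groups are recovered, none of the 300 background genes or the
3 truncated decoys joins a group, and the synolog fraction is
100·36/339 = 10.6%. Cohort statistics follow the same pattern:

```r
outlier_threshold(20, 13)
#> [1] 46
```

a cohort whose genomes have a median of 20 synolog groups with MAD 13 calls
genomes with more than 46 groups outliers.

The pipeline is also scriptable from a shell via `inst/cli/synologr.R`
(subcommands `simulate`, `detect`, `cohort`, `context`, `run-all`).

## Scope notes

Detection is within one genome only: no ortholog assignment across genomes,
and no attempt to distinguish true paralogs from horizontally acquired
pseudoparalogs (impossible in a single-genome analysis). Protein-family
inference itself (OrthoMCL/MCL-style clustering) is out of scope — family
labels are consumed as input.
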