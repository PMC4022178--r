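---
title: "Detecting highly similar intra-genome homologs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting highly similar intra-genome homologs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synologr)
```

## The model

Genes within one genome that descend from a common ancestor — whether by
duplication or by horizontal transfer — are *synologs*; the two origins are
indistinguishable without cross-genome information, which is why the neutral
term is used throughout. The package asks an operational question: which
intra-genome protein pairs are so similar that they indicate recent
duplication, transfer, or active sequence conservation, and how are such
pairs distributed within a genome and across a cohort of genomes?

Two detection modes reflect the two kinds of evidence available in practice.

**De novo mode.** All `choose(n, 2)` intra-genome protein pairs are aligned
with an optimal local (Smith–Waterman) alignment under BLOSUM62 and affine
gap penalties (a gap of length k costs `gap_open + k * gap_extend`, defaults
11 and 1, the blastp defaults). A pair is a synolog pair iff

* identity ≥ `identity_threshold` (default 0.90), with identity defined
  blast-style as matches divided by **all** columns of the local alignment,
  gap columns included, and
* the alignment covers at least `coverage_threshold` (default 0.90) of the
  full length of **each** sequence.

The double coverage requirement is what makes the high identity threshold
safe: a full-length protein and a 40%-length fragment of it can share ~100%
identity over the fragment, but the fragment-side alignment then covers far
less than 90% of the full-length partner, so the pair is rejected rather
than mistaken for a synolog pair.

**Family mode.** When the annotation provides protein-family labels (e.g.
FIGfam-style assignments in which all members share a functional role), genes
sharing a label are synologs by definition, with *no length requirement*.
Pairs are aligned globally (Needleman–Wunsch/Gotoh) to record identities,
with identity defined over residue-pair columns only — a distance-style
convention in which terminal gaps do not dilute identity. Because this mode
has no coverage rule, it performs the truncation check instead: within each
family of two or more members, sequences shorter than `truncation_fraction`
(default 0.5) times the family median length are flagged as severely
truncated — translated pseudogene fragments, typically — and excluded from
pairing and from all counts. When `identity_threshold` is set (rather than
the family-mode default `NA`), families are re-partitioned into components of
pairs meeting the cutoff; this is the two-stage analysis that separates "all
synologs" from "synologs at ≥ 90% identity".

**Grouping.** A *synolog group* is a connected component, with two or more
members, of the graph whose edges are passing pairs. Single linkage is the
weakest consistent reading of "a set of two or more such homologs": members
need a path of passing pairs, not all-pairs passing. It is also
deterministic and makes the group count a simple graph invariant. Group
identifiers are assigned by the lexicographically smallest member id, so
outputs are byte-reproducible.

## Statistics

Per genome, with N genes in scope (after any category filter and the
truncation check): S = genes belonging to groups, G = number of groups, and
the synolog fraction F = 100·S/N (a percentage; full precision is kept
internally and rounded to one decimal for display). Per cohort, every metric
is summarized by median, **unscaled** MAD — the median of absolute deviations
from the median, without the 1.4826 normal-consistency factor — min, max and
the outlier threshold median + 2×MAD. The unscaled convention is the one
under which a cohort with group-count median 20 and MAD 13 yields threshold
46, and fraction median 30.0 with MAD 9.7 yields 49.4:

```{r thresholds}
outlier_threshold(20, 13)
outlier_threshold(30, 9.7)
```

R² between S, G and N is the squared Pearson correlation (identical to OLS
R² for one predictor). When every group has exactly two members, S = 2G and
R²(S, G) = 1 — the degenerate end of the strong S–G coupling that makes
either count usable for ranking genomes. Shares (genomes without synologs;
genomes with at least one group whose every passing pair meets the
high-identity cutoff) are reported as percentages rounded to one decimal by
default, or to the nearest integer when configured with `share_digits = 0` —
both conventions occur in published cohort tables. A gene belonging to
several subcategories is counted once toward N and S (deduplicated by id);
each group is assigned one subcategory by majority vote of its members, ties
broken lexicographically, unlabeled members counting as `"none"`.

## Genomic context

Tandem duplication leaves copies side by side; conserved dispersed copies in
distinct, functionally coherent neighbourhoods suggest older, selectively
retained arrangements. Since "tandem" has no universal quantitative
definition, the package declares one and makes it configurable: genes are
ranked along each contig by start coordinate, and a group is *tandem* iff all
members are on one contig with at most `max_intervening` (default 2)
non-member genes between consecutive members; *dispersed* iff the members
span several contigs or no two members are that close; *mixed* otherwise.
Counting intervening genes rather than base pairs makes calls invariant to
intergenic-length variation, coordinate translation and strand flips.
Neighbour profiles tally the category labels of up to `window` (default 5)
annotated genes on each side of every member, skipping fellow group members
(a duplicate partner is not "context"); operon prediction is deliberately out
of scope, the profile being the implementable surrogate.

## Numerical choices

* **Thresholding.** Identities and coverages are rounded to 6 decimals before
  the `>=` comparison, so threshold-boundary behaviour cannot flip with
  platform floating-point details.
* **Traceback determinism.** Alignment ties are broken with fixed priority
  diagonal > vertical > horizontal, and the local traceback prefers extending
  over restarting; the best local cell is chosen at the smallest row, then
  column. Outputs are therefore bit-reproducible, and the test-suite oracle
  (an independently written plain-R dynamic program) asserts *exact* score
  and identity agreement rather than tolerance bands.
* **X residues.** The ambiguity code X scores as the worst BLOSUM62 entry
  (−4) against everything and never counts as a match, so runs of X in
  translated pseudogene fragments cannot manufacture identity. Terminal stop
  characters are stripped at parse time; any other character is a hard parse
  error.
* **Degenerate inputs.** Empty sequences are errors; a local alignment with
  no positive-scoring pair yields an empty hit (identity 0, coverage 0);
  an empty genome in scope is an error because the synolog fraction is
  undefined.
* **Exhaustive by default, lossless prescreen on demand.** No E-value
  heuristics or hit-count caps are used; every pair is evaluated. For large
  or repeated runs, `prescreen = TRUE` skips pairs that share no exact 8-mer
  — but only where that skip is provably lossless: a passing pair's
  alignment has at least `n = ceil(coverage * max(La, Lb))` columns, at most
  `(1 - t) n` of them non-matching, so its longest exact match run has length
  at least `t n / ((1 - t) n + 1)`; whenever that bound reaches the word
  length k (for t = 0.90, k = 8: sequences of length ≥ 89), a passing pair
  must share a k-mer. Pairs below the guarantee length are always aligned.
  The suite verifies on/off equivalence directly.

## The synthetic generator

The generator emulates the statistical shape of a real proteome's
category-restricted gene set: a majority of mutually unrelated genes plus a
small number of highly similar synolog groups. Background genes are i.i.d.
uniform draws over the 20 canonical residues with lengths uniform in
`length_range` (default 100–400 residues, typical bacterial protein sizes;
independent random proteins of these lengths have global identity below 0.35
in ≳99% of pairs, so chance synologs are effectively impossible). Each
planted group draws one random ancestor and emits copies with exactly
`round((1 - t) L)` substituted positions (star topology, no indels), so each
copy's identity to the ancestor is exact and any two copies are bounded below
by pairwise identity `2t - 1`. The standard fixture uses t = 0.97
(pairwise ≥ 0.94, comfortably above the 0.90 cutoff), 300 background genes,
12 groups of sizes 2–4 — echoing, at desk scale, the size of a single
genome's carbohydrate gene complement — three 30%-length truncated decoys,
and a half-tandem/half-dispersed layout over four subcategories.
Coordinates use a fixed nucleotide gene length of 3L + 3 with 100-bp spacers;
tandem groups occupy consecutive ranks, dispersed members sit ≥ 20 ranks
apart. Everything is deterministic given the design's seed.

What the generator does **not** emulate: realistic amino-acid composition and
substitution structure (no BLOSUM-biased mutations, no rate variation),
indels within homologs (an optional stress mode was considered and left out;
the no-indel default is what makes planted identities exact), operonic
organization, and any relationship between gene function and location.
Passing tests on synthetic data therefore demonstrate the correctness of the
detection arithmetic and bookkeeping — recovery of a planted partition, zero
false positives among unrelated genes, exact summary statistics — not the
biological calibration of the 0.90/0.90 thresholds on real proteomes, which
is inherited from the field's convention for "highly similar".

## Problem sizes used in validation

The shipped tests run the standard fixture (339 genes, ~58 000 potential
pairs, prescreened) across 100 seeds for false positives and 20 seeds for
exact partition recovery, compare both aligners with the brute-force oracle
on 200 random pairs of length ≤ 40 plus an exhaustive alignment-enumeration
oracle on tiny pairs, check cutoff monotonicity on 10 random fixtures, and
check median/MAD against a sort-based oracle on 1000 random lists. These
sizes were chosen to make each probabilistic guarantee observable many times
over while keeping the full suite in the minutes range on a single core.

## Known limitations

* Single-linkage groups can chain through intermediate sequences: two members
  of one group may themselves fall below the pair cutoff. The per-group
  `min_identity` makes such groups visible (and the high-identity flag
  requires every pair to pass).
* Family mode trusts its labels; a mis-assigned family label produces a
  spurious synolog pair that no alignment evidence can veto (only the
  truncation filter intervenes).
* The tandem definition is rank-based and window-parameterized; biologically
  distinct arrangements (e.g. one interposed transposase vs. two) are not
  distinguished beyond the `max_intervening` count.
* Per-pair alignment is quadratic in sequence length and the de novo mode is
  quadratic in gene count; cohorts of full proteomes are feasible with the
  prescreen but the package makes no attempt at heuristic seeding beyond it.
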