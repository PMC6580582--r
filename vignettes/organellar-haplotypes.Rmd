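---
title: "Methods: organellar haplotype discovery with orghap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organellar haplotype discovery with orghap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orghap)
```

## The model

Plant organellar genomes — the chloroplast and the mitochondrion — are
maternally co-transmitted and effectively haploid. Across a panel of
clonally propagated cultivars, the organellar SNP profile therefore
partitions samples into *maternal haplotype groups*: most members of a
group are exact genetic copies, rare members hang one or two private
mutations off the core, and distinct groups are separated by tens to
hundreds of fixed differences. `orghap` formalizes that structure and the
artifact processes that obscure it.

### Genotype model

Variant callers emit diploid-style genotypes even for organelles. Because
a true organellar genotype is haploid, every call is collapsed to one of
three states: an allele index (`0` = reference), `HET` for any mixed call,
or missing. A heterozygous call is not treated as information about
alleles; it is kept as a symptom. Reads from nuclear insertions of
organellar DNA (NUMTs) and from duplicated or repetitive regions co-align
with the organellar reference and systematically produce heterozygous
calls at the same site in *many* samples, whereas sequencing error and
genuine heteroplasmy are idiosyncratic. At the call level the two causes
are indistinguishable, which is why they are filtered jointly and by
recurrence, not by evidence strength.

### Filter cascade

Four stages, in a fixed order:

| stage | rule | default |
|---|---|---|
| indels | keep only sites where REF and every ALT are single bases | on |
| quality | keep sites with population call quality strictly `> min_qual` | 900 |
| multi-het | drop sites with more than `max_het_focal` focal HET calls | 1 |
| selection | `ANY_SAMPLE`: an alternate allele called in any sample; `INTRA_GROUP`: at least two distinct called allele states among focal samples | — |

Design notes, where the underlying procedure left genuine choices open:

* "heterozygous in multiple samples" is read as **two or more** focal
  samples (`max_het_focal = 1`); the bound is a config knob because no
  exact count is canonical. Heterozygous calls in congener or outgroup
  samples never trigger removal — recurrence is only meaningful within the
  focal panel, where samples share the reference's genomic background.
* the quality threshold is **strict** (`qual = 900` is removed), taking
  "greater than" literally.
* the three removal filters commute (each tests a per-site property that
  the others do not change), so their order affects only the attribution
  of removals in the `filter_report`, not the result. The selection stage
  must run last.
* `INTRA_GROUP` requires two distinct *called allele* states among focal
  samples: HET and missing calls do not count. A site that is
  monomorphic-nonreference in the focal group is a fixed difference
  against the reference cultivar, not within-crop polymorphism — this is
  exactly what separates the any-sample SNP count from the much smaller
  intra-group count.

### Similarity, distance, clustering

With per-call missingness, the denominator of any pairwise identity must
vary per pair. `pairwise_similarity()` returns two integer matrices:
`comparable` (sites where both samples are called) and `identical` (the
subset with equal collapsed states; HET equals HET, HET differs from any
allele). Difference counts `comparable − identical` drive clustering;
p-distances `1 − identical/comparable` drive tree building, with pairs at
`comparable = 0` flagged and refused by the tree layer rather than
silently imputed.

Haplotype groups are **single-linkage** clusters at an absolute difference
threshold (default 5): two samples share a haplotype iff a chain of pairs
each differing at ≤ 5 sites connects them. Single linkage fits clonal
data: cluster cores are zero-distance cliques and private mutations
add leaves at distance 1–2, so chaining — single linkage's usual weakness —
is the desired behavior. The default threshold must merge one-off
subgroup members (distance 1) while keeping the two closest haplotypes
(10 SNPs apart in the motivating data) separate; 5 is the midpoint of
that window, and it is exposed as a parameter. Labels `H1, H2, …` are
assigned by decreasing cluster size with lexicographic tie-breaking, so
clustering is invariant to input order; mapping labels to geographic
names is a reporting-layer join with metadata, not part of the algorithm.

Per-cluster **consensus genotypes** take the per-site majority of
non-missing states; ties and all-missing sites become missing rather than
an arbitrary pick, which keeps consensus vectors order-independent.
Inter-haplotype divergence is counted between consensus vectors at sites
where both are non-missing. `detect_subgroups()` lists members at an
exact consensus distance (default 1) together with their distinguishing
sites; members sharing a distinguishing-site signature form a candidate
named subgroup, while unique signatures are isolated private-mutation
carriers. Both appear in real panels, and only the signature groups are
biologically interesting.

### Concordance of the two organelles

Because the two organelles travel together maternally, their partitions
must never "mix". They need not be equal: when two maternal lineages
differ at a single chloroplast site, the chloroplast partition is a
*coarsening* of the mitochondrial one at any reasonable threshold. So
concordance is defined as **refinement**: every cluster of the finer
partition lies inside one cluster of the coarser. A sample with, say, the
chloroplast of one lineage and the mitochondrion of another breaks
refinement in both directions; `organelle_concordance()` finds such
samples by greedily removing the sample involved in the most
refinement-violating pairs until none remain. Identical partitions and
linked transmission give an empty discordance list; a planted
organelle-swap is flagged exactly (verified in the test suite).

### Trees

The external maximum-likelihood step of the original workflow is
deliberately not reproduced; the in-package method is canonical
**neighbor joining** on p-distances. NJ is exact on additive distance
matrices (the test suite checks recovery of random 4–8-taxon trees from
their path-length matrices), deterministic with smallest-index-pair
tie-breaking, and clamps negative branch-length estimates to zero.
Supports come from resampling site columns with replacement (default 100
replicates), rebuilding the tree per replicate, and counting how many
replicates contain each bipartition of the point-estimate tree. Replicate
`r` uses a stream derived deterministically from `(seed, r)`, so runs are
reproducible. Trees are rooted on the outgroup leaf. Topology claims are
asserted only at the level where they are testable against synthetic
truth: the planted near-congener must group with its founder clade, and a
split backed by ≥ 30 fixed differences must reach full support.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is
built around: 201 focal samples in four founder haplotypes of sizes
90/76/18/17; 37 chloroplast + 168 mitochondrial within-crop polymorphic
sites on replicons of 158,462 and 715,001 bp; founder divergences of
96/158/10/146/156/96 SNPs over the combined 205 sites; a 7-sample
subgroup one chloroplast SNP (position 38,168) off the second-largest
haplotype; four congener lineages, one close (51 SNPs) to the NA1-like
founder; a distant outgroup; 813 sites variant only outside the focal
group (so the any-sample set totals 177 + 841 = 1018); and 20 NUMT-mimic,
10 indel and 10 low-quality decoy records. The per-organelle divergence
matrices (chloroplast 33/1/11/32/28/10, mitochondrion
125/9/85/124/118/86) are taken from the per-replicon identity cells of
the motivating survey's exemplar cultivars; they sum to the combined
divergence list, and the four exemplar sample names are reused as the
founder representatives so exemplar-level identity cells are directly
comparable.

### Exact founder construction

Founders are not produced by mutation simulation: the generator *solves*
for haplotypes whose pairwise Hamming distances equal the configured
matrix exactly, by decomposing the matrix into weighted binary splits of
the founder set (blocks of identical sites). For up to four founders the
decomposition is closed-form — for four taxa there are 7 split types
(4 singletons, 3 pair splits) against 6 constraints, and the solver scans
the one free parameter for a non-negative integer solution, preferring
the one that fills the configured site budget. Distance matrices that
violate the triangle or parity constraints of Hamming geometry are
rejected with a config error. For more than four founders an exact
tree-additive matrix is required and blocks are allocated along NJ tree
edges. This matters because realistic divergence matrices (including the
default) are *not* tree-additive, so block allocation on a tree alone
could never be exact. The default configuration fills its site budget
exactly: 36 founder-variable chloroplast sites plus the subgroup site
make 37, and the mitochondrial solution lands on exactly 168.

### Noise processes and truth preservation

Each focal sample copies its founder, then receives
`Poisson(within_group_mut)` private mutations (default mean 0.2, with an
optional hard cap — clonal material carries at most a few), per-call
missingness (default 0.02; 0.15 for the outgroup, whose distant reads
map poorly), and the decoy records described above. Four generator
guarantees make planted truth exact at *any* seed, which the
property-style tests rely on:

* private mutations land only on founder-variable sites, so the planted
  polymorphic site count is invariant;
* planted subgroup members receive no additional private mutations, and
  private mutations can never hit the subgroup site, so the subgroup is
  exactly its planted size at exactly distance 1;
* the subgroup site is exempt from missingness;
* a missingness mask that would erase a site's last visible
  alternate-allele call, or a planted site's focal polymorphism, is
  repaired before application.

What the generator does **not** emulate: coalescent genealogy within
haplotype groups, recombination (organelles are treated as fully linked),
mutation-rate heterogeneity along the genome, base-composition and
strand-context effects, genotype-likelihood noise, and any read-level
process. Passing tests therefore demonstrate that the pipeline's logic
recovers planted structure under the stated noise model, not that a
particular real dataset is free of artifacts the model lacks.

### A note on the origin table

The default country-by-haplotype assignment follows the motivating
survey's published per-country counts. Those printed counts are
internally inconsistent by one sample: one row's cells sum to 39 against
a printed row total of 40, and the affected haplotype column sums to 75
against a published group size of 76. The generator reconciles by adding
the missing sample to that row's cell (USA, NA1-like group), so cells,
row totals and group sizes agree. `contingency()` always computes totals
from cells; `verify_row_totals()` exists to *flag* declared totals that
disagree rather than reproduce them.

## Numerical and degenerate-input choices

* Collapsed calls are stored as an integer matrix (`NA` = missing,
  `-1` = HET); all pairwise counts are exact integer arithmetic, so
  similarity cells, divergence counts and cluster memberships carry no
  floating-point tolerance at all. The only tolerances in the test suite
  are `1e-8` on NJ branch lengths.
* QUAL values round-trip through VCF text exactly because the generator
  draws them at 2 decimals.
* Sites are totally ordered by (replicon lexicographic, position
  ascending); all outputs inherit that order, and two runs with the same
  inputs and seeds are byte-identical (asserted in tests).
* Degenerate inputs: header-only VCFs yield a 0-site matrix with samples
  intact; empty matrices pass through filters with all-zero reports;
  clustering a single sample yields one singleton cluster; trees require
  ≥ 3 samples and refuse distance matrices with empty denominators;
  a 1-founder configuration yields no polymorphic sites.

## Problem sizes

The full study-conditions dataset (1058 sites × 206 samples) runs through
the complete pipeline, bootstrapped trees included, in a few seconds. The
test suite exercises the end-to-end conditions once and then uses
scaled-down configurations — four founders over 16 + 22 polymorphic sites
with 21 focal samples — for the 100-seed filter-truth property, 20-seed
clustering-recovery property, and the other randomized suites; these
sizes keep every property exact while the whole suite completes in well
under a minute.

## Known limitations

* The multi-het filter assumes NUMT artifacts recur across focal samples;
  a NUMT polymorphic in the nuclear genome and present in only one sample
  is indistinguishable from heteroplasmy and survives as a HET call
  (which the intra-group selection then ignores).
* Single linkage with an absolute threshold presumes clonal structure; in
  an outcrossing population with a continuum of divergences the threshold
  window between "within" and "between" may not exist.
* Consensus-based divergence equals representative-based divergence only
  when clusters are internally near-uniform; both routes are available.
* NJ with p-distances is a topology-and-support summary, not a substitution-model
  inference; branch lengths are proportions of differing sites, and no
  multiple-hit correction is applied (over the divergence range involved,
  ≤ 0.8% of sites, saturation is negligible).
* The heterozygous state is collapsed without allele identity, so a
  multiallelic HET exported to PHYLIP becomes the REF/first-ALT ambiguity
  code.
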