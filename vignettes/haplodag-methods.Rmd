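---
title: "Phasing diploid haplotypes with a haplotype DAG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing diploid haplotypes with a haplotype DAG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodag)
```

## The problem

A diploid genome carries two homologous copies of every chromosome. Variant
callers report heterozygous sites — positions where the two copies differ —
but not which alleles co-reside on the same copy. Assigning the alleles of
many heterozygous sites to their two parental chromosome copies is
*phasing*; a maximal set of jointly phased sites is a *haplotype block* or
*phase set*. haplodag performs read-backed phasing for a single sample: the
only evidence used is that a sequenced DNA molecule (a long read, or the two
reads of one paired-end fragment) originates from exactly one chromosome
copy, so the alleles it touches must lie on the same haplotype.

## The haplotype DAG

For one chromosome with $L$ heterozygous biallelic sites, build a graph with
one *sibling pair* of nodes per site (per *level*): node $v_1^l$ carries one
allele of site $l$ and $v_2^l$ the other. Directed edges run only between
adjacent levels, $\delta \to \delta+1$, so the graph is acyclic by
construction and already topologically sorted by level; conceptual dummy
nodes cap both ends. In this package sibling 1 always carries REF and
sibling 2 ALT. Any deterministic assignment works — flipping the siblings at
a level (rewiring incident edges accordingly) leaves the phased haplotype
pair unchanged, a property the test suite asserts — and determinism makes
runs reproducible.

### Edges from continuous fragments

A fragment is *continuous* when the levels it observes form one consecutive
run. For every adjacent level pair it covers, the edge from the observed
node at $\delta$ to the observed node at $\delta+1$ receives one count: an
edge counter starts at 1 when the edge is created and is incremented by 1
for every spanning fragment. Between two levels the accumulated fragments
produce 2 straight edges (unambiguous in phase), 2 crossing edges
(unambiguous out of phase), or 3–4 edges when the evidence conflicts
(sequencing error, misalignment, allele dropout).

### Induced edges across discontinuities

Paired-end fragments are often *discontinuous*: when the insert is longer
than the two read lengths combined, a variant falling in the unsequenced
middle splits the fragment's observations into non-consecutive runs. Each
gap yields a span from a source node (last observed node before the gap) to
a target node (first observed node after it). Spans are processed in a
canonical order — target level ascending, ties by source level descending,
residual ties by sibling index — and each is bridged by a look-ahead
pre-order depth-first traversal. At a visited parent node the single-level
look-ahead induces edges to potential children at the next level:

* if the parent's *sibling* has a read-observed allele and read-evidence
  edges to **both** children (full local ambiguity), the parent receives
  edges to both children;
* otherwise the parent receives an edge to each child that has no
  read-evidence parent edge — excluding, at the target level, the sibling
  of the target node.

Induced edges are created with counter 1 and are never incremented by the
traversal, so a pair of induced edges from one parent later weighs 0.5
each: the floor value for structural, non-read-backed connectivity. A
continuous fragment arriving later at the same pair does increment them.

One design point deserves emphasis. The look-ahead's branch conditions are
evaluated against the *read-evidence* edge framework (edges created by
continuous fragments), not against previously induced edges, while induced
edges do join the live graph immediately — traversals follow them and never
duplicate them. This distinction between observed evidence and structural
edges is what makes the construction well behaved: with it, bridging a gap
over a fully ambiguous pair connects *both* intermediate nodes to the
target (the behaviour the canonical three-level configurations require),
re-running induction is a no-op, and the final edge set does not depend on
the order fragments appear in the input file. Treating freshly induced
edges as evidence instead would let one span's structural edges flip a
later span's branch decisions, making the result order-dependent. The
traversal never expands nodes at the target level, and spans whose
traversal cannot reach their target are counted and reported rather than
repaired.

## Weights and the minimum-weight path

Each edge's weight is its counter normalized over the edges leaving the
same source node:

$$w_{ij}^{\delta} = \frac{n(e_{ij}^{\delta})}{\sum_k n(e_{ik}^{\delta})},$$

so outgoing weights always sum to 1, a single outgoing edge has weight
exactly 1, and weights below 1 appear only where the evidence is
ambiguous. The likelihood of a start-to-end path is the product of its edge
weights; phasing a block means maximizing it, or equivalently minimizing
the path cost $\sum -\log w$ (natural log — the base does not affect the
argmin). Because edges join only adjacent levels, a single forward
dynamic-programming sweep with backtracking finds the optimum in time
linear in nodes plus edges; dummy end nodes attach to both boundary
siblings at zero cost so block ends are unconstrained. Haplotype 1 reads
the path's alleles, haplotype 2 the sibling allele at every level. Costs
are accumulated in log space throughout, so products of many small
probabilities never underflow. Equal-cost ties (common in noiseless data)
are broken toward the lower sibling index during backtracking, a declared
arbitrary choice that only fixes which of the two complementary haplotypes
is printed first.

## Blocks

Adjacent level pairs with no edge at all split the chromosome into blocks;
levels with no edge on either side become singleton blocks that are
reported but not phased. One safeguard goes beyond the pair-wise rule:
a block can have at least one edge between every adjacent pair and still
contain no complete start-to-end path (for instance, pair $d$ has only the
edge $1{\to}1$ and pair $d+1$ only $2{\to}2$). Such conflicting-coverage
corners are rare but possible, so block partitioning also walks the forward
reachable node set and cuts the block where that set empties, recording the
number of cuts on the result. Within every reported multi-level block a
complete path then always exists.

## Evaluation statistics

Accuracy against a truth-phased VCF is the *switch error*: per block,
haplotype 1 is compared with the truth haplotype under both orientations
(haplotype labels are arbitrary) and the discordant-allele count under the
better orientation is the block's error count; the rate divides total
errors by the total phased genomic span, per megabase. The denominator is
the phased span because that is the only per-block quantity in base pairs
the rate can be normalized by. This per-allele definition is the primary
metric; the conventional adjacent-pair switch count (number of
relative-phase flips between consecutive levels) is reported alongside,
clearly labelled, for comparability with the wider phasing literature.
Blocks crossing truth phase-set boundaries are evaluated within each truth
set separately and counted. Block length is the genomic span from first to
last phased variant (inclusive); N50 is the length at which the
descending-sorted cumulative span first reaches half the total. A
stratified report bins blocks into length classes and aggregates per-class
numerators and denominators, so the overall rate is exactly the aggregate
of the classes.

## The simulator: what it emulates and what it does not

`simulate_dataset()` produces fully self-contained inputs: a uniform-random
reference region, heterozygous SNPs and 1–20 bp INDELs placed by a Poisson
process with a random truth phase per site, and reads drawn uniformly from
the two haplotypes with per-base substitution errors. Reads are written
pre-aligned with exact CIGARs (the simulator knows the true coordinates;
mapping is out of scope), as plain coordinate-sorted SAM.

Defaults emulate a human-like short-read regime: 100 kb region, site
density $10^{-3}$ per bp (human-scale heterozygosity), insert size
Normal(316, 50) bp — the median insert of typical paired-end libraries,
and deliberately larger than two 100 bp reads so discontinuous fragments
occur — 25-fold coverage, 1% substitution error, INDELs capped at 20 bp at
a tenth of sites. A 25 bp minimum spacing keeps variant alleles from
overlapping. Long-read mode draws exponential lengths around a 5 kb mean.
The test suite runs regions of 5–100 kb; these sizes exercise every code
path (including discontinuity induction) while keeping the default test
run fast, and results scale with region length only through block counts.

What the simulator does *not* model: indel sequencing errors, homopolymer
and GC bias, chimeric reads, mapping ambiguity or soft-clip artefacts from
a real aligner, and structural variants. Passing the end-to-end tests
therefore demonstrates correctness of the graph construction, induction,
optimization and evaluation on idealized alignments — not robustness to
alignment artefacts in real data, for which the quality filters
(`min_mapq`, `min_baseq`) are the first line of defence.

## Numerical and degenerate-input choices

* Counters are integers; weights are formed once per phase call, so no
  rescaling is ever needed and `cost = 0` iff the edge is the only one
  leaving its source.
* Observations whose base matches neither allele, falls below `min_baseq`,
  or conflicts between the two mates of one fragment are dropped; a
  fragment needs two surviving observations to matter.
* INDEL support is strict: a read supports the ALT of an insertion or
  deletion only when its CIGAR encodes the full event at the site (and the
  inserted bases match); it supports REF only when one aligned block spans
  the whole REF allele with matching bases. Partial overlap contributes
  nothing.
* An empty variant list is an error for graph construction but a warned
  no-op for the command-line pipeline; a chromosome absent from the BAM
  header is a hard contig-mismatch error.
* Identical seeds give byte-identical simulator outputs; the phasing side
  is fully deterministic.

## Known limitations

Only biallelic heterozygous sites are phased; multiallelic records are
skipped, not split, because a level carries exactly two alleles. Polyploid
phasing, population/pedigree phasing and CRAM input are out of scope.
Induced edges carry no evidence weight, so a block bridged only by
discontinuities is phased with uniform edge ambiguity at the bridge —
accuracy there reflects the surrounding evidence, not the bridge itself.
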