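---
title: "Microsynteny networks of gene families: methods and design"
author: "msynnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsynteny networks of gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msynnet)
```

# The problem

Homologous genes that additionally share a conserved local gene-order
context — *syntelogs* — carry phylogenetic signal that sequence
similarity alone does not: a duplicate that has *transposed* to a new
genomic context is distinguishable from one retained in place, even
when the proteins are nearly identical.  `msynnet` implements a
network view of microsynteny for a single gene family across many
genomes: collinear blocks are detected between all genome pairs, every
anchor pair becomes an edge of a global synteny network, the family's
induced subnetwork is clustered into overlapping communities, and the
communities are profiled along a species tree and contrasted by codon
level divergence (Ks).  The approach summarises, for a family such as
fibrillarin-like methyltransferases, which lineages retain the
ancestral genomic context and which carry a relocated (and typically
faster-evolving, often intronless) copy.

# Pipeline stages and their models

## Gene tables

Each genome contributes one record per gene.  Coordinates are stored
0-based half-open internally; GFF3's 1-based closed convention is
converted at the file boundary only, in both directions, so a
read-write round trip is exact.  Among isoforms, the representative is
the transcript with the greatest summed CDS length (exon length when no
CDS is annotated; ties go to the lexicographically smallest transcript
ID).  CDS length is preferred because the same transcript later feeds
the codon-alignment stage.  The coordinate used by all downstream
synteny computation is the gene *rank* — the 0-based position of the
gene among the genes of its chromosome ordered by start — which makes
block detection robust to absolute-coordinate differences between
assemblies.

## Homology filtering

Input hits are 12-column tabular (blast `outfmt 6` dialect).  Self
hits are dropped, an e-value ceiling is applied (default `1e-10`;
exposed as a parameter because all-vs-all search protocols frequently
leave this implicit), and each gene retains its `max_hits = 20` best
partners by bitscore, mirroring the capped hit lists of an
all-against-all search.  A pair survives only when *both* endpoints
retain it — the reciprocal reading — which makes the edge set
independent of input order and the filter idempotent (removing a pair
can only promote the survivors in each gene's ranking).

## Collinear block detection

Anchors (homologous gene pairs placed at rank coordinates $(i, j)$ on a
chromosome pair) are chained by dynamic programming.  A chain of $m$
anchors scores

$$\mathrm{score} = m \cdot \mathrm{match\_score} +
  \mathrm{gap\_penalty} \sum \left[(\Delta i - 1) + (\Delta j - 1)\right],$$

with extensions allowed only between anchors that are strictly monotone
in the chain's orientation (forward: $j$ increasing; inverted: $j$
decreasing) and within `max_gaps` intervening ranks in both genomes.
Defaults (`match_score = 50`, `gap_penalty = -1`, `match_size = 5`,
`max_gaps = 25`) follow the published defaults of the standard
collinearity tool in this field.  Blocks are extracted greedily: the
maximum-score chain is emitted if it has at least `match_size` anchors,
its anchors are removed, and the search repeats — a deterministic
resolution of overlapping chains.  DP ties are broken toward longer
chains, then smaller start $i$, then smaller start $j$; a forward chain
is preferred over an equal-scoring inverted one.  No block-level
significance statistic is computed.  Tandem arrays (mutually homologous
genes within a one-rank window, by default) are reported but not
collapsed before chaining; the paperwork for collapsing is ambiguous
across tools and leaving arrays intact keeps the anchor set faithful to
the annotation.

The DP is validated two ways: against an exhaustive enumeration of all
monotone anchor subsequences on small random sets, and by
planted-structure recovery, where collinear runs of 5–20 anchors are
planted on a $1000 \times 1000$ rank grid with 5% spurious anchors.
The planted-anchor generator rejects noise inside the chainable
extension cone (`max_gaps + 1` ranks) of existing anchors, so that the
planted blocks remain the unambiguous ground truth being scored.

## Network assembly and communities

Every anchor pair of every block becomes one undirected, unweighted
edge; multi-block support is kept as an annotation rather than a
weight, because the community stage treats edges as present/absent.
The family subnetwork is the induced subgraph on the family's gene
ids, with isolated members retained as degree-0 nodes so that
unclustered genes remain visible in the profiles.

Communities are found by k-clique percolation (default $k = 3$): all
k-cliques are enumerated, two cliques are adjacent iff they share
exactly $k - 1$ nodes, and communities are node-set unions of the
connected components of the clique-adjacency graph.  Nodes may belong
to several communities, which is biologically meaningful here (a gene
bridging two contexts).  Output order is deterministic (size, then
smallest member).  The implementation enumerates cliques with `igraph`
but percolates itself, and the test suite checks exact agreement with
a brute-force oracle (subset enumeration plus BFS, no igraph) on
hundreds of random graphs, along with the monotonicity of communities
in $k$ and stability under edge additions and relabeling.

## Profiling

The community-by-species count matrix (plus a presence/absence
variant) is ordered by the species-tree leaf order.  Genes in several
communities are counted in each; a `"none"` row holds unclustered
family genes, so column totals equal per-species copy number whenever
communities do not overlap, and exceed it by exactly the
multi-membership excess otherwise.  Exon-count summaries per community
report n, mean, median, mode (ties to the smallest modal value) and
the full histogram.

## Codon-level divergence

Within each syntelog group, all $\binom{n}{2}$ pairs are processed:
global protein alignment (Needleman–Wunsch, BLOSUM62, gap open 10,
extend 0.5, via `Biostrings`; its traceback is deterministic),
back-translation to a codon alignment (gaps become `---`; one terminal
stop is stripped; the degapped translation must match the protein
exactly), and the Nei–Gojobori (1986) estimator:

* synonymous sites per codon = (synonymous one-step changes)/3, summed
  and averaged between the two sequences, $N = 3n - S$;
* differences counted over all minimal substitution pathways with
  equal weights, pathways through stop codons excluded (if every
  pathway is blocked, all pathways are used);
* Jukes–Cantor correction $K_s = -\tfrac34 \log(1 - \tfrac43 p_s)$,
  likewise $K_a$; a non-positive log argument marks the pair
  *saturated* and the distance undefined.

Saturated pairs are excluded from group means and quartiles but
counted, so the exclusion is always visible.  Quartiles use linear
interpolation between order statistics (R type 7).  Only the standard
genetic code is supported; alternative codes (e.g. the CTG-Ser clade
of yeasts) are out of scope.

### Estimator calibration and a known limitation

On simulated 300-codon pairs (see below), the mean NG86 estimate
recovers the true synonymous distance to within about 2% at $K_s =
0.1$ and 5% at $K_s = 0.5$.  At $K_s = 1.0$ the mean is inflated by
roughly 18–19%.  This is not an implementation artifact — the
estimator agrees to five decimals with an independent NG86
implementation — but intrinsic near-saturation behaviour: under equal
per-change substitution rates, 2-fold degenerate sites are two-state
toggles that saturate faster than the uniform four-state model behind
the Jukes–Cantor correction assumes, so the aggregate corrected
distance overshoots.  Group *comparisons* (conserved vs relaxed) are
unaffected in direction; absolute values near saturation should be
read with this bias in mind.

# The synthetic-data generator

`simulateDataset()` evolves an ancestral genome (by default 2
chromosomes × 40 genes; each gene founds its own family and context
label, 9 exons, 300 random sense codons) along a species tree.  Per
branch, event counts are Poisson(rate × branch length × gene count)
with per-branch RNG substreams derived from (seed, branch label), so
traversal order cannot change results and identical configurations are
byte-identical.  Events:

* **loss** removes a gene and closes ranks;
* **tandem** inserts a copy at the next rank;
* **transposition** inserts a copy elsewhere with a fresh context
  label; RNA-mediated copies become single-exon (retrocopies), and
  transposed copies evolve at `relaxed_multiplier` times the base
  synonymous rate thereafter.  The insertion site is uniform *given*
  that its 30-rank neighborhood shares no family with the donor's
  neighborhood — the defining property of a context change; without
  this constraint a "transposed" copy can land inside a homeologous
  copy of its own neighborhood after WGD and no context change occurs;
* **inversion** reverses a window of gene order and flips strands;
  window lengths are 1 + Geometric (mean ≈ 5 genes), reflecting that
  small local inversions dominate real rearrangement spectra;
* **WGD/WGT** duplicates or triplicates every chromosome, then deletes
  each duplicate gene independently with probability
  1 − `retention_prob` (fractionation); originals are never deleted.

Synonymous sequence evolution applies Poisson(distance × S)
substitutions per branch, each drawn uniformly among the synonymous
single-nucleotide changes of the current sequence, leaving the protein
invariant.  True pairwise synonymous distances are computed from a
gene genealogy recorded during simulation (additive along the path to
the pair's divergence point) and emitted as ground truth, together
with family labels, context labels, the duplication parent map, and an
event log.  Homology hits are emitted directly from family labels —
bitscore a decreasing function of true distance, e-value a monotone
transform — because the homology-search stage is an input boundary of
the pipeline, not part of it.

The focal family is, by default, exempt from stochastic loss,
transposition and tandem duplication (`protect_focal`): it models an
essential gene under strong purifying selection, and it makes the
focal family's copy-number history exactly the history scripted by
`forced_events`, which is what the scenario presets rely on.

What the generator does *not* emulate: nonsynonymous evolution and
codon-usage bias; chromosome fission/fusion; annotation noise
(missing genes, split models); and homology-search artifacts.  Passing
tests therefore demonstrate the correctness and calibration of the
pipeline's algorithms under controlled gene-order evolution, not
robustness to real-data annotation problems.

## Scenario presets

`mammalScenario()`: six ingroup species radiating one time-unit ago
plus an outgroup (stem one unit, outgroup depth two), `ks_rate = 0.25`
per unit; on the ingroup stem the focal gene is duplicated by
RNA-mediated transposition, the copy evolving at twice the base rate.
Expected outcome: a conserved community spanning all seven species and
an ingroup-restricted, single-exon, faster-evolving community — with
conserved ingroup ortholog pairs at true $K_s = 0.5$ and transposed
pairs at 1.0, so the two groups bracket the regime where such
contrasts are typically reported.

`plantScenario()`: eight species in two clades of four, an ancestral
whole-genome triplication with retention probability 0.6, and one
DNA-mediated transposition of a focal copy on one clade's stem.
Expected outcome: one supercluster spanning all species (WGD copies
inherit their context, so homeologs remain syntenic) plus one
lineage-restricted community.

Rates (loss 0.02, tandem 0.01, transposition 0.005, inversion
0.01/0.005 per gene per unit) are not taken from any measured genome —
no quantitative rates are available for the motivating analyses — and
were calibrated once so that the presets robustly reproduce the
qualitative topology they are meant to illustrate (community counts
and memberships across seed sweeps), which is the presets' stated
purpose.  The restricted clade has four species because a three-member
community is destroyed by the loss of any single edge (for example
when a terminal-branch micro-inversion strands the focal anchor on a
segment shorter than `match_size`), making three-species presets
fragile for no illustrative gain.

# Problem sizes and runtime choices

The bundled analyses are sized for interactive use: scenario genomes
are 7–8 species × ~80–180 genes, giving all-pairs block detection over
28–36 genome comparisons in a few seconds; oracle sweeps use 200
random graphs (≤ 25 nodes) and 100 anchor sets (≤ 12 anchors);
estimator calibration uses 500 pairs × 300 codons per distance.  These
sizes were chosen so the whole battery, including both scenarios,
completes in about a minute while keeping every check statistically
meaningful (e.g. the binomial check on fractionation uses 1000 genes;
the calibration means have standard errors well under 1%).

# Degenerate inputs and numerical conventions

Empty anchor sets, empty block sets and edgeless networks propagate as
empty results, not errors.  An empty family list is an error before
any computation.  Codon columns with gaps, ambiguity codes or stops
are excluded from NG86 counts and reported.  A group with fewer than
two genes yields a warning and no summary row.  Mode ties in exon
histograms resolve to the smallest value.  All writers emit UTF-8
tab-separated text with one `#`-prefixed header line; the collinearity
file uses `## block` section headers.
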