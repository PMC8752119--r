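---
title: "Methods: Hi-C host/epiphyte deconvolution and the Alien Index screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hi-C host/epiphyte deconvolution and the Alien Index screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metahic)
```

# The problem

Genome projects for macroalgae (and many other hosts that cannot be grown
axenically) sequence a *community*: the host nuclear genome plus the
genomes of tightly associated epiphytic bacteria. A joint assembly of such
a library mixes host and bacterial contigs, and ordinary coverage/GC
binning can leave substantial ambiguity. `metahic` implements a
deconvolution that exploits Hi-C proximity ligation: crosslinked chromatin
ligates fragments that were close *in the same cell*, so inter-contig
contact counts are dominated by intra-genome pairs. Clustering the contact
graph therefore separates contigs by source genome, and a taxonomic vote
per cluster labels each cluster as host or bacterial. A second, downstream
question — whether any host genes were horizontally acquired from those
bacteria — is answered by an Alien Index (AI) screen over alignment hit
tables, backed by a sister-clade test on per-gene trees.

Every stage can be exercised on synthetic data with planted ground truth,
generated by the package itself; no external data are required.

# Model and procedure

## Hi-C pair classification

Read pairs are classified by the first matching rule, in priority order:

1. `LOW_QUALITY`: `min(mapq1, mapq2) < min_mapq` (default 20).
2. `DUPLICATE`: both 5' coordinates and strands identical to a previously
   seen pair. Ends are compared after canonical ordering (lexicographic
   contig id, then position), so the same molecule observed with its ends
   swapped is still a duplicate.
3. `SELF_LIGATION`: both ends in the same restriction fragment,
   outward-facing (leftmost end on `-`, rightmost on `+`) — a circularised
   single fragment.
4. `NON_LIGATION`: same fragment, inward-facing (`+` then `-`) — an uncut
   molecule that never participated in ligation.
5. `VALID` otherwise.

Restriction fragments come from `restriction_map()` (motif occurrences,
default `GATC`, as 0-based half-open boundaries tiling each contig).

## Contact matrix

`build_contact_matrix()` counts only `VALID` pairs into a symmetric
contig-by-contig matrix; intra-contig pairs increment the diagonal. By
construction the upper triangle plus the diagonal sums exactly to the
number of valid pairs (a conservation law the tests assert). Expected
random contact counts between two contigs scale with the product of their
lengths, so the default normalization is
`counts * 1e6 / (L_i * L_j)` (`length_product`); `row_sum` is provided as
an asymmetric alternative.

Before normalization, `deconvolve()` applies a raw-count floor
(`filter_contact_matrix()`, default `min_count = 2`) to off-diagonal
entries. The reason is a heavy-tailed artifact of length normalization: a
*single* spurious cross-genome pair between two short contigs can receive
a normalized weight comparable to genuine intra-genome links. Requiring at
least two supporting pairs removes almost all such links while genuine
links, supported by many pairs, are untouched. This mirrors standard
practice in metagenome Hi-C binning.

## Clustering

`cluster_contigs()` works on the normalized matrix in two stages:

1. **Threshold graph.** Links below `min_link` are discarded; contigs with
   no qualifying link stay unclustered; connected components of the
   remaining graph are the coarse grouping. The default `min_link` is
   chosen by a weight-aware gap heuristic: sort the nonzero link weights,
   find the widest gap on the log scale that is wider than `log(5)` and
   whose lower side carries less than 25% of the total link weight, and
   threshold inside that gap. Cross-genome noise forms exactly such a
   mode — numerous links, individually weak, small total weight — while
   same-genome links sit orders of magnitude higher. When no qualifying
   gap exists, no noise mode is detectable and every nonzero link is
   kept — on noise-free data this is exactly right, since all surviving
   links are genuine.
2. **Within-component refinement.** Each component is refined by
   average-linkage agglomerative clustering on the similarity
   `log1p(weight)`, cutting at the number of clusters (up to `k_max`) that
   maximizes the mean per-cluster intra/inter contact ratio, ties toward
   fewer clusters. Because merging two clusters of one component can only
   increase that mean (a complete component has zero inter-weight, hence
   an infinite ratio), this criterion effectively confirms the component
   structure rather than splitting it; the scientifically meaningful
   separation is carried by the threshold graph. We keep the refinement
   step because it makes over-merged components recoverable when a user
   forces a permissive `min_link`.

The procedure is fully deterministic given its input.

## Four-group assignment

`deconvolve()` pools the alignment hits of each cluster's members and
calls a bit-score-weighted vote (`assign_taxonomy()`): hits are partitioned
into host-matching (lineage contains `host_pattern`), bacterial
(superkingdom Bacteria/Archaea) and other; the winning class must carry at
least `vote_fraction` (default 0.5) of the summed bit score. Groups:

| group | condition |
|---|---|
| `HOST_CHROMOSOMAL` | clustered, cluster vote = host |
| `EPIPHYTE_BIN` | clustered with bacterial vote, or unclustered with a bacterial call (singleton bin) |
| `HOST_UNPLACED` | unclustered, per-contig vote = host |
| `UNKNOWN` | no qualifying links and/or no taxonomic signal |

Ties at exactly 0.5/0.5 are broken deterministically
(bacterial > host) with a warning, preferring the conservative outcome of
keeping a contig out of the host assembly.

Per-group assembly statistics (`assembly_stats()`): N50 (largest L such
that contigs ≥ L cover half the total length) and GC fraction (G+C over
unambiguous A/C/G/T). `shared_sequence_screen()` reports genes whose
aligned coverage in an external dataset strictly exceeds a threshold
(default "more than 90% of their length"; exactly 0.90 does not pass).

## Alien Index and HGT categories

For one gene with hit table `H`, let `bbh_in` be the best (smallest)
E-value among ingroup hits (same superkingdom as the recipient, default
Eukaryota) and `bbh_out` the best among outgroup hits (Bacteria +
Archaea), after removing hits to the recipient's own lineage at the
`genus` rank (self hits would otherwise mask every donor). A side with no
hits uses `no_hit_default = 1`. Then

    AI = ln(bbh_in + c) - ln(bbh_out + c),   c = exp(-200)

AI is positive exactly when the best bacterial hit is stronger than the
best non-self eukaryotic hit. The pseudo-count `c` bounds `|AI|` by about
200·log(10)/ln(10) ≈ 460 in natural-log units even when an E-value
underflows to 0, and is far below any representable E-value of interest.
Categories:

* `AI ≤ 0` — non-candidate;
* `0 < AI ≤ 10` — weak candidate;
* `AI > 10` and the gene clusters with bacterial sequences in its tree —
  strong candidate;
* `AI > 10` otherwise — partial candidate. A gene is *never* promoted to
  strong without positive tree evidence; an absent tree yields partial.

The tree test (`tree_bacterial_clustering()`) midpoint-roots unrooted
trees, takes the sister group of the query (tips of the smallest clade
containing the query, minus the query) and requires at least
`sister_fraction` (default all) of the sister tips to be
bacterial/archaeal; an optional `min_support` gates the call on the
support value of the query's parent clade.

`screen_genome()` applies this per gene. When a deconvolution result is
supplied, only genes on host-assigned contigs are screened by default: the
screen asks what the *host genome* acquired, and bacterial-bin genes would
otherwise trivially flood the candidate lists.

# Parameters

| parameter | default | unit / meaning |
|---|---|---|
| `min_mapq` | 20 | minimum mapping quality of both ends |
| restriction motif | `GATC` | four-cutter used for fragment maps |
| `min_count` | 2 | raw pairs required per inter-contig link |
| `min_link` | gap heuristic | normalized-contact threshold |
| `k_max` | n contigs | maximum clusters per component |
| `vote_fraction` | 0.5 | bit-score share to win the taxonomy vote |
| `min_hit_evalue` | 1e-5 | hit E-value ceiling for the vote |
| `no_hit_default` | 1.0 | substituted best E-value for an empty side |
| pseudo-count `c` | `exp(-200)` | AI underflow guard |
| `ai_strong`, `ai_candidate` | 10, 0 | category thresholds |
| `sister_fraction` | 1.0 | bacterial fraction required in the sister group |
| coverage threshold | 0.9 (strict `>`) | shared-gene screen |

# The synthetic data generators

`simulate_community()` builds a host of several chromosomes (default 5 ×
200 kb) and a set of bacterial genomes (default 10 × 100 kb), fragments
each into contigs (normal lengths, default mean 20 kb), and adds short
unlinked host contigs and unlinked "unknown" contigs; host sequences are
GC-rich (0.70) against AT-richer bacteria (0.45), echoing the red-algal
setting the method targets. The planted truth table records source genome,
role and linkage for every contig.

`simulate_hic_pairs()` draws each valid pair's category independently:
intra-contig with probability `1 - alpha - epsilon`, intra-genome
(`alpha = 0.5`), or spurious cross-genome (`epsilon = 0.01`); contig and
position are sampled length-weighted, and within-contig separations follow
an insert size (400 bp) plus an exponential decay (scale 15 kb). Artifact
pairs (self-ligation, non-ligation, duplicates, low-quality) are injected
at fixed fractions and book-kept in a ledger; the simulator emits valid
same-fragment pairs in tandem orientation and keeps coordinate keys unique
(apart from the intended duplicates), so the classifier can reproduce the
ledger *exactly* — an end-to-end audit with no tolerance.

**Realism and limits.** The pair model is a three-way multinomial with an
exponential distance kernel; it reproduces the property the method relies
on (intra-genome contact mass ≫ cross-genome mass, decaying with distance)
but not fine chromatin structure (TADs, centromere clustering), mappability
variation, or copy-number effects. Sequence simulation is i.i.d. at a
target GC; there are no repeats, so mapping ambiguity enters only through
the injected low-quality class. E-value structure in
`simulate_hit_table()` is planted directly (self hits ~1e-175; non-self
ingroup hits 1e-30..1e-50, far weaker than self, as for nucleotide-level
comparisons against distant relatives; planted HGT genes receive outgroup
hits that set their AI band deterministically), which makes planted
categories exactly recoverable — the point of an oracle generator, at the
price of not modelling borderline alignment noise. Gene trees are random
background topologies with the query bound as sister to a bacterial or
eukaryotic tip according to the planted category.

# Numerical and design choices

* **Canonical pair ordering** before duplicate detection prevents
  orientation from splitting duplicates — otherwise duplicate counts would
  depend on read-file order.
* **Tandem orientation** for simulated same-fragment valid pairs: a
  same-fragment pair in outward or inward orientation is *definitionally*
  an artifact under the classification rules, so an honest generator must
  not emit it as valid.
* **Gap-heuristic `min_link`** rather than a fixed percentile: percentile
  thresholds sit inside the noise mode once spurious links outnumber
  genuine ones, collapsing the graph into one component. The gap statistic
  adapts to the actual separation between modes and degrades gracefully
  (keeps all links when no noise mode exists).
* **`min_count = 2` raw floor**: length normalization amplifies
  single-pair links between short contigs; the floor operates on raw
  evidence, where "one ligation event" is distinguishable from "many".
* **Deterministic tie-breaks** everywhere (vote ties, cluster-count ties)
  with warnings where a tie is scientifically ambiguous.
* **Midpoint rooting** for unrooted gene trees before the sister-clade
  test; the sister group is undefined on an unrooted tree.
* **Pseudo-count `exp(-200)`** keeps the AI finite under E-value
  underflow while being negligible (≈1.4e-87) relative to every E-value a
  search engine reports.
* Seeds are explicit arguments of every simulator; identical seeds give
  byte-identical output.

# A worked example

```{r example}
spec <- community_spec(host_chromosomes = 2, host_chrom_length = 60000,
                       n_bacteria = 3, bacterial_genome_length = 30000,
                       contig_length_mean = 10000, n_host_unplaced = 2)
comm <- simulate_community(spec, seed = 1)
hp <- simulate_hic_pairs(comm, hic_model(n_pairs = 30000), seed = 1)
cls <- classify_pairs(hp$pairs, hp$rmap)
table(cls)

lens <- setNames(comm$truth$length, comm$truth$contig)
m <- build_contact_matrix(hp$pairs, cls, contigs = comm$truth$contig,
                          lengths = lens)
sim <- simulate_hit_table(comm, seed = 1,
                          hgt_counts = c(strong = 4, partial = 2, weak = 3))
asg <- deconvolve(m, sim$hits, genes = sim$genes)
asg

trees <- simulate_gene_trees(sim$gene_truth, seed = 1)
host_genes <- sim$genes[sim$gene_truth$role == "host", ]
scr <- screen_genome(host_genes,
                     sim$hits[sim$hits$query %in% host_genes$gene, ],
                     trees = trees)
scr$summary
```

The assignment recovers the planted structure exactly on this community,
and the screen's strong/partial/weak counts equal the planted 4/2/3.
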