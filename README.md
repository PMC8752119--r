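# metahic

Deconvolution of a jointly assembled host + epiphyte community using Hi-C
proximity ligation, plus an Alien-Index screen for horizontally
transferred genes.

## The problem

Hosts that cannot be grown axenically — macroalgae are the motivating
case — are sequenced together with their tightly associated epiphytic
bacteria, so the assembly mixes host and bacterial contigs. Hi-C read
pairs come from ligation of chromatin that was crosslinked *inside one
cell*, which makes inter-contig contact counts overwhelmingly
intra-genome. `metahic` uses that signal to separate the assembly:

1. **Pair QC** — each read pair is classified as `VALID`,
   `SELF_LIGATION`, `NON_LIGATION`, `DUPLICATE` or `LOW_QUALITY` using
   restriction-fragment co-membership, strand orientation, coordinate
   identity and mapping quality.
2. **Contact matrix** — valid pairs are counted into a symmetric
   contig-level matrix and normalized by the product of contig lengths.
3. **Clustering + taxonomy vote** — contigs are clustered on the
   thresholded contact graph (a weight-aware gap heuristic picks the
   threshold between the cross-genome noise mode and genuine links), and
   each cluster is labelled by a bit-score-weighted vote over its
   alignment hits. Every contig ends up in one of four groups:
   `HOST_CHROMOSOMAL`, `EPIPHYTE_BIN`, `HOST_UNPLACED`, `UNKNOWN`.
4. **HGT screen** — for each host gene, with `bbh_in`/`bbh_out` the best
   ingroup/outgroup E-values (self-lineage hits removed at the genus
   rank), the Alien Index is

   ```
   AI = ln(bbh_in + c) − ln(bbh_out + c),   c = e^(−200)
   ```

   Genes with `AI > 10` are *strong* candidates if they cluster with
   bacterial sequences in their gene tree (sister-clade test on the
   midpoint-rooted tree) and *partial* otherwise; `0 < AI ≤ 10` is *weak*;
   `AI ≤ 0` is a non-candidate.

A synthetic-data module generates communities, Hi-C pairs with an exact
injection ledger, taxonomy-annotated hit tables and gene trees with
planted ground truth, so the whole pipeline is testable offline. The
methods vignette (`vignettes/metahic-methods.Rmd`) documents the model,
parameters, generator realism and numerical choices.

## Worked example

```r
library(metahic)

spec <- community_spec(host_chromosomes = 2, host_chrom_length = 60000,
                       n_bacteria = 3, bacterial_genome_length = 30000,
                       contig_length_mean = 10000, n_host_unplaced = 2)
comm <- simulate_community(spec, seed = 1)
comm
#> hic_community: 22 contigs from 9 genomes ( 12 host / 8 bacterial / 2 unknown )

hp <- simulate_hic_pairs(comm, hic_model(n_pairs = 30000), seed = 1)
cls <- classify_pairs(hp$pairs, hp$rmap)
table(cls)
#>   LOW_QUALITY     DUPLICATE SELF_LIGATION  NON_LIGATION         VALID
#>           600           600           900           900         30000

lens <- setNames(comm$truth$length, comm$truth$contig)
m <- build_contact_matrix(hp$pairs, cls, contigs = comm$truth$contig,
                          lengths = lens)
sim <- simulate_hit_table(comm, seed = 1,
                          hgt_counts = c(strong = 4, partial = 2, weak = 3))
asg <- deconvolve(m, sim$hits, genes = sim$genes)
asg
#> group_assignment:
#>
#> HOST_CHROMOSOMAL     EPIPHYTE_BIN    HOST_UNPLACED          UNKNOWN
#>               10                8                2                2

trees <- simulate_gene_trees(sim$gene_truth, seed = 1)
host_genes <- sim$genes[sim$gene_truth$role == "host", ]
scr <- screen_genome(host_genes,
                     sim$hits[sim$hits$query %in% host_genes$gene, ],
                     trees = trees)
scr$summary
#>   n_genes n_ai_positive n_strong n_partial n_weak n_non_candidate
#> 1     120             9        4         2      3             111

head(subset(scr$results, category == "strong"), 3)
#>      gene       contig       bbh_in      bbh_out        ai clusters_with_bacteria category
#> 1  g00001 hostchr1_c01 2.424646e-11 9.191963e-50  88.46817                   TRUE   strong
#> 34 g00034 hostchr1_c04 1.477458e-09 3.622377e-57 109.62728                   TRUE   strong
#> 39 g00039 hostchr1_c05 5.770784e-09 3.966126e-54 103.99135                   TRUE   strong
```

The pair-class table reproduces the simulator's injection ledger exactly;
the four-group assignment matches the planted truth contig for contig
(the 22 contigs are 10 linked host + 8 bacterial + 2 unplaced host + 2
unknown); and the screen recovers the planted 4 strong / 2 partial /
3 weak HGT genes with no false positives among the 111 ordinary genes.

## Command line

A thin CLI over the same functions ships in `inst/cli/metahic.R`
(after installation: `system.file("cli", "metahic.R", package =
"metahic")`), with subcommands `simulate`, `contacts`, `deconvolve`,
`hgt`, `stats` and `shared`.

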