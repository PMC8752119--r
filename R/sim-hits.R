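# lineage pools used by the hit simulator (seven-rank convention)
SIM_SELF_LINEAGE <- paste("Eukaryota", "Rhodophyta", "Bangiophyceae",
                          "Bangiales", "Bangiaceae", "Pyropia",
                          "Pyropia haitanensis", sep = ";")
SIM_INGROUP_LINEAGES <- c(
  "Eukaryota;Rhodophyta;Bangiophyceae;Bangiales;Bangiaceae;Porphyra;Porphyra umbilicalis",
  "Eukaryota;Rhodophyta;Florideophyceae;Gigartinales;Gigartinaceae;Chondrus;Chondrus crispus",
  "Eukaryota;Rhodophyta;Cyanidiophyceae;Cyanidiales;Galdieriaceae;Galdieria;Galdieria sulphuraria",
  "Eukaryota;Rhodophyta;Florideophyceae;Gracilariales;Gracilariaceae;Gracilariopsis;Gracilariopsis chorda")
SIM_OUTGROUP_LINEAGES <- c(
  "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Stappiaceae;Stappia;Stappia sp",
  "Bacteria;Bacteroidota;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Maribacter;Maribacter sp",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Phaeomarinobacteraceae;Phaeomarinobacter;Phaeomarinobacter ectocarpi",
  "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Halobacteriaceae;Halobacterium;Halobacterium salinarum")

#' Tile genes uniformly along the contigs of a community
#'
#' Places non-overlapping genes at a fixed spacing (about one gene per
#' kilobase) on every contig long enough to hold at least one; short contigs
#' receive proportionally fewer genes.
#'
#' @param community A `hic_community`.
#' @param gene_length Gene length in bases.
#' @param gene_spacing Start-to-start spacing in bases.
#' @param min_contig_length Contigs shorter than this receive no genes.
#' @return Data frame with columns `gene`, `contig`, `start`, `end`,
#'   `strand` (1-based, closed intervals).
#' @export
tile_genes <- function(community, gene_length = 400L, gene_spacing = 1000L,
                       min_contig_length = 2000L) {
  stopifnot(inherits(community, "hic_community"))
  truth <- community$truth
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    L <- truth$length[i]
    if (L < min_contig_length) next
    n <- (L - 200L) %/% gene_spacing
    if (n < 1) next
    starts <- 200L + (seq_len(n) - 1L) * gene_spacing
    rows[[length(rows) + 1L]] <- data.frame(
      contig = truth$contig[i], start = starts,
      end = pmin(starts + gene_length - 1L, L), strand = "+",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$gene <- sprintf("g%05d", seq_len(nrow(out)))
  out[, c("gene", "contig", "start", "end", "strand")]
}

# assemble hit rows from queries, log10 E-values and lineages
make_hits <- function(query, l10, lineage) {
  n <- length(query)
  if (n == 0) return(NULL)
  data.frame(query = query,
             subject = sprintf("WP_%06d", sample.int(999999L, n, replace = TRUE)),
             pident = round(runif(n, 70, 99), 1),
             length = round(runif(n, 100, 400)),
             evalue = 10^l10,
             bitscore = round(-1.8 * l10 + 25 + rnorm(n, 0, 2), 1),
             lineage = lineage, stringsAsFactors = FALSE)
}

#' Simulate a taxonomy-annotated hit table with planted HGT genes
#'
#' Tiles genes along the community's contigs and emits, per gene, BLAST-like
#' hits (query, subject, percent identity, alignment length, E-value, bit
#' score, lineage) whose E-value structure encodes the planted truth:
#'
#' * genes on host contigs get a very strong self hit (recipient lineage)
#'   plus ingroup hits; planted `strong`/`partial` genes additionally get
#'   outgroup (bacterial) best hits far below their ingroup best, so the
#'   downstream Alien Index exceeds 10; planted `weak` genes get an AI in
#'   (0, 10]; unplanted genes get AI <= 0;
#' * genes on bacterial contigs get bacterial hits only;
#' * genes on unknown contigs receive no hits at all.
#'
#' @param community A `hic_community`.
#' @param seed Integer seed; the table is identical across runs for a fixed
#'   seed.
#' @param hgt_counts Named counts of genes planted per category
#'   (`strong`, `partial`, `weak`), drawn from genes on linked host contigs.
#' @param genes Optional pre-computed gene table from [tile_genes()].
#' @return A `hit_simulation` object: list with `genes`, `hits` and
#'   `gene_truth` (columns `gene`, `contig`, `role`, `category` in
#'   strong/partial/weak/none).
#' @export
simulate_hit_table <- function(community, seed,
                               hgt_counts = c(strong = 30, partial = 10,
                                              weak = 20),
                               genes = NULL) {
  stopifnot(inherits(community, "hic_community"))
  set.seed(as.integer(seed))
  genes <- genes %||% tile_genes(community)
  truth <- community$truth
  role <- truth$role[match(genes$contig, truth$contig)]
  linked <- truth$linked[match(genes$contig, truth$contig)]
  hgt_counts <- hgt_counts[intersect(c("strong", "partial", "weak"),
                                     names(hgt_counts))]
  n_hgt <- sum(hgt_counts)
  host_pool <- which(role == "host" & linked)
  if (n_hgt > length(host_pool))
    stop_config("simulate_hit_table: fewer linked host genes than planted HGT genes")
  planted <- sample(host_pool, n_hgt)
  category <- rep("none", nrow(genes))
  category[planted] <- rep(names(hgt_counts), hgt_counts)

  # vectorized hit generation; unknown-role genes receive no hits at all
  hi <- which(role == "host")
  gh <- genes$gene[hi]
  ch <- category[hi]
  nh <- length(hi)
  high <- ch %in% c("strong", "partial")
  u0 <- runif(nh, -9, -8)                     # weak-gene ingroup anchor
  d <- runif(nh, 0.5, 4)                      # weak-gene AI = d * ln(10)
  # every host gene: one very strong self hit plus two ingroup hits;
  # cross-species ingroup hits are much weaker than the self hit, as for
  # nucleotide-level comparisons against distant congeners
  in1 <- ifelse(ch == "none", runif(nh, -50, -30),
                ifelse(ch == "weak", u0, runif(nh, -12, -8)))
  in2 <- ifelse(ch == "none", runif(nh, -50, -30),
                ifelse(ch == "weak", u0 + 2, runif(nh, -12, -8)))
  # outgroup hits: strong/partial share the hit signature (AI >> 10; the
  # tree placement, not the hit table, separates them); weak genes beat
  # their ingroup best by d decades; some unplanted genes get a marginal
  # bacterial hit that keeps AI <= 0
  out1 <- ifelse(high, runif(nh, -60, -40),
                 ifelse(ch == "weak", u0 - d, runif(nh, -5, -1)))
  keep_out1 <- high | ch == "weak" | runif(nh) < 0.3
  out2 <- runif(nh, -60, -40)
  bi <- which(role == "bacterial")
  gb <- rep(genes$gene[bi], each = 3L)
  hits <- rbind(
    make_hits(gh, runif(nh, -180, -170), SIM_SELF_LINEAGE),
    make_hits(rep(gh, 2L), c(in1, in2),
              sample(SIM_INGROUP_LINEAGES, 2L * nh, replace = TRUE)),
    make_hits(gh[keep_out1], out1[keep_out1],
              sample(SIM_OUTGROUP_LINEAGES, sum(keep_out1), replace = TRUE)),
    make_hits(gh[high], out2[high],
              sample(SIM_OUTGROUP_LINEAGES, sum(high), replace = TRUE)),
    make_hits(gb, runif(length(gb), -120, -80),
              sample(SIM_OUTGROUP_LINEAGES, length(gb), replace = TRUE)))
  hits <- hits[order(match(hits$query, genes$gene)), , drop = FALSE]
  rownames(hits) <- NULL
  gene_truth <- data.frame(gene = genes$gene, contig = genes$contig,
                           role = role, category = category,
                           stringsAsFactors = FALSE)
  out <- list(genes = genes, hits = hits, gene_truth = gene_truth)
  class(out) <- "hit_simulation"
  out
}

#' @export
print.hit_simulation <- function(x, ...) {
  cat("hit_simulation:", nrow(x$genes), "genes,", nrow(x$hits), "hits;",
      "planted:", sum(x$gene_truth$category == "strong"), "strong /",
      sum(x$gene_truth$category == "partial"), "partial /",
      sum(x$gene_truth$category == "weak"), "weak\n")
  invisible(x)
}
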