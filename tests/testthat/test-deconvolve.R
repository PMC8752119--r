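host_lineage <- "Eukaryota;Rhodophyta;Bangiophyceae;Bangiales;Bangiaceae;Pyropia;Pyropia haitanensis"
bact_lineage <- "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Stappiaceae;Stappia;Stappia sp"
other_lineage <- "Eukaryota;Chlorophyta;Ulvophyceae;Ulvales;Ulvaceae;Ulva;Ulva prolifera"

hit_row <- function(lineage, bitscore, evalue = 1e-20, query = "q1") {
  data.frame(query = query, evalue = evalue, bitscore = bitscore,
             lineage = lineage, stringsAsFactors = FALSE)
}

test_that("tax_vote_params validates its inputs", {
  expect_error(tax_vote_params(min_hit_evalue = 0), "min_hit_evalue")
  expect_error(tax_vote_params(vote_fraction = 0.4), "vote_fraction")
  expect_error(tax_vote_params(vote_fraction = 1.1), "vote_fraction")
})

test_that("bit-score vote follows its worked examples", {
  # 60 host vs 40 bacterial: host share 0.6 >= 0.5
  hits <- rbind(hit_row(host_lineage, 60), hit_row(bact_lineage, 40))
  expect_equal(assign_taxonomy(hits), "host")
  # reversed weights
  hits2 <- rbind(hit_row(host_lineage, 40), hit_row(bact_lineage, 60))
  expect_equal(assign_taxonomy(hits2), "bacterial")
  # share below a stricter vote_fraction: no call
  expect_equal(assign_taxonomy(hits, tax_vote_params(vote_fraction = 0.7)),
               "none")
  # exact tie: deterministic break toward bacterial, with a warning
  hits3 <- rbind(hit_row(host_lineage, 50), hit_row(bact_lineage, 50))
  expect_warning(out <- assign_taxonomy(hits3), "tie")
  expect_equal(out, "bacterial")
  # dominant "other" class never wins
  hits4 <- rbind(hit_row(other_lineage, 90), hit_row(bact_lineage, 10))
  expect_equal(assign_taxonomy(hits4), "none")
})

test_that("hits above the E-value ceiling are discarded", {
  hits <- rbind(hit_row(bact_lineage, 500, evalue = 1e-3),
                hit_row(host_lineage, 10, evalue = 1e-10))
  expect_equal(assign_taxonomy(hits), "host")
  expect_equal(assign_taxonomy(hit_row(bact_lineage, 50, evalue = 1)),
               "none")
  expect_equal(assign_taxonomy(NULL), "none")
})

test_that("malformed lineages raise an error naming the record", {
  hits <- hit_row(NA_character_, 50, query = "gene_bad")
  expect_error(assign_taxonomy(hits), "gene_bad")
})

test_that("deconvolution recovers all four groups on a planted community", {
  comm <- simulate_community(tiny_spec(), seed = 31)
  hp <- simulate_hic_pairs(comm, hic_model(n_pairs = 30000), seed = 31)
  cls <- classify_pairs(hp$pairs, hp$rmap)
  lens <- setNames(comm$truth$length, comm$truth$contig)
  m <- build_contact_matrix(hp$pairs, cls, contigs = comm$truth$contig,
                            lengths = lens)
  sim <- simulate_hit_table(comm, seed = 31,
                            hgt_counts = c(strong = 4, partial = 2,
                                           weak = 3))
  asg <- deconvolve(m, sim$hits, genes = sim$genes)
  tr <- comm$truth
  expected <- ifelse(tr$role == "host" & tr$linked, "HOST_CHROMOSOMAL",
              ifelse(tr$role == "host", "HOST_UNPLACED",
              ifelse(tr$role == "bacterial", "EPIPHYTE_BIN", "UNKNOWN")))
  got <- asg$groups$group[match(tr$contig, asg$groups$contig)]
  expect_identical(got, expected)
  expect_setequal(unique(got), c("HOST_CHROMOSOMAL", "EPIPHYTE_BIN",
                                 "HOST_UNPLACED", "UNKNOWN"))
  # every epiphyte bin is pure: one source genome per cluster
  ep <- asg$groups[asg$groups$group == "EPIPHYTE_BIN", ]
  tab <- table(ep$cluster, tr$genome[match(ep$contig, tr$contig)])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("hit queries that are contig ids are used directly", {
  p <- data.frame(contig1 = rep("c1", 3), pos1 = c(1L, 5L, 9L),
                  strand1 = "+", contig2 = rep("c2", 3),
                  pos2 = c(2L, 6L, 10L), strand2 = "+",
                  stringsAsFactors = FALSE)
  m <- build_contact_matrix(p, contigs = c("c1", "c2"),
                            lengths = c(c1 = 1000, c2 = 1000))
  hits <- rbind(hit_row(host_lineage, 60, query = "c1"),
                hit_row(host_lineage, 60, query = "c2"))
  asg <- deconvolve(m, hits, min_count = 1)
  expect_true(all(asg$groups$group == "HOST_CHROMOSOMAL"))
})

test_that("gene-mediated hits without a gene table raise an error", {
  p <- data.frame(contig1 = "c1", pos1 = 1L, strand1 = "+",
                  contig2 = "c2", pos2 = 2L, strand2 = "+",
                  stringsAsFactors = FALSE)
  m <- build_contact_matrix(p, contigs = c("c1", "c2"),
                            lengths = c(c1 = 1000, c2 = 1000))
  hits <- hit_row(host_lineage, 60, query = "gene7")
  expect_error(deconvolve(m, hits), "genes")
})

test_that("n50 matches its worked example and the brute-force oracle", {
  expect_equal(n50(c(10, 9, 8, 7, 6)), 8)
  expect_equal(n50(5), 5)
  expect_equal(n50(c(2, 2, 2, 2)), 2)
  expect_error(n50(numeric(0)))
  set.seed(77)
  for (i in 1:25) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("gc_fraction counts G+C over ACGT only", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("AATT"), 0)
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction(c("AC", "GT")), 0.5)
  expect_equal(gc_fraction("ACGTNNNN"), 0.5)  # ambiguity codes ignored
})

test_that("assembly_stats reports per-group statistics", {
  seqs <- Biostrings::DNAStringSet(c(h1 = "GGGGCCCCGG", h2 = "GGGGGG",
                                     b1 = "AAAATTTT"))
  st <- assembly_stats(seqs)
  expect_equal(st$n_contigs, 3)
  expect_equal(st$total_length, 24)
  expect_equal(st$n50, 8)
  groups <- data.frame(contig = c("h1", "h2", "b1"),
                       group = c("HOST_CHROMOSOMAL", "HOST_CHROMOSOMAL",
                                 "EPIPHYTE_BIN"),
                       cluster = NA_character_, taxonomy = NA_character_,
                       stringsAsFactors = FALSE)
  asg <- structure(list(groups = groups), class = "group_assignment")
  sh <- assembly_stats(seqs, asg, "HOST_CHROMOSOMAL")
  expect_equal(sh$n_contigs, 2)
  expect_equal(sh$gc_fraction, 1)
  expect_error(assembly_stats(seqs, asg, "UNKNOWN"), "no contigs")
})

test_that("shared screen excludes coverage of exactly the threshold", {
  cov <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                    dataset = c("d1", "d2", "d1", "d1"),
                    covered_fraction = c(0.95, 0.91, 0.90, 0.89))
  out <- shared_sequence_screen(cov)
  expect_equal(out$n_datasets[out$gene == "g1"], 2L)
  expect_equal(out$n_datasets[out$gene == "g2"], 0L)  # 0.90 excluded
  expect_false(out$shared[out$gene == "g3"])
  expect_true(out$shared[out$gene == "g1"])
  out2 <- shared_sequence_screen(cov, min_datasets = 2L)
  expect_identical(out2$gene[out2$shared], "g1")
  expect_error(shared_sequence_screen(transform(cov,
                                                covered_fraction = 1.5)),
               "covered_fraction")
})
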