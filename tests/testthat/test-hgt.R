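ing <- "Eukaryota;Rhodophyta;Bangiophyceae;Bangiales;Bangiaceae;Porphyra;Porphyra umbilicalis"
outg <- "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Stappiaceae;Stappia;Stappia sp"
selfl <- "Eukaryota;Rhodophyta;Bangiophyceae;Bangiales;Bangiaceae;Pyropia;Pyropia haitanensis"

ai_hits <- function(ein = NULL, eout = NULL, eself = NULL, query = "g1") {
  rows <- list()
  for (e in ein) rows[[length(rows) + 1]] <-
    data.frame(query = query, evalue = e, lineage = ing)
  for (e in eout) rows[[length(rows) + 1]] <-
    data.frame(query = query, evalue = e, lineage = outg)
  for (e in eself) rows[[length(rows) + 1]] <-
    data.frame(query = query, evalue = e, lineage = selfl)
  do.call(rbind, rows)
}

expected_ai <- function(bbh_in, bbh_out)
  log(bbh_in + exp(-200)) - log(bbh_out + exp(-200))

test_that("taxon_partition validates its inputs", {
  expect_error(taxon_partition(recipient_lineage = ""), "lineage")
  expect_error(taxon_partition(skip_rank = "tribe"), "skip_rank")
  expect_error(taxon_partition(recipient_lineage = "Eukaryota;Rhodophyta"),
               "genus")
  expect_error(taxon_partition(ingroup_superkingdom = "Bacteria"),
               "disjoint")
  expect_error(taxon_partition(pseudocount = 0), "pseudocount")
})

test_that("alien_index matches the closed form", {
  p <- taxon_partition()
  r <- alien_index(ai_hits(ein = 1e-10, eout = 1e-40), p)
  expect_equal(r$ai, expected_ai(1e-10, 1e-40), tolerance = 1e-12)
  expect_equal(r$ai, 30 * log(10), tolerance = 1e-6)
  # best (smallest) E-value on each side is used
  r2 <- alien_index(ai_hits(ein = c(1e-10, 1e-3), eout = c(1e-40, 1e-2)), p)
  expect_equal(r2$ai, r$ai, tolerance = 1e-12)
  expect_equal(r2$n_in, 2L)
  expect_equal(r2$n_out, 2L)
  # equal best hits on both sides: AI exactly 0
  expect_equal(alien_index(ai_hits(ein = 1e-7, eout = 1e-7), p)$ai, 0)
})

test_that("missing sides use no_hit_default and the pseudocount floors AI", {
  p <- taxon_partition()
  # no outgroup hit: AI = log(1e-50 + c) - log(1 + c) < 0
  r <- alien_index(ai_hits(ein = 1e-50), p)
  expect_equal(r$ai, expected_ai(1e-50, 1), tolerance = 1e-12)
  expect_lt(r$ai, -100)
  # no ingroup hit: strongly positive
  r2 <- alien_index(ai_hits(eout = 1e-50), p)
  expect_equal(r2$ai, expected_ai(1, 1e-50), tolerance = 1e-12)
  # the pseudocount bounds |AI| even for E = 0
  r3 <- alien_index(ai_hits(ein = 1, eout = 0), p)
  expect_equal(r3$ai, log(1 + exp(-200)) - (-200), tolerance = 1e-9)
  expect_lt(r3$ai, 201)
})

test_that("self-lineage hits are skipped at the genus rank", {
  p <- taxon_partition()
  # a very strong self hit must not mask the outgroup signal
  r <- alien_index(ai_hits(ein = 1e-10, eout = 1e-40, eself = 1e-180), p)
  expect_equal(r$ai, expected_ai(1e-10, 1e-40), tolerance = 1e-12)
  expect_equal(r$n_in, 1L)
  # only self hits: both sides fall back to no_hit_default
  r2 <- alien_index(ai_hits(eself = 1e-180), p)
  expect_equal(r2$ai, 0)
  expect_equal(r2$n_in, 0L)
  expect_false(r2$no_evidence)
})

test_that("alien_index handles empty and malformed input", {
  p <- taxon_partition()
  r <- alien_index(NULL, p)
  expect_true(r$no_evidence)
  expect_equal(r$ai, 0)
  bad <- data.frame(query = "gX", evalue = 1e-10, lineage = NA_character_)
  expect_error(alien_index(bad, p), "gX")
  two <- rbind(ai_hits(ein = 1e-5, query = "a"),
               ai_hits(ein = 1e-5, query = "b"))
  expect_error(alien_index(two, p), "single query")
})

test_that("AI is antisymmetric and monotone", {
  p <- taxon_partition()
  set.seed(13)
  for (i in 1:20) {
    a <- 10^runif(1, -60, 0)
    b <- 10^runif(1, -60, 0)
    expect_equal(alien_index(ai_hits(ein = a, eout = b), p)$ai,
                 -alien_index(ai_hits(ein = b, eout = a), p)$ai,
                 tolerance = 1e-9)
  }
  # fixed ingroup hit, strengthening outgroup hits: AI strictly increases
  eo <- 10^seq(-5, -60, by = -5)
  ai <- vapply(eo, function(e)
    alien_index(ai_hits(ein = 1e-8, eout = e), p)$ai, 0)
  expect_true(all(diff(ai) > 0))
})

test_that("classify_hgt implements the category rule table", {
  expect_equal(
    classify_hgt(c(-3, 0, 4, 10, 12, 12, 12),
                 c(NA, NA, NA, TRUE, TRUE, FALSE, NA)),
    c("non-candidate", "non-candidate", "weak", "weak",
      "strong", "partial", "partial"))
  # thresholds are configurable
  expect_equal(classify_hgt(7, TRUE, ai_strong = 5), "strong")
  expect_equal(classify_hgt(0.5, NA, ai_candidate = 1), "non-candidate")
})

test_that("sister-clade test follows its worked examples", {
  expect_true(tree_bacterial_clustering(
    "((q:1,Bacteria|b1:1):1,(Eukaryota|e1:1,Eukaryota|e2:1):1);", "q"))
  expect_false(tree_bacterial_clustering(
    "((q:1,Eukaryota|e1:1):1,(Bacteria|b1:1,Bacteria|b2:1):1);", "q"))
  # Archaea count as bacterial donors
  expect_true(tree_bacterial_clustering(
    "((q:1,Archaea|a1:1):1,(Eukaryota|e1:1,Eukaryota|e2:1):1);", "q"))
  # mixed sister group: fraction threshold decides
  mixed <- "((q:1,(Bacteria|b1:1,Eukaryota|e1:1):1):1,(Eukaryota|e2:1,Eukaryota|e3:1):1);"
  expect_false(tree_bacterial_clustering(mixed, "q"))
  expect_true(tree_bacterial_clustering(mixed, "q", sister_fraction = 0.5))
})

test_that("node support gates the sister-clade call", {
  sup <- "((q:1,Bacteria|b1:1)40:1,(Eukaryota|e1:1,Eukaryota|e2:1)99:1);"
  expect_true(tree_bacterial_clustering(sup, "q"))
  expect_false(tree_bacterial_clustering(sup, "q", min_support = 70))
  expect_true(tree_bacterial_clustering(sup, "q", min_support = 30))
})

test_that("tree input errors are reported", {
  expect_error(tree_bacterial_clustering(
    "((q:1,Bacteria|b1:1):1,(Eukaryota|e1:1,Eukaryota|e2:1):1);", "zz"),
    "zz")
  expect_error(tree_bacterial_clustering("((q:1,b:1):1,(c:1,d:1):1);", "q"),
               "taxonomy tag")
})

test_that("simulated gene trees plant the sister placement", {
  gene_truth <- data.frame(gene = c("gS", "gP", "gW"),
                           contig = "c1", role = "host",
                           category = c("strong", "partial", "weak"),
                           stringsAsFactors = FALSE)
  trees <- simulate_gene_trees(gene_truth, seed = 3,
                               categories = c("strong", "partial", "weak"))
  expect_true(tree_bacterial_clustering(trees$gS, "gS"))
  expect_false(tree_bacterial_clustering(trees$gP, "gP"))
  expect_false(tree_bacterial_clustering(trees$gW, "gW"))
  # deterministic per (seed, gene); distinct genes get distinct trees
  again <- simulate_gene_tree("gS", gene_truth, seed = 3)
  expect_identical(ape::write.tree(again), ape::write.tree(trees$gS))
  expect_false(identical(ape::write.tree(trees$gP),
                         ape::write.tree(trees$gS)))
  expect_error(simulate_gene_tree("nope", gene_truth, seed = 1), "nope")
})

test_that("hit simulator plants AI-resolvable categories", {
  comm <- simulate_community(tiny_spec(), seed = 41)
  sim <- simulate_hit_table(comm, seed = 41,
                            hgt_counts = c(strong = 5, partial = 3,
                                           weak = 4))
  expect_equal(sum(sim$gene_truth$category == "strong"), 5)
  expect_equal(sum(sim$gene_truth$category == "partial"), 3)
  expect_equal(sum(sim$gene_truth$category == "weak"), 4)
  # planted genes sit on linked host contigs
  tr <- comm$truth
  planted <- sim$gene_truth[sim$gene_truth$category != "none", ]
  idx <- match(planted$contig, tr$contig)
  expect_true(all(tr$role[idx] == "host" & tr$linked[idx]))
  # unknown-role genes carry no hits
  unk <- sim$gene_truth$gene[sim$gene_truth$role == "unknown"]
  expect_false(any(sim$hits$query %in% unk))
  # deterministic
  sim2 <- simulate_hit_table(comm, seed = 41,
                             hgt_counts = c(strong = 5, partial = 3,
                                            weak = 4))
  expect_identical(sim$hits, sim2$hits)
})

test_that("screen_genome recovers the planted categories", {
  comm <- simulate_community(tiny_spec(), seed = 43)
  sim <- simulate_hit_table(comm, seed = 43,
                            hgt_counts = c(strong = 5, partial = 3,
                                           weak = 4))
  host_genes <- sim$genes[sim$gene_truth$role %in% "host", ]
  host_hits <- sim$hits[sim$hits$query %in% host_genes$gene, ]
  trees <- simulate_gene_trees(sim$gene_truth, seed = 43)
  scr <- screen_genome(host_genes, host_hits, trees = trees)
  truthcat <- sim$gene_truth$category[match(scr$results$gene,
                                            sim$gene_truth$gene)]
  expected <- ifelse(truthcat == "none", "non-candidate", truthcat)
  expect_identical(scr$results$category, expected)
  expect_equal(scr$summary$n_strong, 5)
  expect_equal(scr$summary$n_partial, 3)
  expect_equal(scr$summary$n_weak, 4)
  expect_equal(scr$summary$n_ai_positive, 12)
})

test_that("screen_genome warns about orphan hits and reads tree files", {
  genes <- data.frame(gene = "g1", contig = "c1", stringsAsFactors = FALSE)
  hits <- rbind(ai_hits(eout = 1e-40, query = "g1"),
                ai_hits(eout = 1e-40, query = "orphan"))
  dir <- tempfile("trees")
  gene_truth <- data.frame(gene = "g1", contig = "c1", role = "host",
                           category = "strong", stringsAsFactors = FALSE)
  write_gene_trees(simulate_gene_trees(gene_truth, seed = 1,
                                       categories = "strong"), dir)
  on.exit(unlink(dir, recursive = TRUE))
  expect_warning(scr <- screen_genome(genes, hits, trees = dir), "orphan")
  expect_identical(scr$results$category, "strong")
})
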