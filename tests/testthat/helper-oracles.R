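# Independent brute-force oracles and small fixtures shared by the tests.
# Each oracle re-implements the scientific rule from scratch (loops, no
# shared helper code) so agreement with the package is a real check.

# ---- pair classification oracle -------------------------------------------
# Walks the pairs one by one, keeping an explicit registry of coordinate
# keys seen so far. Rules applied in priority order per pair.
oracle_classify <- function(pairs, rmap, min_mapq = 20L) {
  seen <- character(0)
  n <- nrow(pairs)
  out <- character(n)
  frag_of <- function(contig, pos) {
    b <- rmap[[contig]]
    sum(b <= pos - 1L)  # 0-based half-open fragments
  }
  for (r in seq_len(n)) {
    c1 <- pairs$contig1[r]; p1 <- pairs$pos1[r]; s1 <- pairs$strand1[r]
    c2 <- pairs$contig2[r]; p2 <- pairs$pos2[r]; s2 <- pairs$strand2[r]
    # canonical end order: lexicographic contig, then position
    if (c2 < c1 || (c2 == c1 && p2 < p1)) {
      tmp <- c(c1, p1, s1)
      c1 <- c2; p1 <- as.integer(p2); s1 <- s2
      c2 <- tmp[1]; p2 <- as.integer(tmp[2]); s2 <- tmp[3]
    }
    key <- paste(c1, p1, s1, c2, p2, s2, collapse = " ")
    mq1 <- if (is.null(pairs$mapq1)) 255L else pairs$mapq1[r]
    mq2 <- if (is.null(pairs$mapq2)) 255L else pairs$mapq2[r]
    label <- if (min(mq1, mq2) < min_mapq) {
      "LOW_QUALITY"
    } else if (key %in% seen) {
      "DUPLICATE"
    } else if (c1 == c2 && frag_of(c1, p1) == frag_of(c2, p2) &&
               s1 == "-" && s2 == "+") {
      "SELF_LIGATION"
    } else if (c1 == c2 && frag_of(c1, p1) == frag_of(c2, p2) &&
               s1 == "+" && s2 == "-") {
      "NON_LIGATION"
    } else {
      "VALID"
    }
    seen <- c(seen, key)
    out[r] <- label
  }
  out
}

# ---- N50 oracle ------------------------------------------------------------
# Definition-based: the largest length L present such that contigs of length
# >= L cover at least half the total assembly length.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  best <- NA_real_
  for (L in sort(unique(lengths))) {
    covered <- 0
    for (x in lengths) if (x >= L) covered <- covered + x
    if (covered >= total / 2 && (is.na(best) || L > best)) best <- L
  }
  best
}

# ---- GC oracle -------------------------------------------------------------
# Plain character counting over the concatenated sequences.
oracle_gc <- function(strings) {
  chars <- unlist(strsplit(toupper(paste(strings, collapse = "")), ""))
  n_gc <- sum(chars == "G" | chars == "C")
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  n_gc / n_acgt
}

# ---- sister-clade oracle ---------------------------------------------------
# Exhaustive clade enumeration: root (midpoint) the tree, list the tip set
# under every internal node by walking the edge matrix, take the smallest
# clade containing the query with at least two tips; the sister group is
# that clade minus the query.
oracle_sister_bacterial <- function(tree, query, sister_fraction = 1.0,
                                    bacterial = c("Bacteria", "Archaea")) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  nodes <- unique(tree$edge[, 1])
  tips_under <- function(node) {
    found <- integer(0)
    stack <- node
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      if (v <= ntip) found <- c(found, v) else
        stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
    }
    found
  }
  qi <- which(tree$tip.label == query)
  best <- NULL
  for (v in nodes) {
    tt <- tips_under(v)
    if (qi %in% tt && length(tt) >= 2 &&
        (is.null(best) || length(tt) < length(best))) best <- tt
  }
  sister <- setdiff(best, qi)
  if (length(sister) == 0) return(FALSE)
  sk <- sub("\\|.*$", "", tree$tip.label[sister])
  mean(sk %in% bacterial) >= sister_fraction
}

# ---- shared-gene screen oracle --------------------------------------------
oracle_shared <- function(coverage, threshold = 0.9, min_datasets = 1L) {
  genes <- sort(unique(coverage$gene))
  n <- integer(length(genes))
  for (i in seq_along(genes)) {
    rows <- which(coverage$gene == genes[i])
    for (r in rows)
      if (coverage$covered_fraction[r] > threshold) n[i] <- n[i] + 1L
  }
  data.frame(gene = genes, n_datasets = n, shared = n >= min_datasets,
             stringsAsFactors = FALSE)
}

# ---- small fixtures --------------------------------------------------------
tiny_spec <- function(...) {
  args <- list(host_chromosomes = 2, host_chrom_length = 60000,
               n_bacteria = 3, bacterial_genome_length = 30000,
               contig_length_mean = 10000, contig_length_sd = 2000,
               n_host_unplaced = 2, unknown_fraction = 0.1)
  override <- list(...)
  args[names(override)] <- override
  do.call(community_spec, args)
}

# Run the contact side of the pipeline and score the clustering against the
# planted genome labels of the linked contigs (unclustered contigs become
# singletons). ARI comes from mclust, an independent implementation.
pipeline_ari <- function(seed, epsilon, spec = community_spec(),
                         n_pairs = 100000) {
  comm <- simulate_community(spec, seed)
  model <- hic_model(n_pairs = n_pairs, epsilon = epsilon)
  hp <- simulate_hic_pairs(comm, model, seed)
  cls <- classify_pairs(hp$pairs, hp$rmap)
  lens <- setNames(comm$truth$length, comm$truth$contig)
  m <- build_contact_matrix(hp$pairs, cls, contigs = comm$truth$contig,
                            lengths = lens)
  m <- normalize_matrix(filter_contact_matrix(m), "length_product")
  memb <- cluster_membership(cluster_contigs(m))
  linked <- comm$truth$contig[comm$truth$linked]
  lab <- memb$cluster[match(linked, memb$contig)]
  if (anyNA(lab)) lab[is.na(lab)] <- paste0("solo", seq_len(sum(is.na(lab))))
  mclust::adjustedRandIndex(lab,
                            comm$truth$genome[match(linked,
                                                    comm$truth$contig)])
}
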