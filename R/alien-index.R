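#' Define the taxon partition for the Alien Index
#'
#' Splits hit lineages into three pools relative to the recipient genome:
#' hits to the recipient's own lineage (skipped at `skip_rank`, so the
#' recipient's own deposited sequences never mask a donor), the ingroup
#' (same superkingdom as the recipient, default Eukaryota, minus the
#' recipient lineage) and the outgroup (default Bacteria and Archaea, the
#' candidate donors).
#'
#' @param recipient_lineage Seven-rank semicolon-separated lineage of the
#'   recipient (superkingdom;phylum;class;order;family;genus;species).
#' @param skip_rank Rank at which self hits are recognised
#'   (`"genus"` by default; `"family"`, `"order"`, ... also accepted).
#' @param ingroup_superkingdom Superkingdom defining the ingroup.
#' @param outgroup_superkingdoms Superkingdoms defining the outgroup.
#' @param pseudocount Pseudo-count `c` added to both best E-values inside the
#'   log (default `exp(-200)`).
#' @param log_base Base of the logarithm (default natural log).
#' @return A `taxon_partition` object.
#' @export
taxon_partition <- function(recipient_lineage =
                              paste("Eukaryota", "Rhodophyta",
                                    "Bangiophyceae", "Bangiales",
                                    "Bangiaceae", "Pyropia",
                                    "Pyropia haitanensis", sep = ";"),
                            skip_rank = "genus",
                            ingroup_superkingdom = "Eukaryota",
                            outgroup_superkingdoms = c("Bacteria", "Archaea"),
                            pseudocount = exp(-200),
                            log_base = exp(1)) {
  ranks <- trimws(strsplit(recipient_lineage, ";", fixed = TRUE)[[1]])
  if (length(ranks) < 1 || !all(nzchar(ranks)))
    stop_config("taxon_partition: malformed recipient lineage")
  skip_idx <- match(skip_rank, LINEAGE_RANKS)
  if (is.na(skip_idx))
    stop_config("taxon_partition: 'skip_rank' must be one of ",
                paste(LINEAGE_RANKS, collapse = ", "))
  if (skip_idx > length(ranks))
    stop_config("taxon_partition: recipient lineage has no '", skip_rank,
                "' rank")
  if (ingroup_superkingdom %in% outgroup_superkingdoms)
    stop_config("taxon_partition: ingroup and outgroup must be disjoint")
  if (pseudocount <= 0)
    stop_config("taxon_partition: 'pseudocount' must be > 0")
  out <- list(recipient = ranks, skip_rank = skip_rank, skip_idx = skip_idx,
              ingroup_superkingdom = ingroup_superkingdom,
              outgroup_superkingdoms = outgroup_superkingdoms,
              pseudocount = pseudocount, log_base = log_base)
  class(out) <- "taxon_partition"
  out
}

#' Alien Index of one gene from its alignment hits
#'
#' Removes self-lineage hits at the partition's skip rank, takes the best
#' (smallest) E-value on each side of the partition — `bbh_in` over ingroup
#' hits, `bbh_out` over outgroup hits, substituting `no_hit_default` for an
#' empty side — and computes
#' `AI = log(bbh_in + c) - log(bbh_out + c)` with pseudo-count
#' `c = exp(-200)`. AI is positive exactly when the best outgroup hit is
#' stronger than the best ingroup hit.
#'
#' @param hits Data frame of hits for a single query gene, with columns
#'   `query`, `evalue`, `lineage`.
#' @param partition A [taxon_partition()].
#' @param no_hit_default E-value substituted when a side has no hits
#'   (default 1.0, contributing ~0 to the log).
#' @return One-row data frame: `gene`, `bbh_in`, `bbh_out`, `ai`, `n_in`,
#'   `n_out`, `no_evidence`. An empty hit list yields `ai = 0` with
#'   `no_evidence = TRUE`.
#' @examples
#' p <- taxon_partition()
#' h <- data.frame(query = "g1", evalue = c(1e-5, 1e-40),
#'   lineage = c("Eukaryota;x;x;x;x;Porphyra;Porphyra umbilicalis",
#'               "Bacteria;x;x;x;x;Stappia;Stappia sp"))
#' alien_index(h, p)$ai  # 35 * log(10), approximately
#' @export
alien_index <- function(hits, partition = taxon_partition(),
                        no_hit_default = 1.0) {
  stopifnot(inherits(partition, "taxon_partition"))
  gene <- if (!is.null(hits) && nrow(hits) > 0)
    unique(hits$query) else NA_character_
  if (length(gene) > 1)
    stop_config("alien_index: hits must belong to a single query gene")
  cc <- partition$pseudocount
  lb <- log(partition$log_base)
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(gene = gene, bbh_in = NA_real_, bbh_out = NA_real_,
                      ai = 0, n_in = 0L, n_out = 0L, no_evidence = TRUE,
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(hits$lineage, ";", fixed = TRUE)
  bad <- lengths(parts) < 1 | is.na(hits$lineage)
  if (any(bad))
    stop("malformed lineage string for record: ",
         paste(head(hits$query[bad], 3), collapse = ", "), call. = FALSE)
  sk <- vapply(parts, function(x) trimws(x[1]), "")
  idx <- partition$skip_idx
  self <- vapply(parts, function(x)
    length(x) >= idx && trimws(x[idx]) == partition$recipient[idx],
    FALSE)
  ing <- !self & sk == partition$ingroup_superkingdom
  outg <- !self & sk %in% partition$outgroup_superkingdoms
  bbh_in <- if (any(ing)) min(hits$evalue[ing]) else no_hit_default
  bbh_out <- if (any(outg)) min(hits$evalue[outg]) else no_hit_default
  ai <- (log(bbh_in + cc) - log(bbh_out + cc)) / lb
  data.frame(gene = gene, bbh_in = bbh_in, bbh_out = bbh_out, ai = ai,
             n_in = sum(ing), n_out = sum(outg), no_evidence = FALSE,
             stringsAsFactors = FALSE)
}

#' Categorize a gene's HGT evidence
#'
#' Applies the three-way rule on top of a non-candidate floor:
#' `AI <= ai_candidate` is a non-candidate; `ai_candidate < AI <= ai_strong`
#' is weak; `AI > ai_strong` is strong when the gene clusters with bacterial
#' sequences on its tree and partial otherwise (including when no tree is
#' available: a gene is never promoted to strong without tree evidence).
#'
#' @param ai Numeric AI value(s), or a result from [alien_index()].
#' @param clusters_with_bacteria Logical (may be `NA` for unknown), recycled.
#' @param ai_strong Strong-candidate threshold (default 10).
#' @param ai_candidate Candidate floor (default 0).
#' @return Character vector in
#'   `strong, partial, weak, non-candidate`.
#' @export
classify_hgt <- function(ai, clusters_with_bacteria = NA,
                         ai_strong = 10, ai_candidate = 0) {
  if (is.data.frame(ai)) ai <- ai$ai
  k <- rep_len(clusters_with_bacteria, length(ai))
  out <- rep("non-candidate", length(ai))
  out[ai > ai_candidate & ai <= ai_strong] <- "weak"
  hi <- ai > ai_strong
  out[hi & !is.na(k) & k] <- "strong"
  out[hi & (is.na(k) | !k)] <- "partial"
  out
}

#' Genome-wide HGT screen
#'
#' Computes the Alien Index for every gene, runs the sister-clade
#' bacterial-clustering test where a gene tree is available, categorizes
#' each gene (strong / partial / weak / non-candidate) and summarizes the
#' results, including how many AI-positive genes reside on host chromosomal
#' contigs. By default only genes on host-assigned contigs
#' (`HOST_CHROMOSOMAL`, `HOST_UNPLACED`) are screened when a group
#' assignment is supplied: the screen asks what the host genome acquired,
#' so genes on epiphyte or unknown contigs are out of scope.
#'
#' @param genes Gene table (columns `gene`, `contig`).
#' @param hits Hit table (columns `query`, `evalue`, `lineage`); hits whose
#'   query is absent from `genes` are skipped with a warning.
#' @param partition A [taxon_partition()].
#' @param trees Optional per-gene trees: a named list of `phylo` objects, or
#'   a directory containing `<gene>.nwk` files.
#' @param assignment Optional `group_assignment` from [deconvolve()].
#' @param groups Groups whose genes are screened when `assignment` is given.
#' @param no_hit_default,ai_strong,ai_candidate See [alien_index()] and
#'   [classify_hgt()].
#' @param min_support,sister_fraction Passed to
#'   [tree_bacterial_clustering()].
#' @return An `hgt_screen` object: list with `results` (per-gene data frame:
#'   `gene`, `contig`, `group`, `on_chromosome`, `bbh_in`, `bbh_out`, `ai`,
#'   `clusters_with_bacteria`, `category`) and `summary` (one-row data
#'   frame of counts).
#' @export
screen_genome <- function(genes, hits, partition = taxon_partition(),
                          trees = NULL, assignment = NULL,
                          groups = c("HOST_CHROMOSOMAL", "HOST_UNPLACED"),
                          no_hit_default = 1.0, ai_strong = 10,
                          ai_candidate = 0, min_support = NULL,
                          sister_fraction = 1.0) {
  stopifnot(all(c("gene", "contig") %in% names(genes)))
  orphan <- setdiff(unique(hits$query), genes$gene)
  if (length(orphan) > 0) {
    warning("screen_genome: skipping ", length(orphan),
            " hit queries absent from the gene table: ",
            paste(head(orphan, 3), collapse = ", "), call. = FALSE)
    hits <- hits[!hits$query %in% orphan, , drop = FALSE]
  }
  gene_group <- rep(NA_character_, nrow(genes))
  if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "group_assignment"))
    gi <- match(genes$contig, assignment$groups$contig)
    gene_group <- assignment$groups$group[gi]
    keep <- !is.na(gene_group) & gene_group %in% groups
    genes <- genes[keep, , drop = FALSE]
    gene_group <- gene_group[keep]
  }
  hits_by_gene <- split(hits, hits$query)
  get_tree <- function(g) {
    if (is.null(trees)) return(NULL)
    if (is.character(trees)) {
      f <- file.path(trees, paste0(g, ".nwk"))
      if (file.exists(f)) ape::read.tree(f) else NULL
    } else trees[[g]]
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene[i]
    r <- alien_index(hits_by_gene[[g]], partition, no_hit_default)
    r$gene <- g
    tr <- get_tree(g)
    r$clusters_with_bacteria <- if (is.null(tr)) NA else
      tree_bacterial_clustering(tr, g, min_support = min_support,
                                sister_fraction = sister_fraction)
    r$contig <- genes$contig[i]
    r$group <- gene_group[i]
    r
  })
  res <- do.call(rbind, rows)
  res$category <- classify_hgt(res$ai, res$clusters_with_bacteria,
                               ai_strong, ai_candidate)
  res$on_chromosome <- if (is.null(assignment)) NA else
    res$group == "HOST_CHROMOSOMAL"
  res <- res[, c("gene", "contig", "group", "on_chromosome", "bbh_in",
                 "bbh_out", "ai", "n_in", "n_out", "no_evidence",
                 "clusters_with_bacteria", "category")]
  summary <- data.frame(
    n_genes = nrow(res),
    n_ai_positive = sum(res$ai > ai_candidate),
    n_ai_positive_chromosomal = sum(res$ai > ai_candidate &
                                      res$on_chromosome %in% TRUE),
    n_strong = sum(res$category == "strong"),
    n_partial = sum(res$category == "partial"),
    n_weak = sum(res$category == "weak"),
    n_non_candidate = sum(res$category == "non-candidate"))
  out <- list(results = res, summary = summary)
  class(out) <- "hgt_screen"
  out
}

#' @export
print.hgt_screen <- function(x, ...) {
  cat("hgt_screen:", x$summary$n_genes, "genes;",
      x$summary$n_ai_positive, "with AI > 0 (",
      x$summary$n_strong, "strong /", x$summary$n_partial, "partial /",
      x$summary$n_weak, "weak )\n")
  invisible(x)
}
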