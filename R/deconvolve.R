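#' Parameters for the taxonomic hit vote
#'
#' A contig (or cluster) is called host or bacterial by a bit-score-weighted
#' vote over its alignment hits: hits above the E-value ceiling are
#' discarded, the rest are partitioned into host-matching, bacterial and
#' other by their lineage, and the class with the largest summed bit score
#' wins if its share of the total reaches `vote_fraction`.
#'
#' @param min_hit_evalue E-value ceiling for a hit to count (default 1e-5).
#' @param vote_fraction Minimum bit-score share of the winning class, in
#'   \[0.5, 1\]; at exactly 0.5 ties are broken deterministically
#'   (bacterial > host > none, with a warning).
#' @param host_pattern Fixed substring identifying host-matching lineages
#'   (default the simulator's host genus, `"Pyropia"`).
#' @param bacterial_superkingdoms Superkingdoms counted as bacterial.
#' @return A `tax_vote_params` object.
#' @export
tax_vote_params <- function(min_hit_evalue = 1e-5,
                            vote_fraction = 0.5,
                            host_pattern = "Pyropia",
                            bacterial_superkingdoms = c("Bacteria", "Archaea")) {
  if (!is.finite(min_hit_evalue) || min_hit_evalue <= 0)
    stop_config("tax_vote_params: 'min_hit_evalue' must be > 0")
  if (vote_fraction < 0.5 || vote_fraction > 1)
    stop_config("tax_vote_params: 'vote_fraction' must be in [0.5, 1]")
  out <- list(min_hit_evalue = min_hit_evalue,
              vote_fraction = vote_fraction,
              host_pattern = host_pattern,
              bacterial_superkingdoms = bacterial_superkingdoms)
  class(out) <- "tax_vote_params"
  out
}

# first lineage rank (superkingdom); errors name the offending record
lineage_superkingdom <- function(lineage, record = NULL) {
  bad <- is.na(lineage) | !nzchar(trimws(lineage))
  if (any(bad))
    stop("malformed lineage string for record: ",
         paste(head(record[bad] %||% which(bad), 3), collapse = ", "),
         call. = FALSE)
  vapply(strsplit(lineage, ";", fixed = TRUE),
         function(x) trimws(x[1]), "")
}

#' Taxonomic call for one contig from its alignment hits
#'
#' @param hits Data frame of hits already filtered to the contig, with
#'   columns `evalue`, `bitscore`, `lineage` (and optionally `query` /
#'   `subject` used in error messages).
#' @param params A [tax_vote_params()].
#' @return One of `"host"`, `"bacterial"`, `"none"`.
#' @export
assign_taxonomy <- function(hits, params = tax_vote_params()) {
  stopifnot(inherits(params, "tax_vote_params"))
  if (is.null(hits) || nrow(hits) == 0) return("none")
  hits <- hits[hits$evalue <= params$min_hit_evalue, , drop = FALSE]
  if (nrow(hits) == 0) return("none")
  sk <- lineage_superkingdom(hits$lineage, hits$query %||% hits$subject)
  cls <- rep("other", nrow(hits))
  cls[sk %in% params$bacterial_superkingdoms] <- "bacterial"
  cls[grepl(params$host_pattern, hits$lineage, fixed = TRUE)] <- "host"
  score <- c(host = 0, bacterial = 0, other = 0)
  agg <- tapply(hits$bitscore, cls, sum)
  score[names(agg)] <- agg
  total <- sum(score)
  if (total <= 0) return("none")
  top <- max(score)
  winners <- names(score)[score == top]
  if (length(winners) > 1) {
    # deterministic tie-break: bacterial > host > none
    winners <- intersect(c("bacterial", "host", "other"), winners)[1]
    warning("assign_taxonomy: bit-score tie broken toward '", winners, "'",
            call. = FALSE)
  }
  if (top / total < params$vote_fraction) return("none")
  if (winners == "other") return("none")
  winners
}

# map hit queries to contigs: either hits carry a contig column, queries are
# contig ids themselves, or a gene table provides the mapping
hits_with_contig <- function(hits, contigs, genes = NULL) {
  if (!is.null(hits$contig)) return(hits)
  hits$contig <- ifelse(hits$query %in% contigs, hits$query, NA_character_)
  if (anyNA(hits$contig)) {
    if (is.null(genes))
      stop_config("deconvolve: hit queries are not contig ids; supply 'genes' to map genes to contigs")
    mi <- match(hits$query, genes$gene)
    hits$contig[is.na(hits$contig)] <- genes$contig[mi[is.na(hits$contig)]]
    if (anyNA(hits$contig)) {
      drop <- unique(hits$query[is.na(hits$contig)])
      warning("deconvolve: dropping hits for ", length(drop),
              " queries absent from the gene table", call. = FALSE)
      hits <- hits[!is.na(hits$contig), , drop = FALSE]
    }
  }
  hits
}

#' Deconvolve an assembly into host, epiphyte, unplaced and unknown groups
#'
#' Clusters contigs on the normalized contact graph, calls a
#' bit-score-weighted taxonomy vote per cluster (pooling the hits of all
#' member contigs), and assigns every contig to one of four groups:
#'
#' * `HOST_CHROMOSOMAL` — member of a cluster whose vote is host;
#' * `EPIPHYTE_BIN` — member of a cluster whose vote is bacterial, or an
#'   unclustered contig with a bacterial call (kept as a singleton bin);
#' * `HOST_UNPLACED` — unclustered contig with a host call;
#' * `UNKNOWN` — everything else (no qualifying links and/or no taxonomic
#'   signal).
#'
#' @param m A `contact_matrix`; a raw matrix is length-product normalized
#'   first (requires stored lengths).
#' @param hits Alignment hit table with a `lineage` column; queries may be
#'   contig ids, or gene ids resolved through `genes`.
#' @param params A [tax_vote_params()].
#' @param genes Optional gene table (columns `gene`, `contig`) mapping hit
#'   queries to contigs.
#' @param k_max,min_link Passed to [cluster_contigs()].
#' @param min_count Raw-count floor on inter-contig links (see
#'   [filter_contact_matrix()]); applied only when `m` is raw.
#' @return A `group_assignment` object: list with `groups` (data.frame:
#'   `contig`, `group`, `cluster`, `taxonomy`), `clusters` (data.frame:
#'   `cluster`, `n`, `taxonomy`, `intra`, `inter`, `ratio`) and the
#'   clustering itself.
#' @export
deconvolve <- function(m, hits, params = tax_vote_params(), genes = NULL,
                       k_max = NULL, min_link = NULL, min_count = 2) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization == "raw")
    m <- normalize_matrix(filter_contact_matrix(m, min_count),
                          "length_product")
  clus <- cluster_contigs(m, k_max = k_max, min_link = min_link)
  hits <- hits_with_contig(hits, m$contigs, genes)
  hits_by_contig <- split(hits, hits$contig)

  contig_tax <- vapply(m$contigs, function(cg)
    assign_taxonomy(hits_by_contig[[cg]], params), "")

  groups <- data.frame(contig = m$contigs,
                       group = "UNKNOWN",
                       cluster = NA_character_,
                       taxonomy = unname(contig_tax),
                       stringsAsFactors = FALSE)
  rownames(groups) <- groups$contig

  cluster_rows <- list()
  for (cl in clus$clusters) {
    pooled <- do.call(rbind, hits_by_contig[intersect(cl$members,
                                                      names(hits_by_contig))])
    vote <- assign_taxonomy(pooled, params)
    grp <- switch(vote, host = "HOST_CHROMOSOMAL", bacterial = "EPIPHYTE_BIN",
                  NA_character_)
    if (!is.na(grp)) {
      groups[cl$members, "group"] <- grp
      groups[cl$members, "cluster"] <- cl$id
    } else {
      # no pooled taxonomic signal: fall back to per-contig calls
      tx <- groups[cl$members, "taxonomy"]
      groups[cl$members, "group"] <-
        ifelse(tx == "host", "HOST_UNPLACED",
               ifelse(tx == "bacterial", "EPIPHYTE_BIN", "UNKNOWN"))
      groups[cl$members[tx == "bacterial"], "cluster"] <- cl$id
    }
    cluster_rows[[cl$id]] <- data.frame(
      cluster = cl$id, n = length(cl$members), taxonomy = vote,
      intra = cl$intra, inter = cl$inter, ratio = cl$ratio,
      stringsAsFactors = FALSE)
  }

  # unclustered contigs: host -> unplaced, bacterial -> singleton bin
  uc <- clus$unclustered
  if (length(uc) > 0) {
    tx <- groups[uc, "taxonomy"]
    groups[uc, "group"] <- ifelse(tx == "host", "HOST_UNPLACED",
                                  ifelse(tx == "bacterial", "EPIPHYTE_BIN",
                                         "UNKNOWN"))
    singles <- uc[tx == "bacterial"]
    W <- (m$counts + t(m$counts)) / 2
    for (i in seq_along(singles)) {
      id <- sprintf("bin_s%02d", i)
      groups[singles[i], "cluster"] <- id
      mi <- match(singles[i], m$contigs)
      w <- cluster_weights(W, mi)
      cluster_rows[[id]] <- data.frame(
        cluster = id, n = 1L, taxonomy = "bacterial",
        intra = unname(w[["intra"]]), inter = unname(w[["inter"]]),
        ratio = intra_inter_ratio(unname(w[["intra"]]), unname(w[["inter"]])),
        stringsAsFactors = FALSE)
    }
  }

  clusters_df <- if (length(cluster_rows) > 0)
    do.call(rbind, cluster_rows) else
    data.frame(cluster = character(0), n = integer(0),
               taxonomy = character(0), intra = numeric(0),
               inter = numeric(0), ratio = numeric(0))
  rownames(groups) <- NULL
  rownames(clusters_df) <- NULL
  out <- list(groups = groups, clusters = clusters_df, clustering = clus,
              params = params)
  class(out) <- "group_assignment"
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:\n")
  print(table(factor(x$groups$group, levels = GROUP_LEVELS)))
  invisible(x)
}

#' Largest length L such that contigs >= L cover half the total
#'
#' @param lengths Numeric vector of contig lengths.
#' @return The N50 value.
#' @examples
#' n50(c(10, 9, 8, 7, 6))  # 8
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' GC fraction of a sequence set
#'
#' Counts G+C over A+C+G+T; N and other ambiguity codes are ignored.
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector.
#' @return GC fraction in \[0, 1\] (NaN for zero informative bases).
#' @export
gc_fraction <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  tot <- colSums(f)
  unname((tot[["G"]] + tot[["C"]]) / sum(tot))
}

#' Assembly statistics for one contig group
#'
#' @param seqs Named [Biostrings::DNAStringSet] of all contigs.
#' @param assignment Optional `group_assignment` (from [deconvolve()]); when
#'   supplied together with `group`, statistics are computed for that group
#'   only.
#' @param group Group label in
#'   `HOST_CHROMOSOMAL, EPIPHYTE_BIN, HOST_UNPLACED, UNKNOWN`.
#' @return Data frame with `group`, `n_contigs`, `total_length`,
#'   `gc_fraction` and `n50`.
#' @export
assembly_stats <- function(seqs, assignment = NULL, group = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  label <- "all"
  if (!is.null(assignment) && !is.null(group)) {
    stopifnot(inherits(assignment, "group_assignment"))
    keep <- assignment$groups$contig[assignment$groups$group == group]
    if (length(keep) == 0)
      stop("assembly_stats: group '", group, "' has no contigs",
           call. = FALSE)
    seqs <- seqs[intersect(names(seqs), keep)]
    label <- group
  }
  if (length(seqs) == 0)
    stop("assembly_stats: empty contig set", call. = FALSE)
  lens <- Biostrings::width(seqs)
  data.frame(group = label,
             n_contigs = length(seqs),
             total_length = sum(lens),
             gc_fraction = gc_fraction(seqs),
             n50 = n50(lens),
             stringsAsFactors = FALSE)
}

#' Screen for genes shared with external datasets by alignment coverage
#'
#' A gene counts as shared with a dataset when its aligned-length fraction
#' strictly exceeds the threshold ("more than 90% of their length" at the
#' default); coverage of exactly 0.90 is excluded.
#'
#' @param coverage Data frame with columns `gene`, `dataset`,
#'   `covered_fraction` (each in \[0, 1\]).
#' @param threshold Aligned-length fraction that must be exceeded
#'   (default 0.9).
#' @param min_datasets A gene is reported as shared when it passes the
#'   threshold in at least this many datasets.
#' @return Data frame with one row per gene: `gene`, `n_datasets` (datasets
#'   passing the threshold) and `shared` (`n_datasets >= min_datasets`).
#' @export
shared_sequence_screen <- function(coverage, threshold = 0.9,
                                   min_datasets = 1L) {
  stopifnot(all(c("gene", "dataset", "covered_fraction") %in% names(coverage)))
  cf <- coverage$covered_fraction
  if (any(!is.finite(cf)) || any(cf < 0) || any(cf > 1))
    stop("shared_sequence_screen: 'covered_fraction' must lie in [0, 1]",
         call. = FALSE)
  pass <- cf > threshold
  cnt <- tapply(pass, coverage$gene, sum)
  out <- data.frame(gene = names(cnt),
                    n_datasets = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out$shared <- out$n_datasets >= min_datasets
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}
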