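PAIRS_HEADER <- "#columns: readID chrom1 pos1 strand1 chrom2 pos2 strand2 mapq1 mapq2"
PAIRS_COLS <- c("read_id", "contig1", "pos1", "strand1",
                "contig2", "pos2", "strand2", "mapq1", "mapq2")

#' Write read pairs in the tab-separated pairs format
#'
#' Positions are 1-based 5' mapped coordinates; a `#columns:` header line
#' names the fields.
#'
#' @param pairs Pair data.frame (or a `hic_pairs` object).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  if (inherits(pairs, "hic_pairs")) pairs <- pairs$pairs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PAIRS_HEADER, con)
  write.table(pairs[, PAIRS_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pairs-format file
#'
#' @param path Path to a pairs TSV written by [write_pairs()].
#' @return Pair data.frame.
#' @export
read_pairs <- function(path) {
  out <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names(out) <- PAIRS_COLS[seq_len(ncol(out))]
  out
}

#' Write a hit table (BLAST outfmt-6-like TSV with a lineage column)
#' @param hits Hit data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hit table written by [write_hits()]
#' @param path Path to the TSV.
#' @return Hit data.frame.
#' @export
read_hits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a gene table as GFF3
#'
#' @param genes Gene data.frame (columns `gene`, `contig`, `start`, `end`,
#'   `strand`; 1-based closed intervals).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene table
#'
#' @param path Path to a GFF3 file of gene features.
#' @return Gene data.frame (columns `gene`, `contig`, `start`, `end`,
#'   `strand`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene = S4Vectors::mcols(gr)$ID,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a contact matrix as sparse TSV plus a contig index
#'
#' The matrix file holds the nonzero upper triangle (including the diagonal)
#' as three columns `contig_i`, `contig_j`, `value`; the index file holds
#' `contig`, `length` in matrix order.
#'
#' @param m A `contact_matrix`.
#' @param path Matrix TSV path.
#' @param index_path Contig index TSV path.
#' @return Invisibly, the two paths.
#' @export
write_contact_matrix <- function(m, path, index_path) {
  stopifnot(inherits(m, "contact_matrix"))
  ut <- upper.tri(m$counts, diag = TRUE) & m$counts != 0
  idx <- which(ut, arr.ind = TRUE)
  sparse <- data.frame(contig_i = m$contigs[idx[, 1]],
                       contig_j = m$contigs[idx[, 2]],
                       value = m$counts[ut], stringsAsFactors = FALSE)
  write.table(sparse, path, sep = "\t", quote = FALSE, row.names = FALSE)
  index <- data.frame(contig = m$contigs,
                      length = if (is.null(m$lengths)) NA else
                        as.numeric(m$lengths),
                      stringsAsFactors = FALSE)
  write.table(index, index_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = path, index = index_path))
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param path Matrix TSV path.
#' @param index_path Contig index TSV path.
#' @param normalization Normalization state of the stored values.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, index_path, normalization = "raw") {
  sparse <- read.delim(path, stringsAsFactors = FALSE)
  index <- read.delim(index_path, stringsAsFactors = FALSE)
  contigs <- index$contig
  n <- length(contigs)
  m <- matrix(0, n, n, dimnames = list(contigs, contigs))
  i <- match(sparse$contig_i, contigs)
  j <- match(sparse$contig_j, contigs)
  m[cbind(i, j)] <- sparse$value
  m[cbind(j, i)] <- sparse$value
  lengths <- if (all(is.na(index$length))) NULL else
    setNames(index$length, contigs)
  out <- list(counts = m, contigs = contigs, lengths = lengths,
              normalization = normalization)
  class(out) <- "contact_matrix"
  out
}

#' Write the per-contig group assignment as TSV
#' @param assignment A `group_assignment` from [deconvolve()].
#' @param path Groups TSV path.
#' @param clusters_path Optional clusters TSV path.
#' @return Invisibly, the paths written.
#' @export
write_groups <- function(assignment, path, clusters_path = NULL) {
  stopifnot(inherits(assignment, "group_assignment"))
  write.table(assignment$groups, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(clusters_path))
    write.table(assignment$clusters, clusters_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(c(groups = path, clusters = clusters_path))
}
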