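#' Compute a restriction-fragment map from contig sequences
#'
#' Cuts every contig at each occurrence of the enzyme recognition motif and
#' returns, per contig, the sorted fragment boundaries as 0-based half-open
#' coordinates: the first boundary is 0 and the last equals the contig
#' length, so the fragments tile the contig exactly.
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contigs, or a `hic_community`.
#' @param motif Enzyme recognition motif (default `"GATC"`).
#' @return A `restriction_map`: named list of integer boundary vectors.
#' @examples
#' rm <- restriction_map(Biostrings::DNAStringSet(c(c1 = "AAAGATCAAA")))
#' rm$c1  # 0, 3, 10
#' @export
restriction_map <- function(sequences, motif = "GATC") {
  if (inherits(sequences, "hic_community")) sequences <- sequences$sequences
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop_config("restriction_map: sequences must be named")
  hits <- Biostrings::vmatchPattern(motif, sequences)
  lens <- Biostrings::width(sequences)
  out <- lapply(seq_along(sequences), function(i) {
    cuts <- BiocGenerics::start(hits[[i]]) - 1L
    cuts <- cuts[cuts > 0L & cuts < lens[i]]
    unique(c(0L, sort(cuts), lens[i]))
  })
  names(out) <- names(sequences)
  class(out) <- "restriction_map"
  out
}

#' Build a uniform restriction map from contig lengths alone
#'
#' Convenience constructor when no sequence is at hand: fragments of a fixed
#' width tiling each contig.
#'
#' @param lengths Named integer vector of contig lengths.
#' @param width Fragment width in bases.
#' @return A `restriction_map`.
#' @export
uniform_restriction_map <- function(lengths, width = 500L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  out <- lapply(lengths, function(L)
    unique(c(seq(0L, L - 1L, by = as.integer(width)), as.integer(L))))
  class(out) <- "restriction_map"
  out
}

#' Read a restriction map from a BED file
#'
#' Expects standard BED (0-based half-open) fragments tiling each contig.
#'
#' @param path Path to a BED file with columns chrom, start, end.
#' @return A `restriction_map`.
#' @export
read_restriction_map_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  out <- lapply(split(bed, bed$chrom), function(d) {
    b <- sort(unique(c(d$start, d$end)))
    as.integer(b)
  })
  class(out) <- "restriction_map"
  out
}

# fragment index of positions (1-based) on contigs, per a restriction map;
# internally 0-based half-open with binary search on the boundary vector
fragment_index <- function(rmap, contig, pos) {
  f <- factor(contig, levels = names(rmap))
  if (anyNA(f)) {
    bad <- unique(contig[is.na(f)])
    stop("unknown contig in restriction map lookup: ",
         paste(head(bad, 3), collapse = ", "), call. = FALSE)
  }
  idx <- integer(length(contig))
  by_contig <- split(seq_along(contig), f)
  for (cg in names(by_contig)) {
    sel <- by_contig[[cg]]
    if (length(sel) > 0)
      idx[sel] <- findInterval(pos[sel] - 1L, rmap[[cg]])
  }
  idx
}

# canonical end ordering: lexicographic by contig id then position, so pair
# orientation never splits duplicates
canonicalize_pairs <- function(pairs) {
  swap <- (pairs$contig2 < pairs$contig1) |
    (pairs$contig2 == pairs$contig1 & pairs$pos2 < pairs$pos1)
  out <- pairs
  out$contig1[swap] <- pairs$contig2[swap]
  out$pos1[swap]    <- pairs$pos2[swap]
  out$strand1[swap] <- pairs$strand2[swap]
  out$contig2[swap] <- pairs$contig1[swap]
  out$pos2[swap]    <- pairs$pos1[swap]
  out$strand2[swap] <- pairs$strand1[swap]
  out
}

pair_keys <- function(pairs) {
  cp <- canonicalize_pairs(pairs)
  paste(cp$contig1, cp$pos1, cp$strand1, cp$contig2, cp$pos2, cp$strand2,
        sep = "\r")
}

#' Classify Hi-C read pairs as valid or artifact
#'
#' Assigns each read pair exactly one label by the first matching rule, in
#' this order:
#'
#' 1. `LOW_QUALITY` — `min(mapq1, mapq2) < min_mapq`;
#' 2. `DUPLICATE` — both 5' coordinates and strands identical to a
#'    previously seen pair (ends compared after canonical ordering, so
#'    orientation does not split duplicates);
#' 3. `SELF_LIGATION` — both ends in the same restriction fragment of the
#'    same contig, outward-facing (leftmost end on `-`, rightmost on `+`);
#' 4. `NON_LIGATION` — same fragment, inward-facing (`+` then `-`);
#' 5. `VALID` — otherwise.
#'
#' Self-ligation (circularised) and non-ligation (never-cut) molecules both
#' re-join the two ends of a single restriction fragment, so fragment
#' co-membership plus strand orientation identifies them.
#'
#' @param pairs Data frame with columns `contig1`, `pos1`, `strand1`,
#'   `contig2`, `pos2`, `strand2` and (optionally) `mapq1`, `mapq2`;
#'   positions are 1-based 5' mapped coordinates.
#' @param rmap A [restriction_map()] covering every contig referenced.
#' @param min_mapq Minimum mapping quality (default 20); pairs below are
#'   `LOW_QUALITY`. Missing mapq columns are treated as high quality.
#' @param check_orientation If `FALSE`, any same-fragment pair is labelled
#'   `SELF_LIGATION` regardless of strands (orientation check disabled).
#' @return Factor of labels, one per pair, with levels
#'   `LOW_QUALITY, DUPLICATE, SELF_LIGATION, NON_LIGATION, VALID`.
#' @export
classify_pairs <- function(pairs, rmap, min_mapq = 20L,
                           check_orientation = TRUE) {
  if (min_mapq < 0) stop_config("classify_pairs: 'min_mapq' must be >= 0")
  stopifnot(inherits(rmap, "restriction_map"))
  n <- nrow(pairs)
  if (n == 0)
    return(factor(character(0), levels = PAIR_CLASSES))
  cp <- canonicalize_pairs(pairs)
  keys <- paste(cp$contig1, cp$pos1, cp$strand1, cp$contig2, cp$pos2,
                cp$strand2, sep = "\r")
  dup <- duplicated(keys)
  f1 <- fragment_index(rmap, cp$contig1, cp$pos1)
  f2 <- fragment_index(rmap, cp$contig2, cp$pos2)
  same_frag <- cp$contig1 == cp$contig2 & f1 == f2
  outward <- cp$strand1 == "-" & cp$strand2 == "+"
  inward  <- cp$strand1 == "+" & cp$strand2 == "-"
  lab <- rep("VALID", n)
  if (check_orientation) {
    lab[same_frag & inward] <- "NON_LIGATION"
    lab[same_frag & outward] <- "SELF_LIGATION"
  } else {
    lab[same_frag] <- "SELF_LIGATION"
  }
  lab[dup] <- "DUPLICATE"
  mq1 <- pairs$mapq1 %||% rep(255L, n)
  mq2 <- pairs$mapq2 %||% rep(255L, n)
  lab[pmin(mq1, mq2) < min_mapq] <- "LOW_QUALITY"
  factor(lab, levels = PAIR_CLASSES)
}
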