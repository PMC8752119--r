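#' Build a contig-level contact matrix from classified read pairs
#'
#' Counts only `VALID` pairs. The matrix is symmetric: an inter-contig pair
#' contributes one contact to the (i, j) entry (stored in both mirror cells),
#' and an intra-contig pair increments the diagonal, so the sum of the upper
#' triangle plus the diagonal equals the number of valid pairs exactly.
#'
#' @param pairs Read-pair data.frame (see [classify_pairs()]).
#' @param classes Factor of pair classes aligned with `pairs`; when `NULL`
#'   every pair is treated as valid.
#' @param contigs Ordered character vector of contig ids fixing the matrix
#'   dimensions; pairs referencing absent contigs raise a lookup error.
#' @param lengths Optional named vector of contig lengths, stored for
#'   normalization.
#' @return A `contact_matrix`: list with `counts` (dense symmetric matrix),
#'   `contigs`, `lengths` and `normalization` (`"raw"`).
#' @export
build_contact_matrix <- function(pairs, classes = NULL, contigs,
                                 lengths = NULL) {
  n <- length(contigs)
  if (is.null(classes)) classes <- rep("VALID", nrow(pairs))
  keep <- as.character(classes) == "VALID"
  i <- match(pairs$contig1[keep], contigs)
  j <- match(pairs$contig2[keep], contigs)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(pairs$contig1[keep][is.na(i)],
                    pairs$contig2[keep][is.na(j)]))
    stop("build_contact_matrix: pair references absent contig: ",
         paste(head(bad, 3), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, n, n, dimnames = list(contigs, contigs))
  if (length(i) > 0) {
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    tab <- table(lo + (hi - 1) * n)
    idx <- as.integer(names(tab))
    lo <- ((idx - 1L) %% n) + 1L
    hi <- ((idx - 1L) %/% n) + 1L
    m[cbind(lo, hi)] <- as.numeric(tab)
    off <- lo != hi
    m[cbind(hi[off], lo[off])] <- as.numeric(tab)[off]
  }
  if (!is.null(lengths)) lengths <- lengths[contigs]
  out <- list(counts = m, contigs = contigs, lengths = lengths,
              normalization = "raw")
  class(out) <- "contact_matrix"
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", length(x$contigs), "contigs,",
      sum(x$counts[upper.tri(x$counts, diag = TRUE)]), "total (upper+diag),",
      "normalization:", x$normalization, "\n")
  invisible(x)
}

#' Drop weakly supported inter-contig links from a raw contact matrix
#'
#' Zeroes off-diagonal entries supported by fewer than `min_count` valid
#' pairs. Spurious cross-genome ligation produces many single-pair links
#' whose length-normalized weight can be large when both contigs are short;
#' requiring at least two supporting pairs removes most of them while
#' genuine same-genome links keep their multi-pair support.
#'
#' @param m A raw `contact_matrix`.
#' @param min_count Minimum valid-pair support of an off-diagonal entry
#'   (default 2).
#' @return A raw `contact_matrix` with filtered counts.
#' @export
filter_contact_matrix <- function(m, min_count = 2) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization != "raw")
    stop("filter_contact_matrix: expects a raw matrix", call. = FALSE)
  out <- m
  drop <- out$counts < min_count
  diag(drop) <- FALSE
  out$counts[drop] <- 0
  out
}

#' Normalize a raw contact matrix
#'
#' `length_product` scales each entry by the product of the two contig
#' lengths, `counts(i, j) * 1e6 / (L_i * L_j)`, removing the quadratic
#' dependence of expected contact counts on contig size (and preserving
#' symmetry). `row_sum` divides each row by its raw row total (zero rows
#' stay zero), which is not symmetric in general.
#'
#' @param m A raw `contact_matrix`.
#' @param method `"length_product"` or `"row_sum"`.
#' @param lengths Named contig lengths; taken from the matrix when `NULL`.
#' @return A new `contact_matrix` with updated `normalization`; the input
#'   (raw) matrix is unchanged.
#' @export
normalize_matrix <- function(m, method = c("length_product", "row_sum"),
                             lengths = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  method <- match.arg(method)
  if (m$normalization != "raw")
    stop("normalize_matrix: matrix is already normalized (",
         m$normalization, ")", call. = FALSE)
  out <- m
  if (method == "length_product") {
    lengths <- lengths %||% m$lengths
    if (is.null(lengths))
      stop_config("normalize_matrix: contig lengths required for length_product")
    L <- as.numeric(lengths[m$contigs])
    if (anyNA(L) || any(L <= 0))
      stop_config("normalize_matrix: lengths must be positive for all contigs")
    out$counts <- m$counts * 1e6 / outer(L, L)
  } else {
    rs <- rowSums(m$counts)
    rs[rs == 0] <- 1
    out$counts <- m$counts / rs
  }
  out$normalization <- method
  out
}
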