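#' Intra/inter contact weight ratio of a cluster
#'
#' The grouping criterion: source-genome clusters show strong contacts
#' within and minor contacts to the rest of the assembly.
#'
#' @param cluster A `contig_cluster` (list with `intra` and `inter`), or a
#'   numeric intra weight.
#' @param inter Inter weight when `cluster` is numeric.
#' @return `intra / inter`; `Inf` when `inter == 0` and `intra > 0`; 0 when
#'   `intra == 0`.
#' @examples
#' intra_inter_ratio(10, 2)  # 5
#' intra_inter_ratio(3, 0)   # Inf
#' intra_inter_ratio(0, 0)   # 0
#' @export
intra_inter_ratio <- function(cluster, inter = NULL) {
  if (is.list(cluster)) {
    intra <- cluster$intra
    inter <- cluster$inter
  } else {
    intra <- cluster
  }
  if (intra == 0) return(0)
  if (inter == 0) return(Inf)
  intra / inter
}

# intra (within-member contacts, upper triangle incl. diagonal) and inter
# (member to non-member contacts, counted once) weights for one member set
cluster_weights <- function(W, members_idx) {
  sub <- W[members_idx, members_idx, drop = FALSE]
  intra <- (sum(sub) + sum(diag(sub))) / 2
  inter <- sum(W[members_idx, -members_idx, drop = FALSE])
  c(intra = intra, inter = inter)
}

#' Cluster contigs on the normalized contact graph
#'
#' Contigs with no off-diagonal contact of at least `min_link` are left
#' unclustered. The remaining contigs are first split into connected
#' components of the thresholded contact graph (contigs never join across a
#' sub-threshold gap), then each component is refined by average-linkage
#' agglomerative clustering on the similarity `log1p(normalized contact)`:
#' the cut is chosen among 1..`k_max` clusters to maximize the mean
#' per-cluster intra/inter weight ratio, ties broken toward fewer clusters.
#' The result is deterministic given its input.
#'
#' @param m A normalized `contact_matrix` (see [normalize_matrix()]).
#' @param k_max Maximum number of clusters evaluated per component (default:
#'   number of contigs).
#' @param min_link Minimum normalized contact for a qualifying link. The
#'   default thresholds at the widest log-scale gap separating a weak,
#'   low-total-weight noise mode from the genuine links; when no such gap
#'   exists, all nonzero links qualify.
#' @return A `contig_clusters` object: list with `clusters` (list of
#'   `contig_cluster`s, each with `id`, `members`, `intra`, `inter`,
#'   `ratio`), `unclustered` (contig ids) and `min_link`.
#' @export
cluster_contigs <- function(m, k_max = NULL, min_link = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization == "raw")
    stop_config("cluster_contigs: matrix must be normalized first")
  n <- length(m$contigs)
  empty <- list(clusters = list(), unclustered = character(0),
                min_link = min_link %||% NA_real_)
  class(empty) <- "contig_clusters"
  if (n == 0) return(empty)
  k_max <- k_max %||% n
  if (k_max < 1) stop_config("cluster_contigs: 'k_max' must be >= 1")
  W <- (m$counts + t(m$counts)) / 2  # row_sum normalization is asymmetric
  off <- W
  diag(off) <- 0
  if (is.null(min_link)) {
    nz <- off[upper.tri(off)]
    nz <- sort(nz[nz > 0])
    if (length(nz) == 0) {
      min_link <- Inf
    } else if (length(nz) == 1) {
      min_link <- nz
    } else {
      # spurious cross-genome links are numerous but weak: they sit well
      # below the same-genome links (a wide gap on the log scale) and carry
      # only a small share of the total link weight. Threshold at the widest
      # such gap; with no qualifying gap there is no detectable noise mode
      # and every nonzero link is kept.
      gaps <- diff(log(nz))
      weight_below <- cumsum(nz)[-length(nz)] / sum(nz)
      cand <- which(gaps > log(5) & weight_below < 0.25)
      min_link <- if (length(cand) > 0) {
        i <- cand[which.max(gaps[cand])]
        exp((log(nz[i]) + log(nz[i + 1])) / 2)
      } else min(nz)
    }
  }
  linked <- apply(off >= min_link, 1, any)
  unclustered <- m$contigs[!linked]
  if (!any(linked)) {
    empty$unclustered <- unclustered
    empty$min_link <- min_link
    return(empty)
  }
  eligible <- which(linked)
  adj <- off[eligible, eligible, drop = FALSE] >= min_link
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  membership <- integer(n)  # 0 = unclustered
  next_id <- 0L
  for (cc in seq_len(max(comp))) {
    ix <- eligible[comp == cc]
    if (length(ix) == 1L) {
      next_id <- next_id + 1L
      membership[ix] <- next_id
      next
    }
    S <- log1p(W[ix, ix, drop = FALSE])
    d <- as.dist(max(S) - S)
    hc <- hclust(d, method = "average")
    best_k <- 1L
    best_ratio <- -Inf
    for (k in seq_len(min(k_max, length(ix)))) {
      part <- cutree(hc, k = k)
      # within-component ratios use the full matrix: inter includes
      # contacts to other components
      r <- mean(vapply(split(ix, part), function(mm) {
        w <- cluster_weights(W, mm)
        intra_inter_ratio(w[["intra"]], w[["inter"]])
      }, 0))
      if (r > best_ratio) {
        best_ratio <- r
        best_k <- k
      }
    }
    part <- cutree(hc, k = best_k)
    membership[ix] <- next_id + part
    next_id <- next_id + best_k
  }

  clusters <- lapply(sort(unique(membership[membership > 0])), function(cl) {
    mm <- which(membership == cl)
    w <- cluster_weights(W, mm)
    structure(list(id = NA_character_, members = m$contigs[mm],
                   intra = unname(w[["intra"]]), inter = unname(w[["inter"]]),
                   ratio = intra_inter_ratio(unname(w[["intra"]]),
                                             unname(w[["inter"]]))),
              class = "contig_cluster")
  })
  # stable ids: largest clusters first
  ord <- order(-vapply(clusters, function(cl) length(cl$members), 0L),
               vapply(clusters, function(cl) cl$members[1], ""))
  clusters <- clusters[ord]
  for (i in seq_along(clusters))
    clusters[[i]]$id <- sprintf("cluster%02d", i)
  out <- list(clusters = clusters, unclustered = unclustered,
              min_link = min_link)
  class(out) <- "contig_clusters"
  out
}

#' @export
print.contig_clusters <- function(x, ...) {
  cat("contig_clusters:", length(x$clusters), "clusters,",
      length(x$unclustered), "unclustered (min_link =",
      signif(x$min_link, 4), ")\n")
  invisible(x)
}

#' Cluster membership as a data frame
#'
#' @param clusters A `contig_clusters` object.
#' @return Data frame with columns `contig` and `cluster` (`NA` for
#'   unclustered contigs).
#' @export
cluster_membership <- function(clusters) {
  stopifnot(inherits(clusters, "contig_clusters"))
  rows <- lapply(clusters$clusters, function(cl)
    data.frame(contig = cl$members, cluster = cl$id,
               stringsAsFactors = FALSE))
  rows <- c(rows, list(data.frame(contig = clusters$unclustered,
                                  cluster = rep(NA_character_,
                                                length(clusters$unclustered)),
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
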