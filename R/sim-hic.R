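#' Specify a Hi-C proximity-ligation model
#'
#' Parameterises the pair simulator. A valid pair is intra-contig with
#' probability `1 - alpha - epsilon`, joins two contigs of the same genome
#' with probability `alpha`, and joins two contigs of different genomes
#' (spurious cross-genome ligation) with probability `epsilon`. Within-contig
#' contact distances decay exponentially with scale `intra_contig_decay`
#' beyond the sheared insert size. Signal must dominate noise:
#' `epsilon < alpha` is enforced.
#'
#' @param n_pairs Number of valid pairs to emit.
#' @param intra_contig_decay Distance scale (bases) of the exponential
#'   within-contig contact decay.
#' @param alpha Probability mass of intra-genome, inter-contig pairs.
#' @param epsilon Probability mass of spurious cross-genome pairs.
#' @param insert_size_mean Sheared insert size in bases (default 400),
#'   the minimum within-contig pair separation.
#' @param invalid_fractions Named fractions (of `n_pairs`) of injected
#'   artifact pairs: `self_ligation`, `non_ligation`, `duplicate`,
#'   `low_quality`.
#' @return A `hic_model` object.
#' @export
hic_model <- function(n_pairs = 100000,
                      intra_contig_decay = 15000,
                      alpha = 0.50,
                      epsilon = 0.01,
                      insert_size_mean = 400,
                      invalid_fractions = c(self_ligation = 0.03,
                                            non_ligation = 0.03,
                                            duplicate = 0.02,
                                            low_quality = 0.02)) {
  model <- list(n_pairs = as.integer(n_pairs),
                intra_contig_decay = as.numeric(intra_contig_decay),
                alpha = as.numeric(alpha),
                epsilon = as.numeric(epsilon),
                insert_size_mean = as.numeric(insert_size_mean),
                invalid_fractions = unlist(invalid_fractions))
  if (model$n_pairs < 1)
    stop_config("invalid hic model: 'n_pairs' must be >= 1")
  if (model$intra_contig_decay <= 0)
    stop_config("invalid hic model: 'intra_contig_decay' must be positive")
  if (model$alpha < 0 || model$epsilon < 0 || model$alpha + model$epsilon >= 1)
    stop_config("invalid hic model: need alpha, epsilon >= 0 and alpha + epsilon < 1")
  if (model$epsilon >= model$alpha)
    stop_config("invalid hic model: 'epsilon' must be < 'alpha' (signal would not dominate noise)")
  wanted <- c("self_ligation", "non_ligation", "duplicate", "low_quality")
  miss <- setdiff(wanted, names(model$invalid_fractions))
  model$invalid_fractions[miss] <- 0
  model$invalid_fractions <- model$invalid_fractions[wanted]
  if (any(model$invalid_fractions < 0) || any(model$invalid_fractions > 1) ||
      sum(model$invalid_fractions) >= 1)
    stop_config("invalid hic model: 'invalid_fractions' must lie in [0,1] and sum to < 1")
  class(model) <- "hic_model"
  model
}

# sample n (contig, position) draws weighted by contig length
sample_positions <- function(ids, lens, n) {
  ci <- sample.int(length(ids), n, replace = TRUE, prob = lens)
  pos <- 1L + floor(runif(n) * lens[ci])
  list(contig = ids[ci], pos = as.integer(pos))
}

#' Simulate Hi-C read pairs over a community
#'
#' Emits `n_pairs` valid proximity-ligation pairs whose category
#' (intra-contig / intra-genome / cross-genome) is drawn independently per
#' pair, so the realised fraction of cross-genome pairs among inter-contig
#' pairs is binomial with mean `epsilon / (alpha + epsilon)`. Artifact pairs
#' (self-ligation, non-ligation, duplicates, low-quality) are appended per
#' `invalid_fractions` and bookkept in an injection ledger so that the
#' classifier can be audited exactly: valid same-fragment pairs are emitted
#' in tandem orientation and all coordinate keys are kept unique except for
#' the intended duplicates.
#'
#' Only `linked` contigs of the community participate; unplaced and unknown
#' contigs receive no pairs.
#'
#' @param community A `hic_community`.
#' @param model A [hic_model()].
#' @param seed Integer seed; output is identical across runs for a fixed
#'   seed.
#' @param rmap Optional [restriction_map()]; computed from the community
#'   sequences with the default GATC motif when `NULL`.
#' @return A `hic_pairs` object: list with `pairs` (data.frame: `read_id`,
#'   `contig1`, `pos1`, `strand1`, `contig2`, `pos2`, `strand2`, `mapq1`,
#'   `mapq2`), `ledger` (named injection counts per class) and `rmap`.
#' @export
simulate_hic_pairs <- function(community, model, seed, rmap = NULL) {
  stopifnot(inherits(community, "hic_community"), inherits(model, "hic_model"))
  truth <- community$truth[community$truth$linked, , drop = FALSE]
  if (nrow(truth) == 0)
    stop_config("simulate_hic_pairs: community has no linked contigs")
  if (is.null(rmap))
    rmap <- restriction_map(community$sequences[truth$contig])
  set.seed(as.integer(seed))
  ids <- truth$contig
  lens <- setNames(truth$length, ids)
  genome <- setNames(truth$genome, ids)
  n <- model$n_pairs
  p_ic <- 1 - model$alpha - model$epsilon

  multi_genomes <- names(which(table(genome) >= 2))
  n_genomes <- length(unique(genome))
  cat <- sample(c("IC", "IG", "XG"), n, replace = TRUE,
                prob = c(p_ic, model$alpha, model$epsilon))
  # degenerate communities: reassign draws that cannot be realised
  if (length(multi_genomes) == 0) cat[cat == "IG"] <- "IC"
  if (n_genomes < 2) cat[cat == "XG"] <- "IC"

  contig1 <- character(n); pos1 <- integer(n)
  contig2 <- character(n); pos2 <- integer(n)

  ic <- which(cat == "IC")
  if (length(ic) > 0) {
    ci <- sample.int(length(ids), length(ic), replace = TRUE, prob = lens)
    L <- lens[ci]
    p1 <- 1L + floor(runif(length(ic)) * pmax(L - 50L, 1L))
    d <- round(model$insert_size_mean +
                 rexp(length(ic), rate = 1 / model$intra_contig_decay))
    p2 <- pmin(p1 + pmax(d, 1L), L)
    contig1[ic] <- ids[ci]; pos1[ic] <- as.integer(p1)
    contig2[ic] <- ids[ci]; pos2[ic] <- as.integer(p2)
  }

  ig <- which(cat == "IG")
  if (length(ig) > 0) {
    glen <- vapply(multi_genomes, function(g) sum(lens[genome == g]), 0)
    gdraw <- sample(multi_genomes, length(ig), replace = TRUE, prob = glen)
    for (g in unique(gdraw)) {
      sel <- ig[gdraw == g]
      gids <- ids[genome == g]
      glens <- lens[gids]
      e1 <- sample_positions(gids, glens, length(sel))
      e2 <- sample_positions(gids, glens, length(sel))
      while (any(bad <- e1$contig == e2$contig)) {
        r <- sample_positions(gids, glens, sum(bad))
        e2$contig[bad] <- r$contig; e2$pos[bad] <- r$pos
      }
      contig1[sel] <- e1$contig; pos1[sel] <- e1$pos
      contig2[sel] <- e2$contig; pos2[sel] <- e2$pos
    }
  }

  xg <- which(cat == "XG")
  if (length(xg) > 0) {
    e1 <- sample_positions(ids, lens, length(xg))
    e2 <- sample_positions(ids, lens, length(xg))
    while (any(bad <- genome[e1$contig] == genome[e2$contig])) {
      r <- sample_positions(ids, lens, sum(bad))
      e2$contig[bad] <- r$contig; e2$pos[bad] <- r$pos
    }
    contig1[xg] <- e1$contig; pos1[xg] <- e1$pos
    contig2[xg] <- e2$contig; pos2[xg] <- e2$pos
  }

  strand1 <- sample(c("+", "-"), n, replace = TRUE)
  strand2 <- sample(c("+", "-"), n, replace = TRUE)
  valid <- data.frame(contig1 = contig1, pos1 = pos1, strand1 = strand1,
                      contig2 = contig2, pos2 = pos2, strand2 = strand2,
                      stringsAsFactors = FALSE)
  # same-fragment valid pairs are emitted in tandem orientation so they are
  # never mistaken for ligation artifacts
  same <- valid$contig1 == valid$contig2 &
    fragment_index(rmap, valid$contig1, valid$pos1) ==
    fragment_index(rmap, valid$contig2, valid$pos2)
  valid$strand1[same] <- "+"
  valid$strand2[same] <- "+"
  # keep coordinate keys unique (chance collisions would read as duplicates)
  for (it in 1:100) {
    dup <- duplicated(pair_keys(valid))
    if (!any(dup)) break
    valid$pos2[dup] <- as.integer((valid$pos2[dup] %% lens[valid$contig2[dup]]) + 1L)
    same_d <- dup & valid$contig1 == valid$contig2 &
      fragment_index(rmap, valid$contig1, valid$pos1) ==
      fragment_index(rmap, valid$contig2, valid$pos2)
    valid$strand1[same_d] <- "+"
    valid$strand2[same_d] <- "+"
  }

  frac <- model$invalid_fractions
  n_self <- round(frac[["self_ligation"]] * n)
  n_non  <- round(frac[["non_ligation"]] * n)
  n_dup  <- min(round(frac[["duplicate"]] * n), n)
  n_lq   <- round(frac[["low_quality"]] * n)

  # global fragment table for drawing artifact pairs inside one fragment
  ftab <- do.call(rbind, lapply(ids, function(cg) {
    b <- rmap[[cg]]
    data.frame(contig = cg, start = b[-length(b)], width = diff(b),
               stringsAsFactors = FALSE)
  }))
  frag_pair <- function(k, s1, s2) {
    if (k == 0) return(NULL)
    fi <- sample.int(nrow(ftab), k, replace = TRUE, prob = ftab$width)
    a <- ftab$start[fi] + 1L + floor(runif(k) * ftab$width[fi])
    b <- ftab$start[fi] + 1L + floor(runif(k) * ftab$width[fi])
    data.frame(contig1 = ftab$contig[fi], pos1 = as.integer(pmin(a, b)),
               strand1 = s1,
               contig2 = ftab$contig[fi], pos2 = as.integer(pmax(a, b)),
               strand2 = s2, stringsAsFactors = FALSE)
  }
  self <- frag_pair(n_self, "-", "+")
  non  <- frag_pair(n_non, "+", "-")
  lq <- NULL
  if (n_lq > 0) {
    e1 <- sample_positions(ids, lens, n_lq)
    e2 <- sample_positions(ids, lens, n_lq)
    lq <- data.frame(contig1 = e1$contig, pos1 = e1$pos,
                     strand1 = sample(c("+", "-"), n_lq, TRUE),
                     contig2 = e2$contig, pos2 = e2$pos,
                     strand2 = sample(c("+", "-"), n_lq, TRUE),
                     stringsAsFactors = FALSE)
  }
  dup <- if (n_dup > 0) valid[sample.int(n, n_dup), , drop = FALSE] else NULL

  # injected artifacts must not collide with any other key, or they would be
  # classified as duplicates and break the injection ledger; clashing rows
  # are redrawn from their own class so labels are preserved
  pairs <- rbind(valid, self, non, lq)
  type <- rep(c("V", "S", "N", "L"), c(n, n_self, n_non, n_lq))
  for (it in 1:100) {
    clash <- duplicated(pair_keys(pairs))
    clash[type == "V"] <- FALSE
    if (!any(clash)) break
    for (i in which(clash)) {
      row <- switch(type[i],
        S = frag_pair(1L, "-", "+"),
        N = frag_pair(1L, "+", "-"),
        L = {
          e1 <- sample_positions(ids, lens, 1L)
          e2 <- sample_positions(ids, lens, 1L)
          data.frame(contig1 = e1$contig, pos1 = e1$pos,
                     strand1 = sample(c("+", "-"), 1L),
                     contig2 = e2$contig, pos2 = e2$pos,
                     strand2 = sample(c("+", "-"), 1L),
                     stringsAsFactors = FALSE)
        })
      pairs[i, names(row)] <- row
    }
  }
  pairs <- rbind(pairs, dup)
  pairs$mapq1 <- 60L
  pairs$mapq2 <- 60L
  if (n_lq > 0) pairs$mapq1[n + n_self + n_non + seq_len(n_lq)] <- 5L
  pairs$read_id <- sprintf("P%07d", seq_len(nrow(pairs)))
  pairs <- pairs[, c("read_id", "contig1", "pos1", "strand1",
                     "contig2", "pos2", "strand2", "mapq1", "mapq2")]
  rownames(pairs) <- NULL
  ledger <- c(VALID = n, SELF_LIGATION = n_self, NON_LIGATION = n_non,
              LOW_QUALITY = n_lq, DUPLICATE = n_dup)
  out <- list(pairs = pairs, ledger = ledger, rmap = rmap)
  class(out) <- "hic_pairs"
  out
}

#' @export
print.hic_pairs <- function(x, ...) {
  cat("hic_pairs:", nrow(x$pairs), "read pairs; injection ledger:\n")
  print(x$ledger)
  invisible(x)
}
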