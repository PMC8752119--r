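#' Specify a synthetic host + epiphyte community
#'
#' Defines the composition of a simulated community: one multi-chromosome
#' eukaryotic host plus several epiphytic bacterial genomes, each fragmented
#' into contigs, together with a set of short unplaced host contigs and a set
#' of "unknown" contigs that carry no taxonomic signal. The defaults emulate
#' the study conditions the deconvolution is designed for: five host
#' chromosomes and ten bacterial genomes, with a GC-rich host (0.70) against
#' AT-richer bacteria (0.45).
#'
#' @param host_chromosomes Number of host chromosomes.
#' @param host_chrom_length Length of each host chromosome in bases.
#' @param n_bacteria Number of epiphytic bacterial genomes.
#' @param bacterial_genome_length Length of each bacterial genome in bases.
#' @param contig_length_mean,contig_length_sd Mean and standard deviation of
#'   the contig lengths each genome is fragmented into (bases).
#' @param host_gc,bacterial_gc GC fraction of host and bacterial genomes,
#'   each in (0, 1).
#' @param unknown_fraction Fraction of emitted contigs that carry no
#'   taxonomic signal (no alignment hits) and no Hi-C linkage, in \[0, 1).
#' @param n_host_unplaced Number of short host contigs emitted without Hi-C
#'   linkage (emulating low-coverage unplaced contigs).
#' @param unplaced_length Mean length of unplaced host contigs (bases).
#' @param unknown_length Mean length of unknown contigs (bases).
#' @param unknown_gc GC fraction of unknown contigs.
#' @return A `community_spec` object (a validated list).
#' @examples
#' spec <- community_spec(host_chromosomes = 1, n_bacteria = 2)
#' @export
community_spec <- function(host_chromosomes = 5,
                           host_chrom_length = 200000,
                           n_bacteria = 10,
                           bacterial_genome_length = 100000,
                           contig_length_mean = 20000,
                           contig_length_sd = 5000,
                           host_gc = 0.70,
                           bacterial_gc = 0.45,
                           unknown_fraction = 0.10,
                           n_host_unplaced = 4,
                           unplaced_length = 5000,
                           unknown_length = 8000,
                           unknown_gc = 0.55) {
  spec <- list(host_chromosomes = as.integer(host_chromosomes),
               host_chrom_length = as.integer(host_chrom_length),
               n_bacteria = as.integer(n_bacteria),
               bacterial_genome_length = as.integer(bacterial_genome_length),
               contig_length_mean = as.numeric(contig_length_mean),
               contig_length_sd = as.numeric(contig_length_sd),
               host_gc = as.numeric(host_gc),
               bacterial_gc = as.numeric(bacterial_gc),
               unknown_fraction = as.numeric(unknown_fraction),
               n_host_unplaced = as.integer(n_host_unplaced),
               unplaced_length = as.integer(unplaced_length),
               unknown_length = as.integer(unknown_length),
               unknown_gc = as.numeric(unknown_gc))
  for (f in c("host_chrom_length", "bacterial_genome_length",
              "contig_length_mean", "unplaced_length", "unknown_length")) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
      stop_config("invalid community spec: '", f, "' must be positive")
  }
  for (f in c("host_chromosomes", "n_bacteria", "n_host_unplaced")) {
    if (is.na(spec[[f]]) || spec[[f]] < 0)
      stop_config("invalid community spec: '", f, "' must be >= 0")
  }
  if (spec$host_chromosomes + spec$n_bacteria < 1)
    stop_config("invalid community spec: 'host_chromosomes' + 'n_bacteria' must be >= 1")
  if (spec$contig_length_sd < 0)
    stop_config("invalid community spec: 'contig_length_sd' must be >= 0")
  genome_lengths <- c(if (spec$host_chromosomes > 0) spec$host_chrom_length,
                      if (spec$n_bacteria > 0) spec$bacterial_genome_length)
  if (spec$contig_length_mean > min(genome_lengths))
    stop_config("invalid community spec: 'contig_length_mean' exceeds a genome length")
  for (f in c("host_gc", "bacterial_gc", "unknown_gc")) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0 || spec[[f]] >= 1)
      stop_config("invalid community spec: '", f, "' must be in (0, 1)")
  }
  if (spec$unknown_fraction < 0 || spec$unknown_fraction >= 1)
    stop_config("invalid community spec: 'unknown_fraction' must be in [0, 1)")
  class(spec) <- "community_spec"
  spec
}

#' @export
print.community_spec <- function(x, ...) {
  cat("community_spec:",
      x$host_chromosomes, "host chromosomes x", x$host_chrom_length, "bp;",
      x$n_bacteria, "bacteria x", x$bacterial_genome_length, "bp;",
      "contigs ~N(", x$contig_length_mean, ",", x$contig_length_sd, ")\n")
  invisible(x)
}

# random DNA of length n at a target GC fraction
random_dna <- function(n, gc) {
  intToUtf8(utf8ToInt("ATGC")[sample.int(4L, n, replace = TRUE,
    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))])
}

# split a genome of length L into contiguous non-overlapping contig lengths
# covering L exactly
fragment_genome <- function(L, mean_len, sd_len, min_len = 1000) {
  if (mean_len >= L) return(L)
  lens <- integer(0)
  rem <- L
  while (rem > 1.5 * mean_len) {
    l <- round(rnorm(1, mean_len, sd_len))
    l <- max(min(l, rem - min_len), min_len)
    lens <- c(lens, l)
    rem <- rem - l
  }
  c(lens, rem)
}

#' Simulate a host + epiphyte community with planted truth
#'
#' Generates contig sequences for every genome in the spec, fragmenting each
#' host chromosome and bacterial genome into contiguous non-overlapping
#' contigs that cover its full length, and emits the planted truth table
#' (source genome, role, and whether the contig participates in proximity
#' ligation). Unplaced host contigs and unknown contigs are emitted as
#' unlinked: they receive no Hi-C pairs, emulating contigs whose coverage is
#' too low to cluster.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed; the simulation is byte-identical for a fixed
#'   seed and spec.
#' @return A `hic_community` object: list with `sequences` (a named
#'   [Biostrings::DNAStringSet]), `truth` (data.frame with columns `contig`,
#'   `genome`, `role` in host/bacterial/unknown, `linked`, `length`) and
#'   `spec`.
#' @examples
#' comm <- simulate_community(community_spec(host_chromosomes = 1,
#'   host_chrom_length = 20000, n_bacteria = 1,
#'   bacterial_genome_length = 20000, contig_length_mean = 10000,
#'   n_host_unplaced = 1), seed = 1)
#' comm$truth
#' @export
simulate_community <- function(spec, seed) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(as.integer(seed))
  seqs <- character(0)
  truth <- list()
  add_genome <- function(genome, L, gc, role, linked, fragment = TRUE) {
    lens <- if (fragment) fragment_genome(L, spec$contig_length_mean,
                                          spec$contig_length_sd) else L
    full <- random_dna(sum(lens), gc)
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    ids <- if (length(lens) == 1L) genome else
      sprintf("%s_c%02d", genome, seq_along(lens))
    seqs[ids] <<- substring(full, starts, ends)
    truth[[length(truth) + 1L]] <<- data.frame(
      contig = ids, genome = genome, role = role, linked = linked,
      length = lens, stringsAsFactors = FALSE)
  }
  if (spec$host_chromosomes > 0) {
    for (i in seq_len(spec$host_chromosomes))
      add_genome(sprintf("hostchr%d", i), spec$host_chrom_length,
                 spec$host_gc, "host", TRUE)
  }
  if (spec$n_bacteria > 0) {
    for (i in seq_len(spec$n_bacteria))
      add_genome(sprintf("bact%02d", i), spec$bacterial_genome_length,
                 spec$bacterial_gc, "bacterial", TRUE)
  }
  if (spec$n_host_unplaced > 0) {
    for (i in seq_len(spec$n_host_unplaced)) {
      L <- max(1500L, round(rnorm(1, spec$unplaced_length,
                                  spec$unplaced_length / 5)))
      add_genome(sprintf("hostup%02d", i), L, spec$host_gc, "host",
                 FALSE, fragment = FALSE)
    }
  }
  n_main <- sum(vapply(truth, nrow, 1L))
  n_unknown <- round(spec$unknown_fraction * n_main / (1 - spec$unknown_fraction))
  if (n_unknown > 0) {
    for (i in seq_len(n_unknown)) {
      L <- max(1500L, round(rnorm(1, spec$unknown_length,
                                  spec$unknown_length / 8)))
      add_genome(sprintf("unknown%02d", i), L, spec$unknown_gc, "unknown",
                 FALSE, fragment = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(sequences = Biostrings::DNAStringSet(seqs),
              truth = truth, spec = spec)
  class(out) <- "hic_community"
  out
}

#' @export
print.hic_community <- function(x, ...) {
  cat("hic_community:", nrow(x$truth), "contigs from",
      length(unique(x$truth$genome)), "genomes (",
      sum(x$truth$role == "host"), "host /",
      sum(x$truth$role == "bacterial"), "bacterial /",
      sum(x$truth$role == "unknown"), "unknown )\n")
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Writes contigs as FASTA (80-character lines) and the planted truth table
#' as TSV.
#'
#' @param community A `hic_community`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "hic_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  tt <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(community$sequences, fa, width = 80L)
  write.table(community$truth, tt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, truth = tt))
}

#' Read a community spec (and optional Hi-C model) from a YAML config
#'
#' The YAML file may contain top-level keys `community` and `hic`, whose
#' entries are passed to [community_spec()] and [hic_model()].
#'
#' @param path Path to a YAML file.
#' @return List with elements `spec` and `model` (NULL when absent).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- if (!is.null(cfg$community)) do.call(community_spec, cfg$community)
  model <- if (!is.null(cfg$hic)) do.call(hic_model, cfg$hic)
  list(spec = spec, model = model)
}
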