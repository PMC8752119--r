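#' Does a query gene cluster with bacterial sequences on its tree?
#'
#' Tests whether the sister group of the query tip — the tips of the
#' smallest clade containing the query, minus the query itself — is
#' (at least `sister_fraction`) bacterial. Unrooted trees are midpoint
#' rooted first so the sister group is well defined. Tip labels other than
#' the query must carry a taxonomy tag of the form
#' `"<superkingdom>|<name>"`; tips from the superkingdoms in
#' `bacterial_superkingdoms` count as bacterial. When `min_support` is given
#' and the tree has node support labels, the query's parent clade must also
#' reach that support.
#'
#' @param tree A `phylo` object, a path to a Newick file, or a Newick
#'   string.
#' @param query Tip label of the query gene.
#' @param min_support Optional minimum support of the query's parent clade.
#' @param sister_fraction Minimum fraction of bacterial tips in the sister
#'   group (default 1.0: every sister tip bacterial).
#' @param bacterial_superkingdoms Superkingdom tags counted as bacterial.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tree_bacterial_clustering("((q:1,Bacteria|b1:1):1,(Eukaryota|e1:1,Eukaryota|e2:1):1);", "q")
#' @export
tree_bacterial_clustering <- function(tree, query, min_support = NULL,
                                      sister_fraction = 1.0,
                                      bacterial_superkingdoms =
                                        c("Bacteria", "Archaea")) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1 && file.exists(tree))
      ape::read.tree(tree) else ape::read.tree(text = tree)
    if (is.null(tree))
      stop("tree_bacterial_clustering: unparsable Newick input",
           call. = FALSE)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!query %in% tree$tip.label)
    stop("tree_bacterial_clustering: query tip '", query,
         "' not found in tree", call. = FALSE)
  if (!ape::is.rooted(tree))
    tree <- phangorn::midpoint(tree)
  tagged <- grepl("|", tree$tip.label, fixed = TRUE)
  if (!any(tagged[tree$tip.label != query]))
    stop("tree_bacterial_clustering: no tip carries a parsable ",
         "'superkingdom|name' taxonomy tag", call. = FALSE)
  qi <- match(query, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == qi, 1]
  clade_tips <- phangorn::Descendants(tree, parent, type = "tips")[[1]]
  sister <- setdiff(clade_tips, qi)
  if (length(sister) == 0) return(FALSE)
  if (!is.null(min_support) && !is.null(tree$node.label)) {
    lab <- tree$node.label[parent - ape::Ntip(tree)]
    sup <- suppressWarnings(as.numeric(lab))
    if (!is.na(sup) && sup < min_support) return(FALSE)
  }
  sk <- sub("\\|.*$", "", tree$tip.label[sister])
  frac <- mean(sk %in% bacterial_superkingdoms)
  frac >= sister_fraction
}

# label pools for simulated gene trees
SIM_BACTERIA <- c("Stappia_sp", "Maribacter_sp", "Phaeomarinobacter_ectocarpi",
                  "Flavobacterium_sp", "Sulfitobacter_sp")
SIM_EUKARYOTES <- c("Porphyra_umbilicalis", "Chondrus_crispus",
                    "Galdieria_sulphuraria", "Cyanidioschyzon_merolae",
                    "Gracilariopsis_chorda")

#' Simulate a gene tree with a planted sister placement
#'
#' Builds a random binary background tree of bacterial and eukaryotic tips
#' (labelled `"<superkingdom>|<name>"`, all branch lengths positive) and
#' attaches the query gene as the sister of a bacterial tip when the gene is
#' planted `strong`, and of a eukaryotic tip otherwise, so
#' [tree_bacterial_clustering()] returns `TRUE` exactly for strong-planted
#' genes.
#'
#' @param gene Gene id; must appear in `gene_truth`.
#' @param gene_truth Gene truth table from [simulate_hit_table()] (columns
#'   `gene`, `category`).
#' @param seed Integer seed; the tree is identical across runs for a fixed
#'   seed (trees for different genes differ).
#' @param n_background Number of background tips (half bacterial, half
#'   eukaryotic).
#' @return A rooted `phylo` object whose query tip is labelled `gene`.
#' @export
simulate_gene_tree <- function(gene, gene_truth, seed, n_background = 10L) {
  i <- match(gene, gene_truth$gene)
  if (is.na(i))
    stop("simulate_gene_tree: unknown gene id '", gene, "'", call. = FALSE)
  category <- gene_truth$category[i]
  set.seed(((as.integer(seed) %% 1000003L) * 1009L + (i %% 100000L)) %% .Machine$integer.max)
  nb <- max(4L, as.integer(n_background))
  n_bact <- nb %/% 2L
  labs <- c(paste0("Bacteria|", SIM_BACTERIA[((seq_len(n_bact) - 1L) %%
                                                length(SIM_BACTERIA)) + 1L],
                   "_", seq_len(n_bact)),
            paste0("Eukaryota|",
                   SIM_EUKARYOTES[((seq_len(nb - n_bact) - 1L) %%
                                     length(SIM_EUKARYOTES)) + 1L],
                   "_", seq_len(nb - n_bact)))
  bg <- ape::rtree(nb, tip.label = sample(labs))
  bg$edge.length <- bg$edge.length + 0.01
  target_pool <- if (identical(category, "strong"))
    grep("^Bacteria\\|", bg$tip.label) else grep("^Eukaryota\\|", bg$tip.label)
  target <- sample(target_pool, 1L)
  qt <- ape::read.tree(text = paste0("(", gene, ":0.05);"))
  elen <- bg$edge.length[bg$edge[, 2] == target]
  ape::bind.tree(bg, qt, where = target, position = elen / 2)
}

#' Simulate gene trees for all planted genes of given categories
#'
#' @param gene_truth Gene truth table from [simulate_hit_table()].
#' @param seed Integer seed.
#' @param categories Planted categories that receive a tree (default strong
#'   and partial, mirroring that trees are only inspected for high-AI
#'   genes).
#' @param n_background Background tips per tree.
#' @return Named list of `phylo` objects keyed by gene id.
#' @export
simulate_gene_trees <- function(gene_truth, seed,
                                categories = c("strong", "partial"),
                                n_background = 10L) {
  ids <- gene_truth$gene[gene_truth$category %in% categories]
  out <- lapply(ids, simulate_gene_tree, gene_truth = gene_truth,
                seed = seed, n_background = n_background)
  names(out) <- ids
  out
}

#' Write simulated gene trees as Newick files
#'
#' @param trees Named list of `phylo` objects.
#' @param dir Output directory; files are named `<gene>.nwk`.
#' @return Invisibly, the file paths.
#' @export
write_gene_trees <- function(trees, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(trees), function(g) {
    f <- file.path(dir, paste0(g, ".nwk"))
    ape::write.tree(trees[[g]], file = f)
    f
  }, "")
  invisible(paths)
}
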