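as_dnabin_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("plastome sequences must be aligned (equal lengths)")
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  ape::as.DNAbin(m)
}

#' Pairwise distances between aligned plastome sequences
#'
#' p-distance (`"p"`: mismatches / length) or its Jukes-Cantor correction
#' (`"JC69"`: d = -(3/4) log(1 - 4p/3)). The simulator introduces
#' substitutions only, so the input sequences are positionally homologous
#' without alignment. JC69 errors on saturated pairs (p >= 0.75).
#'
#' @param seqs named character vector of equal-length DNA sequences.
#' @param model `"p"` or `"JC69"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
plastome_distances <- function(seqs, model = c("JC69", "p")) {
  model <- match.arg(model)
  dna <- as_dnabin_matrix(seqs)
  d <- ape::dist.dna(dna, model = if (model == "p") "raw" else "JC69",
                     pairwise.deletion = FALSE)
  m <- as.matrix(d)
  if (any(!is.finite(m)))
    stop("saturated divergence (p >= 0.75): JC69 distance undefined")
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration on the Saitou-Nei Q criterion; negative branch
#' lengths (a known NJ artifact on noisy distances) are clamped to zero and
#' zero-length internal branches are collapsed into polytomies, so a
#' zero-divergence input yields a star.
#'
#' @param dist symmetric distance matrix or `dist` object, `>= 3` taxa.
#' @return an unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(dist) {
  m <- as.matrix(dist)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::di2multi(tr, tol = 1e-10)
}

#' Nonparametric bootstrap supports on the NJ plastome tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' distance + NJ tree for each replicate, and reports for every internal
#' split of the full-data tree the fraction of replicates containing it.
#'
#' @param seqs named character vector of aligned sequences.
#' @param B number of bootstrap replicates (`>= 1`).
#' @param seed integer seed.
#' @param model distance model, see [plastome_distances()].
#' @return the NJ `"phylo"` tree with `node.label` set to support
#'   fractions (root label empty).
#' @export
bootstrap_support <- function(seqs, B = 100L, seed = 1L,
                              model = c("JC69", "p")) {
  model <- match.arg(model)
  stopifnot(B >= 1L)
  main <- neighbor_joining(plastome_distances(seqs, model))
  chars <- strsplit(seqs, "", fixed = TRUE)
  mat <- do.call(rbind, chars)
  rownames(mat) <- names(seqs)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    rs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    reps[[b]] <- neighbor_joining(plastome_distances(rs, model))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- counts / B
  main
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial splits (bipartitions) present in exactly one of
#' the two unrooted trees; 0 means identical topologies.
#'
#' @param t1,t2 `"phylo"` trees on the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Test monophyly of a taxon subset
#'
#' Unrooted sense: true iff some split of the tree separates exactly the
#' given subset from the rest. When an outgroup is supplied the tree is
#' first rooted on it and monophyly is assessed on the rooted tree.
#'
#' @param tree a `"phylo"` tree.
#' @param taxa non-empty character vector of tip labels.
#' @param outgroup optional tip (or tips) to root on.
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, taxa, outgroup = NULL) {
  if (!length(taxa)) stop("taxa subset must be non-empty")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (setequal(taxa, tree$tip.label)) return(TRUE)
  if (length(taxa) == 1L) return(TRUE)
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup, resolve.root = TRUE)
    return(ape::is.monophyletic(tree, taxa))
  }
  anchor <- setdiff(tree$tip.label, taxa)[1L]
  tree <- ape::root(tree, anchor, resolve.root = TRUE)
  ape::is.monophyletic(tree, taxa)
}

# Collapse a tree to one representative leaf per clade (requires each clade
# to be monophyletic; returns NULL otherwise). Tip labels become clade
# names, so clade-level topologies of different trees are comparable.
collapse_to_clades <- function(tree, clade_map, drop = NULL) {
  if (!is.null(drop))
    tree <- ape::drop.tip(tree, intersect(drop, tree$tip.label))
  tips <- tree$tip.label
  clades <- unique(unname(clade_map[tips]))
  reps <- character(0)
  for (cl in clades) {
    members <- tips[clade_map[tips] == cl]
    if (length(members) > 1L && !is_monophyletic(tree, members))
      return(NULL)
    reps[cl] <- members[1L]
  }
  small <- ape::keep.tip(tree, unname(reps))
  small$tip.label <- names(reps)[match(small$tip.label, reps)]
  small
}
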