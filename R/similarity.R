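#' Species correlation matrix over top-cluster abundances
#'
#' Pearson correlation between species' abundance vectors restricted to the
#' selected top clusters, after the configured transform (default:
#' log(1 + reads-per-million), which stabilizes the heavy-tailed cluster
#' size distribution and removes library-size differences).
#'
#' @param am an [abundance_matrix()].
#' @param top cluster ids to use (default: all).
#' @param transform `"log1p_norm"` (default), `"log1p"` (log of raw counts)
#'   or `"none"` (raw counts).
#' @return symmetric correlation matrix with unit diagonal, species x
#'   species.
#' @export
correlation_matrix <- function(am, top = rownames(am$counts),
                               transform = c("log1p_norm", "log1p", "none")) {
  transform <- match.arg(transform)
  if (length(top) < 2L) stop("need at least 2 clusters")
  if (ncol(am$counts) < 2L) stop("need at least 2 species")
  x <- switch(transform,
              log1p_norm = log1p(am$norm[top, , drop = FALSE]),
              log1p = log1p(am$counts[top, , drop = FALSE]),
              none = am$counts[top, , drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance abundance vector for species: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x, method = "pearson")
  r[cbind(seq_len(ncol(r)), seq_len(ncol(r)))] <- 1
  r
}

#' Hierarchical clustering of the species correlation matrix
#'
#' Agglomerative clustering on the distance `d = 1 - r` (default linkage:
#' average/UPGMA). Returns a standard [stats::hclust] dendrogram whose
#' merge heights are non-decreasing.
#'
#' @param corr a symmetric correlation matrix.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an object of class `"hclust"`.
#' @export
hierarchical_cluster <- function(corr, linkage = "average") {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  stats::hclust(stats::as.dist(1 - corr), method = linkage)
}

#' Convert a dendrogram to Newick
#'
#' Branch lengths are height differences (each leaf sits at half the merge
#' height below its parent, the standard ultrametric reading of an hclust
#' tree). The output round-trips through standard Newick parsers.
#'
#' @param dendro an `"hclust"` or `"phylo"` object.
#' @return a Newick string (terminated by `;`).
#' @export
dendrogram_to_newick <- function(dendro) {
  phy <- if (inherits(dendro, "phylo")) dendro else ape::as.phylo(dendro)
  ape::write.tree(phy)
}

#' Check clade grouping in the species dendrogram
#'
#' Reports, per clade, whether its species form a contiguous subtree
#' (monophyletic block) of the dendrogram, and which clades sit on each side
#' of the deepest split (the root): the pair structure of the two deepest
#' branches.
#'
#' @param dendro an `"hclust"` or rooted `"phylo"` dendrogram.
#' @param clade_map named character vector, species -> clade, covering all
#'   leaves.
#' @return a list: `clade_coherent` (named logical), `deep_split_pairs`
#'   (list of two character vectors: the clade sets on each side of the
#'   root).
#' @export
grouping_check <- function(dendro, clade_map) {
  phy <- if (inherits(dendro, "phylo")) dendro else ape::as.phylo(dendro)
  tips <- phy$tip.label
  if (!all(tips %in% names(clade_map)))
    stop("clade_map does not cover all dendrogram leaves")
  clades <- unique(unname(clade_map[tips]))
  coherent <- vapply(clades, function(cl) {
    members <- tips[clade_map[tips] == cl]
    length(members) == 1L || ape::is.monophyletic(phy, members)
  }, logical(1))
  root <- length(tips) + 1L
  kids <- phy$edge[phy$edge[, 1L] == root, 2L]
  side_tips <- lapply(kids, function(k) {
    if (k <= length(tips)) tips[k]
    else ape::extract.clade(phy, k)$tip.label
  })
  pairs <- lapply(side_tips, function(tt) sort(unique(unname(clade_map[tt]))))
  list(clade_coherent = coherent, deep_split_pairs = pairs)
}

# TRUE when the dendrogram shows four coherent clade blocks with the deep
# split uniting exactly the two given clade pairs.
grouping_matches <- function(check, pair_a = c("NWB", "Olyreae"),
                             pair_b = c("Arundinarieae", "PWB")) {
  all(check$clade_coherent) &&
    length(check$deep_split_pairs) == 2L &&
    ((setequal(check$deep_split_pairs[[1L]], pair_a) &&
        setequal(check$deep_split_pairs[[2L]], pair_b)) ||
       (setequal(check$deep_split_pairs[[1L]], pair_b) &&
          setequal(check$deep_split_pairs[[2L]], pair_a)))
}
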