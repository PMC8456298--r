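#' Cluster-by-species abundance matrix
#'
#' Tabulates the cluster table into exact read counts per cluster and
#' species, together with per-species totals and the grand total of
#' clustered reads. A reads-per-thousand normalization (per species, over
#' that species' clustered reads) is stored alongside the raw counts; the
#' per-thousand unit keeps normalized values of order one for desk-scale
#' libraries, as per-million does for real sequencing libraries.
#'
#' @param cluster_table a `"cluster_table"`.
#' @param species optional character vector fixing the species set (and
#'   column order); defaults to the species present in the table.
#' @return a list of class `"abundance_matrix"`: `counts` (matrix
#'   cluster x species), `norm` (reads per thousand clustered reads of the
#'   species), `species_totals`, `grand_total`.
#' @export
abundance_matrix <- function(cluster_table, species = NULL) {
  if (is.null(species)) species <- sort(unique(cluster_table$species))
  clusters <- names(attr(cluster_table, "sizes"))
  if (is.null(clusters)) clusters <- sort(unique(cluster_table$cluster_id))
  counts <- table(factor(cluster_table$cluster_id, levels = clusters),
                  factor(cluster_table$species, levels = species))
  counts <- matrix(as.integer(counts), nrow = length(clusters),
                   dimnames = list(clusters, species))
  totals <- colSums(counts)
  norm <- sweep(counts, 2L, pmax(totals, 1L), "/") * 1e3
  structure(list(counts = counts, norm = norm, species_totals = totals,
                 grand_total = sum(counts)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d clusters x %d species, %s clustered reads\n",
              nrow(x$counts), ncol(x$counts),
              format(x$grand_total, big.mark = ",")))
  invisible(x)
}

#' Select the most abundant clusters up to a cumulative read fraction
#'
#' Clusters are ranked by total read count (descending, ties broken by
#' cluster id ascending); the shortest prefix whose cumulative count reaches
#' `fraction` of all clustered reads is returned. This is the rule behind
#' "top clusters making up 50 percent of clustered reads".
#'
#' @param am an [abundance_matrix()].
#' @param fraction cumulative read fraction in `(0, 1]`.
#' @return character vector of cluster ids, in rank order.
#' @export
select_top_clusters <- function(am, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!nrow(am$counts)) stop("empty abundance matrix")
  sizes <- rowSums(am$counts)
  ord <- order(-sizes, rownames(am$counts))
  cum <- cumsum(sizes[ord])
  n_top <- which(cum >= fraction * am$grand_total)[1L]
  if (is.na(n_top)) n_top <- length(ord)
  rownames(am$counts)[ord[seq_len(n_top)]]
}

#' Cluster presence by clade
#'
#' A cluster is scored present in a clade when at least `min_species`
#' species of that clade each contribute at least `min_reads` reads to the
#' cluster (defaults 1 and 1: any read in any species).
#'
#' @param am an [abundance_matrix()].
#' @param clade_map named character vector, species -> clade; must cover
#'   every species in the matrix.
#' @param top cluster ids to score (default: all).
#' @param min_reads minimum reads per species.
#' @param min_species minimum qualifying species per clade.
#' @return logical matrix, clusters x clades.
#' @export
clade_presence <- function(am, clade_map, top = rownames(am$counts),
                           min_reads = 1L, min_species = 1L) {
  sp <- colnames(am$counts)
  missing <- setdiff(sp, names(clade_map))
  if (length(missing))
    stop("species missing from clade_map: ", paste(missing, collapse = ", "))
  clades <- unique(unname(clade_map[sp]))
  cnt <- am$counts[top, , drop = FALSE]
  out <- vapply(clades, function(cl) {
    cols <- sp[clade_map[sp] == cl]
    rowSums(cnt[, cols, drop = FALSE] >= min_reads) >= min_species
  }, logical(length(top)))
  out <- matrix(out, nrow = length(top),
                dimnames = list(top, clades))
  out
}

#' Shared/exclusive (Venn) repartition over four clades
#'
#' Counts clusters by their exact clade-presence pattern: all 15 non-empty
#' subsets of the four clades get a region count. Clusters present in no
#' clade are reported separately, not assigned to a region. Per-clade totals
#' (each the sum of the 8 regions containing that clade) and the woody-only
#' triple are included.
#'
#' @param presence logical matrix from [clade_presence()] over exactly four
#'   clades.
#' @return a list of class `"clade_partition"`: `regions` (named count per
#'   pattern, names like `"Olyreae+NWB"`), `per_clade`, `woody_triple`,
#'   `n_top`, `n_absent`.
#' @export
venn_partition <- function(presence) {
  if (ncol(presence) != 4L)
    stop("presence matrix must cover exactly 4 clades")
  clades <- colnames(presence)
  pat <- apply(presence, 1L, function(r) paste(clades[r], collapse = "+"))
  absent <- pat == ""
  subsets <- unlist(lapply(1:4, function(m)
    utils::combn(clades, m, paste, collapse = "+", simplify = FALSE)))
  regions <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(pat[!absent])
  regions[names(tab)] <- as.integer(tab)
  per_clade <- vapply(clades, function(cl)
    sum(regions[grepl(cl, names(regions), fixed = TRUE)]), integer(1))
  woody <- setdiff(clades, "Olyreae")
  structure(list(regions = regions, per_clade = per_clade,
                 woody_triple = unname(regions[paste(woody, collapse = "+")]),
                 n_top = nrow(presence), n_absent = sum(absent),
                 clades = clades),
            class = "clade_partition")
}

# Region count for an exact clade subset (order-insensitive helper).
venn_region <- function(cp, clades) {
  want <- vapply(strsplit(names(cp$regions), "+", fixed = TRUE),
                 function(x) setequal(x, clades), logical(1))
  unname(cp$regions[want])
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition> %d clusters over %s\n", x$n_top,
              paste(x$clades, collapse = ", ")))
  cat(sprintf("  common to all four: %d\n",
              venn_region(x, x$clades)))
  cat("  per-clade totals:",
      paste(sprintf("%s %d", names(x$per_clade), x$per_clade),
            collapse = ", "), "\n")
  if (x$n_absent)
    cat(sprintf("  absent from all clades: %d\n", x$n_absent))
  invisible(x)
}
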