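# Normalize the various read containers (read_set, data.frame, named
# character vector) to a data.frame(read_id, species, sequence).
as_read_df <- function(reads) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (is.character(reads)) {
    if (is.null(names(reads))) stop("reads vector must be named by read id")
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (is.null(reads$species))
    reads$species <- sub("_.*$", "", reads$read_id)
  reads
}

#' Remove short reads
#'
#' Length trimming as applied before repeat clustering; the boundary is
#' inclusive (a read of exactly `min_len` bp is kept). Order is preserved.
#'
#' @param reads a read container (read_set, data.frame or named vector).
#' @param min_len minimum read length in bp (default 45).
#' @return the filtered reads data.frame.
#' @export
filter_reads <- function(reads, min_len = 45) {
  stopifnot(min_len >= 0)
  rd <- as_read_df(reads)
  rd[nchar(rd$sequence) >= min_len, , drop = FALSE]
}

local_sub_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

# Align a set of patterns against one subject (local alignment), returning
# identity = matches / alignment columns, the column count and the score.
align_batch <- function(patterns, subject, match = 1, mismatch = -1,
                        gap = -2) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = local_sub_matrix(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  cols <- Biostrings::nchar(aln)
  data.frame(identity = Biostrings::nmatch(aln) / pmax(cols, 1L),
             overlap = cols, score = Biostrings::score(aln))
}

#' Pairwise local-alignment identity between two reads
#'
#' Best local alignment (default scoring: match +1, mismatch -1, gap -2)
#' computed on both strands; identity is matches divided by alignment
#' columns (gaps included). Returns no hit (`NULL`) when the best
#' alignment spans less than `min_overlap_frac` of the shorter read.
#'
#' @param r1,r2 DNA strings (non-empty).
#' @param min_overlap_frac minimum alignment span as a fraction of the
#'   shorter read (default 0.55).
#' @param match,mismatch,gap alignment scores.
#' @param both_strands also try `r2` reverse-complemented?
#' @return `list(identity =, overlap =)` or `NULL` for no hit.
#' @export
pairwise_identity <- function(r1, r2, min_overlap_frac = 0.55,
                              match = 1, mismatch = -1, gap = -2,
                              both_strands = TRUE) {
  stopifnot(nzchar(r1), nzchar(r2))
  cands <- if (both_strands) c(r2, revcomp(r2)) else r2
  res <- align_batch(cands, r1, match, mismatch, gap)
  best <- which.max(res$score)
  min_span <- min_overlap_frac * min(nchar(r1), nchar(r2))
  if (res$overlap[best] < min_span) return(NULL)
  list(identity = res$identity[best], overlap = res$overlap[best])
}

# Candidate pairs sharing >= min_shared canonical k-mers. Exhaustive (no
# bucket caps); quadratic in bucket size, intended for graph construction on
# small-to-moderate read sets.
kmer_candidate_pairs <- function(seqs, k = 15L, min_shared = 2L, stride = 1L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) unique(canonical_kmers(s, k, stride)))
  idx <- data.frame(kmer = unlist(km), read = rep.int(seq_len(n),
                                                     lengths(km)))
  pairs <- list()
  for (grp in split(idx$read, idx$kmer)) {
    if (length(grp) >= 2L && length(grp) <= 2000L) {
      g <- sort(grp)
      pairs[[length(pairs) + 1L]] <- t(utils::combn(g, 2L))
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2L))
  all <- do.call(rbind, pairs)
  key <- paste(all[, 1L], all[, 2L])
  tab <- table(key)
  keep <- names(tab)[tab >= min_shared]
  out <- do.call(rbind, strsplit(keep, " ", fixed = TRUE))
  matrix(as.integer(out), ncol = 2L)
}

#' Build the read similarity graph
#'
#' Candidate read pairs are proposed by shared canonical k-mers (default
#' k = 15, at least 2 shared), then every candidate is verified by
#' [pairwise_identity()]; an edge is added iff identity strictly exceeds
#' `identity_threshold` and the alignment span passes the overlap rule. With
#' `prefilter = FALSE` all pairs are verified (the brute-force oracle mode).
#' No edge in the returned graph violates the thresholds.
#'
#' @param reads a read container.
#' @param identity_threshold clustering identity threshold in `(0, 1]`
#'   (default 0.80: reads of one repeat family share > 80 percent identity).
#' @param min_overlap_frac minimum alignment span fraction.
#' @param k k-mer size for the prefilter.
#' @param min_shared_kmers shared k-mers required to propose a pair.
#' @param prefilter use the k-mer prefilter? `FALSE` = all-vs-all.
#' @param match,mismatch,gap alignment scoring.
#' @return an [igraph::graph] with vertex attribute `name` (read ids) and
#'   edge attributes `identity`, `overlap`.
#' @export
build_similarity_graph <- function(reads, identity_threshold = 0.80,
                                   min_overlap_frac = 0.55, k = 15L,
                                   min_shared_kmers = 2L, prefilter = TRUE,
                                   match = 1, mismatch = -1, gap = -2) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  rd <- as_read_df(reads)
  n <- nrow(rd)
  if (prefilter && any(nchar(rd$sequence) < k))
    stop("k exceeds the shortest read length")
  pairs <- if (prefilter) {
    kmer_candidate_pairs(rd$sequence, k = k, min_shared = min_shared_kmers)
  } else if (n >= 2L) {
    t(utils::combn(seq_len(n), 2L))
  } else matrix(integer(0), ncol = 2L)
  v <- verify_pairs(rd$sequence, pairs, identity_threshold,
                    min_overlap_frac, match, mismatch, gap)
  keep <- v$keep; ident <- v$identity; ovl <- v$overlap
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rd$read_id)
  if (any(keep)) {
    g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]),
                           identity = ident[keep], overlap = ovl[keep])
  }
  g
}

# Vectorized pair verification: local alignment of every (i, j) pair on
# both strands in two batched calls; a pair passes when either strand
# clears the overlap rule with identity strictly above the threshold.
verify_pairs <- function(seqs, pairs, identity_threshold, min_overlap_frac,
                         match = 1, mismatch = -1, gap = -2) {
  m <- nrow(pairs)
  if (!m) return(list(keep = logical(0), identity = numeric(0),
                      overlap = numeric(0)))
  submat <- local_sub_matrix(match, mismatch)
  a <- seqs[pairs[, 1L]]
  b <- seqs[pairs[, 2L]]
  res <- lapply(list(b, revcomp(b)), function(sub) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(a),
      subject = Biostrings::DNAStringSet(sub), type = "local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = abs(gap))
    cols <- Biostrings::nchar(aln)
    list(cols = cols, idn = Biostrings::nmatch(aln) / pmax(cols, 1L))
  })
  min_span <- min_overlap_frac * pmin(nchar(a), nchar(b))
  ok1 <- res[[1]]$cols >= min_span & res[[1]]$idn > identity_threshold
  ok2 <- res[[2]]$cols >= min_span & res[[2]]$idn > identity_threshold
  idn <- ifelse(ok1 & (!ok2 | res[[1]]$idn >= res[[2]]$idn),
                res[[1]]$idn, res[[2]]$idn)
  cols <- ifelse(ok1 & (!ok2 | res[[1]]$idn >= res[[2]]$idn),
                 res[[1]]$cols, res[[2]]$cols)
  list(keep = ok1 | ok2, identity = idn, overlap = cols)
}

#' Partition a similarity graph into repeat clusters
#'
#' Clusters are the connected components of the similarity graph (the
#' transitive notion of a repeat family: reads mutually linked above the
#' identity threshold). Components smaller than `min_cluster_size` are
#' reported as unclustered. Cluster ids are assigned in decreasing component
#' size, ties broken by the smallest member read id.
#'
#' @param graph an [build_similarity_graph()] result.
#' @param min_cluster_size smallest component kept as a cluster (default 2;
#'   pipelines typically raise it to suppress background co-incidences).
#' @return a data.frame of class `"cluster_table"` with columns `read_id`,
#'   `species`, `cluster_id`; unclustered read ids in
#'   `attr(, "unclustered")`, per-cluster sizes in `attr(, "sizes")`.
#' @export
cluster_reads <- function(graph, min_cluster_size = 2L) {
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  membership_table(comp$membership, ids, min_cluster_size)
}

# Shared cluster-table builder: takes raw component membership (integer per
# read), applies the size filter and the deterministic ordering rule.
membership_table <- function(membership, read_ids, min_cluster_size) {
  sizes <- table(membership)
  comp_min <- tapply(read_ids, membership, min)
  keep_comps <- names(sizes)[sizes >= min_cluster_size]
  ord <- keep_comps[order(-as.integer(sizes[keep_comps]),
                          comp_min[keep_comps])]
  new_id <- stats::setNames(sprintf("CL%04d", seq_along(ord)), ord)
  in_cluster <- as.character(membership) %in% keep_comps
  tab <- data.frame(
    read_id = read_ids[in_cluster],
    species = sub("_.*$", "", read_ids[in_cluster]),
    cluster_id = unname(new_id[as.character(membership[in_cluster])]),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster_id, tab$read_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "unclustered") <- read_ids[!in_cluster]
  attr(tab, "sizes") <- stats::setNames(
    as.integer(sizes[ord]), unname(new_id[ord]))
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' @export
print.cluster_table <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat(sprintf("<cluster_table> %d clusters, %d clustered reads, %d unclustered\n",
              length(sizes), nrow(x), length(attr(x, "unclustered"))))
  if (length(sizes)) {
    show <- utils::head(sizes, 5L)
    cat("  largest:", paste(sprintf("%s (%d)", names(show), show),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cluster a pooled read set (scalable path)
#'
#' Produces the same partition semantics as [build_similarity_graph()] +
#' [cluster_reads()] but streams reads through an incremental canonical
#' k-mer index and a union-find structure, verifying with local alignment
#' only candidates that are not already in the read's component (merging two
#' reads already connected cannot change the partition, so those alignments
#' are skipped). High-frequency k-mer buckets are capped, and per read only
#' the strongest few candidates per foreign component are aligned; at
#' repeat-family read depths this leaves the partition essentially identical
#' to the exhaustive graph while doing near-linear work.
#'
#' @param reads a read container.
#' @inheritParams build_similarity_graph
#' @param min_cluster_size smallest component reported as a cluster.
#' @param kmer_sample when `TRUE` (default), only canonical k-mers starting
#'   with A or C are indexed and queried. Sampling k-mers by value (rather
#'   than by read offset, which would make discovery depend on the parity
#'   of two reads' relative positions) halves index and lookup cost at
#'   roughly half the shared-k-mer counts.
#' @param bucket_cap reads indexed per distinct k-mer.
#' @param per_comp_candidates candidates aligned per foreign component.
#' @param exact_below below this read count every pair is verified by
#'   alignment (no k-mer prefilter): small problems are computed exactly,
#'   so the partition is the true transitive closure of the identity
#'   relation.
#' @return a `"cluster_table"` (see [cluster_reads()]).
#' @export
cluster_pooled_reads <- function(reads, identity_threshold = 0.80,
                                 min_overlap_frac = 0.55, k = 15L,
                                 min_shared_kmers = 2L,
                                 min_cluster_size = 5L,
                                 kmer_sample = TRUE, bucket_cap = 64L,
                                 per_comp_candidates = 1L,
                                 exact_below = 150L,
                                 match = 1, mismatch = -1, gap = -2) {
  rd <- as_read_df(reads)
  n <- nrow(rd)
  if (n < exact_below) {
    g <- build_similarity_graph(rd, identity_threshold = identity_threshold,
                                min_overlap_frac = min_overlap_frac,
                                prefilter = FALSE, match = match,
                                mismatch = mismatch, gap = gap)
    return(cluster_reads(g, min_cluster_size = min_cluster_size))
  }
  seqs <- rd$sequence
  rcs <- revcomp(seqs)           # one vectorized call for all reads
  lens <- nchar(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  submat <- local_sub_matrix(match, mismatch)
  buf_i <- integer(0); buf_j <- integer(0)
  flush_size <- 600L
  flush <- function() {
    if (!length(buf_i)) return(invisible())
    ii <- buf_i; jj <- buf_j
    buf_i <<- integer(0); buf_j <<- integer(0)
    # verify queued pairs on both strands in two vectorized calls
    pat <- Biostrings::DNAStringSet(seqs[ii])
    res <- lapply(list(seqs[jj], rcs[jj]), function(sub) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = pat, subject = Biostrings::DNAStringSet(sub),
        type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = abs(gap))
      cols <- Biostrings::nchar(aln)
      list(cols = cols, idn = Biostrings::nmatch(aln) / pmax(cols, 1L))
    })
    min_span <- min_overlap_frac * pmin(lens[ii], lens[jj])
    pass <- (res[[1]]$cols >= min_span &
               res[[1]]$idn > identity_threshold) |
            (res[[2]]$cols >= min_span &
               res[[2]]$idn > identity_threshold)
    for (p in which(pass)) {
      a <- find(ii[p]); b <- find(jj[p])
      if (a != b) parent[max(a, b)] <<- min(a, b)
    }
    invisible()
  }
  index <- new.env(parent = emptyenv(), size = 2L^20L)
  for (i in seq_len(n)) {
    kms <- canonical_kmers(seqs[i], k, 1L, rc_all = rcs[i])
    if (kmer_sample) kms <- kms[substr(kms, 1L, 1L) < "G"]
    kms <- unique(kms)
    if (!length(kms)) next
    cand <- unlist(mget(kms, envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (length(cand)) {
      cand <- sort.int(cand, method = "radix")
      r <- rle(cand)
      ok <- r$lengths >= min_shared_kmers
      hits <- r$values[ok]
      shared <- r$lengths[ok]
      if (length(hits)) {
        ri <- find(i)
        comps <- vapply(hits, find, integer(1))
        keep <- comps != ri
        if (any(keep)) {
          # queue the strongest few candidates per foreign component;
          # verification is batched for speed, so the component view is
          # slightly stale -- that only costs redundant alignments
          ord <- order(-shared)
          taken <- integer(0)
          for (o in ord) {
            if (!keep[o]) next
            if (sum(taken == comps[o]) < per_comp_candidates) {
              buf_i <- c(buf_i, i); buf_j <- c(buf_j, hits[o])
              taken <- c(taken, comps[o])
            }
          }
          if (length(buf_i) >= flush_size) flush()
        }
      }
    }
    for (km in kms) {
      v <- index[[km]]
      if (is.null(v)) index[[km]] <- i
      else if (length(v) < bucket_cap) index[[km]] <- c(v, i)
    }
  }
  flush()
  membership <- vapply(seq_len(n), find, integer(1))
  membership_table(membership, rd$read_id, min_cluster_size)
}

#' Classify a cluster's superfamily by library vote
#'
#' Each read is assigned to the library consensus with the largest shared
#' canonical k-mer containment (fraction of the read's k-mers found in the
#' consensus), provided it clears `floor`; the cluster label is the
#' plurality superfamily among assigned reads, or `"unknown"` when fewer
#' than half the reads hit any consensus.
#'
#' @param cluster_seqs character vector of read sequences in the cluster.
#' @param library a [te_library()].
#' @param k classification k-mer size (smaller than the clustering k, to
#'   tolerate consensus divergence).
#' @param floor minimum containment fraction for a read-level hit.
#' @param sample_cap read sample size per cluster for the vote.
#' @param seed seed for the read subsample.
#' @param index precomputed library k-mer index (built internally when
#'   `NULL`; callers classifying many clusters build it once).
#' @return a superfamily label or `"unknown"`.
#' @export
classify_cluster <- function(cluster_seqs, library, k = 12L, floor = 0.08,
                             sample_cap = 40L, seed = 1L, index = NULL) {
  if (!nrow(library)) stop("library must be non-empty")
  if (!length(cluster_seqs)) return("unknown")
  idx <- if (is.null(index)) library_kmer_index(library, k) else index
  if (length(cluster_seqs) > sample_cap) {
    set.seed(seed)
    cluster_seqs <- sample(cluster_seqs, sample_cap)
  }
  votes <- vapply(cluster_seqs, function(s) {
    kms <- unique(canonical_kmers(s, k))
    if (!length(kms)) return(NA_character_)
    fams <- unlist(mget(kms, envir = idx$env, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (!length(fams)) return(NA_character_)
    tab <- tabulate(fams, nbins = nrow(library))
    best <- which.max(tab)
    if (tab[best] / length(kms) < floor) return(NA_character_)
    library$superfamily[best]
  }, character(1), USE.NAMES = FALSE)
  if (mean(!is.na(votes)) < 0.5) return("unknown")
  tab <- sort(table(votes[!is.na(votes)]), decreasing = TRUE)
  names(tab)[1L]
}

# Canonical k-mer -> family index for a library, memoized per call site.
library_kmer_index <- function(library, k) {
  env <- new.env(parent = emptyenv(), size = 2L^18L)
  for (fi in seq_len(nrow(library))) {
    for (km in unique(canonical_kmers(library$consensus[fi], k))) {
      env[[km]] <- c(env[[km]], fi)
    }
  }
  list(env = env)
}

#' Classify every cluster in a cluster table
#'
#' @param cluster_table a `"cluster_table"`.
#' @param reads the read container the table was built from.
#' @param library a [te_library()].
#' @param ... passed to [classify_cluster()].
#' @return named character vector: cluster id -> superfamily or "unknown".
#' @export
classify_clusters <- function(cluster_table, reads, library, k = 12L, ...) {
  rd <- as_read_df(reads)
  seq_by_id <- stats::setNames(rd$sequence, rd$read_id)
  ids <- unique(cluster_table$cluster_id)
  idx <- library_kmer_index(library, k)
  out <- vapply(ids, function(cl) {
    classify_cluster(seq_by_id[cluster_table$read_id[
      cluster_table$cluster_id == cl]], library, k = k, index = idx, ...)
  }, character(1))
  stats::setNames(out, ids)
}
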