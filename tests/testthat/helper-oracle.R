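# Brute-force clustering oracle: transitive closure of the all-pairs
# > threshold identity relation, computed without the k-mer prefilter or the
# streaming union-find (plain matrix closure over verified pairs).
oracle_partition <- function(seqs, identity_threshold = 0.80,
                             min_overlap_frac = 0.55) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2) {
    pairs <- t(utils::combn(n, 2L))
    a <- unname(seqs[pairs[, 1L]])
    b <- unname(seqs[pairs[, 2L]])
    sub <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
    hit <- rep(FALSE, nrow(pairs))
    for (strand in 1:2) {
      bb <- if (strand == 1) b else revcomp(b)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(a),
        subject = Biostrings::DNAStringSet(bb), type = "local",
        substitutionMatrix = sub, gapOpening = 0, gapExtension = 2)
      cols <- Biostrings::nchar(aln)
      idn <- Biostrings::nmatch(aln) / pmax(cols, 1L)
      hit <- hit | (cols >= min_overlap_frac * pmin(nchar(a), nchar(b)) &
                      idn > identity_threshold)
    }
    for (p in which(hit)) {
      x <- find(pairs[p, 1L]); y <- find(pairs[p, 2L])
      if (x != y) parent[y] <- x
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical form of a partition: labels renumbered by first appearance, so
# two membership vectors can be compared directly.
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# Random mixed-family read set: `n_fam` families plus background reads.
# Returns list(seqs = named character, family = integer truth labels,
# 0 = background).
random_read_set <- function(n_reads, n_fam = 3, read_len = 100,
                            cons_len = 400, copy_div = 0.05,
                            bg_frac = 0.3) {
  fams <- replicate(n_fam, random_dna(cons_len))
  n_bg <- round(n_reads * bg_frac)
  n_rep <- n_reads - n_bg
  fam_of <- sample.int(n_fam, n_rep, replace = TRUE)
  seqs <- vapply(fam_of, function(fi) {
    s <- sample.int(cons_len - read_len + 1L, 1L)
    r <- mutate_sequence(substr(fams[fi], s, s + read_len - 1L), copy_div)
    if (stats::runif(1) < 0.5) revcomp(r) else r
  }, character(1))
  bg <- vapply(seq_len(n_bg), function(i) random_dna(read_len), character(1))
  all_seqs <- c(seqs, bg)
  fam <- c(fam_of, rep(0L, n_bg))
  ord <- sample.int(length(all_seqs))
  all_seqs <- all_seqs[ord]; fam <- fam[ord]
  names(all_seqs) <- sprintf("Sp%d_%05d", sample.int(4, length(all_seqs),
                                                     replace = TRUE),
                             seq_along(all_seqs))
  list(seqs = all_seqs, family = fam)
}

# Exhaustive split enumeration for small unrooted trees: set of non-trivial
# bipartitions, each encoded as the lexicographically smaller side.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  out <- character(0)
  for (p in bp) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    other <- setdiff(tips, side)
    enc <- paste(side, collapse = ",")
    enc2 <- paste(sort(other), collapse = ",")
    out <- c(out, min(enc, enc2))
  }
  unique(out)
}
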