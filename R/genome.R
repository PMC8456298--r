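empty_te_table <- function() {
  data.frame(family_id = character(0), start = integer(0), end = integer(0),
             post_hybrid = logical(0), stringsAsFactors = FALSE)
}

#' Construct a subgenome block
#'
#' A contiguous stretch of nuclear sequence tagged with the ancestral genome
#' it derives from. Blocks are the unit of biased fractionation: after an
#' allopolyploidy event a whole block is either retained or lost. TE copies
#' are annotated as 0-based half-open intervals into the block sequence and
#' never overlap; copies inserted after a hybridization carry the
#' `post_hybrid` flag that determines their survival when the donor subgenome
#' is fractionated away.
#'
#' @param parent_label ancestral-genome letter of the block.
#' @param sequence DNA string.
#' @param te data.frame with columns `family_id`, `start`, `end`,
#'   `post_hybrid` (0-based half-open coordinates).
#' @return a list of class `"subgenome_block"`.
#' @export
subgenome_block <- function(parent_label, sequence, te = empty_te_table()) {
  stopifnot(is.character(parent_label), length(parent_label) == 1L,
            is.character(sequence), length(sequence) == 1L)
  te <- te[order(te$start), , drop = FALSE]
  rownames(te) <- NULL
  n <- nchar(sequence)
  if (nrow(te)) {
    if (any(te$start < 0L) || any(te$end > n) || any(te$end <= te$start))
      stop("TE copy intervals must lie within the block (0-based half-open)")
    if (any(te$start[-1L] < te$end[-nrow(te)]))
      stop("TE copy intervals must not overlap")
  }
  structure(list(parent_label = parent_label, sequence = sequence, te = te),
            class = "subgenome_block")
}

#' Construct a genome state
#'
#' The full nuclear + plastid state of a lineage: an ordered list of
#' subgenome blocks, the ploidy level, and the plastome sequence together
#' with the label of the maternal ancestor it was inherited from. The
#' plastome lineage is the quantity that records maternal inheritance
#' through hybridization events.
#'
#' @param label lineage label.
#' @param blocks list of [subgenome_block()] objects.
#' @param ploidy integer `>= 1` (2 for a diploid).
#' @param plastome plastid genome sequence.
#' @param plastome_lineage label of the maternal ancestor the plastome
#'   descends from (defaults to `label`).
#' @return a list of class `"genome_state"`.
#' @export
genome_state <- function(label, blocks, ploidy = 2L, plastome = "",
                         plastome_lineage = label) {
  stopifnot(ploidy >= 1L, is.list(blocks))
  g <- structure(list(label = label, blocks = blocks,
                      ploidy = as.integer(ploidy), plastome = plastome,
                      plastome_lineage = plastome_lineage),
                 class = "genome_state")
  validate_genome_state(g)
  g
}

#' @export
print.genome_state <- function(x, ...) {
  cat(sprintf("<genome_state> %s: %d blocks, %s bp nuclear, %dX, plastome %s (%s bp)\n",
              x$label, length(x$blocks),
              format(genome_length(x), big.mark = ","), x$ploidy,
              x$plastome_lineage, format(nchar(x$plastome), big.mark = ",")))
  invisible(x)
}

#' Total nuclear length of a genome state
#' @param g a [genome_state()].
#' @return total block length in bp.
#' @export
genome_length <- function(g) {
  sum(vapply(g$blocks, function(b) nchar(b$sequence), numeric(1)))
}

#' Validate genome-state invariants
#'
#' Checks block structure, TE interval containment and non-overlap.
#' @param g a [genome_state()].
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_genome_state <- function(g) {
  for (b in g$blocks) {
    if (!inherits(b, "subgenome_block")) stop("blocks must be subgenome_block objects")
    n <- nchar(b$sequence)
    te <- b$te
    if (nrow(te)) {
      if (any(te$start < 0L) || any(te$end > n) || any(te$end <= te$start))
        stop("TE copy interval outside its block")
      o <- order(te$start)
      if (any(te$start[o][-1L] < te$end[o][-nrow(te)]))
        stop("overlapping TE copy intervals")
    }
  }
  invisible(g)
}

#' Merge two genomes by hybridization
#'
#' Allopolyploidy: the child carries the concatenation of both parents'
#' subgenome blocks (parental labels preserved), the summed ploidy, and the
#' plastome of the maternal parent -- plastid genomes are maternally
#' inherited, so `plastome_lineage` tracks the maternal ancestry.
#'
#' @param parent_a,parent_b [genome_state()] objects.
#' @param maternal label of the maternal parent; must match one of the two.
#' @param label label for the child (default `"A x B"` style).
#' @return the hybrid [genome_state()].
#' @export
hybridize <- function(parent_a, parent_b, maternal,
                      label = paste0(parent_a$label, "x", parent_b$label)) {
  mom <- if (identical(maternal, parent_a$label)) parent_a
         else if (identical(maternal, parent_b$label)) parent_b
         else stop("maternal label '", maternal, "' matches neither parent")
  genome_state(label = label,
               blocks = c(parent_a$blocks, parent_b$blocks),
               ploidy = parent_a$ploidy + parent_b$ploidy,
               plastome = mom$plastome,
               plastome_lineage = mom$plastome_lineage)
}

#' Biased fractionation of one parental subgenome
#'
#' Each block whose `parent_label` equals `removed_parent` is deleted
#' independently with probability `f` (genome dominance: the other
#' subgenome is preferentially retained). TE copies that transposed into
#' retained-parent blocks after the hybridization (`post_hybrid = TRUE`)
#' reside in blocks that are not touched, and therefore survive even when
#' the donor subgenome is eliminated entirely -- the jump-survival mechanism
#' by which a lost ancestor's mobilome persists. If no block of the removed
#' parent remains, ploidy is decremented by 2 (diploidization), floored at 2.
#'
#' @param g a [genome_state()].
#' @param removed_parent parental label whose blocks are lost.
#' @param f per-block removal probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return the fractionated [genome_state()].
#' @export
fractionate <- function(g, removed_parent, f, seed = NULL) {
  if (!is.numeric(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  labels <- vapply(g$blocks, `[[`, character(1), "parent_label")
  if (!removed_parent %in% labels)
    stop("no block carries parent label '", removed_parent, "'")
  if (!is.null(seed)) set.seed(seed)
  drop <- labels == removed_parent & stats::runif(length(labels)) < f
  blocks <- g$blocks[!drop]
  remaining <- vapply(blocks, `[[`, character(1), "parent_label")
  ploidy <- g$ploidy
  if (!removed_parent %in% remaining) ploidy <- max(2L, ploidy - 2L)
  genome_state(g$label, blocks, ploidy, g$plastome, g$plastome_lineage)
}

# Insert one TE copy into a block at offset `at` (0-based), shifting the
# coordinates of downstream copies. `at` must not fall strictly inside an
# existing copy.
insert_te_copy <- function(block, family_id, copy_seq, at, post_hybrid) {
  len <- nchar(copy_seq)
  seq <- block$sequence
  block$sequence <- paste0(substr(seq, 1L, at), copy_seq,
                           substr(seq, at + 1L, nchar(seq)))
  te <- block$te
  if (nrow(te)) {
    shift <- te$start >= at
    te$start[shift] <- te$start[shift] + len
    te$end[shift] <- te$end[shift] + len
  }
  te <- rbind(te, data.frame(family_id = family_id, start = at, end = at + len,
                             post_hybrid = post_hybrid, stringsAsFactors = FALSE))
  block$te <- te[order(te$start), , drop = FALSE]
  rownames(block$te) <- NULL
  block
}

# Sample an insertion offset in a block that keeps `gap` bp of background
# between copies (no nesting, no abutting copies: the model excludes TE
# structural nesting, and a gap of at least one read length means no read
# can span sequence of two different families).
sample_insertion_point <- function(block, gap = 150L) {
  n <- nchar(block$sequence)
  te <- block$te
  for (i in 1:200) {
    at <- sample.int(n + 1L, 1L) - 1L
    if (!nrow(te) || !any(at > te$start - gap & at < te$end + gap)) return(at)
  }
  # dense block: fall back to any point outside existing copies
  for (i in 1:200) {
    at <- sample.int(n + 1L, 1L) - 1L
    if (!any(at > te$start & at < te$end)) return(at)
  }
  0L
}

#' Amplification burst of one repeat family
#'
#' Inserts `n_copies` mutated copies of the family consensus at
#' uniform-random positions across all blocks (weighted by block length,
#' irrespective of the block's parental origin). Copies are flagged
#' `post_hybrid` as requested; post-hybridization copies landing in blocks of
#' the retained parent are the ones that survive subsequent fractionation.
#'
#' @param g a [genome_state()].
#' @param library a [te_library()] containing `family_id`.
#' @param family_id the family to amplify.
#' @param n_copies number of new copies, `>= 0`.
#' @param post_hybrid flag recorded on the new copies.
#' @param copy_divergence expected substitutions/site between a new copy and
#'   the family consensus.
#' @param seed optional integer seed.
#' @return the grown [genome_state()].
#' @export
te_burst <- function(g, library, family_id, n_copies, post_hybrid = FALSE,
                     copy_divergence = 0.05, seed = NULL) {
  idx <- match(family_id, library$family_id)
  if (is.na(idx)) stop("unknown family '", family_id, "'")
  if (n_copies < 0) stop("n_copies must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n_copies == 0) return(g)
  cons <- library$consensus[idx]
  lens <- vapply(g$blocks, function(b) nchar(b$sequence), numeric(1))
  for (i in seq_len(n_copies)) {
    bi <- sample.int(length(g$blocks), 1L, prob = lens)
    copy <- mutate_sequence(cons, copy_divergence)
    at <- sample_insertion_point(g$blocks[[bi]])
    g$blocks[[bi]] <- insert_te_copy(g$blocks[[bi]], family_id, copy, at,
                                     post_hybrid)
    lens[bi] <- lens[bi] + nchar(copy)
  }
  g
}

#' Mobilome-wide amplification burst
#'
#' Distributes `total_copies` insertions across the families of one
#' ancestral origin, sampling families in proportion to their abundance
#' weights. This is how a hybridization transfers the donor lineage's
#' current mobilome profile into the recipient genome: the per-family copy
#' numbers it seeds are correlated with the donor's own abundances.
#'
#' @param g a [genome_state()].
#' @param library a [te_library()].
#' @param origin origin label selecting the donor families.
#' @param total_copies total number of insertions.
#' @param post_hybrid flag recorded on the new copies.
#' @param copy_divergence per-copy divergence from consensus.
#' @param weight_jitter_sd standard deviation of a lognormal perturbation of
#'   the family weights, drawn once per burst. Zero reproduces the donor
#'   abundance profile faithfully (mobilome transfer); positive values give
#'   the burst a lineage-specific amplification signature.
#' @param seed optional integer seed.
#' @return the grown [genome_state()].
#' @export
mobilome_burst <- function(g, library, origin, total_copies,
                           post_hybrid = FALSE, copy_divergence = 0.05,
                           weight_jitter_sd = 0, seed = NULL) {
  fams <- library[library$origin == origin, , drop = FALSE]
  if (!nrow(fams)) stop("no families with origin '", origin, "'")
  if (!is.null(seed)) set.seed(seed)
  if (total_copies == 0) return(g)
  w <- fams$weight
  if (weight_jitter_sd > 0)
    w <- w * exp(stats::rnorm(length(w), 0, weight_jitter_sd))
  draws <- sample(fams$family_id, total_copies, replace = TRUE, prob = w)
  tab <- table(draws)
  for (fam in names(tab)) {
    g <- te_burst(g, library, fam, as.integer(tab[[fam]]),
                  post_hybrid = post_hybrid, copy_divergence = copy_divergence)
  }
  g
}

# Mutate every block sequence and the plastome by d substitutions/site
# (lineage divergence along a branch). TE annotations keep their coordinates
# because substitutions preserve length.
evolve_genome <- function(g, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (d == 0) return(g)
  g$blocks <- lapply(g$blocks, function(b) {
    b$sequence <- mutate_sequence(b$sequence, d)
    b
  })
  if (nzchar(g$plastome)) g$plastome <- mutate_sequence(g$plastome, d)
  g
}

# Build an ancestral diploid genome: background blocks of random sequence
# plus genesis TE copies of the listed origins, copy numbers proportional to
# family weights.
build_ancestor_genome <- function(label, library, origins, copies_per_origin,
                                  n_blocks, block_len, plastome,
                                  copy_divergence = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(i)
    subgenome_block(label, random_dna(block_len)))
  g <- genome_state(label, blocks, ploidy = 2L, plastome = plastome,
                    plastome_lineage = label)
  for (j in seq_along(origins)) {
    g <- mobilome_burst(g, library, origins[j], copies_per_origin[j],
                        post_hybrid = FALSE, copy_divergence = copy_divergence)
  }
  g
}
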