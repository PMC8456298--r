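#' Read-sampling specification
#'
#' Encodes the sequencing-depth arithmetic C = L*N/G relating read length L,
#' read count N and haploid genome size G. Exactly one of `C` or `N` must be
#' given; the other is derived (N is rounded up, then C recomputed from the
#' emitted N so the identity holds exactly).
#'
#' @param L read length in bp (`> 0`).
#' @param G haploid genome size in bp (`> 0`).
#' @param C target coverage (optional if `N` given).
#' @param N number of reads (optional if `C` given).
#' @param paired emit mate pairs from opposite strands of an insert?
#' @param insert_len insert length in bp for paired mode.
#' @param seed integer seed used when drawing reads.
#' @return a list of class `"read_sampling_spec"`.
#' @export
read_sampling_spec <- function(L, G, C = NULL, N = NULL, paired = TRUE,
                               insert_len = 300L, seed = 1L) {
  stopifnot(L > 0, G > 0)
  if (is.null(N)) {
    if (is.null(C)) stop("give either C or N")
    N <- as.integer(ceiling(C * G / L))
  }
  if (paired && N %% 2L == 1L) N <- N + 1L  # whole mate pairs
  C <- L * N / G
  structure(list(L = as.integer(L), N = as.integer(N), G = as.numeric(G),
                 C = C, paired = isTRUE(paired),
                 insert_len = as.integer(insert_len), seed = as.integer(seed)),
            class = "read_sampling_spec")
}

#' Sequencing coverage from the C = LN/G formula
#'
#' @param L read length (bp).
#' @param N number of reads.
#' @param G haploid genome size (bp), `> 0`.
#' @return coverage `L * N / G`.
#' @export
coverage <- function(L, N, G) {
  if (any(G <= 0)) stop("G must be > 0")
  if (any(L < 0) || any(N < 0)) stop("L and N must be >= 0")
  L * N / G
}

# Flatten a genome into one string plus a global TE copy table and block
# origin lookup (1-based global coordinates).
flatten_genome <- function(g) {
  seqs <- vapply(g$blocks, `[[`, character(1), "sequence")
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  te <- do.call(rbind, lapply(seq_along(g$blocks), function(i) {
    t <- g$blocks[[i]]$te
    if (!nrow(t)) return(NULL)
    data.frame(family_id = t$family_id,
               start = t$start + offs[i] + 1L,   # 1-based inclusive
               end = t$end + offs[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(te)) te <- data.frame(family_id = character(0),
                                    start = integer(0), end = integer(0))
  te <- te[order(te$start), , drop = FALSE]
  list(sequence = paste(seqs, collapse = ""), te = te,
       block_starts = offs + 1L,
       block_labels = vapply(g$blocks, `[[`, character(1), "parent_label"))
}

# Majority-overlap truth label for read intervals [s, e] (1-based) against a
# sorted non-overlapping copy table. A read belongs to a family when a copy
# covers more than half the read; otherwise it is background.
label_reads <- function(starts, ends, te, min_frac = 0.5) {
  fam <- rep(NA_character_, length(starts))
  if (!nrow(te)) return(fam)
  L <- ends - starts + 1L
  for (off in 0:1) {
    idx <- findInterval(starts, te$start) + off
    ok <- idx >= 1L & idx <= nrow(te)
    ov <- rep(0L, length(starts))
    ov[ok] <- pmin(ends[ok], te$end[idx[ok]]) - pmax(starts[ok], te$start[idx[ok]]) + 1L
    hit <- ok & ov > L * min_frac & is.na(fam)
    fam[hit] <- te$family_id[idx[hit]]
  }
  fam
}

#' Sample low-coverage reads from a genome
#'
#' Draws reads uniformly along the concatenated nuclear sequence with random
#' strand. In paired mode, mates come from opposite strands of a fragment of
#' length `insert_len`. Every read is truth-labeled by majority overlap with
#' an annotated TE copy (family id) or `"background"`, and carries the
#' ancestral origin of the family (for repeat reads) or of the block at the
#' read midpoint (for background reads). Read identifiers are
#' `"<species>_<serial>/<mate>"`; the species prefix before the first
#' underscore is the contract consumed by the comparative clustering stage.
#'
#' @param g a [genome_state()].
#' @param spec a [read_sampling_spec()]; its `G` is ignored in favor of the
#'   actual genome length when `use_genome_size = TRUE` (default).
#' @param species_id species identifier (must not contain `"_"`).
#' @param use_genome_size recompute N from the genome's true length?
#' @return a list of class `"read_set"` with elements `reads` (data.frame:
#'   `read_id`, `species`, `sequence`, `mate`) and `truth` (data.frame:
#'   `read_id`, `species`, `family_id`, `origin`), plus the realized `spec`.
#' @export
sample_reads <- function(g, spec, species_id, use_genome_size = TRUE) {
  stopifnot(inherits(spec, "read_sampling_spec"))
  if (grepl("_", species_id, fixed = TRUE))
    stop("species_id must not contain '_'")
  fl <- flatten_genome(g)
  G <- nchar(fl$sequence)
  if (use_genome_size && abs(G - spec$G) > 0) {
    spec <- read_sampling_spec(L = spec$L, G = G, C = spec$C,
                               paired = spec$paired,
                               insert_len = spec$insert_len, seed = spec$seed)
  }
  L <- spec$L
  if (L > G) stop("read length exceeds genome length")
  set.seed(spec$seed)
  if (spec$paired) {
    ins <- min(spec$insert_len, G)
    n_frag <- spec$N %/% 2L
    fs <- sample.int(G - ins + 1L, n_frag, replace = TRUE)
    strand <- sample(c(TRUE, FALSE), n_frag, replace = TRUE)
    s1 <- fs; e1 <- fs + L - 1L
    s2 <- fs + ins - L; e2 <- fs + ins - 1L
    prox <- substring(fl$sequence, s1, e1)
    dist <- revcomp(substring(fl$sequence, s2, e2))
    # strand == FALSE: the fragment was sequenced from the minus strand, so
    # mate 1 is the distal (reverse-complemented) end
    r1 <- ifelse(strand, prox, dist)
    r2 <- ifelse(strand, dist, prox)
    starts <- c(rbind(ifelse(strand, s1, s2), ifelse(strand, s2, s1)))
    ends <- starts + L - 1L
    serial <- rep(seq_len(n_frag), each = 2L)
    mate <- rep(1:2, times = n_frag)
    seqs <- c(rbind(r1, r2))
    ids <- sprintf("%s_%06d/%d", species_id, serial, mate)
  } else {
    starts <- sample.int(G - L + 1L, spec$N, replace = TRUE)
    ends <- starts + L - 1L
    strand <- sample(c(TRUE, FALSE), spec$N, replace = TRUE)
    seqs <- substring(fl$sequence, starts, ends)
    seqs[!strand] <- revcomp(seqs[!strand])
    serial <- seq_len(spec$N)
    mate <- rep(0L, spec$N)
    ids <- sprintf("%s_%06d", species_id, serial)
  }
  fam <- label_reads(starts, ends, fl$te)
  origin <- sub("_.*$", "", fam)
  bg <- is.na(fam)
  mid_block <- findInterval((starts + ends) %/% 2L, fl$block_starts)
  origin[bg] <- fl$block_labels[pmax(1L, mid_block[bg])]
  fam[bg] <- "background"
  structure(list(
    reads = data.frame(read_id = ids, species = species_id, sequence = seqs,
                       mate = mate, stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, species = species_id, family_id = fam,
                       origin = origin, stringsAsFactors = FALSE),
    spec = spec), class = "read_set")
}

#' Write reads as FASTQ (phred-33, constant quality)
#'
#' @param read_set a [sample_reads()] result or a reads data.frame.
#' @param path output file.
#' @param qual_char quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(read_set, path, qual_char = "I") {
  rd <- if (inherits(read_set, "read_set")) read_set$reads else read_set
  rec <- paste0("@", rd$read_id, "\n", rd$sequence, "\n+\n",
                strrep(qual_char, nchar(rd$sequence)))
  writeLines(rec, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Wraps [Biostrings::readDNAStringSet()]; the format is inferred from the
#' file extension (`.fq`/`.fastq`, optionally gzipped, are read as FASTQ).
#'
#' @param path input file.
#' @return named character vector of sequences (names = read ids).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
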