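#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases over A/C/G/T. Used to build ancestral genome blocks,
#' repeat-family consensus sequences and plastome haplotypes.
#'
#' @param n sequence length in bp.
#' @param seed optional integer seed (RNG is left untouched if `NULL`).
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Mutate a sequence by i.i.d. substitution
#'
#' Jukes-Cantor-style site-independent substitution: every site is replaced,
#' with probability `d` (capped at 0.75, the saturation divergence for four
#' equifrequent bases), by one of the three other bases chosen uniformly.
#' Length is preserved; no indels are introduced, so sets of sequences derived
#' from a common ancestor stay positionally aligned.
#'
#' @param seq a single DNA string.
#' @param d expected substitutions per site, `>= 0`.
#' @param seed optional integer seed for reproducibility.
#' @return the mutated sequence (same length).
#' @export
mutate_sequence <- function(seq, d, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("substitution rate 'd' must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  p <- min(d, 0.75)
  n <- nchar(seq)
  if (p == 0 || n == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(n) < p)
  if (length(hit)) {
    cur <- match(x[hit], BASES)
    if (anyNA(cur)) stop("sequence contains characters outside {A,C,G,T}")
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

# Stable seed derivation: one master seed, per-(node, event) streams obtained
# by hashing the string form of the arguments. Keeps every simulator stage
# reproducible and independent of evaluation order. Result is < 2^31.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# k-mers of a sequence in canonical (strand-free) form: for each window the
# lexicographic min of the k-mer and its reverse complement.
canonical_kmers <- function(seq, k = 15L, stride = 1L, rc_all = NULL) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  fwd <- substring(seq, starts, starts + k - 1L)
  if (is.null(rc_all)) rc_all <- revcomp(seq)
  # forward window [s, s+k-1] maps to [n-s-k+2, n-s+1] on the reverse strand
  rc <- substring(rc_all, n - (starts + k - 1L) + 1L, n - starts + 1L)
  pmin(fwd, rc)
}
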