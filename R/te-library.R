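SUPERFAMILIES <- c("Gypsy", "Copia", "DNA", "simple", "other")

#' Construct a repeat-family library
#'
#' A library of named consensus sequences with superfamily labels and the
#' ancestral genome each family originates from. Family abundance weights
#' (relative propensity to amplify) are carried alongside so that
#' amplification bursts can re-sample a realistic abundance profile.
#'
#' @param family_id unique family identifiers.
#' @param superfamily one of `"Gypsy"`, `"Copia"`, `"DNA"`, `"simple"`,
#'   `"other"` per family.
#' @param origin ancestral-genome label per family.
#' @param consensus DNA consensus sequence per family (non-empty, A/C/G/T).
#' @param weight positive relative abundance weight per family.
#' @return a `data.frame` of class `"te_library"`.
#' @export
te_library <- function(family_id, superfamily, origin, consensus,
                       weight = rep(1, length(family_id))) {
  if (anyDuplicated(family_id)) stop("family_id must be unique within a library")
  if (!all(superfamily %in% SUPERFAMILIES))
    stop("superfamily must be one of: ", paste(SUPERFAMILIES, collapse = ", "))
  if (any(nchar(consensus) == 0L)) stop("consensus sequences must be non-empty")
  if (any(grepl("[^ACGT]", consensus))) stop("consensus must be over {A,C,G,T}")
  lib <- data.frame(
    family_id = as.character(family_id),
    superfamily = as.character(superfamily),
    origin = as.character(origin),
    consensus = as.character(consensus),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("te_library", "data.frame")
  lib
}

#' Generate a random mobilome for one ancestral genome
#'
#' Draws `n_families` consensus sequences with a configurable superfamily
#' composition (default mirrors the class proportions typical of abundant
#' plant repeat clusters: mostly LTR retrotransposons). `simple` families are
#' tandem arrays of a short random motif; all others are random interspersed
#' consensus sequences. Per-family abundance weights are log-uniform so a
#' minority of families dominates genome repeat content.
#'
#' @param origin ancestral genome label, used to prefix family ids.
#' @param n_families number of families.
#' @param proportions named numeric vector of superfamily proportions.
#' @param len_range consensus length range in bp for interspersed families.
#' @param seed optional integer seed.
#' @return a [te_library()].
#' @export
random_te_library <- function(origin, n_families = 30,
                              proportions = c(Gypsy = 0.40, Copia = 0.25,
                                              DNA = 0.20, simple = 0.10,
                                              other = 0.05),
                              len_range = c(300, 800), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_families >= 1, all(names(proportions) %in% SUPERFAMILIES))
  counts <- diff(c(0L, round(cumsum(proportions / sum(proportions)) * n_families)))
  sf <- rep(names(proportions), counts)
  cons <- character(n_families)
  for (i in seq_len(n_families)) {
    if (sf[i] == "simple") {
      motif <- random_dna(sample(5:12, 1L))
      reps <- ceiling(stats::runif(1, 200, 600) / nchar(motif))
      cons[i] <- substr(strrep(motif, reps), 1L, 200L + sample.int(400L, 1L))
    } else {
      cons[i] <- random_dna(sample(seq(len_range[1], len_range[2]), 1L))
    }
  }
  w <- exp(stats::runif(n_families, log(1), log(4)))
  te_library(
    family_id = sprintf("%s_fam%02d", origin, seq_len(n_families)),
    superfamily = sf, origin = origin, consensus = cons, weight = w
  )
}

#' Derive an ancestor-specific copy of a family library
#'
#' Mutates every consensus by `d` expected substitutions per site and
#' relabels families with the new origin. Applying this independently to two
#' ancestors separates their mobilomes by roughly twice `d`, which at the
#' default 0.30 leaves pairwise identity near 0.5 -- far below any clustering
#' threshold, so families from different ancestors never co-cluster.
#'
#' @param lib a [te_library()] of base family templates.
#' @param origin new ancestral genome label.
#' @param d per-ancestor divergence (expected substitutions/site).
#' @param seed optional integer seed.
#' @return a [te_library()] with family ids prefixed by `origin`.
#' @export
diverge_library <- function(lib, origin, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cons <- vapply(lib$consensus, mutate_sequence, character(1), d = d,
                 USE.NAMES = FALSE)
  te_library(
    family_id = sub("^[^_]*_", paste0(origin, "_"), lib$family_id),
    superfamily = lib$superfamily, origin = origin,
    consensus = cons, weight = lib$weight
  )
}
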