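# Build the concrete family library a scenario describes. Ancestor-specific
# families are derived from common base templates by per-ancestor divergence;
# the shared "ancestral" families keep one consensus across all genomes.
build_scenario_library <- function(s, master_seed) {
  spec <- s$library_spec
  libs <- list()
  if (!is.null(spec$per_origin)) {
    # independent family sets per origin (lineage-specific family births)
    for (o in names(spec$per_origin)) {
      libs[[o]] <- random_te_library(
        o, n_families = spec$per_origin[[o]],
        seed = derive_seed(master_seed, "telib", o))
    }
    out <- do.call(rbind, libs)
    rownames(out) <- NULL
    class(out) <- c("te_library", "data.frame")
    return(out)
  }
  if (spec$families_per_ancestor > 0) {
    base <- random_te_library("BASE", n_families = spec$families_per_ancestor,
                              seed = derive_seed(master_seed, "telib", "base"))
    for (o in spec$origins) {
      libs[[o]] <- if (spec$ancestor_divergence > 0) {
        diverge_library(base, o, spec$ancestor_divergence,
                        seed = derive_seed(master_seed, "telib", o))
      } else {
        # single-ancestor scenarios: the base library itself, relabeled
        te_library(sub("^BASE_", paste0(o, "_"), base$family_id),
                   base$superfamily, o, base$consensus, base$weight)
      }
    }
  }
  if (spec$n_ancestral_families > 0) {
    libs[["ANC"]] <- random_te_library(
      "ANC", n_families = spec$n_ancestral_families,
      seed = derive_seed(master_seed, "telib", "ANC"))
  }
  out <- do.call(rbind, libs)
  rownames(out) <- NULL
  class(out) <- c("te_library", "data.frame")
  out
}

#' Simulate a scenario end to end
#'
#' Walks the lineage graph root-to-tips: genesis nodes receive fresh diploid
#' genomes with their ancestral mobilome, descent branches apply i.i.d.
#' substitution to nuclear and plastid sequence, hybridization nodes merge
#' parents with maternal plastome inheritance, and the per-node events
#' (amplification bursts, biased fractionation) run in their listed order.
#' Every tip species then yields paired reads at its configured coverage
#' with full truth labels. All randomness derives from `master_seed` via
#' per-(node, event) streams, so two runs with the same seed are identical.
#'
#' @param s a [scenario()].
#' @param master_seed integer master seed.
#' @param out_dir optional directory: per-species FASTQ, genome FASTA, one
#'   plastome FASTA, a combined truth TSV and the family library FASTA are
#'   written there.
#' @return a list of class `"ssa_simulation"`: `read_sets` (named list of
#'   [sample_reads()] results), `genomes` (tip genome states), `plastomes`
#'   (named character incl. the outgroup), `truth` (combined data.frame),
#'   `library`, `scenario`, `seed`.
#' @export
simulate_scenario <- function(s, master_seed, out_dir = NULL) {
  validate_scenario(s)
  lib <- build_scenario_library(s, master_seed)
  base_plastome <- random_dna(s$plastome_len,
                              seed = derive_seed(master_seed, "plastome"))
  genomes <- list()
  read_sets <- list()
  tip_genomes <- list()
  plastomes <- character(0)
  sp_par <- s$species_params
  for (nd in s$nodes) {
    g <- switch(nd$kind,
      genesis = {
        gen <- nd$genesis
        g0 <- build_ancestor_genome(
          gen$label, lib, gen$origins, gen$copies,
          n_blocks = gen$n_blocks, block_len = s$block_len,
          plastome = mutate_sequence(
            base_plastome, nd$branch,
            seed = derive_seed(master_seed, nd$id, "plastome")),
          copy_divergence = s$copy_divergence,
          seed = derive_seed(master_seed, nd$id, "genesis"))
        g0
      },
      descend = evolve_genome(genomes[[nd$parents]], nd$branch,
                              seed = derive_seed(master_seed, nd$id, "branch")),
      hybrid = {
        pa <- genomes[[nd$parents[1L]]]
        pb <- genomes[[nd$parents[2L]]]
        mat <- if (identical(nd$maternal, nd$parents[1L])) pa$label
               else if (identical(nd$maternal, nd$parents[2L])) pb$label
               else nd$maternal
        hybridize(pa, pb, mat, label = nd$id)
      },
      stop("unknown node kind: ", nd$kind))
    for (i in seq_along(nd$events)) {
      ev <- nd$events[[i]]
      ev_seed <- derive_seed(master_seed, nd$id, "event", i)
      g <- switch(ev$kind,
        te_burst = mobilome_burst(g, lib, ev$origin, ev$total_copies,
                                  post_hybrid = isTRUE(ev$post_hybrid),
                                  copy_divergence = s$copy_divergence,
                                  weight_jitter_sd = ev$jitter %||% 0,
                                  seed = ev_seed),
        fractionation = fractionate(g, ev$removed_parent, ev$f,
                                    seed = ev_seed),
        stop("unknown event kind: ", ev$kind))
    }
    genomes[[nd$id]] <- g
    if (isTRUE(nd$emit_plastome)) {
      nm <- if (isTRUE(nd$tip)) nd$species else nd$id
      plastomes[[nm]] <- g$plastome
    }
    if (isTRUE(nd$tip)) {
      par_row <- sp_par[sp_par$species == nd$species, , drop = FALSE]
      if (!nrow(par_row)) stop("no species_params for tip ", nd$species)
      spec <- read_sampling_spec(
        L = par_row$read_len, G = genome_length(g), C = par_row$coverage,
        paired = TRUE, insert_len = s$insert_len,
        seed = derive_seed(master_seed, nd$id, "reads"))
      read_sets[[nd$species]] <- sample_reads(g, spec, nd$species)
      tip_genomes[[nd$species]] <- g
    }
  }
  truth <- do.call(rbind, lapply(names(read_sets), function(sp) {
    t <- read_sets[[sp]]$truth
    t$clade <- s$clade_map[[sp]]
    t
  }))
  rownames(truth) <- NULL
  sim <- structure(list(read_sets = read_sets, genomes = tip_genomes,
                        plastomes = plastomes, truth = truth, library = lib,
                        scenario = s, seed = master_seed),
                   class = "ssa_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssa_simulation <- function(x, ...) {
  n_reads <- sum(vapply(x$read_sets, function(r) nrow(r$reads), numeric(1)))
  cat(sprintf("<ssa_simulation> %d species, %s reads, %d repeat families, seed %d\n",
              length(x$read_sets), format(n_reads, big.mark = ","),
              nrow(x$library), x$seed))
  invisible(x)
}

#' Write simulation artifacts to disk
#'
#' Emits per-species FASTQ (phred-33), per-species genome FASTA, a single
#' aligned plastome FASTA, the family library FASTA, and a combined truth
#' TSV (`read_id`, `species`, `clade`, `family_id`, `origin_genome`).
#'
#' @param sim an `"ssa_simulation"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$read_sets)) {
    write_fastq(sim$read_sets[[sp]], file.path(dir, paste0(sp, ".fastq")))
    fl <- flatten_genome(sim$genomes[[sp]])
    write_fasta(stats::setNames(fl$sequence, sp),
                file.path(dir, paste0(sp, "_genome.fasta")))
  }
  write_fasta(sim$plastomes, file.path(dir, "plastomes.fasta"))
  write_fasta(stats::setNames(sim$library$consensus, sim$library$family_id),
              file.path(dir, "te_library.fasta"))
  tr <- sim$truth
  names(tr)[names(tr) == "origin"] <- "origin_genome"
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
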