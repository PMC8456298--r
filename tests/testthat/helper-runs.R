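# Memoized pipeline evaluations shared across test files. The
# default-scenario runs are the study conditions (4 clades x 4 species,
# 2-8 Mb genomes, coverages 0.5-5.1x); each is computed once per seed,
# scored against its simulation truth, and only the slim evaluation (not
# the full report with reads and genomes) is kept, so five cached runs fit
# comfortably in memory.
.run_cache <- new.env(parent = emptyenv())

# Full pipeline runs execute in a fresh subprocess when callr is available:
# the peak working set of a run (reads, k-mer index) is then returned to
# the OS between seeds instead of fragmenting one long-lived R heap.
run_slim <- function(kind, seed) {
  worker <- function(kind, seed) {
    library(mobdiv)
    cfg <- if (kind == "null") {
      pipeline_config(scenario = null_scenario(), seed = seed)
    } else {
      pipeline_config(seed = seed)
    }
    rep <- suppressMessages(run_pipeline(cfg))
    sc <- verify_report(rep)
    list(scorecard = sc, superfamily = rep$superfamily,
         top_clusters = rep$top_clusters, top_fraction = rep$top_fraction,
         venn = rep$venn, grouping = rep$grouping)
  }
  if (requireNamespace("callr", quietly = TRUE)) {
    callr::r(worker, args = list(kind = kind, seed = seed))
  } else {
    out <- worker(kind, seed)
    gc(verbose = FALSE)
    out
  }
}

get_default_eval <- function(seed) {
  key <- paste0("default_", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_slim("default", seed)
  .run_cache[[key]]
}

get_null_eval <- function(seed = 42) {
  key <- paste0("null_", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_slim("null", seed)
  .run_cache[[key]]
}

# A small, fast simulation for unit-level checks of simulator outputs.
get_small_sim <- function(seed = 7) {
  key <- paste0("smallsim_", seed)
  if (is.null(.run_cache[[key]])) {
    s <- default_scenario(n_species_per_clade = 2, block_len = 8000,
                          n_blocks = c(H = 6, C = 7, D = 6),
                          genesis_copies = 60, ancestral_copies = 16,
                          burst_tw = 10, burst_nwb = 80, burst_ag2 = 40,
                          burst_ag3 = 30, burst_pwb = 40, burst_aru = 30,
                          burst_clade = 30, burst_oly = 20,
                          burst_tip = 8, plastome_len = 4000)
    .run_cache[[key]] <- simulate_scenario(s, seed)
  }
  .run_cache[[key]]
}
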