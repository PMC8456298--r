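CLADES <- c("Olyreae", "Arundinarieae", "NWB", "PWB")

# Node constructor used by scenario builders. Node kinds:
#  - genesis: a new diploid ancestor (blocks + genesis mobilome)
#  - descend: inherit from one parent, mutating by `branch` subs/site
#  - hybrid:  merge two parents (maternal plastome inheritance)
# Events (applied in order after inheritance): mobilome_burst, fractionate.
scn_node <- function(id, kind, parents = character(0), branch = 0,
                     maternal = NULL, genesis = NULL, events = list(),
                     tip = FALSE, species = NULL, emit_plastome = tip) {
  list(id = id, kind = kind, parents = parents, branch = branch,
       maternal = maternal, genesis = genesis, events = events,
       tip = tip, species = species, emit_plastome = emit_plastome)
}

ev_burst <- function(origin, total_copies, post_hybrid = FALSE, jitter = 0) {
  list(kind = "te_burst", origin = origin, total_copies = total_copies,
       post_hybrid = post_hybrid, jitter = jitter)
}
ev_fractionate <- function(removed_parent, f) {
  list(kind = "fractionation", removed_parent = removed_parent, f = f)
}

#' Default evolutionary scenario: hybrid origins of the woody bamboo clades
#'
#' Encodes the bamboo origins model: three diploid ancestors -- a herbaceous
#' H genome (ancestor of the Olyreae) and two woody genomes C and D -- plus a
#' small set of families shared by all ancestors (ancient, still-active
#' repeat families). The tropical woody ancestor arises from an ancient
#' hybridization between a maternal H and a paternal C genome; its H
#' subgenome is then lost by biased fractionation, but H-mobilome elements
#' that transposed into the retained C blocks after the hybridization
#' survive. The tropical woody lineage splits into the Neotropical (NWB) and
#' Paleotropical (PWB) woody bamboos: the NWB lineage undergoes further
#' rounds of hybridization with the herbaceous lineage (re-acquiring its
#' mobilome, with an extra round in the Arthrostylidiinae+Guaduinae
#' sublineage), while the PWB lineage hybridizes with the D genome followed
#' by fractionation in favor of C. The temperate Arundinarieae arise
#' independently as a C x D allotetraploid. Consequences the pipeline should
#' recover: all Olyreae, NWB and PWB tips share the maternal H plastome while
#' Arundinarieae do not; repeat content pairs Olyreae with NWB and
#' Arundinarieae with PWB.
#'
#' @param n_species_per_clade tips per clade (default 4).
#' @param block_len subgenome block length in bp (fractionation unit).
#' @param n_blocks named vector: background blocks per ancestor (H, C, D).
#' @param families_per_ancestor distinctive families per ancestral mobilome.
#' @param n_ancestral_families families shared by all ancestors.
#' @param ancestor_divergence per-ancestor consensus divergence from the base
#'   family templates (substitutions/site).
#' @param copy_divergence within-family copy divergence.
#' @param fractionation_f removal probability for fractionated subgenomes in
#'   the main (complete-loss) events.
#' @param ag_retention_f removal probability in the final, incomplete
#'   fractionation of the Arthrostylidiinae+Guaduinae lineage (< 1 leaves
#'   residual herbaceous blocks and keeps the lineage tetraploid).
#' @param genesis_copies TE copies seeded per ancestor from its own mobilome
#'   (scalar or named vector over H, C, D).
#' @param ancestral_copies TE copies seeded from the shared ancient families.
#' @param burst_tw,burst_nwb,burst_ag2,burst_ag3,burst_pwb,burst_aru,burst_tip
#'   copy totals of the amplification bursts tied to each event (see
#'   vignette).
#' @param burst_clade,burst_oly clade-ancestor amplification of the
#'   lineage's own mobilome with a lineage-specific signature (independent
#'   differential amplification between extant lineages).
#' @param read_len,insert_len read and insert length in bp.
#' @param coverages optional named list of per-clade coverage vectors; the
#'   default spans 0.5-5.1x with median near 1.3x.
#' @param plastome_len plastome length in bp.
#' @return a list of class `"scenario"`.
#' @export
default_scenario <- function(n_species_per_clade = 4,
                             block_len = 50000,
                             n_blocks = c(H = 34, C = 38, D = 34),
                             families_per_ancestor = 30,
                             n_ancestral_families = 8,
                             ancestor_divergence = 0.30,
                             copy_divergence = 0.05,
                             fractionation_f = 1.0,
                             ag_retention_f = 0.85,
                             genesis_copies = c(H = 900, C = 540, D = 780),
                             ancestral_copies = 120,
                             burst_tw = 12, burst_nwb = 1000,
                             burst_ag2 = 150, burst_ag3 = 120,
                             burst_pwb = 1500, burst_aru = 750,
                             burst_clade = 500, burst_oly = 375,
                             burst_tip = 60,
                             read_len = 150, insert_len = 300,
                             coverages = NULL, plastome_len = 20000) {
  k <- n_species_per_clade
  if (length(genesis_copies) == 1L)
    genesis_copies <- c(H = genesis_copies, C = genesis_copies,
                        D = genesis_copies)
  if (is.null(coverages)) {
    coverages <- list(
      Olyreae       = c(5.1, 1.0, 1.4, 2.2, 1.2, 1.7)[seq_len(k)],
      Arundinarieae = c(0.5, 0.9, 1.3, 1.8, 1.1, 1.5)[seq_len(k)],
      NWB           = c(0.7, 1.1, 1.6, 2.4, 0.9, 1.4)[seq_len(k)],
      PWB           = c(0.8, 1.2, 1.5, 2.0, 1.0, 1.3)[seq_len(k)]
    )
  }
  species <- list(
    Olyreae = sprintf("Oly%d", seq_len(k)),
    Arundinarieae = sprintf("Aru%d", seq_len(k)),
    NWB = sprintf("Nwb%d", seq_len(k)),
    PWB = sprintf("Pwb%d", seq_len(k))
  )
  f <- fractionation_f
  nodes <- list(
    scn_node("OUT", "genesis", branch = 0.10,
             genesis = list(label = "O", origins = "ANC",
                            copies = ancestral_copies / 2,
                            n_blocks = 10),
             emit_plastome = TRUE),
    scn_node("H0", "genesis", branch = 0.04,
             genesis = list(label = "H", origins = c("H", "ANC"),
                            copies = c(genesis_copies[["H"]], ancestral_copies),
                            n_blocks = unname(n_blocks["H"]))),
    scn_node("C0", "genesis", branch = 0.04,
             genesis = list(label = "C", origins = c("C", "ANC"),
                            copies = c(genesis_copies[["C"]], ancestral_copies),
                            n_blocks = unname(n_blocks["C"]))),
    scn_node("D0", "genesis", branch = 0.04,
             genesis = list(label = "D", origins = c("D", "ANC"),
                            copies = c(genesis_copies[["D"]], ancestral_copies),
                            n_blocks = unname(n_blocks["D"]))),
    # herbaceous lineage: serial donors for the successive hybridizations.
    # Nuclear branch lengths are short: the families that dominate repeat
    # clusters are recently amplified, so within-family identity stays high
    # even across clades that exchanged mobilomes.
    scn_node("H1", "descend", parents = "H0", branch = 0.002),
    scn_node("H2", "descend", parents = "H1", branch = 0.002),
    scn_node("H3", "descend", parents = "H2", branch = 0.002),
    scn_node("H4", "descend", parents = "H3", branch = 0.002),
    scn_node("OLY", "descend", parents = "H4", branch = 0.002,
             events = list(ev_burst("H", burst_oly, jitter = 0.3))),
    # woody C/D lineage sampling points
    scn_node("C1", "descend", parents = "C0", branch = 0.002),
    scn_node("C2", "descend", parents = "C0", branch = 0.004),
    scn_node("D1", "descend", parents = "D0", branch = 0.004),
    scn_node("D2", "descend", parents = "D0", branch = 0.006),
    # ancient hybridization: maternal H x paternal C, then biased
    # fractionation removes the H subgenome; a small post-hybridization burst
    # of H elements survives in the retained C blocks
    scn_node("TW", "hybrid", parents = c("H1", "C1"), maternal = "H",
             events = list(ev_burst("H", burst_tw, post_hybrid = TRUE),
                           ev_fractionate("H", f))),
    # shared tropical-woody stem: gives the {NWB, PWB} plastome split a
    # positive internal branch before the two lineages separate
    scn_node("TWd", "descend", parents = "TW", branch = 0.005),
    scn_node("NWBstem", "descend", parents = "TWd", branch = 0.005),
    scn_node("PWBstem", "descend", parents = "TWd", branch = 0.005),
    # NWB: renewed hybridization with the herbaceous lineage (event 1),
    # massive H mobilome re-entry, fractionation
    scn_node("NWB", "hybrid", parents = c("NWBstem", "H2"),
             maternal = "NWBstem",
             events = list(ev_burst("H", burst_nwb, post_hybrid = TRUE),
                           ev_fractionate("H", f),
                           ev_burst("C", burst_clade, jitter = 1.0))),
    scn_node("CHU", "descend", parents = "NWB", branch = 0.005),
    scn_node("AGstem", "descend", parents = "NWB", branch = 0.004),
    # Arthrostylidiinae+Guaduinae: two further rounds with the herbaceous
    # lineage (events 2 and 3); the last fractionation is incomplete so the
    # extant lineage stays tetraploid with residual H blocks
    scn_node("AG2", "hybrid", parents = c("AGstem", "H3"),
             maternal = "AGstem",
             events = list(ev_burst("H", burst_ag2, post_hybrid = TRUE),
                           ev_fractionate("H", f))),
    scn_node("AG", "hybrid", parents = c("AG2", "H4"), maternal = "AG2",
             events = list(ev_burst("H", burst_ag3, post_hybrid = TRUE),
                           ev_fractionate("H", ag_retention_f))),
    # PWB: hybridization with the D genome, biased fractionation in favor of
    # C; D mobilome survives as post-hybridization insertions
    scn_node("PWB", "hybrid", parents = c("PWBstem", "D2"),
             maternal = "PWBstem",
             events = list(ev_burst("D", burst_pwb, post_hybrid = TRUE,
                                    jitter = 0.8),
                           ev_fractionate("D", f),
                           ev_burst("C", burst_clade, jitter = 1.0))),
    # temperate clade: straightforward C x D allotetraploid, no maternal H;
    # the merger reactivates the D mobilome (genome-shock amplification)
    scn_node("ARU", "hybrid", parents = c("C2", "D1"), maternal = "C",
             events = list(ev_burst("D", burst_aru, post_hybrid = TRUE,
                                    jitter = 0.8),
                           ev_burst("C", burst_clade, jitter = 1.0)))
  )
  tips <- list()
  tip_parent <- c(Olyreae = "OLY", Arundinarieae = "ARU", PWB = "PWB")
  for (clade in CLADES) {
    for (i in seq_len(k)) {
      sp <- species[[clade]][i]
      parent <- if (clade == "NWB") {
        # half the NWB tips from each sublineage (Chusqueinae-like vs
        # Arthrostylidiinae+Guaduinae-like)
        if (i <= ceiling(k / 2)) "CHU" else "AG"
      } else tip_parent[[clade]]
      own <- switch(clade, Olyreae = "H", Arundinarieae = "C",
                    NWB = "C", PWB = "C")
      tips[[length(tips) + 1L]] <- scn_node(
        paste0("tip_", sp), "descend", parents = parent, branch = 0.004,
        events = list(ev_burst(own, burst_tip, jitter = 0.5)),
        tip = TRUE, species = sp)
    }
  }
  clade_map <- stats::setNames(rep(CLADES, each = k), unlist(species[CLADES]))
  params <- data.frame(
    species = unlist(species[CLADES]),
    clade = rep(CLADES, each = k),
    coverage = unlist(coverages[CLADES]),
    read_len = read_len, stringsAsFactors = FALSE)
  scenario(
    nodes = c(nodes, tips), clade_map = clade_map, species_params = params,
    library_spec = list(families_per_ancestor = families_per_ancestor,
                        n_ancestral_families = n_ancestral_families,
                        ancestor_divergence = ancestor_divergence,
                        origins = c("H", "C", "D")),
    copy_divergence = copy_divergence, block_len = block_len,
    plastome_len = plastome_len, insert_len = insert_len,
    outgroup = "OUT")
}

#' Null scenario: vertical descent without hybridization
#'
#' Four clades diverging from a single diploid ancestor along the species
#' tree ((Olyreae, NWB), (Arundinarieae, PWB)), with no hybridization, no
#' allopolyploidy and no fractionation. Lineage-specific repeat families
#' arise on the two deep stems and in each clade ancestor and are inherited
#' vertically, so the repeat profile carries the species-tree signal the
#' same way shared subgenomes do in [default_scenario()]. Under this
#' control both the plastome tree and the repeat dendrogram track the same
#' species tree, so the clade-collapsed topologies agree -- the cytonuclear
#' conflict seen under [default_scenario()] is attributable to the
#' hybridization events.
#'
#' @inheritParams default_scenario
#' @param n_base_families ancestral families present in every lineage.
#' @param n_stem_families families born on each deep stem (shared by the
#'   two clades that descend from it).
#' @param n_clade_families families born in each clade ancestor.
#' @param base_copies,stem_copies,clade_copies genesis/burst copy totals
#'   for the three family classes.
#' @param burst_tip per-tip amplification (noise).
#' @return a list of class `"scenario"`.
#' @export
null_scenario <- function(n_species_per_clade = 3,
                          block_len = 50000,
                          n_base_families = 16,
                          n_stem_families = 8,
                          n_clade_families = 6,
                          copy_divergence = 0.05,
                          base_copies = 200, stem_copies = 200,
                          clade_copies = 300, burst_tip = 30,
                          read_len = 150, insert_len = 300,
                          plastome_len = 20000) {
  k <- n_species_per_clade
  species <- list(
    Olyreae = sprintf("Oly%d", seq_len(k)),
    Arundinarieae = sprintf("Aru%d", seq_len(k)),
    NWB = sprintf("Nwb%d", seq_len(k)),
    PWB = sprintf("Pwb%d", seq_len(k))
  )
  clade_origin <- c(Olyreae = "OLYf", Arundinarieae = "ARUf",
                    NWB = "NWBf", PWB = "PWBf")
  nodes <- list(
    scn_node("OUT", "genesis", branch = 0.10,
             genesis = list(label = "O", origins = "B", copies = 60,
                            n_blocks = 10), emit_plastome = TRUE),
    scn_node("B0", "genesis", branch = 0.02,
             genesis = list(label = "B", origins = "B",
                            copies = base_copies, n_blocks = 30)),
    # new families arise on the deep stems and in the clade ancestors and
    # are inherited by every descendant
    scn_node("ON", "descend", parents = "B0", branch = 0.004,
             events = list(ev_burst("ONf", stem_copies))),
    scn_node("AP", "descend", parents = "B0", branch = 0.004,
             events = list(ev_burst("APf", stem_copies))),
    scn_node("OLY", "descend", parents = "ON", branch = 0.004,
             events = list(ev_burst("OLYf", clade_copies))),
    scn_node("NWB", "descend", parents = "ON", branch = 0.004,
             events = list(ev_burst("NWBf", clade_copies))),
    scn_node("ARU", "descend", parents = "AP", branch = 0.004,
             events = list(ev_burst("ARUf", clade_copies))),
    scn_node("PWB", "descend", parents = "AP", branch = 0.004,
             events = list(ev_burst("PWBf", clade_copies)))
  )
  tip_parent <- c(Olyreae = "OLY", Arundinarieae = "ARU",
                  NWB = "NWB", PWB = "PWB")
  tips <- list()
  for (clade in CLADES) {
    for (i in seq_len(k)) {
      sp <- species[[clade]][i]
      tips[[length(tips) + 1L]] <- scn_node(
        paste0("tip_", sp), "descend", parents = tip_parent[[clade]],
        branch = 0.003,
        events = list(ev_burst(clade_origin[[clade]], burst_tip,
                               jitter = 0.5)),
        tip = TRUE, species = sp)
    }
  }
  clade_map <- stats::setNames(rep(CLADES, each = k), unlist(species[CLADES]))
  params <- data.frame(
    species = unlist(species[CLADES]),
    clade = rep(CLADES, each = k),
    coverage = rep(c(1.0, 1.4, 2.0, 1.2, 1.6, 1.1)[seq_len(k)], 4),
    read_len = read_len, stringsAsFactors = FALSE)
  per_origin <- c(B = n_base_families, ONf = n_stem_families,
                  APf = n_stem_families,
                  OLYf = n_clade_families, NWBf = n_clade_families,
                  ARUf = n_clade_families, PWBf = n_clade_families)
  scenario(
    nodes = c(nodes, tips), clade_map = clade_map, species_params = params,
    library_spec = list(per_origin = as.list(per_origin),
                        families_per_ancestor = 0,
                        n_ancestral_families = 0,
                        ancestor_divergence = 0, origins = names(per_origin)),
    copy_divergence = copy_divergence, block_len = block_len,
    plastome_len = plastome_len, insert_len = insert_len,
    outgroup = "OUT")
}

#' Construct and validate a scenario
#'
#' @param nodes list of scenario nodes in topological order (parents before
#'   children).
#' @param clade_map named character vector, species -> clade.
#' @param species_params data.frame with `species`, `clade`, `coverage`,
#'   `read_len`.
#' @param library_spec how to build the concrete family library at
#'   simulation time.
#' @param copy_divergence,block_len,plastome_len,insert_len simulator scales.
#' @param outgroup id of the plastome-only outgroup node, or `NULL`.
#' @return a list of class `"scenario"`.
#' @export
scenario <- function(nodes, clade_map, species_params, library_spec,
                     copy_divergence = 0.05, block_len = 50000,
                     plastome_len = 20000, insert_len = 300,
                     outgroup = NULL) {
  s <- structure(list(nodes = nodes, clade_map = clade_map,
                      species_params = species_params,
                      library_spec = library_spec,
                      copy_divergence = copy_divergence,
                      block_len = block_len, plastome_len = plastome_len,
                      insert_len = insert_len, outgroup = outgroup),
                 class = "scenario")
  validate_scenario(s)
  s
}

#' Validate scenario invariants
#'
#' Checks topological ordering, that every hybridization names two lineages
#' already extant and a maternal parent among them, that branch lengths are
#' non-negative, and that the clade map covers every tip species.
#'
#' @param s a [scenario()].
#' @return `s`, invisibly; errors on violation.
#' @export
validate_scenario <- function(s) {
  seen <- character(0)
  tip_species <- character(0)
  for (nd in s$nodes) {
    if (any(duplicated(c(seen, nd$id)))) stop("duplicate node id: ", nd$id)
    if (!all(nd$parents %in% seen))
      stop("node '", nd$id, "' references lineages not yet defined ",
           "(inconsistent event ordering)")
    if (!is.null(nd$branch) && nd$branch < 0)
      stop("negative branch length at node '", nd$id, "'")
    if (nd$kind == "hybrid") {
      if (length(nd$parents) != 2L)
        stop("hybridization at '", nd$id, "' must name two parent lineages")
      if (is.null(nd$maternal))
        stop("hybridization at '", nd$id, "' must name a maternal parent")
    }
    for (ev in nd$events) {
      if (ev$kind == "fractionation" && (ev$f < 0 || ev$f > 1))
        stop("fractionation probability out of [0,1] at '", nd$id, "'")
      if (ev$kind == "te_burst" && ev$total_copies < 0)
        stop("negative burst size at '", nd$id, "'")
    }
    if (isTRUE(nd$tip)) tip_species <- c(tip_species, nd$species)
    seen <- c(seen, nd$id)
  }
  if (!all(tip_species %in% names(s$clade_map)))
    stop("clade_map does not cover all tip species")
  if (!all(s$clade_map %in% CLADES))
    stop("clades must be among: ", paste(CLADES, collapse = ", "))
  invisible(s)
}

#' @export
print.scenario <- function(x, ...) {
  tips <- sum(vapply(x$nodes, function(n) isTRUE(n$tip), logical(1)))
  cat(sprintf("<scenario> %d nodes, %d tip species in %d clades\n",
              length(x$nodes), tips, length(unique(x$clade_map))))
  invisible(x)
}

#' Symbolic lineage summary (plastome ancestry and ploidy bookkeeping)
#'
#' Traverses the scenario graph without simulating sequence, following the
#' maternal parent through each hybridization and applying the ploidy rules
#' (ploidy sums at hybridization; a complete fractionation of one subgenome
#' decrements it by 2). Serves as an independent check on the simulator's
#' per-tip plastome lineage and ploidy.
#'
#' @param s a [scenario()].
#' @return data.frame with one row per tip: `species`, `clade`,
#'   `plastome_lineage`, `ploidy`.
#' @export
scenario_lineage_summary <- function(s) {
  state <- list()
  rows <- list()
  for (nd in s$nodes) {
    st <- switch(nd$kind,
      genesis = list(plastome_lineage = nd$genesis$label, ploidy = 2L,
                     subgenomes = nd$genesis$label),
      descend = state[[nd$parents]],
      hybrid = {
        a <- state[[nd$parents[1L]]]; b <- state[[nd$parents[2L]]]
        mom <- if (identical(nd$maternal, nd$parents[1L]) ||
                   identical(nd$maternal, a$plastome_lineage) ||
                   nd$maternal %in% a$subgenomes) a else b
        list(plastome_lineage = mom$plastome_lineage,
             ploidy = a$ploidy + b$ploidy,
             subgenomes = c(a$subgenomes, b$subgenomes))
      })
    for (ev in nd$events) {
      if (ev$kind == "fractionation" && ev$f >= 1) {
        st$subgenomes <- setdiff(st$subgenomes, ev$removed_parent)
        st$ploidy <- max(2L, st$ploidy - 2L)
      }
    }
    state[[nd$id]] <- st
    if (isTRUE(nd$tip)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = nd$species, clade = s$clade_map[[nd$species]],
        plastome_lineage = st$plastome_lineage, ploidy = st$ploidy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
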