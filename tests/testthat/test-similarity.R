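toy_am <- function(counts) {
  structure(list(counts = counts, norm = counts,
                 species_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "abundance_matrix")
}

test_that("correlation matrix reproduces direct Pearson computation", {
  counts <- rbind(c1 = c(1, 1, 3), c2 = c(2, 2, 2), c3 = c(3, 3, 1))
  colnames(counts) <- c("SpA", "SpB", "SpC")
  r <- correlation_matrix(toy_am(counts), transform = "none")
  expect_equal(unname(r["SpA", "SpB"]), 1)                 # identical vectors
  expect_equal(unname(r["SpA", "SpC"]), -1)                # (1,2,3) vs (3,2,1)
  expect_equal(diag(r), c(SpA = 1, SpB = 1, SpC = 1))

  set.seed(41)
  counts4 <- matrix(rpois(5 * 4, 20), 5, 4,
                    dimnames = list(paste0("c", 1:5), paste0("Sp", 1:4)))
  r4 <- correlation_matrix(toy_am(counts4), transform = "none")
  # brute-force Pearson from the definition
  for (i in 1:4) for (j in 1:4) {
    x <- counts4[, i]; y <- counts4[, j]
    expected <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r4[i, j]), expected, tolerance = 1e-12)
  }

  flat <- counts; flat[, 2] <- 5
  expect_error(correlation_matrix(toy_am(flat), transform = "none"), "SpB")

  # permuting cluster order leaves the matrix unchanged
  perm <- sample(nrow(counts4))
  r4p <- correlation_matrix(toy_am(counts4[perm, ]), transform = "none")
  expect_equal(r4, r4p)
})

test_that("hierarchical clustering merges blocks and matches a brute-force UPGMA", {
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(r2)
  expect_equal(hc2$height, 0.6)    # single merge at d = 1 - r

  # block-diagonal correlation: deepest split separates the blocks
  r <- diag(6) * 0 + 0.1
  r[1:3, 1:3] <- 0.9; r[4:6, 4:6] <- 0.9; diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("s", 1:6)
  hc <- hierarchical_cluster(r)
  top_split <- stats::cutree(hc, 2)
  expect_length(unique(top_split[1:3]), 1L)
  expect_length(unique(top_split[4:6]), 1L)
  expect_false(top_split[["s1"]] == top_split[["s4"]])

  # average-linkage heights equal naive O(n^3) agglomeration on 8 species
  set.seed(42)
  x <- matrix(rnorm(8 * 10), ncol = 8, dimnames = list(NULL, paste0("s", 1:8)))
  rr <- stats::cor(x)
  d <- 1 - rr
  naive_upgma_heights <- function(d) {
    act <- lapply(seq_len(nrow(d)), identity)   # members of each active group
    heights <- numeric(0)
    dm <- d
    while (length(act) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(act)) for (j in seq_along(act)) {
        if (i >= j) next
        dij <- mean(d[unlist(act[[i]]), unlist(act[[j]])])
        if (dij < best[1]) best <- c(dij, i, j)
      }
      heights <- c(heights, best[1])
      act[[best[2]]] <- c(act[[best[2]]], act[[best[3]]])
      act[[best[3]]] <- NULL
    }
    heights
  }
  expect_equal(sort(hierarchical_cluster(rr)$height),
               sort(naive_upgma_heights(d)), tolerance = 1e-12)
  expect_error(hierarchical_cluster(matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
})

test_that("newick export round-trips and preserves leaves", {
  hc2 <- hierarchical_cluster(
    matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))))
  nwk <- dendrogram_to_newick(hc2)
  expect_true(nwk %in% c("(a:0.2,b:0.2);", "(b:0.2,a:0.2);"))

  set.seed(43)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * 12), ncol = n,
                dimnames = list(NULL, paste0("sp", 1:n)))
    hc <- hierarchical_cluster(stats::cor(x))
    phy <- ape::read.tree(text = dendrogram_to_newick(hc))
    expect_setequal(phy$tip.label, paste0("sp", 1:n))
    # topology survives the round trip
    expect_equal(robinson_foulds(phy, ape::as.phylo(hc)), 0L)
  }
})

test_that("grouping check reports coherent blocks and the deep split pairs", {
  clade_map <- c(Oly1 = "Olyreae", Oly2 = "Olyreae",
                 Nwb1 = "NWB", Nwb2 = "NWB",
                 Aru1 = "Arundinarieae", Aru2 = "Arundinarieae",
                 Pwb1 = "PWB", Pwb2 = "PWB")
  # engineered correlation: (Oly+NWB) vs (Arund+PWB) deep split
  base <- matrix(-0.5, 8, 8, dimnames = list(names(clade_map),
                                             names(clade_map)))
  within_pair <- list(c("Oly1", "Oly2"), c("Nwb1", "Nwb2"),
                      c("Aru1", "Aru2"), c("Pwb1", "Pwb2"))
  for (p in within_pair) base[p, p] <- 0.9
  base[c("Oly1", "Oly2"), c("Nwb1", "Nwb2")] <- 0.5
  base[c("Nwb1", "Nwb2"), c("Oly1", "Oly2")] <- 0.5
  base[c("Aru1", "Aru2"), c("Pwb1", "Pwb2")] <- 0.5
  base[c("Pwb1", "Pwb2"), c("Aru1", "Aru2")] <- 0.5
  diag(base) <- 1
  hc <- hierarchical_cluster(base)
  chk <- grouping_check(hc, clade_map)
  expect_true(all(chk$clade_coherent))
  expect_true(mobdiv:::grouping_matches(chk))

  # single-clade tree is trivially coherent
  one <- base[1:2, 1:2]
  chk1 <- grouping_check(hierarchical_cluster(one),
                         clade_map[c("Oly1", "Oly2")])
  expect_true(all(chk1$clade_coherent))

  # randomized leaf shuffles break coherence essentially always
  set.seed(44)
  broken <- 0L
  for (i in 1:20) {
    shuffled_map <- stats::setNames(sample(unname(clade_map)),
                                    names(clade_map))
    chk_s <- grouping_check(hc, shuffled_map)
    if (!all(chk_s$clade_coherent)) broken <- broken + 1L
  }
  expect_gte(broken, 18L)
})
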