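toy_cluster_table <- function(rows) {
  # rows: data.frame(read_id, species, cluster_id)
  tab <- rows
  class(tab) <- c("cluster_table", "data.frame")
  sizes <- sort(table(tab$cluster_id), decreasing = TRUE)
  attr(tab, "sizes") <- stats::setNames(as.integer(sizes), names(sizes))
  attr(tab, "unclustered") <- character(0)
  tab
}

test_that("abundance matrix tabulates exactly and reconciles totals", {
  rows <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    species = c(rep("SpA", 3), rep("SpB", 7)),
    cluster_id = rep("CL0001", 10))
  am <- abundance_matrix(toy_cluster_table(rows))
  expect_equal(unname(am$counts["CL0001", c("SpA", "SpB")]), c(3L, 7L))
  expect_equal(sum(am$counts["CL0001", ]), 10L)
  expect_equal(am$grand_total, 10L)

  empty <- toy_cluster_table(rows[0, ])
  am0 <- abundance_matrix(empty)
  expect_equal(nrow(am0$counts), 0L)

  # column sums equal independently tallied per-species clustered counts
  sim_rows <- data.frame(
    read_id = sprintf("r%03d", 1:60),
    species = sample(c("SpA", "SpB", "SpC"), 60, replace = TRUE),
    cluster_id = sample(sprintf("CL%04d", 1:5), 60, replace = TRUE))
  am2 <- abundance_matrix(toy_cluster_table(sim_rows))
  expect_equal(am2$species_totals[sort(unique(sim_rows$species))],
               c(table(sim_rows$species))[sort(unique(sim_rows$species))],
               ignore_attr = TRUE)
})

am_from_sizes <- function(sizes) {
  rows <- data.frame(
    read_id = sprintf("r%05d", seq_len(sum(sizes))),
    species = "SpA",
    cluster_id = rep(sprintf("CL%04d", seq_along(sizes)), sizes))
  abundance_matrix(toy_cluster_table(rows))
}

test_that("top-cluster selection returns the minimal sufficient prefix", {
  am <- am_from_sizes(c(50, 30, 20))
  expect_equal(select_top_clusters(am, 0.5), "CL0001")      # boundary exact
  am2 <- am_from_sizes(c(40, 30, 30))
  expect_equal(select_top_clusters(am2, 0.5), c("CL0001", "CL0002"))
  expect_error(select_top_clusters(am_from_sizes(integer(0)), 0.5))

  # property: prefix is sufficient and minimal for random size vectors
  set.seed(31)
  for (i in 1:25) {
    sizes <- sample.int(200, sample(3:12, 1), replace = TRUE)
    frac <- stats::runif(1, 0.1, 0.95)
    am3 <- am_from_sizes(sizes)
    top <- select_top_clusters(am3, frac)
    csum <- sum(rowSums(am3$counts)[top])
    expect_gte(csum, frac * am3$grand_total)
    if (length(top) > 1) {
      expect_lt(csum - rowSums(am3$counts)[top[length(top)]],
                frac * am3$grand_total)
    }
  }
  # idempotent and stable under row permutation of the cluster table
  expect_identical(select_top_clusters(am, 0.5), select_top_clusters(am, 0.5))
})

toy_presence_am <- function() {
  # clusters engineered with known clade patterns over 8 species
  species <- c(Oly1 = "Olyreae", Oly2 = "Olyreae",
               Aru1 = "Arundinarieae", Aru2 = "Arundinarieae",
               Nwb1 = "NWB", Nwb2 = "NWB", Pwb1 = "PWB", Pwb2 = "PWB")
  counts <- rbind(
    CLa = c(5, 4, 3, 2, 6, 1, 2, 3),   # everywhere
    CLb = c(3, 2, 0, 0, 0, 0, 0, 0),   # Olyreae only
    CLc = c(2, 0, 0, 0, 4, 1, 0, 0),   # Olyreae + NWB
    CLd = c(0, 0, 3, 1, 0, 0, 2, 5),   # Arundinarieae + PWB
    CLe = c(0, 0, 1, 0, 0, 0, 0, 0),   # Arundinarieae singleton read
    CLf = c(0, 0, 0, 0, 0, 0, 0, 0))   # absent everywhere
  colnames(counts) <- names(species)
  am <- list(counts = counts,
             norm = counts,
             species_totals = colSums(counts),
             grand_total = sum(counts))
  class(am) <- "abundance_matrix"
  list(am = am, clade_map = species)
}

test_that("clade presence follows the min_reads / min_species rule", {
  x <- toy_presence_am()
  pr <- clade_presence(x$am, x$clade_map)
  expect_equal(unname(pr["CLa", c("Olyreae", "Arundinarieae", "NWB", "PWB")]),
               c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(unname(pr["CLb", ]), c(TRUE, FALSE, FALSE, FALSE))
  # a clade supported by a single read disappears at min_reads = 2
  pr2 <- clade_presence(x$am, x$clade_map, min_reads = 2)
  expect_false(pr2["CLe", "Arundinarieae"])
  expect_true(pr["CLe", "Arundinarieae"])
  bad_map <- x$clade_map[-1]
  expect_error(clade_presence(x$am, bad_map), "missing from clade_map")
})

test_that("venn partition counts match exhaustive enumeration and conserve totals", {
  x <- toy_presence_am()
  pr <- clade_presence(x$am, x$clade_map)
  cp <- venn_partition(pr)
  # brute-force oracle: count patterns by direct enumeration
  for (nm in names(cp$regions)) {
    members <- strsplit(nm, "+", fixed = TRUE)[[1]]
    expected <- sum(apply(pr, 1, function(r)
      setequal(colnames(pr)[r], members)))
    expect_equal(unname(cp$regions[nm]), expected, info = nm)
  }
  expect_equal(cp$n_absent, 1L)
  expect_equal(sum(cp$regions), nrow(pr) - cp$n_absent)
  # per-clade total = sum of the 8 regions containing that clade
  for (cl in colnames(pr)) {
    expect_equal(unname(cp$per_clade[cl]), sum(pr[, cl]))
  }
  # all-present matrix puts everything in the quadruple region
  all_pr <- matrix(TRUE, 3, 4,
                   dimnames = list(paste0("c", 1:3), colnames(pr)))
  cp_all <- venn_partition(all_pr)
  expect_equal(unname(cp_all$regions[paste(colnames(pr), collapse = "+")]), 3L)
  expect_equal(sum(cp_all$regions), 3L)
})
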