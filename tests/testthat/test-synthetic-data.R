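test_that("mutate_sequence: zero rate is identity, rate is realized, seeds reproduce", {
  expect_identical(mutate_sequence("ACGT", 0, seed = 5), "ACGT")
  expect_error(mutate_sequence("ACGT", -0.1), "non-negative")

  s <- random_dna(1000, seed = 11)
  m <- mutate_sequence(s, 0.10, seed = 1)
  expect_equal(nchar(m), 1000)
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(frac - 0.10), 0.03)   # binomial bound, 1 kb

  expect_identical(mutate_sequence(s, 0.25, seed = 99),
                   mutate_sequence(s, 0.25, seed = 99))
  # saturation cap: d > 0.75 behaves like 0.75
  m2 <- mutate_sequence(s, 5, seed = 3)
  frac2 <- mean(strsplit(s, "")[[1]] != strsplit(m2, "")[[1]])
  expect_lt(abs(frac2 - 0.75), 0.04)
})

make_diploid <- function(label, n_blocks = 3, block_len = 2000, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(i)
    subgenome_block(label, random_dna(block_len)))
  genome_state(label, blocks, ploidy = 2L,
               plastome = random_dna(500), plastome_lineage = label)
}

test_that("hybridize concatenates blocks, sums ploidy, inherits maternal plastome", {
  h <- make_diploid("H", seed = 1)
  c_ <- make_diploid("C", n_blocks = 4, seed = 2)
  hy <- hybridize(h, c_, maternal = "H")
  expect_equal(hy$ploidy, 4L)
  expect_equal(length(hy$blocks), 7L)
  expect_equal(genome_length(hy), genome_length(h) + genome_length(c_))
  expect_identical(hy$plastome, h$plastome)
  expect_identical(hy$plastome_lineage, "H")

  auto <- hybridize(h, h, maternal = "H")   # self-cross: autopolyploid
  expect_equal(auto$ploidy, 4L)
  expect_equal(length(auto$blocks), 2L * length(h$blocks))

  expect_error(hybridize(h, c_, maternal = "X"), "matches neither parent")
})

test_that("fractionate removes the target subgenome and spares post-hybrid copies in retained blocks", {
  h <- make_diploid("H", seed = 3)
  c_ <- make_diploid("C", seed = 4)
  lib <- te_library("H_fam01", "Gypsy", "H", random_dna(300, seed = 5))
  hy <- hybridize(h, c_, maternal = "H")
  hy <- te_burst(hy, lib, "H_fam01", 30, post_hybrid = TRUE, seed = 6)

  expect_identical(fractionate(hy, "H", 0, seed = 1)$blocks, hy$blocks)

  fr <- fractionate(hy, "H", 1, seed = 7)
  labs <- vapply(fr$blocks, `[[`, character(1), "parent_label")
  expect_false("H" %in% labs)
  expect_equal(fr$ploidy, 2L)   # diploidization on complete loss
  surv <- do.call(rbind, lapply(fr$blocks, `[[`, "te"))
  # the H family persists only as post-hybridization jumps into C blocks
  expect_true(nrow(surv) > 0)
  expect_true(all(surv$post_hybrid))
  expect_true(all(surv$family_id == "H_fam01"))

  expect_error(fractionate(hy, "Z", 0.5), "no block")
  expect_error(fractionate(hy, "H", 1.5), "\\[0, 1\\]")
})

test_that("fractionate retention count falls in the binomial 99% interval", {
  blocks <- lapply(1:100, function(i) subgenome_block("H", random_dna(200)))
  g <- genome_state("H", blocks, plastome = "ACGT")
  fr <- fractionate(g, "H", 0.9, seed = 42)
  kept <- length(fr$blocks)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.1)
  expect_gte(kept, ci[1]); expect_lte(kept, ci[2])
})

test_that("te_burst grows the genome additively and reproducibly", {
  g <- make_diploid("C", seed = 8)
  lib <- te_library("C_fam01", "Copia", "C", random_dna(1000, seed = 9))
  expect_identical(te_burst(g, lib, "C_fam01", 0, seed = 1), g)
  expect_error(te_burst(g, lib, "nope", 3), "unknown family")

  g50 <- te_burst(g, lib, "C_fam01", 50, seed = 10)
  expect_equal(genome_length(g50) - genome_length(g), 50 * 1000)
  g50b <- te_burst(g, lib, "C_fam01", 50, seed = 10)
  expect_identical(g50, g50b)
  validate_genome_state(g50)   # intervals stay within blocks, no overlap
})

test_that("read sampling honors C = LN/G and labels reads by majority overlap", {
  spec <- read_sampling_spec(L = 150, G = 3e8, C = 0.5, paired = TRUE)
  expect_equal(spec$N, 1e6)                      # N = C*G/L exactly
  expect_equal(coverage(150, spec$N, 3e8), 0.5)
  spec2 <- read_sampling_spec(L = 150, G = 1e6 + 1, C = 0.5)
  expect_lte(abs(spec2$C - 0.5), 2 * 150 / 1e6)  # rounding bound

  # genome with one family occupying ~10% of its length
  set.seed(13)
  blocks <- lapply(1:4, function(i) subgenome_block("H", random_dna(45000)))
  g <- genome_state("H", blocks, plastome = "ACGT")
  lib <- te_library("H_fam01", "Gypsy", "H", random_dna(1000, seed = 14))
  g <- te_burst(g, lib, "H_fam01", 20, copy_divergence = 0, seed = 15)
  fam_frac <- 20000 / genome_length(g)
  rs <- sample_reads(g, read_sampling_spec(L = 100, G = genome_length(g),
                                           C = 10, seed = 3), "SpA")
  obs <- mean(rs$truth$family_id == "H_fam01")
  expect_lt(abs(obs - fam_frac), 0.01)
  # truth covers every read; ids carry the species prefix
  expect_setequal(rs$truth$read_id, rs$reads$read_id)
  expect_true(all(startsWith(rs$reads$read_id, "SpA_")))
})

test_that("default scenario encodes maternal plastome capture and ploidy history", {
  s <- default_scenario()
  expect_s3_class(s, "scenario")          # construction passes validation
  summ <- scenario_lineage_summary(s)
  oly <- summ[summ$clade == "Olyreae", ]
  aru <- summ[summ$clade == "Arundinarieae", ]
  woody <- summ[summ$clade %in% c("NWB", "PWB"), ]
  # herbaceous plastome captured by both Bambuseae lineages, not Arundinarieae
  expect_true(all(woody$plastome_lineage == unique(oly$plastome_lineage)))
  expect_true(all(aru$plastome_lineage != unique(oly$plastome_lineage)))
  expect_true(all(oly$ploidy == 2L))
  expect_true(all(summ$ploidy >= 2L))
})

test_that("scenario validation rejects inconsistent event ordering", {
  s <- default_scenario()
  bad <- s
  n <- length(bad$nodes)
  bad$nodes <- bad$nodes[c(n, seq_len(n - 1L))]  # a tip before its parent
  expect_error(validate_scenario(bad), "not yet defined")
})

test_that("simulation is reproducible and respects the symbolic lineage summary", {
  sim <- get_small_sim()
  s <- sim$scenario
  summ <- scenario_lineage_summary(s)
  got <- data.frame(species = names(sim$genomes),
                    plastome_lineage = vapply(sim$genomes, `[[`, "",
                                              "plastome_lineage"),
                    ploidy = vapply(sim$genomes, `[[`, 1L, "ploidy"))
  m <- merge(summ, got, by = "species")
  expect_equal(m$plastome_lineage.x, m$plastome_lineage.y)
  # the symbolic summary decrements ploidy only for certain (f = 1) losses;
  # an incomplete fractionation can still lose every block by chance, so the
  # simulated ploidy may diploidize below the symbolic value but never above
  expect_true(all(m$ploidy.y <= m$ploidy.x))
  det <- m$clade != "NWB"   # lineages without partial fractionation
  expect_equal(m$ploidy.x[det], m$ploidy.y[det])

  # determinism: same master seed, byte-identical FASTQ
  sim2 <- simulate_scenario(s, sim$seed)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(sim$read_sets[[1]], f1)
  write_fastq(sim2$read_sets[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("truth-labeled read fraction tracks genomic family fraction", {
  sim <- get_small_sim()
  sp <- names(sim$read_sets)[1]
  g <- sim$genomes[[sp]]
  fl <- mobdiv:::flatten_genome(g)
  tr <- sim$read_sets[[sp]]$truth
  # pick the most abundant family in this genome
  lens <- tapply(fl$te$end - fl$te$start + 1L, fl$te$family_id, sum)
  fam <- names(which.max(lens))
  frac_genome <- lens[[fam]] / nchar(fl$sequence)
  frac_reads <- mean(tr$family_id == fam)
  n <- nrow(tr)
  sigma <- sqrt(frac_genome * (1 - frac_genome) / n)
  expect_lt(abs(frac_reads - frac_genome), 3 * sigma + 0.02)
})
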