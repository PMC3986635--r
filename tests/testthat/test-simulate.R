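# Community design, rarefaction fitting, fragment sampling, the error
# model, and the end-to-end simulator.

genome_pool <- function(n) {
  data.frame(genome_id = sprintf("g%02d", seq_len(n)),
             taxon_id = sprintf("t%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("degenerate and maximum-entropy communities are exact", {
  p1 <- design_community(genome_pool(3), H_target = 0, dominance_cap = 1,
                         max_taxa = 1, seed = 1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$abundance, 1)
  expect_equal(attr(p1, "H_realized"), 0)

  # H = ln(S), cap = 1: the uniform community
  pu <- design_community(genome_pool(8), H_target = log(8), dominance_cap = 1,
                         max_taxa = 8, seed = 2)
  expect_equal(pu$abundance, rep(1 / 8, 8), tolerance = 1e-6)
})

test_that("realized entropy hits the target and the cap binds", {
  pool <- genome_pool(60)
  prof <- design_community(pool, H_target = 3.2, dominance_cap = 0.05,
                           max_taxa = 40, seed = 3)
  # entropy recomputed independently from the emitted profile
  H <- -sum(prof$abundance * log(prof$abundance))
  expect_lt(abs(H - 3.2), 1e-3)
  expect_lte(max(prof$abundance), 0.05 + 1e-12)
  expect_equal(sum(prof$abundance), 1, tolerance = 1e-9)

  # random feasible configurations (both scenario caps)
  set.seed(99)
  for (i in 1:20) {
    S <- sample(10:50, 1)
    cap <- sample(c(0.05, 0.80), 1)
    if (cap * S < 1) next
    hmin <- if (cap == 0.05) -log(0.05) else
      -(0.8 * log(0.8) + 0.2 * log(0.2))
    H_t <- stats::runif(1, hmin + 0.01, log(S) - 0.01)
    p <- design_community(genome_pool(S), H_t, cap, S, seed = i)
    expect_lt(abs(-sum(p$abundance * log(p$abundance)) - H_t), 1e-3)
    expect_lte(max(p$abundance), cap + 1e-12)
  }
})

test_that("infeasible community configurations are rejected", {
  pool <- genome_pool(40)
  expect_error(design_community(pool, log(40) + 0.5, 1, 40), "ln\\(max_taxa\\)")
  expect_error(design_community(pool, 1, 0.05, 10), "dominance_cap")
  # entropy below the cap-constrained floor (< ln 20 at cap 0.05)
  expect_error(design_community(pool, 2.5, 0.05, 40), "minimum entropy")
})

test_that("rarefaction fit reproduces the expected accumulation curve", {
  pool <- genome_pool(10)
  prof <- design_community(pool, log(10), 1, 10, seed = 4)  # uniform
  cv <- fit_rarefaction(1000, 10, prof)
  # Monte-Carlo rarefaction oracle: 100 resamples of 1000 reads
  set.seed(5)
  mc <- mean(replicate(100, {
    length(unique(sample.int(10, 1000, replace = TRUE, prob = prof$abundance)))
  }))
  expect_lt(abs(predict(cv, 1000) - mc) / mc, 0.05)
  # fit passes near all three anchors for random profiles
  for (seed in 1:5) {
    S <- sample(5:30, 1)
    pr <- design_community(genome_pool(S), stats::runif(1, 0.7 * log(S), log(S)),
                           1, S, seed = 600 + seed)
    cc <- fit_rarefaction(2000, S, pr)
    res <- abs(predict(cc, cc$anchors$n) - cc$anchors$s)
    expect_lt(max(res) / S, 0.15)
  }
})

test_that("single-taxon profiles produce a flagged constant-like curve", {
  prof <- design_community(genome_pool(2), 0, 1, 1, seed = 6)
  expect_warning(cv <- fit_rarefaction(500, 1, prof), "degenerate")
  expect_true(cv$degenerate)
  expect_equal(cv$anchors$s[cv$anchors$n == 500], 1)
  expect_true(all(predict(cv, 1:500) <= 1 + 1e-9))
})

test_that("fragments respect coordinates, lengths, and strand", {
  g <- random_dna(100000, seed = 7)
  expect_identical(nrow(sample_fragments(g, 0)), 0L)
  fr <- sample_fragments(g, 10000, 350, 600, seed = 8, genome_id = "gX",
                         taxon_id = "tX")
  lens <- fr$end - fr$start
  expect_true(all(lens >= 350 & lens <= 600))
  expect_true(all(fr$start >= 0 & fr$end <= 100000))
  # uniform length distribution (chi-square on 251 cells)
  cs <- stats::chisq.test(table(factor(lens, levels = 350:600)))
  expect_gt(cs$p.value, 0.01)
  # coordinate round trip: sequence equals the slice or its reverse complement
  idx <- sample.int(10000, 200)
  for (i in idx) {
    slice <- substr(g, fr$start[i] + 1, fr$end[i])
    expected <- if (fr$strand[i] == "+") slice else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    expect_identical(fr$sequence[i], expected)
  }
  expect_error(sample_fragments(random_dna(400), 5, 350, 600), "genome-too-short")
})

test_that("error model: zero rates are identity, saturation flips all bases", {
  fr <- sample_fragments(random_dna(5000, seed = 9), 20, seed = 10)
  same <- apply_error_model(fr, 0, 0)
  expect_identical(same$sequence, fr$sequence)
  expect_true(all(same$n_substitutions == 0L))
  expect_true(all(same$n_homopolymer_edits == 0L))

  flipped <- apply_error_model(fr, substitution_rate = 1 - 1e-12,
                               homopolymer_rate = 0, seed = 11)
  for (i in 1:5) {
    a <- strsplit(fr$sequence[i], "")[[1]]
    b <- strsplit(flipped$sequence[i], "")[[1]]
    expect_true(all(a != b))
    expect_equal(flipped$n_substitutions[i], length(a))
  }
})

test_that("realized substitution rate matches the binomial expectation", {
  fr <- sample_fragments(random_dna(200000, seed = 12), 2000, 480, 520,
                         seed = 13)
  mut <- apply_error_model(fr, substitution_rate = 0.01,
                           homopolymer_rate = 0, seed = 14)
  n_bases <- sum(nchar(fr$sequence))
  realized <- sum(mut$n_substitutions) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(realized - 0.01), 3 * se)
  # with no homopolymer edits, counters equal the Hamming distance
  i <- which.max(mut$n_substitutions)
  a <- strsplit(fr$sequence[i], "")[[1]]
  b <- strsplit(mut$sequence[i], "")[[1]]
  expect_equal(sum(a != b), mut$n_substitutions[i])
})

test_that("homopolymer edits change lengths by one per edited run", {
  fr <- data.frame(read_id = "r1", sequence = "AAACGGGGTCCA",
                   source_genome_id = "g", source_taxon_id = "t",
                   start = 0L, end = 12L, strand = "+",
                   n_substitutions = 0L, n_homopolymer_edits = 0L,
                   stringsAsFactors = FALSE)
  # rate high enough to force edits on every eligible run
  mut <- apply_error_model(fr, 0, 0.99, seed = 15)
  dlen <- nchar(mut$sequence) - nchar(fr$sequence)
  expect_lte(abs(dlen), mut$n_homopolymer_edits)
  expect_gt(mut$n_homopolymer_edits, 0)
})

test_that("simulate_metagenome emits exactly n_reads, reproducibly", {
  mk <- make_mock_genomes(6, genome_length = 3000, seed = 16)
  cfg <- list(H_target = 1.2, n_reads = 100, max_taxa = 4,
              dominance_cap = 0.6, genome_set = mk$genomes, seed = 17)
  sim1 <- simulate_metagenome(cfg)
  sim2 <- simulate_metagenome(cfg)
  expect_equal(nrow(sim1$reads), 100L)
  expect_identical(sim1$reads, sim2$reads)  # seeded determinism
  expect_true(all(sim1$reads$end - sim1$reads$start >= 350))
  expect_true(all(sim1$reads$end - sim1$reads$start <= 600))

  # byte-identical files on rerun
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_simulation(sim1, d1)
  f2 <- write_simulation(sim2, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # single-genome config: every truth row names that genome
  cfg1 <- list(H_target = 0, n_reads = 100, max_taxa = 1, dominance_cap = 1,
               genome_set = mk$genomes, seed = 18)
  expect_warning(simg <- simulate_metagenome(cfg1), "degenerate")
  expect_equal(nrow(simg$reads), 100L)
  expect_length(unique(simg$reads$source_genome_id), 1L)

  # truth table re-parses through the package reader
  tt <- read_truth(f1[["truth"]])
  expect_equal(nrow(tt), 100L)
  expect_identical(tt$read_id, sim1$reads$read_id)
  expect_equal(tt$length, sim1$reads$end - sim1$reads$start)
})

test_that("diverge_genome produces the requested divergence", {
  g <- random_dna(10000, seed = 19)
  expect_identical(diverge_genome(g, 0, 0), g)
  d <- diverge_genome(g, 0.1, 0, seed = 20)
  # alignment-identity oracle on a 1 kb window
  aln <- Biostrings::pairwiseAlignment(substr(g, 1, 1000), substr(d, 1, 1000),
                                       type = "global")
  pid <- Biostrings::pid(aln) / 100
  expect_lt(abs(pid - 0.90), 0.02)
  # indels change length within expected bounds
  di <- diverge_genome(g, 0, 0.05, seed = 21)
  expect_lt(abs(nchar(di) - 10000), 4 * sqrt(2 * 10000 * 0.05))
})

test_that("mock genomes have the requested GC and a loadable taxonomy", {
  mk1 <- make_mock_genomes(1, genome_length = 2000, seed = 22)
  ln <- lineage(mk1$taxonomy, mk1$genomes$taxon_id[1])
  expect_true(all(ln != NO_RANK()))  # full 7-level lineage

  mk <- make_mock_genomes(2, genome_length = 100000, gc_content = 0.5,
                          seed = 23)
  gc <- mean(strsplit(mk$genomes$sequence[1], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)

  # the generated taxonomy round-trips through load_taxonomy
  tr2 <- load_taxonomy(write_taxonomy_tsv(mk$taxonomy))
  expect_identical(sort(taxon_ids(tr2)), sort(taxon_ids(mk$taxonomy)))

  # reduced tree depth drops the shallowest ranks
  mk5 <- make_mock_genomes(4, genome_length = 1000, tree_depth = 5, seed = 24)
  ln5 <- lineage(mk5$taxonomy, mk5$genomes$taxon_id[1])
  expect_identical(unname(ln5[["domain"]]), NO_RANK())
  expect_identical(unname(ln5[["phylum"]]), NO_RANK())
  expect_true(ln5[["class"]] != NO_RANK())
})
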