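# BLAST parsing, LCA assignment, the naive Bayes classifier, epsilon
# cutoffs, BLAST combination, and external-table ingestion.

random_hits <- function(n, seed) {
  set.seed(seed)
  data.frame(query_id = sprintf("q%03d", sample.int(50, n, replace = TRUE)),
             subject_id = sprintf("s%02d", sample.int(20, n, replace = TRUE)),
             percent_identity = round(stats::runif(n, 70, 100), 2),
             alignment_length = sample.int(500, n, replace = TRUE),
             mismatches = sample.int(40, n, replace = TRUE),
             gap_opens = sample.int(5, n, replace = TRUE),
             q_start = sample.int(100, n, replace = TRUE),
             q_end = sample.int(600, n, replace = TRUE),
             s_start = sample.int(10000, n, replace = TRUE),
             s_end = sample.int(10000, n, replace = TRUE),
             e_value = 10^-stats::runif(n, 0, 30),
             bit_score = round(stats::runif(n, 40, 900), 1),
             stringsAsFactors = FALSE)
}

test_that("BLAST tabular parsing round-trips and reports bad lines", {
  expect_identical(nrow(read_blast_tabular(character())), 0L)
  one <- "q1\ts1\t98.5\t400\t6\t0\t1\t400\t100\t499\t1e-120\t720"
  h <- read_blast_tabular(one)
  expect_equal(nrow(h), 1L)
  expect_equal(h$percent_identity, 98.5)
  expect_equal(h$e_value, 1e-120)
  expect_equal(h$bit_score, 720)

  hits <- random_hits(500, seed = 31)
  back <- read_blast_tabular(write_blast_tabular(hits))
  expect_equal(back, hits, tolerance = 1e-12)

  expect_error(read_blast_tabular("q1\ts1\t98.5"), "line 1")
})

test_that("LCA assignment filters by e-value and summarizes hits", {
  tr <- fixture_tree()
  taxa <- c(s1 = "sSub", s2 = "sCer", s3 = "sGeo", s4 = "sPhg")
  mk_hit <- function(q, s, e, bs) {
    data.frame(query_id = q, subject_id = s, percent_identity = 99,
               alignment_length = 400L, mismatches = 1L, gap_opens = 0L,
               q_start = 1L, q_end = 400L, s_start = 1L, s_end = 400L,
               e_value = e, bit_score = bs, stringsAsFactors = FALSE)
  }
  # single surviving hit: that hit's taxon
  a1 <- lca_assign(mk_hit("q1", "s1", 1e-40, 500), taxa, tr)
  expect_identical(a1$taxon_id, "sSub")
  expect_equal(a1$score, 500)

  # two species of one genus -> genus; two genera of one family -> family
  a2 <- lca_assign(rbind(mk_hit("q2", "s1", 1e-40, 500),
                         mk_hit("q2", "s2", 1e-30, 450)), taxa, tr)
  expect_identical(a2$taxon_id, "gBac")
  a3 <- lca_assign(rbind(mk_hit("q3", "s1", 1e-40, 500),
                         mk_hit("q3", "s3", 1e-30, 450)), taxa, tr)
  expect_identical(a3$taxon_id, "fBac")

  # all hits above the 1e-5 cutoff -> UNASSIGNED
  a4 <- lca_assign(mk_hit("q4", "s1", 1e-3, 60), taxa, tr)
  expect_identical(a4$taxon_id, UNASSIGNED())

  # subject without taxon mapping is dropped with a warning
  expect_warning(
    a5 <- lca_assign(rbind(mk_hit("q5", "s1", 1e-40, 500),
                           mk_hit("q5", "sXX", 1e-50, 600)), taxa, tr),
    "no taxon")
  expect_identical(a5$taxon_id, "sSub")

  # LCA monotonicity: adding a hit never deepens the assignment
  base_path <- oracle_path(tr, a2$taxon_id)
  expect_true(a3$taxon_id %in% oracle_path(tr, "sSub"))
  a_more <- lca_assign(rbind(mk_hit("q6", "s1", 1e-40, 500),
                             mk_hit("q6", "s2", 1e-30, 450),
                             mk_hit("q6", "s4", 1e-20, 300)), taxa, tr)
  expect_true(a_more$taxon_id %in% base_path)  # ancestor-or-self of gBac
})

test_that("lca_assign_all covers hitless reads as UNASSIGNED", {
  tr <- fixture_tree()
  taxa <- c(s1 = "sSub")
  hits <- read_blast_tabular(
    "q1\ts1\t99\t400\t1\t0\t1\t400\t1\t400\t1e-40\t500")
  out <- lca_assign_all(hits, taxa, tr, read_ids = c("q1", "q2"))
  expect_identical(out$taxon_id, c("sSub", UNASSIGNED()))
  expect_identical(attr(out, "kept_subjects")$q2, character())
})

test_that("NBC training validates inputs and learns composition", {
  # probability mass concentrated on the homopolymer k-mer
  m <- train_nbc(c(gA = strrep("A", 200)), c(gA = "tA"), k = 4)
  p <- exp(m$logp["gA", ])
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # both strands counted: AAAA and TTTT share the mass
  expect_gt(p[["AAAA"]] + p[["TTTT"]], 0.5)
  expect_equal(p[["AAAA"]], p[["TTTT"]], tolerance = 1e-12)

  # disjoint-composition genomes have nearly orthogonal profiles (the
  # alphabets {A,T} and {G,C} are each closed under reverse complement,
  # so strand collapsing keeps the k-mer supports disjoint)
  set.seed(32)
  gAT <- paste(sample(c("A", "T"), 5000, TRUE), collapse = "")
  gGC <- paste(sample(c("G", "C"), 5000, TRUE), collapse = "")
  m2 <- train_nbc(c(x = gAT, y = gGC), c(x = "tx", y = "ty"), k = 4)
  px <- exp(m2$logp["x", ]); py <- exp(m2$logp["y", ])
  cosine <- sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  expect_lt(cosine, 0.1)

  expect_error(train_nbc(c(g1 = strrep("A", 100)), c(other = "t"), k = 4),
               "without a taxon")
  expect_error(train_nbc(c(g1 = "ACGT"), c(g1 = "t"), k = 8), "shorter than k")
  expect_error(train_nbc(c(g1 = strrep("A", 100)), c(g1 = "t"), k = 3),
               "k must be")
})

test_that("NBC models serialize losslessly", {
  mk <- mock10()
  m <- train_nbc(mk$genomes[1:3, ], k = 4)
  f <- tempfile()
  write_nbc_model(m, f)
  m2 <- read_nbc_model(f)
  expect_equal(m2$k, m$k)
  expect_identical(m2$taxa, m$taxa)
  expect_equal(m2$logp, m$logp, tolerance = 1e-15)
})

test_that("NBC classification recovers sources and breaks ties deterministically", {
  mk <- mock10()
  model <- train_nbc(mk$genomes, k = 8)
  set.seed(33)
  src <- sample.int(10, 100, replace = TRUE)
  reads <- vapply(src, function(i) {
    s <- mk$genomes$sequence[i]
    st <- sample.int(nchar(s) - 500L, 1L)
    substr(s, st, st + 499L)
  }, "")
  a <- nbc_classify(model, reads)
  expect_gte(mean(a$taxon_id == mk$genomes$taxon_id[src]), 0.95)
  expect_identical(a$read_length, rep(500L, 100L))

  # single-genome model: argmax over one
  m1 <- train_nbc(mk$genomes[1, ], k = 8)
  a1 <- nbc_classify(m1, reads[1])
  expect_identical(a1$taxon_id, mk$genomes$taxon_id[1])

  # two identical genomes: forced tie, lexicographically first id wins
  dup <- data.frame(genome_id = c("zz", "aa"),
                    taxon_id = c("t_zz", "t_aa"),
                    sequence = mk$genomes$sequence[1],
                    stringsAsFactors = FALSE)
  md <- train_nbc(dup, k = 6)
  expect_message(ad <- nbc_classify(md, reads[1]), "tie")
  expect_identical(ad$taxon_id, "t_aa")

  # reads shorter than k are flagged UNASSIGNED
  ashort <- nbc_classify(model, "ACGTA")
  expect_identical(ashort$taxon_id, UNASSIGNED())
  expect_true(attr(ashort, "too_short"))
})

test_that("epsilon cutoff retains by posterior floor, monotonically", {
  a <- data.frame(read_id = c("r1", "r2", "r3"), method_id = "nbc",
                  taxon_id = c("tA", "tA", "tB"), score = c(0, 0, 0),
                  read_length = 100L, stringsAsFactors = FALSE)
  # posteriors: r1 ~ 1 (huge margin), r2 = 0.5 (tie), r3 ~ 0.73
  ll <- rbind(c(0, -1000), c(0, 0), c(0, -1))
  dimnames(ll) <- list(a$read_id, c("gA", "gB"))
  attr(a, "loglik") <- ll

  e0 <- apply_epsilon_cutoff(a, epsilon_config(0))
  expect_true(all(e0$taxon_id != UNASSIGNED()))
  e1 <- apply_epsilon_cutoff(a, epsilon_config(1))
  expect_identical(e1$taxon_id != UNASSIGNED(), c(TRUE, FALSE, FALSE))
  e6 <- apply_epsilon_cutoff(a, epsilon_config(0.6))
  expect_identical(e6$taxon_id != UNASSIGNED(), c(TRUE, FALSE, TRUE))

  # monotone non-increasing retained counts over a sweep
  counts <- vapply(c(0, 0.3, 0.5, 0.6, 0.73, 0.9, 1), function(e) {
    sum(apply_epsilon_cutoff(a, epsilon_config(e))$taxon_id != UNASSIGNED())
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("BLAST combination restricts candidates to surviving hits", {
  tr <- fixture_tree()
  mk <- mock10()
  # attach fixture taxa to three mock genomes
  g <- mk$genomes[1:3, ]
  g$taxon_id <- c("sSub", "sCer", "sGeo")
  model <- train_nbc(g, k = 6)
  read <- substr(g$sequence[3], 1000, 1450)

  hit <- function(q, s, e) data.frame(
    query_id = q, subject_id = s, percent_identity = 99,
    alignment_length = 400L, mismatches = 1L, gap_opens = 0L, q_start = 1L,
    q_end = 400L, s_start = 1L, s_end = 400L, e_value = e, bit_score = 500,
    stringsAsFactors = FALSE)
  taxa <- stats::setNames(g$taxon_id, g$genome_id)

  # hits name exactly one genome: its taxon wins regardless of NBC ranking
  b1 <- lca_assign(hit("q1", g$genome_id[1], 1e-40), taxa, tr)
  c1 <- combine_blast_nbc(b1, model, read, tr)
  expect_identical(c1$taxon_id, "sSub")

  # no surviving hits: never assigned (contaminant behavior)
  b0 <- lca_assign(hit("q2", g$genome_id[1], 1e-2), taxa, tr)
  c0 <- combine_blast_nbc(b0, model, read, tr)
  expect_identical(c0$taxon_id, UNASSIGNED())

  # containment: the combined call is always within the hit taxon set
  b2 <- lca_assign(rbind(hit("q3", g$genome_id[2], 1e-40),
                         hit("q3", g$genome_id[3], 1e-40)), taxa, tr)
  c2 <- combine_blast_nbc(b2, model, read, tr)
  expect_true(c2$taxon_id %in% c("sCer", "sGeo"))
  expect_identical(c2$taxon_id, "sGeo")  # NBC picks the true source
})

test_that("external assignment tables ingest, resolve names, and round-trip", {
  tr <- fixture_tree()
  tab <- c("r1\tsSub\t0.9\t400", "r2\tBacillus\t0.8\t380", "r3\tUNASSIGNED")
  a <- ingest_external_assignments(tab, "phymm", tree = tr)
  expect_equal(nrow(a), 3L)
  expect_identical(a$taxon_id, c("sSub", "gBac", UNASSIGNED()))
  expect_equal(a$score, c(0.9, 0.8, NA))
  expect_identical(a$method_id, rep("phymm", 3))

  expect_warning(
    au <- ingest_external_assignments("r1\tNot A Name", "m", tree = tr),
    "could not be resolved")
  expect_identical(au$taxon_id, UNASSIGNED())

  expect_error(ingest_external_assignments(c("r1\tsSub", "r1\tsCer"), "m"),
               "duplicate read_id")

  # ingest . export is the identity on generated tables
  set.seed(34)
  gen <- data.frame(read_id = sprintf("r%03d", 1:50), method_id = "ext",
                    taxon_id = sample(taxon_ids(tr), 50, replace = TRUE),
                    score = round(stats::runif(50), 3),
                    read_length = sample.int(600, 50),
                    stringsAsFactors = FALSE)
  back <- read_assignments(write_assignments(gen))
  expect_equal(back, gen, tolerance = 1e-12)
})
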