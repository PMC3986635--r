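# Fixtures and independent oracles used across the suite.  The oracles
# deliberately use different algorithms from the package implementations
# (path enumeration instead of joint climbing, explicit rule tables
# instead of the vectorized classifiers).

RANKS7 <- canonical_ranks()

# A small fixed taxonomy: two domains (one bacteria-like with a full
# lineage, one virus-like whose lineage skips phylum..genus), used by many
# assignment tests.
fixture_tree <- function() {
  load_taxonomy(c(
    "root\troot\tno rank\troot",
    "dBac\troot\tsuperkingdom\tBacteria",
    "pFir\tdBac\tphylum\tFirmicutes",
    "cBac\tpFir\tclass\tBacilli",
    "oBac\tcBac\torder\tBacillales",
    "fBac\toBac\tfamily\tBacillaceae",
    "gBac\tfBac\tgenus\tBacillus",
    "gGeo\tfBac\tgenus\tGeobacillus",
    "sSub\tgBac\tspecies\tBacillus subtilis",
    "sCer\tgBac\tspecies\tBacillus cereus",
    "sGeo\tgGeo\tspecies\tGeobacillus kaustophilus",
    "gOth\tfBac\tgenus\tOtherbacillus",
    "sOth\tgOth\tspecies\tOtherbacillus x",
    "dVir\troot\tsuperkingdom\tViruses",
    "sPhg\tdVir\tspecies\tPhage X"
  ))
}

# Random ranked tree: node 1 is the root; each later node attaches to a
# uniformly chosen earlier node with a random rank label.
random_tree <- function(n, seed) {
  set.seed(seed)
  ranks <- c(RANKS7, "no rank", "superkingdom")
  id <- sprintf("n%03d", seq_len(n))
  parent <- c(id[1L], id[sapply(seq_len(n - 1L), function(i) sample.int(i, 1L))])
  rk <- c("no rank", sample(ranks, n - 1L, replace = TRUE))
  load_taxonomy(sprintf("%s\t%s\t%s\tname %s", id, parent, rk, id))
}

# Random tree whose rank labels respect the canonical order along every
# root path (as real taxonomies do): each node's rank is strictly deeper
# than every ranked ancestor's, or "no rank".
random_consistent_tree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("n%03d", seq_len(n))
  parent <- character(n)
  rk <- character(n)
  deepest <- integer(n)  # index into RANKS7 of deepest ranked ancestor (0 = none)
  parent[1L] <- id[1L]
  rk[1L] <- "no rank"
  deepest[1L] <- 0L
  for (i in seq_len(n)[-1L]) {
    p <- sample.int(i - 1L, 1L)
    parent[i] <- id[p]
    allowed <- if (deepest[p] < 7L) (deepest[p] + 1L):7L else integer()
    if (!length(allowed) || stats::runif(1) < 0.3) {
      rk[i] <- "no rank"
      deepest[i] <- deepest[p]
    } else {
      pick <- allowed[sample.int(length(allowed), 1L)]
      rk[i] <- RANKS7[pick]
      deepest[i] <- pick
    }
  }
  load_taxonomy(sprintf("%s\t%s\t%s\tname %s", id, parent, rk, id))
}

# Oracle: root-to-node path by repeated parent lookup.
oracle_path <- function(tree, x) {
  p <- x
  while (x != tree$root) {
    x <- tree$parent[[x]]
    p <- c(x, p)
  }
  p  # root first
}

# Oracle: lineage by walking the full path and taking the deepest-first
# (i.e. nearest) node per canonical rank.
oracle_lineage <- function(tree, x) {
  path <- rev(oracle_path(tree, x))  # node first, root last
  out <- stats::setNames(rep(NO_RANK(), 7L), RANKS7)
  for (node in path) {
    r <- tree$rank[[node]]
    if (r == "superkingdom") r <- "domain"
    if (r %in% RANKS7 && out[[r]] == NO_RANK()) out[[r]] <- node
  }
  out
}

# Oracle: LCA as the deepest element of the intersection of root paths.
oracle_lca <- function(tree, ids) {
  paths <- lapply(ids, function(x) oracle_path(tree, x))
  common <- Reduce(intersect, paths)
  common[[length(common)]]  # paths are root-first, so last common is deepest
}

# Oracle: rule-table agreement classifier over already-projected labels.
oracle_classify <- function(proj, rank = "genus", confused_keys = character(),
                            confused_methods = c("phymm", "nbc")) {
  K <- length(proj)
  n_un <- sum(proj == UNASSIGNED())
  n_nr <- sum(proj == NO_RANK())
  ranked <- proj[proj != UNASSIGNED() & proj != NO_RANK()]
  if (n_un * 2 > K) return("UNASSIGNED_MAJORITY")
  if (length(ranked) == K && all(ranked == ranked[1L])) return("ALL_SAME")
  if (n_nr == K) return("NO_RANK")
  if (rank == "genus" && all(confused_methods %in% names(proj))) {
    a <- proj[[confused_methods[1L]]]
    b <- proj[[confused_methods[2L]]]
    if (a != UNASSIGNED() && a != NO_RANK() && b != UNASSIGNED() &&
        b != NO_RANK() && a != b &&
        paste(sort(c(a, b)), collapse = "\r") %in% confused_keys) {
      return("CONFUSED")
    }
  }
  if (length(ranked) >= 2L && any(table(ranked) >= 2L)) return("TWO_SAME")
  if (n_nr * 2 > K) return("NO_RANK")
  "ALL_DIFFERENT"
}

# Build a long assignment table from a reads-by-methods matrix of calls.
calls_to_assignments <- function(calls, read_lengths = NULL) {
  reads <- rownames(calls)
  if (is.null(reads)) reads <- sprintf("r%04d", seq_len(nrow(calls)))
  parts <- lapply(colnames(calls), function(m) {
    data.frame(read_id = reads, method_id = m, taxon_id = calls[, m],
               score = NA_real_,
               read_length = if (is.null(read_lengths)) NA_integer_ else
                 as.integer(read_lengths),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# Shared small mock-genome set (built once per test run).
mock10 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_mock_genomes(10, genome_length = 50000, seed = 20260101)
    }
    cache
  }
})

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
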