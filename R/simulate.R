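# Diversity-driven metagenome read simulation: community design from a
# Shannon H' target under a dominance cap, rarefaction-curve fitting,
# fragment sampling, and a 454-style error model (point substitutions plus
# homopolymer-run edits).

# Geometric rank-abundance series p_i proportional to theta^(i-1), clipped
# at the dominance cap by water-filling: because weights are decreasing,
# the capped set is always a prefix, so we search for the smallest prefix
# length k such that redistributing the remaining mass over the tail keeps
# every entry at or below the cap.
.capped_geometric <- function(S, theta, cap) {
  if (S == 1L) return(1)
  w <- theta^(seq_len(S) - 1)
  p <- w / sum(w)
  for (k in 0:(S - 1L)) {
    tail_mass <- 1 - k * cap
    if (tail_mass < 0) break
    tail_w <- w[(k + 1L):S]
    q <- tail_w / sum(tail_w) * tail_mass
    if (all(q <= cap + 1e-12)) {
      return(c(rep(cap, k), q))
    }
  }
  rep(1 / S, S)  # cap == 1/S exactly: uniform is the only feasible profile
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Feasible entropy range for S taxa under a dominance cap: the most
# concentrated profile packs floor(1/cap) entries at the cap (+ remainder),
# the least concentrated is uniform.
.entropy_bounds <- function(S, cap) {
  if (S == 1L) return(c(0, 0))
  k <- floor(1 / cap + 1e-9)
  k <- min(k, S)
  r <- 1 - k * cap
  hmin <- if (r > 1e-12) -(k * cap * log(cap) + r * log(r)) else -k * cap * log(cap)
  c(hmin, log(S))
}

#' Design a community profile from a Shannon-diversity target
#'
#' Selects `max_taxa` genomes uniformly at random and assigns relative
#' abundances from a geometric rank-abundance series `p_i` proportional to
#' `theta^(i-1)`, truncated at the dominance cap with the excess mass
#' redistributed proportionally over the tail.  `theta` is solved by
#' bisection so that the realized Shannon entropy matches `H_target` to
#' within 1e-3 nats.
#'
#' Feasibility: `H_target` must lie between the entropy of the most
#' concentrated cap-respecting profile (about `ln(1/cap)` nats) and
#' `ln(max_taxa)`; additionally `dominance_cap * max_taxa >= 1`.
#'
#' @param genomes Data frame with columns `genome_id` and `taxon_id` (extra
#'   columns such as `sequence` are carried through).
#' @param H_target Target Shannon diversity H' in nats.
#' @param dominance_cap Maximum relative abundance for any single species,
#'   in (0, 1] (the simulated scenarios use 0.05 and 0.80).
#' @param max_taxa Number of genomes to include.
#' @param seed Optional integer seed.
#' @return A `community_profile`: data frame with `genome_id`, `taxon_id`,
#'   `abundance`, plus attributes `H_target`, `H_realized`,
#'   `dominance_cap`.
#' @export
design_community <- function(genomes, H_target, dominance_cap, max_taxa,
                             seed = NULL) {
  stopifnot(is.data.frame(genomes),
            all(c("genome_id", "taxon_id") %in% names(genomes)))
  max_taxa <- as.integer(max_taxa)
  if (dominance_cap <= 0 || dominance_cap > 1) {
    stop("configuration error: dominance_cap must be in (0, 1]", call. = FALSE)
  }
  if (dominance_cap * max_taxa < 1 - 1e-9) {
    stop("configuration error: dominance_cap * max_taxa must be >= 1 ",
         "(no valid probability vector exists)", call. = FALSE)
  }
  if (nrow(genomes) < max_taxa) {
    stop("configuration error: need at least max_taxa candidate genomes",
         call. = FALSE)
  }
  bounds <- .entropy_bounds(max_taxa, dominance_cap)
  if (H_target > bounds[2] + 1e-9) {
    stop("configuration error: H_target exceeds ln(max_taxa) = ",
         signif(bounds[2], 6), call. = FALSE)
  }
  if (H_target < bounds[1] - 1e-9) {
    stop("configuration error: H_target = ", H_target, " is below the ",
         "minimum entropy ", signif(bounds[1], 6),
         " attainable when every abundance is capped at ", dominance_cap,
         call. = FALSE)
  }
  .set_seed_if(seed)
  pick <- genomes[sample.int(nrow(genomes), max_taxa), , drop = FALSE]
  if (max_taxa == 1L) {
    p <- 1
  } else {
    ent <- function(theta) .shannon(.capped_geometric(max_taxa, theta, dominance_cap))
    lo <- 1e-12
    hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (ent(mid) < H_target) lo <- mid else hi <- mid
    }
    p <- .capped_geometric(max_taxa, hi, dominance_cap)
  }
  H <- .shannon(p)
  if (abs(H - H_target) > 1e-3) {
    stop("configuration error: could not reach H_target within 1e-3 nats ",
         "(realized ", signif(H, 6), ")", call. = FALSE)
  }
  prof <- data.frame(pick, abundance = p, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(prof,
            H_target = H_target, H_realized = H,
            dominance_cap = dominance_cap,
            class = c("community_profile", "data.frame"))
}

#' Fit the rarefaction (species-accumulation) curve through three anchors
#'
#' Computes the expected accumulation curve
#' `E[S(n)] = sum_i (1 - (1 - p_i)^n)`, locates the "maximum linear point"
#' (the largest read count where the local slope is still at least `1/e`
#' of the initial slope; the fraction is configurable), and least-squares
#' fits `S(n) = a * ln(1 + b * n)` through the three anchor points
#' `(0, 0)`, `(n_linear, E[S(n_linear)])` and `(n_reads, max_taxa)`.
#'
#' A single-taxon profile is degenerate (the accumulation curve is constant
#' after the first read): the curve is returned with `degenerate = TRUE`
#' and parameters chosen so the fit passes exactly through
#' `(n_reads, 1)` and stays at or below 1 on the sampled range.
#'
#' @param n_reads Total reads to be sampled.
#' @param max_taxa Expected number of taxa (the end anchor's height).
#' @param profile A `community_profile`.
#' @param slope_fraction Slope threshold defining the maximum linear point,
#'   as a fraction of the initial slope (default `1/e`).
#' @return A `rarefaction_curve`: list with `a`, `b`, `anchors` (data
#'   frame), `degenerate`.  Use [predict.rarefaction_curve()] to evaluate.
#' @export
fit_rarefaction <- function(n_reads, max_taxa, profile,
                            slope_fraction = exp(-1)) {
  stopifnot(n_reads > 0, max_taxa >= 1)
  p <- profile$abundance
  if (length(p) == 1L || max(p) >= 1 - 1e-12) {
    warning("degenerate single-taxon profile: accumulation curve is constant",
            call. = FALSE)
    b <- 1
    a <- 1 / log(1 + b * n_reads)
    anchors <- data.frame(n = c(0, 1, n_reads), s = c(0, 1, 1))
    return(structure(list(a = a, b = b, anchors = anchors, degenerate = TRUE),
                     class = "rarefaction_curve"))
  }
  es <- function(n) sum(1 - (1 - p)^n)
  slope <- function(n) sum(-log(1 - p) * (1 - p)^n)  # dE[S]/dn, decreasing
  thresh <- slope_fraction * slope(0)
  lo <- 0
  hi <- n_reads
  if (slope(n_reads) >= thresh) {
    n_lin <- n_reads
  } else {
    while (hi - lo > 1) {  # largest integer n with slope(n) >= thresh
      mid <- floor((lo + hi) / 2)
      if (slope(mid) >= thresh) lo <- mid else hi <- mid
    }
    n_lin <- lo
  }
  anchors <- data.frame(n = c(0, n_lin, n_reads),
                        s = c(0, es(n_lin), max_taxa))
  b0 <- if (n_lin > 0) 1 / n_lin else 1 / max(1, n_reads / 10)
  a0 <- max_taxa / log(1 + b0 * n_reads)
  fit <- minpack.lm::nlsLM(
    s ~ a * log(1 + b * n), data = anchors,
    start = list(a = a0, b = b0),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
                 anchors = anchors, degenerate = FALSE),
            class = "rarefaction_curve")
}

#' Evaluate a fitted rarefaction curve
#' @param object A `rarefaction_curve`.
#' @param n Read counts at which to evaluate.
#' @param ... Ignored.
#' @return Expected number of taxa at each `n`.
#' @export
predict.rarefaction_curve <- function(object, n, ...) {
  object$a * log(1 + object$b * n)
}

#' Sample error-free fragments from a genome
#'
#' Fragment lengths are uniform on `[fragment_min, fragment_max]`, start
#' positions uniform over valid positions, strand Bernoulli(0.5) with
#' minus-strand fragments reverse-complemented.  Coordinates are 0-based
#' half-open on the forward strand.
#'
#' @param genome_sequence Single DNA string.
#' @param n Number of fragments.
#' @param fragment_min,fragment_max Length range in bp (defaults 350-600).
#' @param seed Optional integer seed.
#' @param genome_id,taxon_id Provenance recorded in the truth columns.
#' @return Data frame of simulated reads: `read_id`, `sequence`,
#'   `source_genome_id`, `source_taxon_id`, `start`, `end`, `strand`,
#'   `n_substitutions`, `n_homopolymer_edits`.
#' @export
sample_fragments <- function(genome_sequence, n, fragment_min = 350L,
                             fragment_max = 600L, seed = NULL,
                             genome_id = "genome", taxon_id = NA_character_) {
  stopifnot(length(genome_sequence) == 1L, fragment_min <= fragment_max,
            fragment_min >= 1)
  L <- nchar(genome_sequence)
  if (L < fragment_max) {
    stop("genome-too-short error: genome '", genome_id, "' has length ", L,
         " < fragment_max = ", fragment_max, call. = FALSE)
  }
  n <- as.integer(n)
  empty <- data.frame(read_id = character(), sequence = character(),
                      source_genome_id = character(),
                      source_taxon_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_substitutions = integer(),
                      n_homopolymer_edits = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  .set_seed_if(seed)
  lens <- fragment_min + sample.int(fragment_max - fragment_min + 1L, n,
                                    replace = TRUE) - 1L
  start <- as.integer(floor(stats::runif(n) * (L - lens + 1L)))  # 0-based
  end <- start + lens
  seqs <- substring(genome_sequence, start + 1L, end)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  neg <- strand == "-"
  if (any(neg)) {
    seqs[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
  }
  data.frame(read_id = sprintf("%s_r%06d", genome_id, seq_len(n)),
             sequence = seqs,
             source_genome_id = genome_id,
             source_taxon_id = taxon_id,
             start = start, end = end, strand = strand,
             n_substitutions = 0L, n_homopolymer_edits = 0L,
             stringsAsFactors = FALSE)
}

# Batch error model over a character vector of sequences.  Substitutions
# first (uniform among the three alternative bases), then homopolymer-run
# edits on the substituted sequence: each maximal run of length >= 2 is
# lengthened or shortened by 1 (equal odds) with probability
# min(1, homopolymer_rate * run_length).  Returns sequences plus per-read
# edit counters.
.mutate_sequences <- function(seqs, substitution_rate, homopolymer_rate) {
  n_reads <- length(seqs)
  chs <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chs)
  flat <- unlist(chs, use.names = FALSE)
  read_of <- rep.int(seq_len(n_reads), lens)
  n_sub <- integer(n_reads)
  if (substitution_rate > 0 && length(flat)) {
    hit <- which(stats::runif(length(flat)) < substitution_rate)
    if (length(hit)) {
      alt <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"), nrow = 3L,
                    dimnames = list(NULL, .BASES))
      base_ix <- match(flat[hit], .BASES)
      known <- !is.na(base_ix)  # leave ambiguity codes untouched
      if (any(known)) {
        h <- hit[known]
        pick <- sample.int(3L, length(h), replace = TRUE)
        flat[h] <- alt[cbind(pick, base_ix[known])]
        n_sub <- tabulate(read_of[h], nbins = n_reads)
      }
    }
  }
  n_hp <- integer(n_reads)
  if (homopolymer_rate > 0 && length(flat)) {
    # interleave a separator after each read so runs never span reads
    total <- length(flat) + n_reads
    flat2 <- character(total)
    flat2[seq_along(flat) + (read_of - 1L)] <- flat
    sep_pos <- cumsum(lens + 1L)
    flat2[sep_pos] <- "|"
    read_of2 <- rep.int(seq_len(n_reads), lens + 1L)
    r <- rle(flat2)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    eligible <- r$lengths >= 2L & r$values != "|"
    if (any(eligible)) {
      idx <- which(eligible)
      pr <- pmin(1, homopolymer_rate * r$lengths[idx])
      edit <- stats::runif(length(idx)) < pr
      idx <- idx[edit]
      if (length(idx)) {
        dir <- ifelse(stats::runif(length(idx)) < 0.5, -1L, 1L)
        r$lengths[idx] <- r$lengths[idx] + dir
        n_hp <- tabulate(read_of2[run_start[idx]], nbins = n_reads)
      }
    }
    big <- paste(inverse.rle(r), collapse = "")
    seqs <- strsplit(big, "|", fixed = TRUE)[[1L]]
    if (length(seqs) != n_reads) {
      stop("internal error: read boundary lost in homopolymer stage")
    }
  } else {
    first <- cumsum(c(1L, lens[-n_reads]))
    seqs <- substring(paste(flat, collapse = ""), first, first + lens - 1L)
  }
  list(sequence = seqs, n_substitutions = n_sub, n_homopolymer_edits = n_hp)
}

#' Apply the sequencing error model to simulated reads
#'
#' Point substitutions and homopolymer-run edits are modeled separately,
#' after the characteristic error modes of pyrosequencing platforms.  Each
#' base is substituted with probability `substitution_rate` (uniform among
#' the three alternatives); each maximal homopolymer run of length >= 2 is
#' lengthened or shortened by one base (equal odds) with probability
#' `min(1, homopolymer_rate * run_length)`.  Rates of zero leave the reads
#' untouched.
#'
#' @param reads Data frame of simulated reads (one or more rows), as
#'   returned by [sample_fragments()].
#' @param substitution_rate Per-base substitution probability in `[0, 1)`.
#' @param homopolymer_rate Per-run probability scale in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The reads with mutated `sequence` and updated
#'   `n_substitutions` / `n_homopolymer_edits` counters.
#' @export
apply_error_model <- function(reads, substitution_rate = 0.001,
                              homopolymer_rate = 0.01, seed = NULL) {
  stopifnot(is.data.frame(reads),
            substitution_rate >= 0, substitution_rate < 1,
            homopolymer_rate >= 0, homopolymer_rate < 1)
  if (!nrow(reads)) return(reads)
  .set_seed_if(seed)
  m <- .mutate_sequences(reads$sequence, substitution_rate, homopolymer_rate)
  reads$sequence <- m$sequence
  reads$n_substitutions <- reads$n_substitutions + m$n_substitutions
  reads$n_homopolymer_edits <- reads$n_homopolymer_edits + m$n_homopolymer_edits
  reads
}

#' Simulate a metagenome read set
#'
#' End-to-end simulator: designs the community from the H' target and
#' dominance cap, fits the rarefaction curve, allocates the read budget
#' across genomes by a multinomial draw on the abundances, samples
#' fragments, and applies the error model.  The run is fully reproducible
#' from `config$seed`; each stage draws from a named substream derived
#' with [derive_seed()].
#'
#' @param config A list (see [simulation_config()]) with fields `H_target`,
#'   `n_reads`, `max_taxa`, `dominance_cap`, `fragment_min`, `fragment_max`,
#'   `substitution_rate`, `homopolymer_rate`, `seed`, and `genome_set` (a
#'   data frame with `genome_id`, `taxon_id`, `sequence`).
#' @return A `metagenome_simulation`: list with `reads` (data frame with
#'   sequence + truth columns), `profile`, `curve`, `config`.  Use
#'   [write_simulation()] to emit the reads FASTA and truth TSV.
#' @export
simulate_metagenome <- function(config) {
  config <- simulation_config(config)
  gs <- config$genome_set
  stopifnot(is.data.frame(gs),
            all(c("genome_id", "taxon_id", "sequence") %in% names(gs)))
  profile <- design_community(gs, config$H_target, config$dominance_cap,
                              config$max_taxa,
                              seed = derive_seed(config$seed, "community"))
  curve <- fit_rarefaction(config$n_reads, config$max_taxa, profile)
  set.seed(derive_seed(config$seed, "allocation"))
  counts <- as.integer(stats::rmultinom(1L, config$n_reads, profile$abundance))
  parts <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    if (counts[i] == 0L) next
    parts[[i]] <- sample_fragments(
      profile$sequence[i], counts[i],
      config$fragment_min, config$fragment_max,
      seed = derive_seed(config$seed, paste0("fragments/", profile$genome_id[i])),
      genome_id = profile$genome_id[i], taxon_id = profile$taxon_id[i])
  }
  reads <- do.call(rbind, parts[!vapply(parts, is.null, logical(1L))])
  rownames(reads) <- NULL
  reads <- apply_error_model(reads, config$substitution_rate,
                             config$homopolymer_rate,
                             seed = derive_seed(config$seed, "errors"))
  structure(list(reads = reads, profile = profile, curve = curve,
                 config = config),
            class = "metagenome_simulation")
}

#' Build / validate a simulation configuration
#'
#' Fills defaults (fragment range 350-600 bp; substitution rate 0.001;
#' homopolymer rate 0.01; seed 1) and checks the feasibility invariants:
#' `0 < dominance_cap <= 1`, `fragment_min <= fragment_max`,
#' `dominance_cap * max_taxa >= 1` and `H_target <= ln(max_taxa)`.
#'
#' @param config Named list of configuration values.
#' @return The completed configuration list (class `simulation_config`).
#' @export
simulation_config <- function(config) {
  if (inherits(config, "simulation_config")) return(config)
  defaults <- list(fragment_min = 350L, fragment_max = 600L,
                   substitution_rate = 0.001, homopolymer_rate = 0.01,
                   seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  required <- c("H_target", "n_reads", "max_taxa", "dominance_cap", "genome_set")
  miss <- required[!required %in% names(config)]
  if (length(miss)) {
    stop("configuration error: missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (config$fragment_min > config$fragment_max) {
    stop("configuration error: fragment_min > fragment_max", call. = FALSE)
  }
  if (config$dominance_cap <= 0 || config$dominance_cap > 1) {
    stop("configuration error: dominance_cap must be in (0, 1]", call. = FALSE)
  }
  if (config$dominance_cap * config$max_taxa < 1 - 1e-9) {
    stop("configuration error: dominance_cap * max_taxa must be >= 1",
         call. = FALSE)
  }
  if (config$H_target > log(config$max_taxa) + 1e-9) {
    stop("configuration error: H_target exceeds ln(max_taxa)", call. = FALSE)
  }
  class(config) <- "simulation_config"
  config
}

#' Write simulated reads (FASTA) and the truth table (TSV)
#'
#' The truth table has one row per read (`read_id`, `genome_id`,
#' `taxon_id`, `start`, `end`, `strand`, `length`) and a
#' `#coords=0-based-half-open` header line; `length` is the pre-error
#' fragment length `end - start`.
#'
#' @param sim A `metagenome_simulation`.
#' @param out_prefix Path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.truth.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(sim, out_prefix) {
  stopifnot(inherits(sim, "metagenome_simulation"))
  fasta <- paste0(out_prefix, ".fasta")
  truth <- paste0(out_prefix, ".truth.tsv")
  write_fasta(data.frame(id = sim$reads$read_id, sequence = sim$reads$sequence),
              fasta)
  con <- file(truth, "w")
  on.exit(close(con))
  writeLines(c("#coords=0-based-half-open",
               "read_id\tgenome_id\ttaxon_id\tstart\tend\tstrand\tlength"), con)
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%d",
                     sim$reads$read_id, sim$reads$source_genome_id,
                     sim$reads$source_taxon_id, sim$reads$start,
                     sim$reads$end, sim$reads$strand,
                     sim$reads$end - sim$reads$start), con)
  invisible(c(fasta = fasta, truth = truth))
}

#' Diverge a genome by substitutions and single-base indels
#'
#' A simplified novel-taxon generator: applies per-base substitutions and
#' per-position single-base insertions/deletions at the given rates.  Used
#' to build divergent genomes that behave as taxa absent from the training
#' set in downstream evaluation scenarios.
#'
#' @param genome_sequence Single DNA string.
#' @param substitution_rate Per-base substitution probability in `[0, 0.5)`.
#' @param indel_rate Per-position probability of an insertion and,
#'   independently, of a deletion, each in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return The diverged sequence (single string).
#' @export
diverge_genome <- function(genome_sequence, substitution_rate, indel_rate,
                           seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate < 0.5,
            indel_rate >= 0, indel_rate < 0.5)
  .set_seed_if(seed)
  ch <- strsplit(genome_sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(n) < substitution_rate)
    if (length(hit)) {
      alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                      "A", "C", "G"), nrow = 3L, dimnames = list(NULL, .BASES))
      bi <- match(ch[hit], .BASES)
      ok <- !is.na(bi)
      ch[hit[ok]] <- alt[cbind(sample.int(3L, sum(ok), replace = TRUE), bi[ok])]
    }
  }
  if (indel_rate > 0) {
    del <- stats::runif(n) < indel_rate
    ins <- stats::runif(n) < indel_rate
    ins_vec <- character(n)
    if (any(ins)) ins_vec[ins] <- sample(.BASES, sum(ins), replace = TRUE)
    ch <- paste0(ifelse(del, "", ch), ins_vec)
  }
  paste(ch, collapse = "")
}

#' Generate mock genomes with a balanced seven-rank taxonomy
#'
#' Emits i.i.d. random genomes at a given GC content, attached to a
#' generated taxonomy covering all seven canonical ranks (binary grouping
#' above species; a single root above domain).  `tree_depth` controls how
#' many of the deepest canonical ranks are materialized (default 7, i.e.
#' all; smaller values drop the shallowest ranks so those lineages project
#' to `NO_RANK` there, emulating virus-like lineages).
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length of each genome in bp.
#' @param gc_content Target GC fraction.
#' @param tree_depth Number of canonical ranks (from species upward) to
#'   include, 1-7.
#' @param seed Optional integer seed.
#' @param dir Optional directory: when given, writes `genomes.fasta`,
#'   `taxonomy.tsv` (4-column dialect) and `genome_taxon_map.tsv`.
#' @return List with `genomes` (data frame `genome_id`, `taxon_id`,
#'   `sequence`), `taxonomy` (a `taxonomy_tree`), `map` (data frame
#'   `genome_id`, `taxon_id`) and, if `dir` was given, `files`.
#' @export
make_mock_genomes <- function(n_genomes, genome_length = 50000L,
                              gc_content = 0.5, tree_depth = 7L,
                              seed = NULL, dir = NULL) {
  stopifnot(n_genomes >= 1, genome_length >= 1,
            gc_content >= 0, gc_content <= 1,
            tree_depth >= 1, tree_depth <= 7)
  .set_seed_if(seed)
  ranks <- utils::tail(canonical_ranks(), tree_depth)
  short <- c(domain = "dom", phylum = "phy", class = "cls", order = "ord",
             family = "fam", genus = "gen", species = "sp")
  depth_of <- match(ranks, canonical_ranks())  # 1 = domain ... 7 = species
  rows <- list(data.frame(taxon_id = "root", parent_id = "root",
                          rank = "no rank", name = "root",
                          stringsAsFactors = FALSE))
  id_at <- function(rank, i) sprintf("%s%03d", short[[rank]], i)
  group_ix <- function(i, rank_depth) {
    # species index i collapses by powers of two toward the root
    pmax(1L, ceiling(i / 2L^(7L - rank_depth)))
  }
  for (j in seq_along(ranks)) {
    d <- depth_of[j]
    idx <- unique(group_ix(seq_len(n_genomes), d))
    parent_rank <- if (j == 1L) NA else ranks[j - 1L]
    for (i in idx) {
      pid <- if (is.na(parent_rank)) "root" else {
        id_at(parent_rank, group_ix(which(group_ix(seq_len(n_genomes), d) == i)[1L],
                                    depth_of[j - 1L]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = id_at(ranks[j], i), parent_id = pid, rank = ranks[j],
        name = sprintf("Mock %s %d", ranks[j], i), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tsv <- sprintf("%s\t%s\t%s\t%s", tab$taxon_id, tab$parent_id, tab$rank, tab$name)
  taxonomy <- load_taxonomy(tsv, format = "tsv")
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  seqs <- vapply(seq_len(n_genomes), function(i) {
    paste(sample(.BASES, genome_length, replace = TRUE, prob = probs),
          collapse = "")
  }, "")
  genomes <- data.frame(
    genome_id = sprintf("g%03d", seq_len(n_genomes)),
    taxon_id = vapply(seq_len(n_genomes),
                      function(i) id_at("species", i), ""),
    sequence = seqs, stringsAsFactors = FALSE)
  out <- list(genomes = genomes, taxonomy = taxonomy,
              map = genomes[, c("genome_id", "taxon_id")])
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genomes.fasta")
    tx <- file.path(dir, "taxonomy.tsv")
    mp <- file.path(dir, "genome_taxon_map.tsv")
    write_fasta(data.frame(id = genomes$genome_id, sequence = genomes$sequence), fa)
    writeLines(tsv, tx)
    utils::write.table(out$map, mp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out$files <- c(genomes = fa, taxonomy = tx, map = mp)
  }
  out
}

#' Built-in simulation scenario configurations
#'
#' Parameter sets mirroring the four simulated diversity scenarios: 60,000
#' reads each, fragment lengths 350-600 bp, dominance cap 0.05
#' (non-dominant) or 0.80 (dominant).  The per-scenario diversity targets
#' and community sizes are package defaults chosen to be realistic for
#' skin-like communities (see the methods vignette); all values can be
#' overridden.
#'
#' @param name One of `"all_genomes"`, `"all_genomes_dominant"`,
#'   `"bacterial_genomes"`, `"bacterial_genomes_dominant"`.
#' @return Named list of simulation parameters (without `genome_set`).
#' @export
scenario_config <- function(name = c("all_genomes", "all_genomes_dominant",
                                     "bacterial_genomes",
                                     "bacterial_genomes_dominant")) {
  name <- match.arg(name)
  base <- list(n_reads = 60000L, fragment_min = 350L, fragment_max = 600L,
               substitution_rate = 0.001, homopolymer_rate = 0.01)
  extra <- switch(name,
    all_genomes = list(max_taxa = 40L, dominance_cap = 0.05, H_target = 3.4),
    all_genomes_dominant = list(max_taxa = 40L, dominance_cap = 0.80,
                                H_target = 1.5),
    bacterial_genomes = list(max_taxa = 30L, dominance_cap = 0.05,
                             H_target = 3.2),
    bacterial_genomes_dominant = list(max_taxa = 30L, dominance_cap = 0.80,
                                      H_target = 1.5))
  c(base, extra, list(scenario = name))
}
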