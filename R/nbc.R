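# Naive Bayes k-mer classifier: a compact composition-based assigner so
# the full pipeline runs without external binaries.  Training counts all
# overlapping k-mers per genome on both strands (strand-collapsed by
# adding reverse-complement counts), with add-one smoothing and
# log-normalization over the 4^k k-mer space.

#' Train the naive Bayes k-mer classifier
#'
#' @param genomes Data frame with `genome_id` and `sequence` columns (as
#'   produced by [make_mock_genomes()]), or a named character vector of
#'   sequences.
#' @param genome_taxa Named character vector mapping genome ids to taxon
#'   ids, or a data frame with `genome_id` and `taxon_id`.  May be omitted
#'   when `genomes` is a data frame that already carries `taxon_id`.
#' @param k K-mer size, 4-12 (default 8).
#' @return An `nbc_model`: list with `k`, `logp` (genomes x 4^k matrix of
#'   log k-mer probabilities), `taxa` (genome -> taxon map).
#' @export
train_nbc <- function(genomes, genome_taxa = NULL, k = 8L) {
  k <- as.integer(k)
  if (k < 4L || k > 12L) stop("k must be in [4, 12]", call. = FALSE)
  if (is.data.frame(genomes)) {
    seqs <- stats::setNames(genomes$sequence, genomes$genome_id)
    if (is.null(genome_taxa) && "taxon_id" %in% names(genomes)) {
      genome_taxa <- stats::setNames(genomes$taxon_id, genomes$genome_id)
    }
  } else {
    seqs <- genomes
  }
  if (is.data.frame(genome_taxa)) {
    genome_taxa <- stats::setNames(genome_taxa$taxon_id, genome_taxa$genome_id)
  }
  if (is.null(names(seqs))) stop("genomes must be named", call. = FALSE)
  orphans <- setdiff(names(seqs), names(genome_taxa))
  if (length(orphans)) {
    stop("training error: genome(s) without a taxon mapping: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) <= k)) {
    stop("training error: genome(s) shorter than k: ",
         paste(names(seqs)[nchar(seqs) <= k], collapse = ", "), call. = FALSE)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = k) +
    Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(dss),
                                         width = k)
  logp <- log(counts + 1) - log(rowSums(counts) + 4^k)
  rownames(logp) <- names(seqs)
  structure(list(k = k, logp = logp,
                 taxa = genome_taxa[names(seqs)]),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("nbc_model: k =", x$k, ",", nrow(x$logp), "genomes,",
      length(unique(x$taxa)), "taxa\n")
  invisible(x)
}

#' Classify reads with the naive Bayes k-mer model
#'
#' Each read's score under genome g is the sum over its k-mers of the
#' genome's log k-mer probability; the assigned taxon is the argmax
#' genome's taxon.  Ties are broken by lexicographic genome id (and
#' reported via a message).  Reads shorter than k are `UNASSIGNED` and
#' flagged in the `too_short` attribute.
#'
#' @param model An `nbc_model`.
#' @param read_sequences Character vector of read sequences.
#' @param read_ids Optional read ids (defaults to `read_1`, ...).
#' @param method_id Method label (default `"nbc"`).
#' @param restrict Optional character vector of genome ids: score only
#'   these candidates (used by the BLAST-combined mode).
#' @return Assignment data frame with attributes `loglik` (reads x
#'   genomes matrix of log-likelihoods) and `too_short` (logical vector).
#' @export
nbc_classify <- function(model, read_sequences, read_ids = NULL,
                         method_id = "nbc", restrict = NULL) {
  stopifnot(inherits(model, "nbc_model"))
  n <- length(read_sequences)
  if (is.null(read_ids)) read_ids <- sprintf("read_%d", seq_len(n))
  logp <- model$logp
  if (!is.null(restrict)) {
    restrict <- intersect(restrict, rownames(logp))
    if (!length(restrict)) {
      out <- .assignment_row(read_ids, method_id,
                             read_length = nchar(read_sequences))
      attr(out, "loglik") <- matrix(NA_real_, n, 0L)
      attr(out, "too_short") <- nchar(read_sequences) < model$k
      return(out)
    }
    logp <- logp[restrict, , drop = FALSE]
  }
  # lexicographic genome order makes argmax ties deterministic
  logp <- logp[order(rownames(logp)), , drop = FALSE]
  too_short <- nchar(read_sequences) < model$k
  ll <- matrix(NA_real_, n, nrow(logp),
               dimnames = list(read_ids, rownames(logp)))
  ok <- which(!too_short)
  if (length(ok)) {
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(read_sequences[ok]), width = model$k)
    ll[ok, ] <- counts %*% t(logp)
  }
  taxon <- rep(.UNASSIGNED, n)
  score <- rep(NA_real_, n)
  if (length(ok)) {
    best_ix <- max.col(ll[ok, , drop = FALSE], ties.method = "first")
    rmax <- ll[cbind(ok, best_ix)]
    ties <- rowSums(ll[ok, , drop = FALSE] == rmax) > 1L
    if (any(ties)) {
      message("nbc_classify: ", sum(ties), " tie(s) broken by lexicographic ",
              "genome id")
    }
    taxon[ok] <- unname(model$taxa[rownames(logp)[best_ix]])
    score[ok] <- rmax
  }
  out <- .assignment_row(read_ids, method_id, taxon_id = taxon, score = score,
                         read_length = nchar(read_sequences))
  attr(out, "loglik") <- ll
  attr(out, "too_short") <- too_short
  out
}

#' LCA-flavored variant of the k-mer classifier
#'
#' Assigns the lowest common ancestor of the taxa of all genomes scoring
#' within `margin` log-units of the best genome.  This yields conservative
#' higher-rank calls when several references are nearly equally likely,
#' and serves as an LCA-style member of a method roster when no BLAST
#' output is available.
#'
#' @param model An `nbc_model`.
#' @param read_sequences Character vector of read sequences.
#' @param tree A `taxonomy_tree` containing the model's taxa.
#' @param margin Log-likelihood window below the best score (default 10).
#' @param read_ids Optional read ids.
#' @param method_id Method label (default `"nbc_lca"`).
#' @return Assignment data frame.
#' @export
nbc_lca_classify <- function(model, read_sequences, tree, margin = 10,
                             read_ids = NULL, method_id = "nbc_lca") {
  base <- nbc_classify(model, read_sequences, read_ids = read_ids,
                       method_id = method_id)
  ll <- attr(base, "loglik")
  for (i in seq_len(nrow(base))) {
    if (base$taxon_id[i] == .UNASSIGNED) next
    within <- ll[i, ] >= max(ll[i, ]) - margin
    base$taxon_id[i] <- lca(tree, unique(unname(model$taxa[colnames(ll)[within]])))
  }
  base
}

#' Noise-perturbed variant of the k-mer classifier
#'
#' Adds i.i.d. Gaussian noise to the per-genome log-likelihoods before the
#' argmax, producing a deliberately degraded method for consistency
#' studies (a stand-in third roster member).
#'
#' @param model An `nbc_model`.
#' @param read_sequences Character vector of read sequences.
#' @param noise_sd Standard deviation of the added noise in log-units.
#' @param seed Optional integer seed.
#' @param read_ids Optional read ids.
#' @param method_id Method label (default `"nbc_noisy"`).
#' @return Assignment data frame.
#' @export
nbc_noisy_classify <- function(model, read_sequences, noise_sd = 30,
                               seed = NULL, read_ids = NULL,
                               method_id = "nbc_noisy") {
  base <- nbc_classify(model, read_sequences, read_ids = read_ids,
                       method_id = method_id)
  ll <- attr(base, "loglik")
  .set_seed_if(seed)
  ll2 <- ll + matrix(stats::rnorm(length(ll), sd = noise_sd), nrow(ll))
  ok <- which(base$taxon_id != .UNASSIGNED)
  if (length(ok)) {
    best_ix <- max.col(ll2[ok, , drop = FALSE], ties.method = "first")
    base$taxon_id[ok] <- unname(model$taxa[colnames(ll)[best_ix]])
    base$score[ok] <- ll2[cbind(ok, best_ix)]
  }
  attr(base, "loglik") <- ll2
  base
}

#' Serialize an NBC model to plain text
#'
#' Header lines carry `k` and the genome-to-taxon map; the body is one row
#' of full-precision log-probabilities per genome.
#'
#' @param model An `nbc_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_nbc_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k\t%d", model$k), con)
  writeLines(sprintf("#genome\t%s\t%s", names(model$taxa), model$taxa), con)
  writeLines(paste0("#kmers\t", paste(colnames(model$logp), collapse = "\t")),
             con)
  for (g in rownames(model$logp)) {
    writeLines(paste(c(g, sprintf("%.17g", model$logp[g, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read an NBC model written by [write_nbc_model()]
#' @param path Input file path.
#' @return An `nbc_model`.
#' @export
read_nbc_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  k <- as.integer(strsplit(lines[grepl("^#k\t", lines)][1L], "\t")[[1L]][2L])
  gm <- strsplit(lines[grepl("^#genome\t", lines)], "\t", fixed = TRUE)
  taxa <- stats::setNames(vapply(gm, `[[`, "", 3L), vapply(gm, `[[`, "", 2L))
  kmers <- strsplit(lines[grepl("^#kmers\t", lines)][1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- strsplit(lines[!startsWith(lines, "#")], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, "", 1L)
  logp <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1L])))
  dimnames(logp) <- list(ids, kmers)
  structure(list(k = k, logp = logp, taxa = taxa[ids]), class = "nbc_model")
}
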