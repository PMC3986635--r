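# Per-read taxonomic assignment: BLAST tabular parsing, LCA summarization
# of hits, epsilon cutoffs, BLAST-restricted combination, and adapters for
# externally produced assignment tables.

.BLAST_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "e_value",
                 "bit_score")

#' Parse BLAST tabular output (outfmt 6)
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param stream File path, connection, or character vector of lines.
#' @return Data frame with one row per hit (columns `query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `e_value`,
#'   `bit_score`).
#' @export
read_blast_tabular <- function(stream) {
  lines <- .as_lines(stream)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  empty <- stats::setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE),
    .BLAST_COLS)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("BLAST tabular parse error at line ", bad[1L], ": expected 12 ",
         "columns, found ", lengths(fields)[bad[1L]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = as.numeric(m[, 3L]),
    alignment_length = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_opens = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    e_value = as.numeric(m[, 11L]), bit_score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  if (any(out$e_value < 0) || any(!is.finite(out$bit_score))) {
    stop("BLAST tabular parse error: negative e-value or non-finite ",
         "bit score", call. = FALSE)
  }
  out
}

#' Serialize BLAST hits back to outfmt-6 lines
#' @param hits Data frame as returned by [read_blast_tabular()].
#' @param path Optional output file.
#' @return Invisibly, the character vector of lines.
#' @export
write_blast_tabular <- function(hits, path = NULL) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$subject_id,
                   format(hits$percent_identity, trim = TRUE, digits = 15),
                   hits$alignment_length, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   format(hits$e_value, trim = TRUE, digits = 15),
                   format(hits$bit_score, trim = TRUE, digits = 15))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

.assignment_row <- function(read_id, method_id, taxon_id = .UNASSIGNED,
                            score = NA_real_, read_length = NA_integer_) {
  data.frame(read_id = read_id, method_id = method_id, taxon_id = taxon_id,
             score = score, read_length = as.integer(read_length),
             stringsAsFactors = FALSE)
}

#' LCA assignment from BLAST hits of one query
#'
#' Hits with `e_value <= e_cutoff` are kept (default cutoff 1e-5); the
#' assignment is the lowest common ancestor of the kept hits' taxa.  With
#' no surviving hits the read is `UNASSIGNED`.  The score is the best
#' surviving bit score.  Subjects absent from `subject_taxa` are dropped
#' with a warning.
#'
#' @param hits Data frame of BLAST hits for a single query.
#' @param subject_taxa Named character vector mapping subject ids to taxon
#'   ids.
#' @param tree A `taxonomy_tree`.
#' @param e_cutoff E-value cutoff (> 0), default `1e-5`.
#' @param method_id Method label for the output row (default `"lca"`).
#' @return One-row assignment data frame (`read_id`, `method_id`,
#'   `taxon_id`, `score`, `read_length`) with attribute `kept_subjects`:
#'   the subject ids whose hits survived the cutoff.
#' @export
lca_assign <- function(hits, subject_taxa, tree, e_cutoff = 1e-5,
                       method_id = "lca") {
  stopifnot(e_cutoff > 0)
  query <- if (nrow(hits)) hits$query_id[1L] else NA_character_
  if (nrow(hits) && length(unique(hits$query_id)) > 1L) {
    stop("lca_assign() expects hits for a single query; see lca_assign_all()",
         call. = FALSE)
  }
  kept <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  taxa <- unname(subject_taxa[kept$subject_id])
  unmapped <- is.na(taxa)
  if (any(unmapped)) {
    warning("dropping ", sum(unmapped), " hit(s) whose subject has no taxon",
            " mapping: ",
            paste(utils::head(unique(kept$subject_id[unmapped]), 3L),
                  collapse = ", "), call. = FALSE)
    kept <- kept[!unmapped, , drop = FALSE]
    taxa <- taxa[!unmapped]
  }
  if (!nrow(kept)) {
    out <- .assignment_row(query, method_id)
    attr(out, "kept_subjects") <- character()
    return(out)
  }
  out <- .assignment_row(query, method_id, taxon_id = lca(tree, taxa),
                         score = max(kept$bit_score))
  attr(out, "kept_subjects") <- unique(kept$subject_id)
  out
}

#' LCA assignment over a full BLAST table
#'
#' Splits hits by query and applies [lca_assign()] to each.  Reads listed
#' in `read_ids` but absent from the hit table are emitted as
#' `UNASSIGNED`.
#'
#' @inheritParams lca_assign
#' @param read_ids Optional character vector of all read ids to report.
#' @return Assignment data frame, one row per read, with attribute
#'   `kept_subjects`: a named list of surviving subject ids per read.
#' @export
lca_assign_all <- function(hits, subject_taxa, tree, e_cutoff = 1e-5,
                           method_id = "lca", read_ids = NULL) {
  groups <- if (nrow(hits)) split(hits, hits$query_id) else list()
  rows <- lapply(groups, lca_assign, subject_taxa = subject_taxa,
                 tree = tree, e_cutoff = e_cutoff, method_id = method_id)
  kept <- lapply(rows, attr, "kept_subjects")
  out <- if (length(rows)) do.call(rbind, rows) else
    .assignment_row(character(), character())[0L, ]
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, out$read_id)
    if (length(missing)) {
      out <- rbind(out, .assignment_row(missing, method_id))
      kept[missing] <- replicate(length(missing), character(),
                                 simplify = FALSE)
    }
    out <- out[match(read_ids, out$read_id), , drop = FALSE]
    kept <- kept[read_ids]
  }
  rownames(out) <- NULL
  attr(out, "kept_subjects") <- kept
  out
}

#' Epsilon-cutoff configuration
#' @param epsilon Retention floor in `[0, 1]`.
#' @param mode `"nbc_only"` or `"lca_plus_nbc"`.
#' @return List of class `epsilon_config`.
#' @export
epsilon_config <- function(epsilon, mode = c("nbc_only", "lca_plus_nbc")) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  structure(list(epsilon = epsilon, mode = match.arg(mode)),
            class = "epsilon_config")
}

# Posterior mass of the best candidate from a log-likelihood vector,
# computed stably via log-sum-exp.
.posterior_best <- function(loglik) {
  ll <- loglik[is.finite(loglik)]
  if (!length(ll)) return(NA_real_)
  m <- max(ll)
  exp(m - (m + log(sum(exp(ll - m)))))
}

#' Apply an epsilon retention cutoff to classifier output
#'
#' The per-genome log-likelihood vector is converted to a posterior by
#' softmax; the assignment is retained iff the posterior mass of the best
#' candidate is at least `epsilon`.  `epsilon = 0` retains every
#' assignment; `epsilon = 1` retains only reads whose posterior is exactly
#' 1; the number of retained reads is non-increasing in `epsilon`.
#'
#' @param assignment Assignment data frame carrying a `loglik` attribute
#'   (a reads-by-genomes matrix), as returned by [nbc_classify()].
#' @param eps_config An [epsilon_config()] (or a bare epsilon value).
#' @return The assignment data frame with non-retained rows set to
#'   `UNASSIGNED` (score `NA`); the `loglik` attribute is preserved.
#' @export
apply_epsilon_cutoff <- function(assignment, eps_config) {
  if (!inherits(eps_config, "epsilon_config")) {
    eps_config <- epsilon_config(eps_config)
  }
  ll <- attr(assignment, "loglik")
  if (is.null(ll)) {
    stop("assignment lacks the per-genome log-likelihood vector", call. = FALSE)
  }
  eps <- eps_config$epsilon
  if (eps > 0) {
    post <- apply(ll, 1L, .posterior_best)
    drop <- !is.na(post) & post < eps & assignment$taxon_id != .UNASSIGNED
    assignment$taxon_id[drop] <- .UNASSIGNED
    assignment$score[drop] <- NA_real_
  }
  assignment
}

#' Combine BLAST evidence with the naive Bayes classifier
#'
#' Candidate genomes are restricted to those with a surviving BLAST hit
#' for the read; the classifier's argmax is taken over that restricted
#' set.  Reads with no surviving hits are never assigned, so reads foreign
#' to the reference set (contaminants) stay unclassified.
#'
#' @param blast_assignment One-row output of [lca_assign()] for the read
#'   (its `kept_subjects` attribute supplies the restriction set).
#' @param model An `nbc_model`.
#' @param read_sequence The read sequence.
#' @param tree A `taxonomy_tree` (carried for interface symmetry; the
#'   taxon comes from the model's genome-to-taxon map).
#' @param method_id Method label (default `"nbc_blast"`).
#' @return One-row assignment data frame.
#' @export
combine_blast_nbc <- function(blast_assignment, model, read_sequence, tree,
                              method_id = "nbc_blast") {
  read_id <- blast_assignment$read_id[1L]
  candidates <- intersect(attr(blast_assignment, "kept_subjects"),
                          rownames(model$logp))
  if (!length(candidates)) {
    return(.assignment_row(read_id, method_id,
                           read_length = nchar(read_sequence)))
  }
  a <- nbc_classify(model, read_sequence, read_ids = read_id,
                    method_id = method_id, restrict = candidates)
  a
}

#' Ingest an external per-read assignment table
#'
#' Adapter for outputs of external classifiers: a TSV with columns
#' `read_id`, `taxon` (id or scientific name), and optionally `score` and
#' `length`.  Names are resolved against the taxonomy's name index;
#' unresolvable taxa become `UNASSIGNED` with a warning.  The literal
#' `UNASSIGNED` is passed through.
#'
#' @param stream File path, connection, or character vector of lines.
#' @param method_id Method label for all rows.
#' @param tree Optional `taxonomy_tree` used to resolve names to ids.
#' @return Assignment data frame (`read_id`, `method_id`, `taxon_id`,
#'   `score`, `read_length`).
#' @export
ingest_external_assignments <- function(stream, method_id, tree = NULL) {
  lines <- .as_lines(stream)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^read_id\t", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) return(.assignment_row(character(), character())[0L, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("ingest error: line ", which(nf < 2L)[1L],
         " has fewer than 2 columns", call. = FALSE)
  }
  read_id <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(read_id)) {
    stop("ingest error: duplicate read_id within method '", method_id, "': ",
         read_id[duplicated(read_id)][1L], call. = FALSE)
  }
  taxon <- vapply(fields, `[[`, "", 2L)
  score <- vapply(fields, function(f)
    if (length(f) >= 3L && nzchar(f[[3L]])) as.numeric(f[[3L]]) else NA_real_,
    numeric(1L))
  len <- vapply(fields, function(f)
    if (length(f) >= 4L && nzchar(f[[4L]])) as.integer(f[[4L]]) else NA_integer_,
    integer(1L))
  resolved <- taxon
  if (!is.null(tree)) {
    keep <- taxon != .UNASSIGNED
    r <- resolve_taxa(tree, taxon[keep])
    if (anyNA(r)) {
      warning("ingest: ", sum(is.na(r)), " taxon name(s) could not be ",
              "resolved and were set to UNASSIGNED: ",
              paste(utils::head(unique(taxon[keep][is.na(r)]), 3L),
                    collapse = ", "), call. = FALSE)
    }
    resolved[keep] <- ifelse(is.na(r), .UNASSIGNED, r)
  }
  .assignment_row(read_id, method_id, taxon_id = resolved, score = score,
                  read_length = len)
}

#' Write an assignment table as TSV
#'
#' Columns `read_id`, `method_id`, `taxon_id`, `score`, `read_length`;
#' `UNASSIGNED` is spelled literally and missing scores/lengths are empty.
#'
#' @param assignments Assignment data frame.
#' @param path Optional output file.
#' @return Invisibly, the lines.
#' @export
write_assignments <- function(assignments, path = NULL) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, digits = 15))
  lines <- c("read_id\tmethod_id\ttaxon_id\tscore\tread_length",
             sprintf("%s\t%s\t%s\t%s\t%s", assignments$read_id,
                     assignments$method_id, assignments$taxon_id,
                     fmt(assignments$score), fmt(assignments$read_length)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read an assignment table written by [write_assignments()]
#' @param stream File path, connection, or character vector of lines.
#' @return Assignment data frame.
#' @export
read_assignments <- function(stream) {
  lines <- .as_lines(stream)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1L], "read_id\t")) lines <- lines[-1L]
  if (!length(lines)) return(.assignment_row(character(), character())[0L, ])
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, function(x)
    if (length(x) >= i) x[[i]] else "", "")
  .assignment_row(get(1L), get(2L), taxon_id = get(3L),
                  score = suppressWarnings(as.numeric(get(4L))),
                  read_length = suppressWarnings(as.integer(get(5L))))
}
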