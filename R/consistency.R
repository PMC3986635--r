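# Per-read agreement classification across K methods, >=2-method consensus
# calling, per-rank agreement tables and pairwise disagreement cross-tabs.

.AGREEMENT_CLASSES <- c("ALL_SAME", "TWO_SAME", "ALL_DIFFERENT", "NO_RANK",
                        "CONFUSED", "UNASSIGNED_MAJORITY")

#' Confused-genera configuration
#'
#' A set of genus-level taxon pairs treated as systematically
#' interchangeable between two named composition-based methods.  Pairs are
#' symmetric.  The default set is empty: the genera concerned are a
#' property of specific external classifiers and are supplied by the user.
#'
#' @param pairs Two-column matrix or data frame of genus taxon ids (may
#'   have zero rows).
#' @param methods The two method ids between which the confusion applies.
#' @return List of class `confused_genera`.
#' @export
confused_genera <- function(pairs = NULL, methods = c("phymm", "nbc")) {
  if (is.null(pairs)) {
    pairs <- matrix(character(), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
  }
  stopifnot(ncol(pairs) == 2L, length(methods) == 2L)
  key <- apply(pairs, 1L, function(r) paste(sort(r), collapse = "\r"))
  structure(list(keys = unique(key), methods = methods),
            class = "confused_genera")
}

.is_confused_pair <- function(confused, a, b) {
  if (is.null(confused)) return(FALSE)
  paste(sort(c(a, b)), collapse = "\r") %in% confused$keys
}

#' Classify one read's cross-method agreement at a rank
#'
#' Each method's call is projected to the requested canonical rank
#' (`UNASSIGNED` stays `UNASSIGNED`), then the pattern is classified:
#'
#' * `UNASSIGNED_MAJORITY` - a strict majority of methods made no call
#'   (consensus on absence is not an assignment);
#' * `ALL_SAME` - all projections equal a single ranked taxon;
#' * `NO_RANK` - all projections are `NO_RANK`, or a strict majority are
#'   and no ranked pair agrees;
#' * `CONFUSED` - at genus rank, the two designated composition-based
#'   methods disagree on a pair listed in the confused-genera set;
#' * `TWO_SAME` - some (but not all) methods share a ranked taxon; the
#'   modal sharing pair is recorded;
#' * `ALL_DIFFERENT` - otherwise.
#'
#' @param calls Named character vector: method id -> taxon id or
#'   `UNASSIGNED` (at least two methods).
#' @param tree A `taxonomy_tree`.
#' @param rank Canonical rank.
#' @param confused Optional [confused_genera()].
#' @return List with `rank`, `class`, `agreeing_pair` (character(2) or
#'   `NULL`), `consensus_taxon` (taxon id or `NA`).
#' @export
classify_agreement <- function(calls, tree, rank, confused = NULL) {
  rank <- .check_rank_arg(rank)
  if (length(calls) < 2L || is.null(names(calls))) {
    stop("classify_agreement() needs >= 2 named method calls", call. = FALSE)
  }
  proj <- stats::setNames(.project_many(tree, calls, rank), names(calls))
  K <- length(proj)
  rec <- function(class, pair = NULL, consensus = NA_character_) {
    list(rank = rank, class = class, agreeing_pair = pair,
         consensus_taxon = consensus)
  }
  if (sum(proj == .UNASSIGNED) > K / 2) return(rec("UNASSIGNED_MAJORITY"))
  ranked <- proj[!(proj %in% c(.UNASSIGNED, .NORANK))]
  if (length(ranked) == K && length(unique(ranked)) == 1L) {
    return(rec("ALL_SAME", pair = names(proj),
               consensus = unname(ranked[1L])))
  }
  if (all(proj == .NORANK)) return(rec("NO_RANK"))
  if (rank == "genus" && !is.null(confused)) {
    ms <- confused$methods
    if (all(ms %in% names(proj))) {
      a <- proj[[ms[1L]]]
      b <- proj[[ms[2L]]]
      if (!(a %in% c(.UNASSIGNED, .NORANK)) &&
          !(b %in% c(.UNASSIGNED, .NORANK)) && a != b &&
          .is_confused_pair(confused, a, b)) {
        return(rec("CONFUSED"))
      }
    }
  }
  if (length(ranked) >= 2L) {
    tab <- sort(table(ranked), decreasing = TRUE)
    if (tab[1L] >= 2L) {
      modal <- names(sort(table(ranked)[table(ranked) == tab[1L]]))[1L]
      pair <- names(ranked)[ranked == modal][1:2]
      return(rec("TWO_SAME", pair = pair, consensus = modal))
    }
  }
  if (sum(proj == .NORANK) > K / 2) return(rec("NO_RANK"))
  rec("ALL_DIFFERENT")
}

#' Consensus (>=2-method) assignment for one read at a rank
#'
#' The ranked taxon shared by at least two methods after rank projection;
#' `NA` when no taxon is shared.  Agreement on `NO_RANK` or on
#' `UNASSIGNED` is not an assignment.
#'
#' @inheritParams classify_agreement
#' @return A taxon id, or `NA_character_` when there is no consensus.
#' @export
consensus_assign <- function(calls, tree, rank) {
  rank <- .check_rank_arg(rank)
  if (length(calls) < 2L) {
    stop("consensus_assign() needs >= 2 method calls", call. = FALSE)
  }
  proj <- .project_many(tree, calls, rank)
  ranked <- proj[!(proj %in% c(.UNASSIGNED, .NORANK))]
  if (!length(ranked)) return(NA_character_)
  tab <- table(ranked)
  tab <- tab[tab >= 2L]
  if (!length(tab)) return(NA_character_)
  # with >3 methods two taxa could tie at the threshold: highest count
  # wins, then lexicographic order
  names(sort(tab, decreasing = TRUE))[1L]
}

# long assignment table -> reads x methods character matrix
.calls_matrix <- function(assignments) {
  reads <- unique(assignments$read_id)
  methods <- unique(assignments$method_id)
  m <- matrix(.UNASSIGNED, length(reads), length(methods),
              dimnames = list(reads, methods))
  m[cbind(match(assignments$read_id, reads),
          match(assignments$method_id, methods))] <- assignments$taxon_id
  m
}

#' Per-rank agreement table
#'
#' Counts reads in each agreement class at each rank.  Reads absent for a
#' method are treated as `UNASSIGNED` there.  Counts per rank always sum
#' to the total number of reads.
#'
#' @param assignments Long assignment data frame (`read_id`, `method_id`,
#'   `taxon_id`).
#' @param tree A `taxonomy_tree`.
#' @param ranks Ranks to tabulate (default all seven canonical ranks).
#' @param confused Optional [confused_genera()].
#' @return Data frame with columns `rank`, `class`, `count`.
#' @export
agreement_table <- function(assignments, tree, ranks = canonical_ranks(),
                            confused = NULL) {
  m <- .calls_matrix(assignments)
  out <- list()
  for (rank in ranks) {
    rank <- .check_rank_arg(rank)
    pm <- m
    for (j in seq_len(ncol(m))) pm[, j] <- .project_many(tree, m[, j], rank)
    cls <- vapply(seq_len(nrow(pm)), function(i) {
      .classify_projected(stats::setNames(pm[i, ], colnames(pm)), rank,
                          confused)
    }, "")
    counts <- table(factor(cls, levels = .AGREEMENT_CLASSES))
    out[[rank]] <- data.frame(rank = rank, class = names(counts),
                              count = as.integer(counts),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# classify an already-projected call vector (shared by agreement_table so
# projection is done once per rank, not once per read)
.classify_projected <- function(proj, rank, confused = NULL) {
  K <- length(proj)
  if (sum(proj == .UNASSIGNED) > K / 2) return("UNASSIGNED_MAJORITY")
  ranked <- proj[!(proj %in% c(.UNASSIGNED, .NORANK))]
  if (length(ranked) == K && length(unique(ranked)) == 1L) return("ALL_SAME")
  if (all(proj == .NORANK)) return("NO_RANK")
  if (rank == "genus" && !is.null(confused)) {
    ms <- confused$methods
    if (all(ms %in% names(proj))) {
      a <- proj[[ms[1L]]]
      b <- proj[[ms[2L]]]
      if (!(a %in% c(.UNASSIGNED, .NORANK)) &&
          !(b %in% c(.UNASSIGNED, .NORANK)) && a != b &&
          .is_confused_pair(confused, a, b)) {
        return("CONFUSED")
      }
    }
  }
  if (length(ranked) >= 2L && max(table(ranked)) >= 2L) return("TWO_SAME")
  if (sum(proj == .NORANK) > K / 2) return("NO_RANK")
  "ALL_DIFFERENT"
}

#' Cross-tabulate pairwise disagreements at a rank
#'
#' Among reads where the two methods' rank projections are both ranked
#' taxa and differ, reports the percentage per ordered (method_a taxon,
#' method_b taxon) pair, in descending order.
#'
#' @param assignments Long assignment data frame.
#' @param tree A `taxonomy_tree`.
#' @param method_a,method_b The two method ids.
#' @param rank Canonical rank.
#' @param top_n Number of rows to keep (default 10).
#' @return Data frame `taxon_a`, `taxon_b`, `n`, `percent` (descending);
#'   empty when the methods never disagree.
#' @export
cross_tab_disagreements <- function(assignments, tree, method_a, method_b,
                                    rank, top_n = 10L) {
  rank <- .check_rank_arg(rank)
  m <- .calls_matrix(assignments)
  if (!all(c(method_a, method_b) %in% colnames(m))) {
    stop("method(s) not present in the assignment table", call. = FALSE)
  }
  a <- .project_many(tree, m[, method_a], rank)
  b <- .project_many(tree, m[, method_b], rank)
  ok <- !(a %in% c(.UNASSIGNED, .NORANK)) & !(b %in% c(.UNASSIGNED, .NORANK)) &
    a != b
  empty <- data.frame(taxon_a = character(), taxon_b = character(),
                      n = integer(), percent = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(ok)) return(empty)
  tab <- table(paste(a[ok], b[ok], sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(taxon_a = vapply(parts, `[[`, "", 1L),
                    taxon_b = vapply(parts, `[[`, "", 2L),
                    n = as.integer(tab),
                    percent = 100 * as.integer(tab) / sum(ok),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$taxon_a, out$taxon_b), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
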