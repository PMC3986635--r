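# Truth-based evaluation: per-rank sensitivity and precision for each
# method and the combined (>=2-agree) strategy, plus true/false-positive
# splits of the agreement classes.
#
# Sensitivity = 100 * correct / all reads in the dataset (abstentions
# count against it); precision = 100 * correct / assignments made (they do
# not).  Precision is NA when a method assigned nothing: 0/0 is undefined,
# and the raw counts are always emitted alongside so any convention can be
# recomputed.

#' Score one or more assignments against truth at a rank
#'
#' Both the call and the truth taxon are projected to the rank.  Equal
#' ranked taxa are `CORRECT`; a call of `NO_RANK` against a truth lineage
#' that also lacks the rank is `CORRECT` (the method correctly reported
#' the absence); `UNASSIGNED` stays `UNASSIGNED`; everything else is
#' `WRONG`.
#'
#' @param assignment Character vector of taxon ids (or `UNASSIGNED`).
#' @param truth_taxon Character vector of true source taxon ids.
#' @param tree A `taxonomy_tree`.
#' @param rank Canonical rank.
#' @return Character vector over `{CORRECT, WRONG, UNASSIGNED}`.
#' @export
score_correctness <- function(assignment, truth_taxon, tree, rank) {
  rank <- .check_rank_arg(rank)
  .check_in_tree(tree, truth_taxon)
  pa <- .project_many(tree, assignment, rank)
  pt <- .project_many(tree, truth_taxon, rank)
  out <- rep("WRONG", length(pa))
  out[pa == .UNASSIGNED] <- "UNASSIGNED"
  ranked <- !(pa %in% c(.UNASSIGNED, .NORANK))
  out[ranked & pa == pt] <- "CORRECT"
  out[pa == .NORANK & pt == .NORANK] <- "CORRECT"
  out
}

#' Sensitivity / precision table per rank and method
#'
#' For each method: sensitivity = 100 * n_correct / n_total and precision
#' = 100 * n_correct / n_assigned (NA when nothing was assigned), where
#' n_assigned counts reads for which the method emitted any taxon.  The
#' `COMBINED` rows use the >=2-method consensus at each rank; its
#' "assigned" denominator is the number of reads with a consensus taxon.
#'
#' @param assignments Long assignment data frame (`read_id`, `method_id`,
#'   `taxon_id`).
#' @param truth Data frame with `read_id` and `taxon_id` (the true source
#'   taxon), covering every read.
#' @param tree A `taxonomy_tree`.
#' @param ranks Ranks to evaluate (default all seven).
#' @param include_combined Add the `COMBINED` consensus rows (default
#'   TRUE; requires >= 2 methods).
#' @return Data frame with `rank`, `method_id`, `sensitivity`,
#'   `precision`, `n_correct`, `n_assigned`, `n_total`.
#' @export
metrics_table <- function(assignments, truth, tree,
                          ranks = canonical_ranks(),
                          include_combined = TRUE) {
  m <- .calls_matrix(assignments)
  miss <- setdiff(rownames(m), truth$read_id)
  if (length(miss)) {
    stop("evaluation error: read(s) missing from truth: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  truth_taxa <- truth$taxon_id[match(rownames(m), truth$read_id)]
  n_total <- nrow(m)
  methods <- colnames(m)
  out <- list()
  for (rank in ranks) {
    rank <- .check_rank_arg(rank)
    pt <- .project_many(tree, truth_taxa, rank)
    for (meth in methods) {
      st <- score_correctness(m[, meth], truth_taxa, tree, rank)
      n_assigned <- sum(m[, meth] != .UNASSIGNED)
      n_correct <- sum(st == "CORRECT")
      out[[length(out) + 1L]] <- data.frame(
        rank = rank, method_id = meth,
        sensitivity = 100 * n_correct / n_total,
        precision = if (n_assigned > 0) 100 * n_correct / n_assigned else NA_real_,
        n_correct = n_correct, n_assigned = n_assigned, n_total = n_total,
        stringsAsFactors = FALSE)
    }
    if (include_combined && length(methods) >= 2L) {
      cons <- vapply(seq_len(n_total), function(i) {
        v <- consensus_assign(stats::setNames(m[i, ], methods), tree, rank)
        if (is.na(v)) .UNASSIGNED else v
      }, "")
      n_assigned <- sum(cons != .UNASSIGNED)
      n_correct <- sum(cons != .UNASSIGNED & cons == pt)
      out[[length(out) + 1L]] <- data.frame(
        rank = rank, method_id = "COMBINED",
        sensitivity = 100 * n_correct / n_total,
        precision = if (n_assigned > 0) 100 * n_correct / n_assigned else NA_real_,
        n_correct = n_correct, n_assigned = n_assigned, n_total = n_total,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide (rank x method) sensitivity/precision layout
#'
#' Reshapes [metrics_table()] output into the familiar wide table with one
#' row per (rank, statistic) and one column per method.
#'
#' @param metrics Output of [metrics_table()].
#' @return Data frame with columns `rank`, `statistic`, then one column
#'   per method.
#' @export
metrics_wide <- function(metrics) {
  methods <- unique(metrics$method_id)
  ranks <- unique(metrics$rank)
  rows <- list()
  for (rank in ranks) {
    sub <- metrics[metrics$rank == rank, ]
    for (stat in c("sensitivity", "precision")) {
      vals <- sub[[stat]][match(methods, sub$method_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rank, statistic = stat,
        as.list(stats::setNames(round(vals, 2), methods)),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' True/false-positive split of the agreement classes
#'
#' Partitions each rank-by-class agreement count by correctness against
#' truth.  For classes carrying a consensus taxon (`ALL_SAME`,
#' `TWO_SAME`) the consensus call is compared to the projected truth; for
#' the remaining classes a read counts as a true positive when at least
#' one method's projected call matches the projected truth.
#'
#' @param assignments Long assignment data frame.
#' @param truth Data frame with `read_id`, `taxon_id`.
#' @param tree A `taxonomy_tree`.
#' @param ranks Ranks to evaluate.
#' @param confused Optional [confused_genera()].
#' @return Data frame with `rank`, `class`, `tp`, `fp` (tp + fp per class
#'   equals the [agreement_table()] count).
#' @export
true_false_split <- function(assignments, truth, tree,
                             ranks = canonical_ranks(), confused = NULL) {
  m <- .calls_matrix(assignments)
  truth_taxa <- truth$taxon_id[match(rownames(m), truth$read_id)]
  if (anyNA(truth_taxa)) {
    stop("evaluation error: read(s) missing from truth", call. = FALSE)
  }
  out <- list()
  for (rank in ranks) {
    rank <- .check_rank_arg(rank)
    pt <- .project_many(tree, truth_taxa, rank)
    pm <- m
    for (j in seq_len(ncol(m))) pm[, j] <- .project_many(tree, m[, j], rank)
    tp <- stats::setNames(integer(length(.AGREEMENT_CLASSES)),
                          .AGREEMENT_CLASSES)
    fp <- tp
    for (i in seq_len(nrow(pm))) {
      proj <- stats::setNames(pm[i, ], colnames(pm))
      cls <- .classify_projected(proj, rank, confused)
      correct <- if (cls %in% c("ALL_SAME", "TWO_SAME")) {
        rec <- classify_agreement(stats::setNames(m[i, ], colnames(m)),
                                  tree, rank, confused)
        !is.na(rec$consensus_taxon) && rec$consensus_taxon == pt[i]
      } else {
        any(proj == pt[i] & !(proj %in% c(.UNASSIGNED, .NORANK))) ||
          (pt[i] == .NORANK && any(proj == .NORANK))
      }
      if (correct) tp[cls] <- tp[cls] + 1L else fp[cls] <- fp[cls] + 1L
    }
    out[[rank]] <- data.frame(rank = rank, class = .AGREEMENT_CLASSES,
                              tp = as.integer(tp), fp = as.integer(fp),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
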