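# Derived analyses: read-length versus consistency with polynomial
# regression and threshold lengths, epsilon-sweep curves, and per-category
# confidence-score summaries.

#' Read length versus >=2-method consistency
#'
#' Bins reads by length, computes per bin the proportion of reads whose
#' >=2-method consensus at the given rank is a real taxon, and fits an
#' ordinary least-squares polynomial (default degree 3, weighted by bin
#' size) of the proportion on the bin midpoint.
#'
#' @param assignments Long assignment data frame with a `read_length`
#'   column (lengths may be attached to any of the methods' rows).
#' @param tree A `taxonomy_tree`.
#' @param rank Canonical rank.
#' @param bin_width Bin width in bp (default 25).
#' @param degree Polynomial degree (default 3).
#' @return A `length_consistency_curve`: list with `bins` (data frame
#'   `midpoint`, `n`, `proportion`), `coefficients`, `degree`, `range`.
#' @export
length_consistency <- function(assignments, tree, rank, bin_width = 25L,
                               degree = 3L) {
  rank <- .check_rank_arg(rank)
  stopifnot(bin_width >= 1)
  m <- .calls_matrix(assignments)
  len <- tapply(assignments$read_length, assignments$read_id,
                function(x) suppressWarnings(max(x, na.rm = TRUE)))
  len <- as.numeric(len[rownames(m)])
  if (all(!is.finite(len))) stop("no read lengths present", call. = FALSE)
  keep <- is.finite(len)
  m <- m[keep, , drop = FALSE]
  len <- len[keep]
  consistent <- vapply(seq_len(nrow(m)), function(i) {
    !is.na(consensus_assign(stats::setNames(m[i, ], colnames(m)), tree, rank))
  }, logical(1L))
  bin <- floor(len / bin_width)
  mids <- (sort(unique(bin)) + 0.5) * bin_width
  n <- as.integer(table(bin))
  prop <- as.numeric(tapply(consistent, bin, mean))
  bins <- data.frame(midpoint = mids, n = n, proportion = prop)
  fit <- stats::lm(proportion ~ stats::poly(midpoint, degree, raw = TRUE),
                   data = bins, weights = n)
  structure(list(bins = bins, coefficients = unname(stats::coef(fit)),
                 degree = degree, range = range(len)),
            class = "length_consistency_curve")
}

#' Evaluate a fitted length-consistency polynomial
#' @param object A `length_consistency_curve`.
#' @param length Read lengths (bp) at which to evaluate.
#' @param ... Ignored.
#' @return Fitted proportions.
#' @export
predict.length_consistency_curve <- function(object, length, ...) {
  cf <- object$coefficients
  sapply(length, function(L) sum(cf * L^(seq_along(cf) - 1L)))
}

#' Threshold read length for a target consistency level
#'
#' The smallest length (on a 1-bp grid over the observed range) at which
#' the fitted polynomial reaches the level *and stays at or above it* for
#' the rest of the range.  The sustained-crossing rule avoids the
#' ambiguity of polynomials that dip back below the level.
#'
#' @param curve A `length_consistency_curve`.
#' @param level Target proportion in (0, 1), e.g. 0.75.
#' @return Length in bp, or `NA` when the level is never sustainably
#'   reached (`NOT_REACHED`).
#' @export
threshold_length <- function(curve, level = 0.75) {
  stopifnot(level > 0, level < 1)
  grid <- seq(ceiling(curve$range[1L]), floor(curve$range[2L]), by = 1)
  fitted <- predict(curve, grid)
  ok <- fitted >= level
  sustained <- rev(cumprod(rev(ok))) == 1
  if (!any(sustained)) return(NA_real_)
  grid[which(sustained)[1L]]
}

#' Epsilon sweep of classifier retention
#'
#' For each epsilon and mode, counts reads retained by the epsilon cutoff:
#' `nbc_only` scores every read with the k-mer classifier; `lca_plus_nbc`
#' first restricts each read's candidates to genomes with surviving BLAST
#' hits, so reads without hits (e.g. contaminants) are never assigned at
#' any epsilon.  Also reports how many retained reads belong to a
#' designated contaminant set, and (optionally) how many retained calls
#' agree with a reference method at the chosen rank.
#'
#' @param reads Data frame with `read_id` and `sequence`.
#' @param model An `nbc_model`.
#' @param tree A `taxonomy_tree`.
#' @param epsilons Numeric vector of epsilon values; must include 0.
#' @param modes Subset of `c("nbc_only", "lca_plus_nbc")`.
#' @param blast_hits BLAST hit data frame (needed for `lca_plus_nbc`).
#' @param subject_taxa Named subject -> taxon map (for `lca_plus_nbc`).
#' @param rank Rank at which concordance is measured (default phylum).
#' @param e_cutoff BLAST e-value cutoff (default 1e-5).
#' @param contaminant_ids Read ids regarded as contaminants.
#' @param reference_assignments Optional assignment data frame of another
#'   method for the concordance count.
#' @return Data frame `mode`, `epsilon`, `n_assigned`,
#'   `n_contaminant_assigned`, `n_concordant`.
#' @export
epsilon_sweep <- function(reads, model, tree, epsilons,
                          modes = c("nbc_only", "lca_plus_nbc"),
                          blast_hits = NULL, subject_taxa = NULL,
                          rank = "phylum", e_cutoff = 1e-5,
                          contaminant_ids = character(),
                          reference_assignments = NULL) {
  if (!any(epsilons == 0)) stop("epsilons must include 0", call. = FALSE)
  rank <- .check_rank_arg(rank)
  modes <- match.arg(modes, several.ok = TRUE)
  ref <- NULL
  if (!is.null(reference_assignments)) {
    ref <- stats::setNames(
      .project_many(tree, reference_assignments$taxon_id, rank),
      reference_assignments$read_id)
  }
  out <- list()
  for (mode in modes) {
    if (mode == "nbc_only") {
      base <- nbc_classify(model, reads$sequence, read_ids = reads$read_id)
    } else {
      if (is.null(blast_hits) || is.null(subject_taxa)) {
        stop("lca_plus_nbc mode needs blast_hits and subject_taxa",
             call. = FALSE)
      }
      blast <- lca_assign_all(blast_hits, subject_taxa, tree,
                              e_cutoff = e_cutoff, read_ids = reads$read_id)
      kept <- attr(blast, "kept_subjects")
      rows <- lapply(seq_len(nrow(reads)), function(i) {
        b <- blast[i, , drop = FALSE]
        attr(b, "kept_subjects") <- kept[[reads$read_id[i]]]
        combine_blast_nbc(b, model, reads$sequence[i], tree)
      })
      lls <- lapply(rows, attr, "loglik")
      base <- do.call(rbind, rows)
      # pad per-read restricted log-likelihood vectors to a common matrix
      ll <- matrix(-Inf, nrow(base), nrow(model$logp),
                   dimnames = list(base$read_id, rownames(model$logp)))
      for (i in seq_along(lls)) {
        if (!is.null(lls[[i]]) && ncol(lls[[i]]))
          ll[i, colnames(lls[[i]])] <- lls[[i]][1L, ]
      }
      ll[base$taxon_id == .UNASSIGNED, ] <- NA_real_
      attr(base, "loglik") <- ll
    }
    for (eps in epsilons) {
      a <- apply_epsilon_cutoff(base, epsilon_config(eps, mode))
      assigned <- a$taxon_id != .UNASSIGNED
      conc <- NA_integer_
      if (!is.null(ref)) {
        pr <- .project_many(tree, a$taxon_id, rank)
        rr <- unname(ref[a$read_id])
        conc <- sum(assigned & !is.na(rr) & pr == rr &
                      !(pr %in% c(.UNASSIGNED, .NORANK)))
      }
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, epsilon = eps, n_assigned = sum(assigned),
        n_contaminant_assigned = sum(assigned &
                                       a$read_id %in% contaminant_ids),
        n_concordant = conc, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-category score summaries (mean and 95% CI)
#'
#' Mean confidence score per read category with a t-interval 95% CI
#' half-width (NA when a category has fewer than two reads).
#'
#' @param scores Numeric vector of per-read scores.
#' @param categories Character vector of category labels (same length).
#' @return Data frame `category`, `mean`, `ci_half_width`, `n`.
#' @export
score_category_summary <- function(scores, categories) {
  stopifnot(length(scores) == length(categories))
  keep <- !is.na(scores) & !is.na(categories)
  scores <- scores[keep]
  categories <- as.character(categories[keep])
  cats <- sort(unique(categories))
  rows <- lapply(cats, function(cat) {
    x <- scores[categories == cat]
    n <- length(x)
    ci <- if (n >= 2L) {
      stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
    } else NA_real_
    data.frame(category = cat, mean = mean(x), ci_half_width = ci, n = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
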