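# Taxonomy loading, canonical-rank projection and lowest common ancestors.
#
# A taxonomy_tree stores parent/rank/name as vectors indexed by taxon id.
# Taxon ids are opaque strings so mock taxonomies work exactly like NCBI's.

.new_taxonomy <- function(id, parent, rank, name) {
  id <- as.character(id)
  parent <- as.character(parent)
  rank <- .normalize_rank(as.character(rank))
  name <- as.character(name)
  names(parent) <- id
  names(rank) <- id
  names(name) <- id
  # root: parent equal to self, or empty/NA parent
  is_root <- is.na(parent) | parent == "" | parent == id
  if (sum(is_root) != 1L) {
    stop("malformed taxonomy: expected exactly one root, found ",
         sum(is_root), call. = FALSE)
  }
  root <- id[is_root]
  parent[is_root] <- root
  dangling <- setdiff(unique(parent), id)
  if (length(dangling)) {
    stop("missing-node error: parent id(s) absent from taxonomy: ",
         paste(utils::head(dangling, 5L), collapse = ", "), call. = FALSE)
  }
  tree <- structure(
    list(id = id, parent = parent, rank = rank, name = name, root = root),
    class = "taxonomy_tree"
  )
  .check_acyclic(tree)
  tree
}

# every node must reach the root in at most n steps
.check_acyclic <- function(tree) {
  n <- length(tree$id)
  for (x in tree$id) {
    steps <- 0L
    cur <- x
    while (cur != tree$root) {
      cur <- tree$parent[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        stop("malformed taxonomy: cycle detected at node '", x, "'",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Load a taxonomy from NCBI-dump or simple-TSV input
#'
#' Accepts the NCBI taxonomy dump dialect (`nodes.dmp` + `names.dmp`, fields
#' separated by `"\t|\t"`, records ending `"\t|"`, names filtered to class
#' `"scientific name"`) or a simple 4-column TSV
#' (`taxon_id, parent_id, rank, name`), which is convenient for fixtures.
#'
#' @param nodes File path, connection, or character vector of lines: the
#'   nodes table (NCBI dialect) or the 4-column TSV.
#' @param names Optional names table (NCBI dialect only).
#' @param format One of `"auto"`, `"ncbi"`, `"tsv"`.
#' @return A `taxonomy_tree` object.
#' @examples
#' tsv <- c("1\t1\tno rank\troot",
#'          "2\t1\tdomain\tBacteria",
#'          "3\t2\tgenus\tExamplea")
#' tree <- load_taxonomy(tsv)
#' lineage(tree, "3")
#' @export
load_taxonomy <- function(nodes, names = NULL, format = c("auto", "ncbi", "tsv")) {
  format <- match.arg(format)
  node_lines <- .as_lines(nodes)
  node_lines <- node_lines[nzchar(trimws(node_lines))]
  if (!length(node_lines)) stop("empty taxonomy input", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\t|\t", node_lines[[1L]], fixed = TRUE)) "ncbi" else "tsv"
  }
  if (format == "ncbi") {
    fields <- strsplit(sub("\t\\|$", "", node_lines), "\t|\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("malformed NCBI nodes record (need >= 3 fields)", call. = FALSE)
    }
    id <- vapply(fields, `[[`, "", 1L)
    parent <- vapply(fields, `[[`, "", 2L)
    rank <- vapply(fields, `[[`, "", 3L)
    name <- id
    if (!is.null(names)) {
      nm_lines <- .as_lines(names)
      nm_lines <- nm_lines[nzchar(trimws(nm_lines))]
      nf <- strsplit(sub("\t\\|$", "", nm_lines), "\t|\t", fixed = TRUE)
      keep <- vapply(nf, function(f) length(f) >= 4L && f[[4L]] == "scientific name",
                     logical(1L))
      nf <- nf[keep]
      nm_id <- vapply(nf, `[[`, "", 1L)
      nm_name <- vapply(nf, `[[`, "", 2L)
      hit <- match(id, nm_id)
      name <- ifelse(is.na(hit), id, nm_name[hit])
    }
  } else {
    fields <- strsplit(node_lines[!startsWith(node_lines, "#")], "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L)) {
      bad <- which(lengths(fields) != 4L)[1L]
      stop("malformed taxonomy TSV at record ", bad, ": expected 4 columns",
           call. = FALSE)
    }
    id <- vapply(fields, `[[`, "", 1L)
    parent <- vapply(fields, `[[`, "", 2L)
    rank <- vapply(fields, `[[`, "", 3L)
    name <- vapply(fields, `[[`, "", 4L)
  }
  if (anyDuplicated(id)) {
    stop("malformed taxonomy: duplicated taxon id(s): ",
         paste(utils::head(unique(id[duplicated(id)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  .new_taxonomy(id, parent, rank, name)
}

#' Write a taxonomy as the simple 4-column TSV
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output file path (omit to return the lines invisibly).
#' @return Invisibly, the character vector of lines written.
#' @export
write_taxonomy_tsv <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  lines <- sprintf("%s\t%s\t%s\t%s", tree$id, tree$parent[tree$id],
                   tree$rank[tree$id], tree$name[tree$id])
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree with", length(x$id), "nodes; root =", x$root, "\n")
  tab <- table(x$rank)
  cat("ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Taxon ids of a taxonomy
#' @param tree A `taxonomy_tree`.
#' @return Character vector of all taxon ids.
#' @export
taxon_ids <- function(tree) tree$id

.check_in_tree <- function(tree, ids) {
  miss <- setdiff(ids, tree$id)
  if (length(miss)) {
    stop("unknown taxon id(s): ", paste(utils::head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Project a taxon onto the seven canonical ranks
#'
#' Each canonical rank is filled with the nearest ancestor-or-self carrying
#' that rank label; a rank with no such ancestor gets the `NO_RANK`
#' sentinel.  Projection only climbs upward: a taxon above the requested
#' rank (e.g. a domain projected to species) yields `NO_RANK`, mirroring
#' how lineages that genuinely lack a level (phyla in viruses) are labeled.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id A taxon id present in the tree.
#' @return Named character vector over [canonical_ranks()]; entries are
#'   taxon ids or `"NO_RANK"`.
#' @export
lineage <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxon_id <- as.character(taxon_id)
  .check_in_tree(tree, taxon_id)
  out <- stats::setNames(rep(.NORANK, 7L), canonical_ranks())
  cur <- taxon_id
  repeat {
    r <- tree$rank[[cur]]
    if (r %in% canonical_ranks() && out[[r]] == .NORANK) out[[r]] <- cur
    if (cur == tree$root) break
    cur <- tree$parent[[cur]]
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon,
#' computed by depth-equalized joint climbing.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_ids Non-empty character vector of taxon ids in the tree.
#' @return A single taxon id.
#' @export
lca <- function(tree, taxon_ids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxon_ids <- unique(as.character(taxon_ids))
  if (!length(taxon_ids)) stop("lca() requires a non-empty set", call. = FALSE)
  .check_in_tree(tree, taxon_ids)
  Reduce(function(a, b) .lca2(tree, a, b), taxon_ids)
}

.depth <- function(tree, x) {
  d <- 0L
  while (x != tree$root) {
    x <- tree$parent[[x]]
    d <- d + 1L
  }
  d
}

.lca2 <- function(tree, a, b) {
  da <- .depth(tree, a)
  db <- .depth(tree, b)
  while (da > db) { a <- tree$parent[[a]]; da <- da - 1L }
  while (db > da) { b <- tree$parent[[b]]; db <- db - 1L }
  while (a != b) { a <- tree$parent[[a]]; b <- tree$parent[[b]] }
  a
}

#' Project a taxon to one canonical rank
#'
#' Equivalent to `lineage(tree, taxon_id)[[rank]]`.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Taxon id in the tree.
#' @param rank One of the seven canonical ranks ("superkingdom" is accepted
#'   as a synonym of "domain").
#' @return A taxon id, or `"NO_RANK"` when the lineage lacks that rank.
#' @export
project_to_rank <- function(tree, taxon_id, rank) {
  rank <- .check_rank_arg(rank)
  lineage(tree, taxon_id)[[rank]]
}

# Vectorized projection used by the consistency/metrics layers: projects a
# character vector of taxon ids (possibly with UNASSIGNED entries) to one
# rank, computing each unique taxon once.
.project_many <- function(tree, taxa, rank) {
  rank <- .check_rank_arg(rank)
  taxa <- as.character(taxa)
  out <- rep(.UNASSIGNED, length(taxa))
  real <- !is.na(taxa) & taxa != .UNASSIGNED
  if (any(real)) {
    uniq <- unique(taxa[real])
    proj <- vapply(uniq, function(t) lineage(tree, t)[[rank]], "")
    out[real] <- proj[match(taxa[real], uniq)]
  }
  out[is.na(taxa)] <- .UNASSIGNED
  out
}

#' Resolve scientific names to taxon ids
#'
#' @param tree A `taxonomy_tree`.
#' @param x Character vector of taxon ids or scientific names.
#' @return Character vector of taxon ids, `NA` where unresolvable.
#' @export
resolve_taxa <- function(tree, x) {
  x <- as.character(x)
  out <- ifelse(x %in% tree$id, x, NA_character_)
  need <- is.na(out) & !is.na(x)
  if (any(need)) {
    hit <- match(x[need], tree$name)
    out[need] <- ifelse(is.na(hit), NA_character_, tree$id[hit])
  }
  out
}
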