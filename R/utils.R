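# Shared constants and small helpers.

#' Canonical taxonomic ranks
#'
#' The seven comparison levels used throughout the package, ordered from
#' shallowest to deepest: domain, phylum, class, order, family, genus,
#' species.  NCBI's "superkingdom" is treated as "domain".
#'
#' @return Character vector of length 7.
#' @export
canonical_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Sentinel for a lineage that lacks a canonical rank
#'
#' Distinct from [UNASSIGNED()]: `NO_RANK` means the taxonomy genuinely has
#' no node at the requested rank on the lineage (e.g. viruses at phylum),
#' while `UNASSIGNED` means a method made no call for the read.
#'
#' @return The string `"NO_RANK"`.
#' @export
NO_RANK <- function() "NO_RANK"

#' Sentinel for a read with no taxonomic call
#'
#' @return The string `"UNASSIGNED"`.
#' @export
UNASSIGNED <- function() "UNASSIGNED"

.NORANK <- "NO_RANK"
.UNASSIGNED <- "UNASSIGNED"
.BASES <- c("A", "C", "G", "T")

#' Derive a stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed via named
#' substreams, so individual stages are independently replayable.
#'
#' @param seed Integer root seed.
#' @param stream Character name of the substream (e.g. `"community"`).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 7) %% 2147483647)
}

# normalize a rank label to the canonical vocabulary (or NA if not canonical)
.normalize_rank <- function(rank) {
  r <- tolower(trimws(rank))
  r[r == "superkingdom"] <- "domain"
  r
}

.check_rank_arg <- function(rank) {
  r <- .normalize_rank(rank)
  if (length(r) != 1L || !(r %in% canonical_ranks())) {
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(canonical_ranks(), collapse = ", "), call. = FALSE)
  }
  r
}

# Accept a file path, a connection, or a character vector of lines.
.as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x)) {
    out <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
    return(if (is.null(out)) character() else out)
  }
  stop("expected a file path, connection, or character vector of lines",
       call. = FALSE)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
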