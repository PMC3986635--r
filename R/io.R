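# Shared I/O: FASTA via Biostrings, truth tables, genome->taxon maps, and
# structured (YAML) pipeline configuration.

#' Read a FASTA file
#'
#' Sequences are uppercased; records containing characters outside
#' A/C/G/T are kept but flagged in the `ambiguous` column.
#'
#' @param path FASTA file path.
#' @return Data frame with `id` (first whitespace token of the header),
#'   `sequence`, `ambiguous`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (any(Biostrings::width(x) == 0L)) {
    stop("FASTA format error: record with empty sequence: ",
         names(x)[Biostrings::width(x) == 0L][1L], call. = FALSE)
  }
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, sequence = unname(seqs),
             ambiguous = grepl("[^ACGT]", seqs), stringsAsFactors = FALSE)
}

#' Write records as FASTA
#'
#' @param records Data frame with `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (any(!nzchar(records$sequence))) {
    stop("FASTA format error: empty sequence for record ",
         records$id[!nzchar(records$sequence)][1L], call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(stats::setNames(toupper(records$sequence),
                                                records$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a truth table written by [write_simulation()]
#' @param path Truth TSV path.
#' @return Data frame with `read_id`, `genome_id`, `taxon_id`, `start`,
#'   `end`, `strand`, `length`.
#' @export
read_truth <- function(path) {
  lines <- .as_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1L], "read_id\t")) lines <- lines[-1L]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 7L)) {
    stop("truth table parse error: expected 7 columns", call. = FALSE)
  }
  get <- function(i) vapply(f, `[[`, "", i)
  data.frame(read_id = get(1L), genome_id = get(2L), taxon_id = get(3L),
             start = as.integer(get(4L)), end = as.integer(get(5L)),
             strand = get(6L), length = as.integer(get(7L)),
             stringsAsFactors = FALSE)
}

#' Read a 2-column genome -> taxon map (TSV)
#' @param path TSV path (no header, or a `genome_id` header line).
#' @return Named character vector mapping genome ids to taxon ids.
#' @export
read_genome_taxon_map <- function(path) {
  lines <- .as_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1L], "genome_id\t")) lines <- lines[-1L]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L)) {
    stop("genome->taxon map parse error: expected 2 columns", call. = FALSE)
  }
  stats::setNames(vapply(f, `[[`, "", 2L), vapply(f, `[[`, "", 1L))
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path or a named list.  Fills defaults (BLAST
#' e-value cutoff 1e-5; fragment range 350-600 bp; k = 8; epsilon list 0;
#' ranks = all seven; bin width 25; polynomial degree 3) and reports all
#' violations at once.
#'
#' @param config YAML file path or named list with sections `simulation`,
#'   `assignment`, `evaluation`, `paths` (or `mock`), and top-level
#'   `seed`.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  sim <- config$simulation
  if (is.null(sim)) sim <- list()
  sim_defaults <- list(n_reads = 60000L, fragment_min = 350L,
                       fragment_max = 600L, substitution_rate = 0.001,
                       homopolymer_rate = 0.01)
  for (k in names(sim_defaults)) {
    if (is.null(sim[[k]])) sim[[k]] <- sim_defaults[[k]]
  }
  for (k in c("H_target", "max_taxa", "dominance_cap")) {
    if (is.null(sim[[k]])) note(paste0("simulation.", k, " is required"))
  }
  if (sim$fragment_min > sim$fragment_max) {
    note("simulation.fragment_min > simulation.fragment_max")
  }
  if (!is.null(sim$dominance_cap)) {
    if (sim$dominance_cap <= 0 || sim$dominance_cap > 1) {
      note("simulation.dominance_cap must be in (0, 1]")
    } else if (!is.null(sim$max_taxa) &&
               sim$dominance_cap * sim$max_taxa < 1 - 1e-9) {
      note("simulation.dominance_cap * simulation.max_taxa must be >= 1")
    }
  }
  if (!is.null(sim$H_target) && !is.null(sim$max_taxa) &&
      sim$H_target > log(sim$max_taxa) + 1e-9) {
    note("simulation.H_target exceeds ln(simulation.max_taxa)")
  }

  asn <- config$assignment
  if (is.null(asn)) asn <- list()
  asn_defaults <- list(k = 8L, e_cutoff = 1e-5, epsilons = 0,
                       methods = c("nbc", "nbc_lca", "nbc_noisy"),
                       lca_margin = 10, noise_sd = 30)
  for (k in names(asn_defaults)) {
    if (is.null(asn[[k]])) asn[[k]] <- asn_defaults[[k]]
  }
  if (asn$k < 4L || asn$k > 12L) note("assignment.k must be in [4, 12]")
  if (asn$e_cutoff <= 0) note("assignment.e_cutoff must be > 0")

  ev <- config$evaluation
  if (is.null(ev)) ev <- list()
  ev_defaults <- list(ranks = canonical_ranks(), bin_width = 25L, degree = 3L)
  for (k in names(ev_defaults)) {
    if (is.null(ev[[k]])) ev[[k]] <- ev_defaults[[k]]
  }
  bad_ranks <- setdiff(.normalize_rank(ev$ranks), canonical_ranks())
  if (length(bad_ranks)) {
    note(paste0("evaluation.ranks contains unknown rank(s): ",
                paste(bad_ranks, collapse = ", ")))
  }

  paths <- config$paths
  mock <- config$mock
  if (is.null(paths) && is.null(mock)) {
    note("either paths (genomes_fasta/genome_taxon_map/taxonomy) or mock must be given")
  }
  if (!is.null(paths)) {
    for (k in c("genomes_fasta", "genome_taxon_map", "taxonomy_nodes")) {
      if (is.null(paths[[k]])) {
        note(paste0("paths.", k, " is required"))
      } else if (!file.exists(paths[[k]])) {
        note(paste0("paths.", k, " does not exist: ", paths[[k]]))
      }
    }
  }
  if (!is.null(mock)) {
    mock_defaults <- list(n_genomes = 10L, genome_length = 50000L,
                          gc_content = 0.5, tree_depth = 7L)
    for (k in names(mock_defaults)) {
      if (is.null(mock[[k]])) mock[[k]] <- mock_defaults[[k]]
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(simulation = sim, assignment = asn, evaluation = ev,
                 paths = paths, mock = mock, seed = as.integer(config$seed),
                 log_level = if (is.null(config$log_level)) "info" else
                   config$log_level),
            class = "pipeline_config")
}

#' Write a normalized configuration back to YAML
#'
#' The emitted file re-validates to an identical configuration.
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
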