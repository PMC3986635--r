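# Top-level pipeline: simulate -> assign -> evaluate -> report, with a
# checksummed manifest so identical config + seed reproduces identical
# outputs byte for byte.

.log <- function(level, config_level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[config_level]]) {
    message("[", level, "] ", ...)
  }
}

#' Run the full simulation / assignment / evaluation pipeline
#'
#' Stages: (1) load or generate the reference genomes and taxonomy;
#' (2) simulate the read set; (3) produce per-read assignments for the
#' configured method roster (`nbc`, `nbc_lca`, `nbc_noisy`, plus `lca`
#' and `nbc_blast` when a BLAST table is supplied in
#' `paths$blast_tabular`); (4) agreement tables, sensitivity/precision
#' metrics, and disagreement cross-tabs; (5) read-length consistency
#' curve.  Every artifact is listed with its MD5 checksum in
#' `manifest.tsv`.  A stage failure aborts with the stage name; partial
#' outputs are retained.
#'
#' @param config A `pipeline_config` (see [validate_config()]) or
#'   anything it accepts.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lv <- config$log_level
  stage <- function(name, expr) {
    .log("info", lv, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  refs <- stage("references", {
    if (!is.null(config$paths)) {
      fa <- read_fasta(config$paths$genomes_fasta)
      map <- read_genome_taxon_map(config$paths$genome_taxon_map)
      tree <- load_taxonomy(config$paths$taxonomy_nodes,
                            names = config$paths$taxonomy_names)
      list(genomes = data.frame(genome_id = fa$id,
                                taxon_id = unname(map[fa$id]),
                                sequence = fa$sequence,
                                stringsAsFactors = FALSE),
           taxonomy = tree)
    } else {
      mk <- make_mock_genomes(config$mock$n_genomes,
                              config$mock$genome_length,
                              config$mock$gc_content,
                              config$mock$tree_depth,
                              seed = derive_seed(config$seed, "mock"))
      list(genomes = mk$genomes, taxonomy = mk$taxonomy)
    }
  })

  sim <- stage("simulate", {
    sc <- c(config$simulation,
            list(genome_set = refs$genomes, seed = config$seed))
    simulate_metagenome(simulation_config(sc))
  })
  write_simulation(sim, file.path(out_dir, "reads"))

  model <- stage("train", {
    train_nbc(refs$genomes, k = config$assignment$k)
  })

  assignments <- stage("assign", {
    roster <- config$assignment$methods
    blast <- NULL
    if (!is.null(config$paths$blast_tabular)) {
      blast <- read_blast_tabular(config$paths$blast_tabular)
    }
    parts <- list()
    for (meth in roster) {
      parts[[meth]] <- switch(
        meth,
        nbc = nbc_classify(model, sim$reads$sequence,
                           read_ids = sim$reads$read_id),
        nbc_lca = nbc_lca_classify(model, sim$reads$sequence, refs$taxonomy,
                                   margin = config$assignment$lca_margin,
                                   read_ids = sim$reads$read_id),
        nbc_noisy = nbc_noisy_classify(model, sim$reads$sequence,
                                       noise_sd = config$assignment$noise_sd,
                                       seed = derive_seed(config$seed,
                                                          "assignment-noise"),
                                       read_ids = sim$reads$read_id),
        lca = {
          if (is.null(blast)) stop("method 'lca' needs paths.blast_tabular")
          lca_assign_all(blast, stats::setNames(refs$genomes$taxon_id,
                                                refs$genomes$genome_id),
                         refs$taxonomy, e_cutoff = config$assignment$e_cutoff,
                         read_ids = sim$reads$read_id)
        },
        stop("unknown method in roster: ", meth)
      )
      attr(parts[[meth]], "loglik") <- NULL
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
  write_assignments(assignments, file.path(out_dir, "assignments.tsv"))

  truth <- data.frame(read_id = sim$reads$read_id,
                      taxon_id = sim$reads$source_taxon_id,
                      stringsAsFactors = FALSE)
  roster <- unique(assignments$method_id)
  if (length(roster) < 2L) {
    .log("info", lv, "single-method roster: consistency stages skipped")
  } else {
    stage("evaluate", {
      agree <- agreement_table(assignments, refs$taxonomy,
                               ranks = config$evaluation$ranks)
      utils::write.table(agree, file.path(out_dir, "agreement.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      met <- metrics_table(assignments, truth, refs$taxonomy,
                           ranks = config$evaluation$ranks)
      utils::write.table(met, file.path(out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(metrics_wide(met),
                         file.path(out_dir, "metrics_wide.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ct <- cross_tab_disagreements(assignments, refs$taxonomy,
                                    roster[1L], roster[2L], "phylum")
      utils::write.table(ct, file.path(out_dir, "cross_tab_phylum.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    stage("report", {
      lc <- length_consistency(assignments, refs$taxonomy, "phylum",
                               bin_width = config$evaluation$bin_width,
                               degree = config$evaluation$degree)
      utils::write.table(lc$bins,
                         file.path(out_dir, "length_consistency_phylum.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
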