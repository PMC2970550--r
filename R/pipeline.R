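#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings keeping the package's internal genome
#' representation (a named character vector of contig sequences).
#'
#' @param path FASTA path.
#' @return `read_genome_fasta`: named character vector.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of contig sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Replicate-overlap differential-expression analysis
#'
#' Runs the full DE procedure on two (or more) haploid/tetraploid replicate
#' pairs: per-pair reciprocal binomial candidate calling, the shared
#' expressed-gene background, equal-top-N overlap between the first two
#' pairs' ranked lists separately for repressed and induced genes with the
#' adaptive top-N choice, and cross-pair fold-change summaries of the final
#' overlap genes. When no top-N in the grid achieves the required overlap
#' significance for a direction (inconsistent replicates), that direction's
#' final list is empty and a note records it.
#'
#' @param pairs List of at least two pairs, each a list with `haploid` and
#'   `tetraploid` [count_table()] objects on a common gene universe.
#' @param alpha Per-tail binomial significance threshold (default 0.001).
#' @param min_count Expressed threshold (default 15).
#' @param p_max Maximal overlap p-value (default 1e-10).
#' @param top_n_grid Candidate top-N values (default multiples of 5 up to the
#'   shorter candidate list).
#' @return Object of class `de_analysis`.
#' @export
run_de_analysis <- function(pairs, alpha = 0.001, min_count = 15,
                            p_max = 1e-10, top_n_grid = NULL) {
  if (!is.list(pairs) || length(pairs) < 2) {
    stop("need at least two replicate pairs (overlap is undefined for one)")
  }
  calls <- lapply(pairs, function(p) {
    call_candidates(p$haploid, p$tetraploid, alpha = alpha,
                    min_count = min_count)
  })
  tables <- unlist(lapply(pairs, function(p) list(p$haploid, p$tetraploid)),
                   recursive = FALSE)
  background <- filter_expressed(tables, threshold = min_count)
  population <- length(background)
  pick <- function(direction) {
    la <- calls[[1]][[direction]]$gene_id
    lb <- calls[[2]][[direction]]$gene_id
    shortest <- min(length(la), length(lb))
    if (shortest == 0) {
      return(list(selection = NULL, genes = character(0),
                  note = "no candidates in a replicate"))
    }
    grid <- top_n_grid
    if (is.null(grid)) {
      grid <- if (shortest >= 5) unique(c(seq(5, shortest, by = 5), shortest))
        else seq_len(shortest)
    }
    sel <- tryCatch(
      select_top_n(la, lb, population, p_max = p_max, grid = grid),
      error = function(e) e
    )
    if (inherits(sel, "error")) {
      return(list(selection = NULL, genes = character(0),
                  note = conditionMessage(sel)))
    }
    list(selection = sel, genes = sel$overlap, note = NA_character_)
  }
  repressed <- pick("repressed")
  induced <- pick("induced")
  summ <- function(genes) {
    if (length(genes) == 0) {
      return(data.frame(gene_id = character(0), mean_fold = numeric(0),
                        sd_fold = numeric(0), n_pairs = integer(0),
                        sd_defined = logical(0)))
    }
    summarize_de(genes, pairs)
  }
  structure(
    list(pairs = calls, background = background,
         population_size = population,
         selection = list(repressed = repressed$selection,
                          induced = induced$selection),
         repressed = repressed$genes, induced = induced$genes,
         notes = c(repressed = repressed$note, induced = induced$note),
         summary = list(repressed = summ(repressed$genes),
                        induced = summ(induced$genes)),
         params = list(alpha = alpha, min_count = min_count, p_max = p_max)),
    class = "de_analysis"
  )
}

#' @export
print.de_analysis <- function(x, ...) {
  cat(sprintf(paste0("de_analysis: background %d genes; final overlap: ",
                     "%d repressed, %d induced\n"),
              x$population_size, length(x$repressed), length(x$induced)))
  invisible(x)
}

#' Promoter motif enrichment for gene lists
#'
#' Extracts every gene's promoter, scores the best match of each motif in
#' every promoter (both strands), and for each supplied gene list runs the
#' adaptive-cutoff binomial enrichment against the all-genes background,
#' followed by the three-way relevance filter.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotation Feature table.
#' @param matrices Named list of [ll_matrix()] objects.
#' @param gene_lists Named list of character vectors (e.g.
#'   `list(repressed = ..., induced = ...)`).
#' @param contig_lengths Optional named vector of contig lengths.
#' @param grid Cutoff grid (default [cutoff_grid()]).
#' @return Object of class `motif_scan`: per-list result tables (`results`),
#'   filtered tables (`filtered`), and the promoter universe used.
#' @export
run_motif_enrichment <- function(genome, annotation, matrices, gene_lists,
                                 contig_lengths = NULL, grid = cutoff_grid()) {
  if (is.null(contig_lengths)) {
    contig_lengths <- stats::setNames(nchar(genome), names(genome))
  }
  proms <- extract_promoters(annotation, contig_lengths)
  seqs <- promoter_sequences(proms, genome)
  all_scores <- lapply(matrices, best_match_scores, sequences = seqs)
  per_list <- lapply(gene_lists, function(genes) {
    genes <- intersect(genes, names(seqs))
    if (length(genes) == 0) {
      return(list(results = list(), table = NULL, filtered = NULL))
    }
    res <- lapply(matrices, function(m) {
      sc <- all_scores[[m$motif_id]]
      tryCatch(optimize_cutoff(m, sc[genes], sc, grid = grid),
               error = function(e) NULL)
    })
    res <- Filter(Negate(is.null), res)
    tab <- motif_enrichment_table(res)
    list(results = res, table = tab, filtered = filter_motif_results(res))
  })
  structure(list(per_list = per_list,
                 results = lapply(per_list, `[[`, "table"),
                 filtered = lapply(per_list, `[[`, "filtered"),
                 promoter_universe = names(seqs),
                 scores = all_scores),
            class = "motif_scan")
}

# ---- command-style entry points -------------------------------------------

.config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(report, path) {
  report$package_version <- as.character(utils::packageVersion("ploidyseq"))
  report$config_hash <- .config_hash(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Generate a synthetic dataset on disk
#'
#' Writes the count tables (one TSV per sample), the toy genome (FASTA), its
#' annotation (GFF3), the planted-truth manifest (TSV), the configuration
#' (YAML) and a JSON run report into `out_dir`. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param motif_matrix Optional [ll_matrix()] to plant.
#' @return The dataset list from [simulate_dataset()], invisibly.
#' @export
cmd_simulate <- function(config = simulation_config(), out_dir,
                         motif_matrix = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) stop("unwritable path: ", out_dir)
  ds <- simulate_dataset(config, motif_matrix = motif_matrix)
  for (pid in names(ds$pairs)) {
    write_count_table(ds$pairs[[pid]]$haploid,
                      file.path(out_dir, sprintf("counts_haploid_%s.tsv", pid)))
    write_count_table(ds$pairs[[pid]]$tetraploid,
                      file.path(out_dir, sprintf("counts_tetraploid_%s.tsv", pid)))
  }
  write_genome_fasta(ds$genome, file.path(out_dir, "genome.fa"))
  write_annotation(ds$annotation, file.path(out_dir, "annotation.gff3"),
                   contig_lengths = ds$contig_lengths)
  truth <- ds$truth
  if (!is.null(ds$motif_sites) && nrow(ds$motif_sites) > 0) {
    truth <- merge(truth, ds$motif_sites[, c("gene_id", "position", "site_strand")],
                   by = "gene_id", all.x = TRUE)
    truth <- truth[order(truth$gene_id), , drop = FALSE]
  }
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$contig_length <- if (is.null(cfg$contig_length)) NA else cfg$contig_length
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  .write_report(list(command = "simulate", seed = config$seed,
                     n_genes = config$n_genes, n_de = config$n_de,
                     n_replicate_pairs = config$n_replicate_pairs,
                     config = cfg),
                file.path(out_dir, "report.json"))
  invisible(ds)
}

#' Run the DE procedure on count-table files
#'
#' @param pair_files List of length-2 character vectors
#'   `c(haploid_path, tetraploid_path)`, one per replicate pair (at least
#'   two pairs).
#' @param out_dir Output directory.
#' @param alpha,min_count,p_max,top_n_grid See [run_de_analysis()].
#' @return The [run_de_analysis()] result, invisibly.
#' @export
cmd_decall <- function(pair_files, out_dir, alpha = 0.001, min_count = 15,
                       p_max = 1e-10, top_n_grid = NULL) {
  if (length(pair_files) < 2) {
    stop("need at least two replicate pairs (overlap is undefined for one)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- lapply(pair_files, function(pf) {
    list(haploid = read_count_table(pf[1]), tetraploid = read_count_table(pf[2]))
  })
  res <- run_de_analysis(pairs, alpha = alpha, min_count = min_count,
                         p_max = p_max, top_n_grid = top_n_grid)
  for (i in seq_along(res$pairs)) {
    for (dir in c("repressed", "induced")) {
      utils::write.table(res$pairs[[i]][[dir]],
                         file.path(out_dir, sprintf("candidates_pair%d_%s.tsv", i, dir)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (dir in c("repressed", "induced")) {
    utils::write.table(res$summary[[dir]],
                       file.path(out_dir, sprintf("overlap_%s.tsv", dir)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  curve_of <- function(sel) if (is.null(sel)) NULL else sel$curve
  .write_report(list(
    command = "decall", alpha = alpha, min_count = min_count, p_max = p_max,
    background_size = res$population_size,
    n_repressed = length(res$repressed), n_induced = length(res$induced),
    repressed = res$repressed, induced = res$induced,
    top_n = list(repressed = if (is.null(res$selection$repressed)) NA else
                   res$selection$repressed$top_n,
                 induced = if (is.null(res$selection$induced)) NA else
                   res$selection$induced$top_n),
    p_overlap = list(repressed = if (is.null(res$selection$repressed)) NA else
                       res$selection$repressed$p_overlap,
                     induced = if (is.null(res$selection$induced)) NA else
                       res$selection$induced$p_overlap),
    curves = list(repressed = curve_of(res$selection$repressed),
                  induced = curve_of(res$selection$induced)),
    notes = as.list(res$notes)
  ), file.path(out_dir, "de_report.json"))
  invisible(res)
}

#' Run gene-set enrichment from files
#'
#' @param query Character vector of gene ids, or path to a one-column file.
#' @param gene_sets_path GMT (`.gmt`) or two-column TSV of term assignments.
#' @param background Character vector of background gene ids, or path to a
#'   one-column file.
#' @param out_dir Output directory.
#' @return The [enrich()] table, invisibly.
#' @export
cmd_enrich <- function(query, gene_sets_path, background, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(query) == 1 && file.exists(query)) query <- readLines(query)
  if (length(background) == 1 && file.exists(background)) {
    background <- readLines(background)
  }
  collection <- if (grepl("\\.gmt$", gene_sets_path)) {
    read_gmt(gene_sets_path, background)
  } else {
    read_gene_sets_tsv(gene_sets_path, background)
  }
  tab <- enrich(query, collection)
  utils::write.table(tab, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_report(list(command = "enrich", query_size = length(query),
                     background_size = length(collection$background),
                     n_terms = length(collection$sets),
                     n_enriched_terms = nrow(tab)),
                file.path(out_dir, "enrich_report.json"))
  invisible(tab)
}

#' Run promoter motif enrichment from files
#'
#' @param fasta_path Genome FASTA.
#' @param gff_path GFF3 annotation.
#' @param motifs_path Motif matrix file (see [read_motif_matrices()]).
#' @param gene_lists Named list of gene-id vectors, or of paths to
#'   one-column files.
#' @param out_dir Output directory.
#' @return The [run_motif_enrichment()] result, invisibly.
#' @export
cmd_scanmotifs <- function(fasta_path, gff_path, motifs_path, gene_lists,
                           out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(fasta_path)
  annotation <- read_annotation(gff_path)
  matrices <- read_motif_matrices(motifs_path)
  gene_lists <- lapply(gene_lists, function(g) {
    if (length(g) == 1 && file.exists(g)) readLines(g) else g
  })
  res <- run_motif_enrichment(genome, annotation, matrices, gene_lists)
  for (nm in names(res$results)) {
    tab <- res$results[[nm]]
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(out_dir, sprintf("motifs_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    filt <- res$filtered[[nm]]
    if (!is.null(filt)) {
      utils::write.table(filt,
                         file.path(out_dir, sprintf("motifs_%s_filtered.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    curves <- do.call(rbind, lapply(res$per_list[[nm]]$results, function(r) {
      cbind(motif_id = r$motif_id, r$curve)
    }))
    if (!is.null(curves)) {
      utils::write.table(curves,
                         file.path(out_dir, sprintf("motifs_%s_grid.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  .write_report(list(command = "scanmotifs",
                     n_motifs = length(matrices),
                     promoter_universe = length(res$promoter_universe),
                     n_filtered = lapply(res$filtered, function(f)
                       if (is.null(f)) 0L else nrow(f))),
                file.path(out_dir, "motif_report.json"))
  invisible(res)
}
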