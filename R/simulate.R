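#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study conditions the pipeline was built for: a yeast-scale
#' transcriptome (6,000 genes) sequenced to roughly 9 million reads per
#' sample, two haploid/tetraploid replicate pairs, a heavy-tailed (log-normal)
#' expression-frequency profile, a planted set of differential genes with
#' fold changes of at least 4 in either direction on genes expressed strongly
#' enough to be detectable (expected count >= 100), and a toy genome whose
#' intergenic gaps span both sides of the 5 kb promoter cap.
#'
#' @param seed Integer seed; fully determines every generator output.
#' @param n_genes Number of genes.
#' @param depth_per_sample Reads per sample (default 9e6).
#' @param freq_log_sd Log-scale SD of the frequency profile (default 1).
#' @param n_de Number of planted differential genes (default 60; split half
#'   repressed, half induced).
#' @param fold_range Interval of planted induced folds (default `c(4, 8)`);
#'   repressed genes get the reciprocal interval.
#' @param de_min_expected Planted genes are drawn among genes whose expected
#'   count per sample is at least this (default 100).
#' @param n_replicate_pairs Number of haploid/tetraploid pairs (default 2).
#' @param gene_length Gene length range in bp, or a single constant.
#' @param intergenic_gap Intergenic gap range in bp, or a single constant
#'   (default `c(200, 6000)` so some upstream neighbours fall nearer than
#'   5 kb and some farther).
#' @param strand_mode `"alternate"`, `"plus"` or `"random"` gene strands.
#' @param overlap_feature Plant one non-gene feature overlapping a gene's
#'   coding start (exercises the promoter skip rule)? Default `TRUE`.
#' @param contig_name Contig name for the toy genome.
#' @param contig_length Optional fixed contig length; an error is raised if
#'   the genes and gaps do not fit.
#' @param motif_fraction Fraction of planted-DE promoters receiving a
#'   consensus motif site (default 0.8).
#' @param motif_background_rate Per-promoter probability of a background
#'   site (default 0.05).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 6000L,
                              depth_per_sample = 9e6,
                              freq_log_sd = 1,
                              n_de = 60L,
                              fold_range = c(4, 8),
                              de_min_expected = 100,
                              n_replicate_pairs = 2L,
                              gene_length = c(500L, 2000L),
                              intergenic_gap = c(200L, 6000L),
                              strand_mode = c("alternate", "plus", "random"),
                              overlap_feature = TRUE,
                              contig_name = "chrS",
                              contig_length = NULL,
                              motif_fraction = 0.8,
                              motif_background_rate = 0.05) {
  strand_mode <- match.arg(strand_mode)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_de < 0 || n_de > n_genes) stop("n_de must lie in [0, n_genes]")
  if (depth_per_sample < 1) stop("depth_per_sample must be positive")
  if (freq_log_sd < 0) stop("freq_log_sd must be non-negative")
  if (any(fold_range <= 0)) stop("fold_range must exclude 0")
  if (motif_fraction < 0 || motif_fraction > 1 ||
      motif_background_rate < 0 || motif_background_rate > 1) {
    stop("motif rates must lie in [0, 1]")
  }
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 depth_per_sample = depth_per_sample,
                 freq_log_sd = freq_log_sd, n_de = as.integer(n_de),
                 fold_range = sort(fold_range),
                 de_min_expected = de_min_expected,
                 n_replicate_pairs = as.integer(n_replicate_pairs),
                 gene_length = as.integer(gene_length),
                 intergenic_gap = as.integer(intergenic_gap),
                 strand_mode = strand_mode,
                 overlap_feature = isTRUE(overlap_feature),
                 contig_name = contig_name,
                 contig_length = contig_length,
                 motif_fraction = motif_fraction,
                 motif_background_rate = motif_background_rate),
            class = "simulation_config")
}

# All sub-generators derive their own stream from the one global seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

.gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a transcriptome frequency profile
#'
#' Per-gene expression frequencies drawn log-normally and normalized to sum
#' to 1; `freq_log_sd` controls how heavy-tailed the transcriptome is
#' (0 gives a flat profile).
#'
#' @param n_genes Number of genes.
#' @param freq_log_sd Log-scale SD.
#' @param seed Integer seed.
#' @return Named vector of positive frequencies summing to 1.
#' @export
simulate_frequency_profile <- function(n_genes, freq_log_sd = 1, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  set.seed(derive_seed(seed, 1L))
  x <- stats::rlnorm(n_genes, meanlog = 0, sdlog = freq_log_sd)
  stats::setNames(x / sum(x), .gene_ids(n_genes))
}

#' Simulate one haploid/tetraploid count-table pair
#'
#' Haploid counts are a single multinomial draw of `depths[1]` reads over the
#' frequency profile; tetraploid counts are drawn over the profile multiplied
#' by the planted folds and renormalized. Multinomial (rather than per-gene
#' binomial) sampling makes library totals exact, matching their use as the
#' frequency denominator; it is also the null model under which the
#' reciprocal binomial tests are approximately valid.
#'
#' @param freqs Frequency profile summing to 1 (see
#'   [simulate_frequency_profile()]).
#' @param de_spec Named numeric vector of planted fold changes
#'   (tetraploid/haploid); genes not named keep fold 1.
#' @param depths Length-2 vector of haploid and tetraploid read totals.
#' @param seed Integer seed.
#' @param pair_id Replicate pair label (e.g. `"A"`).
#' @return List with `haploid` and `tetraploid` [count_table()] objects.
#' @export
simulate_count_pair <- function(freqs, de_spec = numeric(0),
                                depths = c(9e6, 9e6), seed = 1L,
                                pair_id = "A") {
  if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
  if (length(depths) == 1) depths <- rep(depths, 2)
  unknown <- setdiff(names(de_spec), names(freqs))
  if (length(unknown)) stop("fold planted on unknown gene: ",
                            paste(unknown, collapse = ", "))
  if (any(de_spec <= 0)) stop("planted folds must be positive")
  fold <- stats::setNames(rep(1, length(freqs)), names(freqs))
  fold[names(de_spec)] <- de_spec
  f_t <- freqs * fold
  f_t <- f_t / sum(f_t)
  set.seed(derive_seed(seed, 2L))
  k_h <- stats::rmultinom(1, depths[1], freqs)[, 1]
  k_t <- stats::rmultinom(1, depths[2], f_t)[, 1]
  list(
    haploid = count_table(stats::setNames(k_h, names(freqs)),
                          sample_id = paste0("haploid_", pair_id),
                          library_total = depths[1], ploidy = "1n"),
    tetraploid = count_table(stats::setNames(k_t, names(freqs)),
                             sample_id = paste0("tetraploid_", pair_id),
                             library_total = depths[2], ploidy = "4n")
  )
}

.draw_lengths <- function(n, range, seed) {
  if (length(range) == 1) return(rep(as.integer(range), n))
  set.seed(seed)
  sample(range[1]:range[2], n, replace = TRUE)
}

#' Simulate an annotated toy genome
#'
#' Genes are packed along one contig separated by intergenic gaps drawn from
#' the configured distribution, on strands chosen per `strand_mode`. With
#' `overlap_feature = TRUE` a small non-gene feature (`dubious_orf`) is
#' planted overlapping the coding start of one gene, so that the promoter
#' rule that skips features overlapping the start is exercised. The contig
#' sequence is uniform random A/C/G/T. Output is fully determined by the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector), `annotation`
#'   (feature data frame) and `contig_lengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  glen <- .draw_lengths(n, config$gene_length, derive_seed(config$seed, 3L))
  gaps <- .draw_lengths(n + 1, config$intergenic_gap, derive_seed(config$seed, 4L))
  # gap_i is the distance from gene i's coding start back to the previous
  # feature's end (a length-1 anchor at position 1 precedes the first gene),
  # i.e. exactly the upstream promoter extent when below the 5 kb cap
  starts <- 1 + cumsum(gaps[seq_len(n)] + c(0, glen[-n] - 1L))
  ends <- starts + glen - 1
  strand <- switch(config$strand_mode,
                   plus = rep("+", n),
                   alternate = rep(c("+", "-"), length.out = n),
                   random = {
                     set.seed(derive_seed(config$seed, 5L))
                     sample(c("+", "-"), n, replace = TRUE)
                   })
  ann <- data.frame(seqid = config$contig_name, type = "gene",
                    start = starts, end = ends, strand = strand,
                    gene_id = .gene_ids(n), stringsAsFactors = FALSE)
  ann <- rbind(data.frame(seqid = config$contig_name, type = "telomere",
                          start = 1L, end = 1L, strand = "+",
                          gene_id = "tel00001", stringsAsFactors = FALSE),
               ann)
  if (config$overlap_feature && n >= 2) {
    g <- ann[ann$gene_id == .gene_ids(n)[2], ]
    if (g$strand == "+") {
      dub <- data.frame(seqid = config$contig_name, type = "dubious_orf",
                        start = max(1, g$start - 25), end = g$start + 100,
                        strand = "+", gene_id = "dub00001",
                        stringsAsFactors = FALSE)
    } else {
      dub <- data.frame(seqid = config$contig_name, type = "dubious_orf",
                        start = g$end - 100, end = g$end + 25,
                        strand = "+", gene_id = "dub00001",
                        stringsAsFactors = FALSE)
    }
    ann <- rbind(ann, dub)
  }
  total <- max(ann$end) + gaps[n + 1]
  if (!is.null(config$contig_length)) {
    if (total > config$contig_length) {
      stop("infeasible packing: genes and gaps need ", total,
           " bp but contig_length is ", config$contig_length)
    }
    total <- as.integer(config$contig_length)
  }
  set.seed(derive_seed(config$seed, 6L))
  seq <- intToUtf8(sample(utf8ToInt("ACGT"), total, replace = TRUE))
  genome <- stats::setNames(seq, config$contig_name)
  list(genome = genome, annotation = ann,
       contig_lengths = stats::setNames(as.integer(total), config$contig_name))
}

#' Plant motif sites into promoters
#'
#' Overwrites (no indels, so coordinates stay stable) a consensus site of the
#' matrix at a random position within the promoter of each selected gene:
#' a configured fraction of the target genes, plus background genes at the
#' background rate. Each site's strand is random, so roughly half the planted
#' sites are reverse-complemented; a strand-symmetric scanner recovers both.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotation Feature table.
#' @param matrix An [ll_matrix()].
#' @param target_genes Gene ids receiving sites at `fraction`.
#' @param fraction Fraction of target promoters receiving a site.
#' @param background_rate Per-promoter site probability outside the targets.
#' @param seed Integer seed.
#' @param contig_lengths Named vector of contig lengths.
#' @return List with the modified `genome` and a `sites` data frame
#'   (`gene_id`, `contig`, `position`, `site_strand`).
#' @export
plant_motif_sites <- function(genome, annotation, matrix, target_genes,
                              fraction = 1, background_rate = 0, seed = 1L,
                              contig_lengths = NULL) {
  stopifnot(inherits(matrix, "ll_matrix"))
  if (is.null(contig_lengths)) {
    contig_lengths <- stats::setNames(nchar(genome), names(genome))
  }
  proms <- extract_promoters(annotation, contig_lengths)
  missing_prom <- setdiff(target_genes, proms$gene_id)
  if (length(missing_prom)) {
    stop("target gene without promoter: ", paste(missing_prom, collapse = ", "))
  }
  W <- matrix$width
  if (any(W >= proms$end[proms$gene_id %in% target_genes] -
            proms$start[proms$gene_id %in% target_genes] + 1)) {
    stop("matrix width must be smaller than every target promoter")
  }
  set.seed(derive_seed(seed, 7L))
  n_t <- round(fraction * length(target_genes))
  chosen <- sort(sample(target_genes, n_t))
  others <- setdiff(proms$gene_id, target_genes)
  bg_chosen <- others[stats::runif(length(others)) < background_rate]
  site <- consensus_site(matrix)
  site_codes <- list("+" = utf8ToInt(site),
                     "-" = utf8ToInt(reverse_complement(site)))
  # edit contigs as integer code vectors: one conversion per contig instead
  # of one whole-genome copy per planted site
  codes <- lapply(genome, utf8ToInt)
  rows <- list()
  for (g in sort(c(chosen, bg_chosen))) {
    p <- proms[proms$gene_id == g, ]
    if (p$end - p$start + 1 <= W) next
    pos <- sample(p$start:(p$end - W + 1), 1)
    strand <- sample(c("+", "-"), 1)
    codes[[p$contig]][pos:(pos + W - 1)] <- site_codes[[strand]]
    rows[[g]] <- data.frame(gene_id = g, contig = p$contig, position = pos,
                            site_strand = strand, stringsAsFactors = FALSE)
  }
  genome <- stats::setNames(vapply(codes, intToUtf8, character(1)),
                            names(genome))
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), contig = character(0),
               position = integer(0), site_strand = character(0))
  rownames(sites) <- NULL
  list(genome = genome, sites = sites)
}

#' Simulate a complete synthetic dataset
#'
#' Draws the frequency profile, plants differential genes (half repressed
#' with folds in the reciprocal of `fold_range`, half induced with folds in
#' `fold_range`, all on genes expressed strongly enough to be recoverable),
#' simulates the replicate count-table pairs, builds the annotated toy genome
#' and, when a motif matrix is supplied, plants motif sites into the
#' promoters of the planted differential genes. The truth manifest records
#' every planted fold and site.
#'
#' @param config A [simulation_config()].
#' @param motif_matrix Optional [ll_matrix()] to plant.
#' @param de_spec Optional named fold vector overriding the automatic
#'   planting.
#' @return List with `config`, `freqs`, `de_spec`, `pairs`, `genome`,
#'   `annotation`, `contig_lengths`, `motif_sites`, `truth`.
#' @export
simulate_dataset <- function(config = simulation_config(), motif_matrix = NULL,
                             de_spec = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  freqs <- simulate_frequency_profile(config$n_genes, config$freq_log_sd,
                                      config$seed)
  if (is.null(de_spec)) {
    # planted genes sit in a detectable but moderate expression band
    # (expected count between de_min_expected and 10x that), so the planted
    # mass stays a negligible fraction of the library and renormalizing the
    # tetraploid profile leaves non-planted frequencies essentially unchanged
    expected <- freqs * config$depth_per_sample
    eligible <- names(freqs)[expected >= config$de_min_expected &
                               expected <= 10 * config$de_min_expected]
    if (length(eligible) < config$n_de) {
      stop("not enough genes with expected count in [",
           config$de_min_expected, ", ", 10 * config$de_min_expected,
           "] to plant ", config$n_de, " differential genes")
    }
    set.seed(derive_seed(config$seed, 8L))
    de_genes <- sort(sample(eligible, config$n_de))
    n_rep <- config$n_de %/% 2
    folds <- c(1 / stats::runif(n_rep, config$fold_range[1], config$fold_range[2]),
               stats::runif(config$n_de - n_rep, config$fold_range[1],
                            config$fold_range[2]))
    de_spec <- stats::setNames(folds, de_genes)
  }
  pairs <- lapply(seq_len(config$n_replicate_pairs), function(i) {
    simulate_count_pair(freqs, de_spec,
                        depths = rep(config$depth_per_sample, 2),
                        seed = derive_seed(config$seed, 100L + i),
                        pair_id = LETTERS[i])
  })
  names(pairs) <- LETTERS[seq_len(config$n_replicate_pairs)]
  gen <- simulate_genome(config)
  motif_sites <- NULL
  if (!is.null(motif_matrix)) {
    planted <- plant_motif_sites(gen$genome, gen$annotation, motif_matrix,
                                 target_genes = names(de_spec),
                                 fraction = config$motif_fraction,
                                 background_rate = config$motif_background_rate,
                                 seed = config$seed,
                                 contig_lengths = gen$contig_lengths)
    gen$genome <- planted$genome
    motif_sites <- planted$sites
  }
  truth <- data.frame(gene_id = names(de_spec), fold = unname(de_spec),
                      direction = ifelse(de_spec < 1, "repressed", "induced"),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(config = config, freqs = freqs, de_spec = de_spec, pairs = pairs,
       genome = gen$genome, annotation = gen$annotation,
       contig_lengths = gen$contig_lengths, motif_sites = motif_sites,
       truth = truth)
}
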