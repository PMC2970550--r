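test_that("frequency profiles are normalized, heavy-tailed and seeded", {
  expect_equal(unname(simulate_frequency_profile(1, 1, seed = 3)), 1.0)
  f <- simulate_frequency_profile(1000, 0, seed = 3)
  expect_equal(unname(f), rep(0.001, 1000))
  f <- simulate_frequency_profile(1000, 1, seed = 3)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
  expect_identical(f, simulate_frequency_profile(1000, 1, seed = 3))
  expect_false(identical(f, simulate_frequency_profile(1000, 1, seed = 4)))
  expect_error(simulate_frequency_profile(0), "positive")
})

test_that("count pairs follow multinomial moments and the planted folds", {
  freqs <- stats::setNames(c(1e-4, rep((1 - 1e-4) / 99, 99)),
                           sprintf("g%03d", 1:100))
  # mean count of the 1e-4 gene over 200 seeds is 100 within 3 standard errors
  ks <- vapply(1:200, function(s) {
    simulate_count_pair(freqs, depths = c(1e6, 1e6), seed = s)$haploid$counts[["g001"]]
  }, numeric(1))
  se <- sqrt(100 * (1 - 1e-4) / 200)
  expect_lt(abs(mean(ks) - 100), 3 * se)
  # planted fold 0.25 scales the tetraploid expectation
  freqs2 <- stats::setNames(rep(1e-3, 1000), sprintf("g%04d", 1:1000))
  kt <- vapply(1:100, function(s) {
    simulate_count_pair(freqs2, c(g0001 = 0.25), depths = c(1e6, 1e6),
                        seed = 1000 + s)$tetraploid$counts[["g0001"]]
  }, numeric(1))
  expect_lt(abs(mean(kt) - 250), 4 * sqrt(250 / 100))
  # determinism and library totals
  p1 <- simulate_count_pair(freqs, depths = c(1e5, 2e5), seed = 9)
  p2 <- simulate_count_pair(freqs, depths = c(1e5, 2e5), seed = 9)
  expect_identical(p1$haploid$counts, p2$haploid$counts)
  expect_identical(p1$tetraploid$counts, p2$tetraploid$counts)
  expect_equal(sum(p1$haploid$counts), 1e5)
  expect_equal(p1$tetraploid$library_total, 2e5)
  expect_error(simulate_count_pair(freqs, c(nope = 2), seed = 1), "unknown gene")
})

test_that("toy genomes honor the gap-driven promoter geometry", {
  base_cfg <- function(gap) {
    simulation_config(seed = 11, n_genes = 30, n_de = 0, gene_length = 700,
                      intergenic_gap = gap, strand_mode = "plus",
                      overlap_feature = FALSE)
  }
  g <- simulate_genome(base_cfg(1200))
  ps <- extract_promoters(g$annotation, g$contig_lengths)
  expect_true(all(ps$upstream_extent == 1200))
  g <- simulate_genome(base_cfg(10000))
  ps <- extract_promoters(g$annotation, g$contig_lengths)
  expect_true(all(ps$upstream_extent == 5000))
  # byte-identical FASTA/GFF3 for a fixed seed
  cfg <- simulation_config(seed = 5, n_genes = 12, n_de = 0,
                           gene_length = c(300, 500),
                           intergenic_gap = c(200, 6000))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    gg <- simulate_genome(cfg)
    write_genome_fasta(gg$genome, file.path(d, "g.fa"))
    write_annotation(gg$annotation, file.path(d, "g.gff3"),
                     contig_lengths = gg$contig_lengths)
  }
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
  # the planted overlapping feature spans a coding start
  gg <- simulate_genome(simulation_config(seed = 5, n_genes = 12, n_de = 0,
                                          gene_length = c(300, 500),
                                          intergenic_gap = c(200, 6000)))
  dub <- gg$annotation[gg$annotation$type == "dubious_orf", ]
  g2 <- gg$annotation[gg$annotation$gene_id == "g00002", ]
  cs <- if (g2$strand == "+") g2$start else g2$end
  expect_true(dub$start <= cs && cs <= dub$end)
  # infeasible packing is rejected
  expect_error(simulate_genome(simulation_config(seed = 1, n_genes = 10, n_de = 0,
                                                 gene_length = 1000,
                                                 intergenic_gap = 1000,
                                                 contig_length = 5000)),
               "infeasible")
})

test_that("annotation GFF3 output reads back identically", {
  cfg <- simulation_config(seed = 2, n_genes = 8, n_de = 0,
                           gene_length = c(300, 500),
                           intergenic_gap = c(200, 1000))
  g <- simulate_genome(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(g$annotation, path, contig_lengths = g$contig_lengths)
  back <- read_annotation(path)
  expect_equal(back[, c("seqid", "type", "start", "end", "strand", "gene_id")],
               g$annotation[, c("seqid", "type", "start", "end", "strand",
                                "gene_id")])
})

test_that("planted motif sites reach the maximum score, on either strand", {
  cfg <- simulation_config(seed = 13, n_genes = 40, n_de = 0,
                           gene_length = c(300, 500),
                           intergenic_gap = c(300, 700),
                           strand_mode = "alternate")
  g <- simulate_genome(cfg)
  mt <- toy_motif("PL", "ACGGTCAT")
  targets <- sprintf("g%05d", 1:10)
  planted <- plant_motif_sites(g$genome, g$annotation, mt, targets,
                               fraction = 1, background_rate = 0, seed = 17,
                               contig_lengths = g$contig_lengths)
  expect_setequal(planted$sites$gene_id, targets)
  expect_true(any(planted$sites$site_strand == "-"))
  proms <- extract_promoters(g$annotation, g$contig_lengths)
  seqs <- promoter_sequences(proms[proms$gene_id %in% targets, ],
                             planted$genome)
  scores <- best_match_scores(mt, seqs)
  expect_true(all(abs(scores - mt$max_score) < 1e-9))
  # minus-strand insertions score identically (checked against enumeration)
  minus_gene <- planted$sites$gene_id[planted$sites$site_strand == "-"][1]
  s <- seqs[[minus_gene]]
  expect_equal(scan_oracle(mt, s), mt$max_score)
  # with no planting anywhere, consensus hits are absent from random promoters
  bare <- promoter_sequences(proms, g$genome)
  expect_true(all(best_match_scores(mt, bare) < mt$max_score))
  expect_error(plant_motif_sites(g$genome, g$annotation, mt, "nope",
                                 contig_lengths = g$contig_lengths),
               "without promoter")
})

test_that("full datasets are seed-deterministic with a valid truth manifest", {
  cfg <- simulation_config(seed = 23, n_genes = 300, depth_per_sample = 2e5,
                           n_de = 10, gene_length = c(300, 500),
                           intergenic_gap = c(250, 600), de_min_expected = 50)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$pairs$A$haploid$counts, d2$pairs$A$haploid$counts)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$truth), 10)
  expect_setequal(unique(d1$truth$direction), c("repressed", "induced"))
  expect_true(all(d1$truth$fold > 0))
  # replicate pairs differ from each other but share the profile
  expect_false(identical(d1$pairs$A$haploid$counts, d1$pairs$B$haploid$counts))
})
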