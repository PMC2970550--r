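test_that("log-likelihood matrices validate and convert from probabilities", {
  m <- ll_matrix(rbind(c(1, -1, -1, -1), c(-1, 1, -1, -1)), "M1")
  expect_equal(m$max_score, 2)
  expect_equal(consensus_site(m), "AC")
  expect_error(ll_matrix(rbind(c(-1, -1, -1, -1)), "bad"), "positive")
  # probability rows equal to the background convert to all-zero scores
  pm <- ll_matrix(rbind(c(0.25, 0.25, 0.25, 0.25), c(0.97, 0.01, 0.01, 0.01)),
                  "M2", type = "prob")
  expect_equal(unname(pm$scores[1, ]), rep(0, 4), tolerance = 1e-12)
  expect_gt(pm$scores[2, 1], 0)
  expect_lt(pm$scores[2, 2], 0)
})

test_that("motif files round-trip through the block text format", {
  m1 <- toy_motif("Ste12ish", "ATGAAACA")
  m2 <- ll_matrix(rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1)),
                  "Probby", type = "prob")
  path <- withr::local_tempfile(fileext = ".motifs")
  write_motif_matrices(list(m1, m2), path)
  back <- read_motif_matrices(path)
  expect_identical(names(back), c("Ste12ish", "Probby"))
  expect_equal(back$Ste12ish$scores, m1$scores, tolerance = 1e-9)
  expect_equal(back$Probby$max_score, m2$max_score, tolerance = 1e-9)
  # prob-typed block converts on read
  writeLines(c(">P type=prob", "0.25\t0.25\t0.25\t0.25",
               "0.97\t0.01\t0.01\t0.01"), path)
  expect_equal(unname(read_motif_matrices(path)$P$scores[1, ]), rep(0, 4),
               tolerance = 1e-12)
})

test_that("best match score maximizes over windows on both strands", {
  m <- ll_matrix(rbind(c(1, -1, -1, -1), c(1, -1, -1, -1)), "AA")
  expect_equal(best_match_score(m, "AAT"), 2)
  expect_equal(best_match_score(m, "GCT"), best_match_score(m, "AGC"))  # TT on rc
  mt <- toy_motif()
  expect_equal(best_match_score(mt, consensus_site(mt)), mt$max_score)
  expect_error(best_match_score(mt, "ACGTACG"), "shorter")
  # N scores the per-position minimum
  expect_equal(best_match_score(m, "NA"),
               max(min(m$scores[1, ]) + m$scores[2, 1],   # NA forward
                   m$scores[1, 4] + min(m$scores[2, ])))  # TN reverse-comp
})

test_that("best match score agrees with brute-force enumeration and is strand-invariant", {
  mt <- toy_motif("X", "ACGGTA")
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(10:60, 1))
    sc <- best_match_score(mt, s)
    expect_equal(sc, scan_oracle(mt, s))
    expect_equal(sc, best_match_score(mt, reverse_complement(s)))
  }
})

test_that("match calling uses an inclusive fractional cutoff", {
  mt <- toy_motif()
  scores <- c(lo = 0, exact = 0.5 * mt$max_score, hi = mt$max_score)
  calls <- call_matches(scores, mt, 0.5)
  expect_identical(unname(calls), c(FALSE, TRUE, TRUE))
  expect_error(call_matches(scores, mt, 0), "cutoff")
  expect_error(call_matches(scores, mt, 1.2), "cutoff")
  # match counts are monotone non-increasing in the cutoff
  set.seed(8)
  sc <- runif(200, -5, mt$max_score)
  n_matches <- vapply(cutoff_grid(), function(cf) sum(call_matches(sc, mt, cf)),
                      numeric(1))
  expect_true(all(diff(n_matches) <= 0))
})

test_that("binomial motif test is the upper tail at the background rate", {
  expect_equal(binomial_motif_test(10, 10, 0.5), 2^-10)
  expect_equal(binomial_motif_test(0, 10, 0.5), 1.0)
  # exact summation oracle
  exact_upper <- function(m, n, p) {
    sum(vapply(m:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
  }
  expect_equal(binomial_motif_test(5, 10, 0.5), exact_upper(5, 10, 0.5),
               tolerance = 1e-12)
  expect_equal(binomial_motif_test(5, 10, 0.5), 0.623, tolerance = 1e-3)
  expect_equal(binomial_motif_test(3, 50, 0), 0)
})

test_that("the cutoff grid has 15 inclusive points from 0.30 to 1.00", {
  g <- cutoff_grid()
  expect_length(g, 15)
  expect_equal(g[1], 0.30)
  expect_equal(g[15], 1.00)
  expect_equal(unique(round(diff(g), 10)), 0.05)
})

test_that("cutoff optimization returns the most significant grid point", {
  mt <- toy_motif()
  set.seed(21)
  bg <- vapply(1:400, function(i) best_match_score(mt, random_dna(300)),
               numeric(1))
  # plant the consensus into 80% of a 60-promoter set
  set_seqs <- replicate(60, random_dna(300))
  for (i in 1:48) {
    substr(set_seqs[i], 100, 107) <- consensus_site(mt)
  }
  set_sc <- vapply(set_seqs, function(s) best_match_score(mt, s), numeric(1))
  res <- optimize_cutoff(mt, set_sc, bg)
  expect_s3_class(res, "motif_enrichment")
  expect_equal(nrow(res$curve), 15)
  expect_equal(res$p_binomial, min(res$curve$p_binomial))
  # ties break toward the smaller cutoff
  first_min <- res$curve$cutoff_fraction[
    which(res$curve$p_binomial == min(res$curve$p_binomial))][1]
  expect_equal(res$cutoff_fraction, first_min)
  expect_gte(res$set_freq, 0.8)
  expect_error(optimize_cutoff(mt, numeric(0), bg), "empty")
})

test_that("the three-way filter keeps only strong, frequent, enriched motifs", {
  row <- function(p, freq, fold) {
    data.frame(motif_id = "m", cutoff_fraction = 0.5, set_matches = 1,
               set_size = 4, set_freq = freq, bg_matches = 1, bg_size = 100,
               bg_freq = freq / fold, fold = fold, p_binomial = p)
  }
  # all bounds inclusive
  expect_equal(nrow(filter_motif_results(row(0.005, 0.25, 1.5))), 1)
  expect_equal(nrow(filter_motif_results(row(0.004, 0.24, 10))), 0)
  expect_equal(nrow(filter_motif_results(row(0.006, 0.9, 10))), 0)
  expect_equal(nrow(filter_motif_results(row(0.004, 0.5, 1.49))), 0)
})
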