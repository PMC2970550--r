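test_that("binomial CMF matches exact summation on a randomized grid", {
  expect_equal(binomial_cmf(2, 10, 0.5), 56 / 1024)
  expect_equal(binomial_cmf(10, 10, 0.123), 1.0)
  expect_equal(binomial_cmf(0, 10, 0.1), 0.9^10)
  set.seed(101)
  for (i in 1:60) {
    n <- sample(1:2000, 1)
    k <- sample(0:n, 1)
    f <- runif(1)
    expect_equal(binomial_cmf(k, n, f), exact_binomial_cmf(k, n, f),
                 tolerance = 1e-9)
  }
  expect_error(binomial_cmf(11, 10, 0.5), "exceeds")
  expect_error(binomial_cmf(2, 10, 1.5), "frequency")
})

test_that("reciprocal p-values take the observed tail and handle zero frequencies", {
  # equal observations: no call in either direction
  p <- reciprocal_pvalues(100, 1e6, 100, 1e6)
  expect_true(p$p_t_given_h > 0.05 && p$p_h_given_t > 0.05)
  expect_equal(p$p_t_given_h, exact_binomial_cmf(100, 1e6, 1e-4),
               tolerance = 1e-9)
  # 4-fold drop at this depth is far in the tail in both directions
  p <- reciprocal_pvalues(100, 1e6, 25, 1e6)
  expect_true(p$p_t_given_h < 0.001 && p$p_h_given_t < 0.001)
  expect_equal(p$p_t_given_h, exact_binomial_cmf(25, 1e6, 1e-4),
               tolerance = 1e-9)
  # zero-count gene: silent-side frequency conventions
  p <- reciprocal_pvalues(0, 1e6, 50, 1e6)
  expect_equal(p$p_t_given_h, 0)
  expect_equal(p$p_h_given_t, (1 - 5e-5)^1e6)
  expect_error(reciprocal_pvalues(10, 0, 10, 100), "zero library total")
})

test_that("reciprocal p-values are antisymmetric under swapping the samples", {
  set.seed(77)
  for (i in 1:25) {
    N <- 1e5
    k1 <- rpois(1, 200)
    k2 <- rpois(1, 60)
    a <- reciprocal_pvalues(k1, N, k2, N)
    b <- reciprocal_pvalues(k2, N, k1, N)
    expect_equal(a$p_t_given_h, b$p_h_given_t)
    expect_equal(a$p_h_given_t, b$p_t_given_h)
  }
})

test_that("the tail p-value decreases as the observation moves outward", {
  # repression tail: smaller k_t, smaller p
  ps <- vapply(seq(100, 20, by = -10), function(kt) {
    reciprocal_pvalues(100, 1e6, kt, 1e6)$p_t_given_h
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # induction tail
  ps <- vapply(seq(100, 300, by = 25), function(kt) {
    reciprocal_pvalues(100, 1e6, kt, 1e6)$p_t_given_h
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("fold change normalizes by totals and pseudocounts only zeros", {
  expect_equal(fold_change(100, 1e6, 25, 1e6), 0.25)
  expect_equal(fold_change(123, 1e6, 123, 1e6), 1.0)
  expect_equal(fold_change(0, 1e6, 50, 1e6), 100)   # 50 / 0.5
  expect_equal(fold_change(100, 2e6, 100, 1e6), 2)  # depth normalization
})

test_that("candidate calling retains both-tail significant genes, ranked by fold", {
  freqs <- stats::setNames(rep(1e-3, 1000), sprintf("g%04d", 1:1000))
  de <- c(g0001 = 0.25, g0002 = 4, g0003 = 0.1)
  pair <- simulate_count_pair(freqs, de, depths = c(1e6, 1e6), seed = 5)
  cc <- call_candidates(pair$haploid, pair$tetraploid)
  expect_s3_class(cc, "de_calls")
  expect_true(all(c("g0001", "g0003") %in% cc$repressed$gene_id))
  expect_true("g0002" %in% cc$induced$gene_id)
  # repressed ranked by ascending fold: the 10x repression outranks the 4x
  expect_lt(which(cc$repressed$gene_id == "g0003"),
            which(cc$repressed$gene_id == "g0001"))
  # per-gene record invariants
  expect_true(all(cc$records$p_t_given_h >= 0 & cc$records$p_t_given_h <= 1))
  ok_dir <- with(cc$records, (direction == "repressed") == (f_t < f_h) |
                   direction != "repressed")
  expect_true(all(ok_dir))
  expect_true(all(with(cc$records, passes == (expressed & direction != "none" &
    p_t_given_h < 0.001 & p_h_given_t < 0.001))))
  expect_error(call_candidates(pair$haploid, pair$tetraploid, alpha = 1.1),
               "alpha")
})

test_that("overlap significance matches exhaustive subset enumeration", {
  expect_equal(overlap_significance(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(overlap_significance(0, 5, 5, 10), 1.0)
  expect_equal(overlap_significance(1, 1, 1, 100), 0.01)
  set.seed(9)
  for (i in 1:8) {
    N <- sample(6:12, 1)
    n_a <- sample(1:(N - 1), 1)
    n_b <- sample(1:(N - 1), 1)
    m <- sample(0:min(n_a, n_b), 1)
    expect_equal(overlap_significance(m, n_a, n_b, N),
                 enum_overlap_p(m, n_a, n_b, N), tolerance = 1e-9)
  }
  expect_error(overlap_significance(6, 5, 5, 10), "inconsistent")
})

test_that("top-N overlap intersects equal-size heads of the ranked lists", {
  la <- sprintf("g%02d", 1:20)
  sel <- overlap_top_candidates(la, la, 10, 5000)
  expect_equal(length(sel$overlap), 10)
  expect_lt(sel$p_overlap, 1e-20)
  sel <- overlap_top_candidates(la, sprintf("h%02d", 1:20), 10, 5000)
  expect_equal(length(sel$overlap), 0)
  expect_equal(sel$p_overlap, 1)
  lb <- c(la[1:5], sprintf("h%02d", 1:15))
  sel <- overlap_top_candidates(la, lb, 10, 5000)
  expect_gte(length(sel$overlap), 5)
  expect_error(overlap_top_candidates(la, lb, 0, 5000), "positive")
  expect_error(overlap_top_candidates(la, lb, 25, 5000), "exceeds")
})

test_that("adaptive top-N picks the largest grid value meeting the p bound", {
  la <- sprintf("g%02d", 1:20)
  sel <- select_top_n(la, la, 5000, p_max = 1e-10, grid = seq(5, 40, 5))
  expect_equal(sel$top_n, 20)
  expect_equal(nrow(sel$curve), 4)  # 25..40 unusable for length-20 lists
  # p at the selected point agrees with enumeration-scale closed form
  expect_equal(sel$p_overlap, overlap_significance(20, 20, 20, 5000))
  # independent random lists are rejected as inconsistent
  set.seed(3)
  ra <- sample(sprintf("x%04d", 1:5000), 30)
  rb <- sample(sprintf("x%04d", 1:5000), 30)
  expect_error(select_top_n(ra, rb, 5000, grid = c(10, 20, 30)),
               "inconsistent")
  # single grid value: selection happens iff the closed-form tail qualifies
  g5 <- sprintf("g%02d", 1:5)
  p5 <- overlap_significance(5, 5, 5, 1000)
  sel5 <- tryCatch(select_top_n(g5, g5, 1000, p_max = 1e-10, grid = 5),
                   error = function(e) e)
  expect_identical(inherits(sel5, "error"), !(p5 < 1e-10))
})

test_that("cross-pair summaries report mean and SD of fold change", {
  t1 <- list(haploid = toy_table(c(a = 100, b = 50), total = 1e6),
             tetraploid = toy_table(c(a = 20, b = 50), total = 1e6))
  t2 <- list(haploid = toy_table(c(a = 100, b = 50), total = 1e6),
             tetraploid = toy_table(c(a = 30, b = 50), total = 1e6))
  s <- summarize_de(c("a", "b"), list(t1, t2))
  expect_equal(s$mean_fold[s$gene_id == "a"], 0.25)
  expect_equal(s$sd_fold[s$gene_id == "a"], stats::sd(c(0.2, 0.3)))
  expect_equal(s$sd_fold[s$gene_id == "b"], 0)
  expect_true(all(s$sd_defined))
  # single pair: SD reported as 0 and flagged undefined
  s1 <- summarize_de("a", list(t1))
  expect_equal(s1$sd_fold, 0)
  expect_false(s1$sd_defined)
  expect_error(summarize_de("zz", list(t1)), "missing")
})
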