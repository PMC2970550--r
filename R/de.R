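#' Binomial cumulative mass function
#'
#' `P(X <= k)` for `X ~ Binomial(n, f)`: the sum of the probabilities of all
#' counts less than or equal to the observed count. This is the kernel of the
#' reciprocal differential-expression p-values. Computed via the regularized
#' incomplete beta function ([stats::pbinom()]), which stays accurate for
#' library-scale `n` (1e8 and beyond) where naive summation would not.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials (library total).
#' @param f Success frequency in `[0, 1]`.
#' @return `P(X <= k)`, vectorized over the inputs.
#' @export
binomial_cmf <- function(k, n, f) {
  if (any(f < 0 | f > 1)) stop("frequency outside [0, 1]")
  if (any(k < 0)) stop("negative count")
  if (any(k > n)) stop("k exceeds n")
  stats::pbinom(k, n, f)
}

#' Reciprocal binomial p-values for one gene
#'
#' With haploid count `k_h` out of `N_h` reads and tetraploid count `k_t` out
#' of `N_t`, the haploid frequency `f_h = k_h / N_h` parameterizes a binomial
#' null for the tetraploid observation, and vice versa. Each p-value is
#' one-sided in the direction of the observed change: the lower tail
#' `P(X <= k)` when the other sample's frequency is below the null frequency,
#' and the upper tail `P(X >= k)` otherwise. A zero null frequency is handled
#' by the conventions `P(X <= k | f = 0) = 1` and `P(X >= k | f = 0) = 0` for
#' `k > 0`, so a gene silent in one sample but read in the other is maximally
#' significant in one direction.
#'
#' All arguments are vectorized over genes.
#'
#' @param k_h,k_t Integer counts in the haploid and tetraploid samples.
#' @param N_h,N_t Positive library totals.
#' @return List with components `p_t_given_h` (tetraploid observation under
#'   the haploid frequency) and `p_h_given_t` (the reciprocal).
#' @export
reciprocal_pvalues <- function(k_h, N_h, k_t, N_t) {
  if (any(N_h <= 0) || any(N_t <= 0)) stop("zero library total")
  if (any(k_h < 0) || any(k_t < 0)) stop("negative count")
  if (any(k_h > N_h) || any(k_t > N_t)) stop("count exceeds library total")
  f_h <- k_h / N_h
  f_t <- k_t / N_t
  one_tail <- function(k, n, f_null, f_obs) {
    lower <- f_obs <= f_null
    p <- numeric(length(k))
    p[lower] <- stats::pbinom(k[lower], n[lower], f_null[lower])
    p[!lower] <- stats::pbinom(k[!lower] - 1, n[!lower], f_null[!lower],
                               lower.tail = FALSE)
    p
  }
  k_h <- rep_len(k_h, max(length(k_h), length(k_t)))
  k_t <- rep_len(k_t, length(k_h))
  N_h <- rep_len(N_h, length(k_h))
  N_t <- rep_len(N_t, length(k_h))
  f_h <- k_h / N_h
  f_t <- k_t / N_t
  list(
    p_t_given_h = one_tail(k_t, N_t, f_h, f_t),
    p_h_given_t = one_tail(k_h, N_h, f_t, f_h)
  )
}

#' Frequency fold change (tetraploid over haploid)
#'
#' `((k_t / N_t) / (k_h / N_h))` after normalizing each count by its library
#' total; values below 1 mean repressed in the tetraploid. A pseudocount is
#' substituted for a count only when that count is zero, so that silent genes
#' get a large but finite fold change for ranking; p-values never use the
#' pseudocount.
#'
#' @param k_h,k_t Counts (may be fractional).
#' @param N_h,N_t Positive library totals.
#' @param pseudocount Replacement for zero counts (default 0.5).
#' @return Positive fold change(s).
#' @export
fold_change <- function(k_h, N_h, k_t, N_t, pseudocount = 0.5) {
  if (any(N_h <= 0) || any(N_t <= 0)) stop("zero library total")
  kh <- ifelse(k_h == 0, pseudocount, k_h)
  kt <- ifelse(k_t == 0, pseudocount, k_t)
  (kt / N_t) / (kh / N_h)
}

#' Call differential-expression candidates for one haploid/tetraploid pair
#'
#' For every gene expressed in at least one of the two samples (count at or
#' above `min_count`), both reciprocal binomial p-values are computed and the
#' gene is retained when both fall below `alpha`. Retained genes are split by
#' direction and ranked by fold change: repressed genes ascending (strongest
#' repression first), induced genes descending. Ties are broken
#' lexicographically by gene id. Fractional counts (from multimap weighting)
#' are floored to integers for the binomial model; fold changes use the raw
#' counts.
#'
#' @param haploid,tetraploid [count_table()] objects over the same genes.
#' @param alpha Per-tail significance threshold (default 0.001).
#' @param min_count Expressed threshold (default 15).
#' @return An object of class `de_calls`: list with `records` (per-gene data
#'   frame), `repressed` and `induced` (ranked candidate data frames),
#'   `background` (expressed gene ids), `alpha`, `min_count`.
#' @export
call_candidates <- function(haploid, tetraploid, alpha = 0.001, min_count = 15) {
  stopifnot(inherits(haploid, "count_table"), inherits(tetraploid, "count_table"))
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  genes <- sort(names(haploid$counts))
  if (length(genes) == 0) stop("empty gene universe")
  if (!identical(genes, sort(names(tetraploid$counts)))) {
    stop("tables do not share a gene universe")
  }
  c_h <- haploid$counts[genes]
  c_t <- tetraploid$counts[genes]
  N_h <- haploid$library_total
  N_t <- tetraploid$library_total
  k_h <- floor(c_h)
  k_t <- floor(c_t)
  p <- reciprocal_pvalues(k_h, N_h, k_t, N_t)
  f_h <- k_h / N_h
  f_t <- k_t / N_t
  fold <- fold_change(c_h, N_h, c_t, N_t)
  direction <- ifelse(f_t < f_h, "repressed",
                      ifelse(f_t > f_h, "induced", "none"))
  expressed <- pmax(c_h, c_t) >= min_count
  passes <- expressed & direction != "none" &
    p$p_t_given_h < alpha & p$p_h_given_t < alpha
  records <- data.frame(
    gene_id = genes,
    k_h = unname(k_h), k_t = unname(k_t),
    f_h = unname(f_h), f_t = unname(f_t),
    fold_change = unname(fold),
    p_t_given_h = p$p_t_given_h,
    p_h_given_t = p$p_h_given_t,
    direction = direction,
    expressed = unname(expressed),
    passes = unname(passes),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  rank_dir <- function(dir, decreasing) {
    sub <- records[records$passes & records$direction == dir, , drop = FALSE]
    ord <- order(sub$fold_change, sub$gene_id,
                 decreasing = c(decreasing, FALSE), method = "radix")
    sub <- sub[ord, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  structure(
    list(records = records,
         repressed = rank_dir("repressed", decreasing = FALSE),
         induced = rank_dir("induced", decreasing = TRUE),
         background = sort(genes[expressed]),
         alpha = alpha, min_count = min_count,
         sample_ids = c(haploid$sample_id, tetraploid$sample_id)),
    class = "de_calls"
  )
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("de_calls (%s vs %s): %d expressed, %d repressed, %d induced (alpha=%g)\n",
              x$sample_ids[1], x$sample_ids[2], length(x$background),
              nrow(x$repressed), nrow(x$induced), x$alpha))
  invisible(x)
}

#' Hypergeometric significance of an observed list overlap
#'
#' `P(|A intersect B| >= m)` when `A` and `B` are uniform random subsets of
#' sizes `n_a` and `n_b` drawn from a population of the given size: the upper
#' tail of `Hypergeometric(population, n_a, n_b)`.
#'
#' @param m Observed overlap size.
#' @param n_a,n_b Sizes of the two lists.
#' @param population Size of the common background universe.
#' @return Upper-tail probability.
#' @export
overlap_significance <- function(m, n_a, n_b, population) {
  if (m < 0 || m > min(n_a, n_b)) stop("inconsistent overlap size")
  if (n_a > population || n_b > population) stop("list larger than population")
  if (m == 0) return(1)
  stats::phyper(m - 1, n_a, population - n_a, n_b, lower.tail = FALSE)
}

#' Overlap of the equal top N of two ranked candidate lists
#'
#' Intersects the first `top_n` entries of each replicate's ranked candidate
#' list and attaches the hypergeometric significance of the observed overlap
#' against random sampling from the expressed background.
#'
#' @param list_a,list_b Ranked character vectors of gene ids.
#' @param top_n How many top-ranking candidates to take from each list.
#' @param population Size of the background gene universe.
#' @return An object of class `overlap_selection`.
#' @export
overlap_top_candidates <- function(list_a, list_b, top_n, population) {
  if (top_n <= 0) stop("top_n must be positive")
  if (top_n > min(length(list_a), length(list_b))) {
    stop("top_n exceeds a candidate list length")
  }
  a <- utils::head(list_a, top_n)
  b <- utils::head(list_b, top_n)
  ov <- sort(intersect(a, b))
  structure(
    list(top_n = top_n, candidates_a = a, candidates_b = b,
         overlap = ov, population_size = population,
         p_overlap = overlap_significance(length(ov), top_n, top_n, population)),
    class = "overlap_selection"
  )
}

#' @export
print.overlap_selection <- function(x, ...) {
  cat(sprintf("overlap_selection: top %d of each list, overlap %d, p = %.3g (population %d)\n",
              x$top_n, length(x$overlap), x$p_overlap, x$population_size))
  invisible(x)
}

#' Adaptive choice of the top-N cutoff
#'
#' Evaluates every candidate `top_n` in `grid` and returns the largest one
#' whose overlap remains highly significant (`p_overlap < p_max`), i.e. the
#' most generous cutoff that still guarantees the two replicates agree far
#' beyond chance. The full `(top_n, overlap, p)` curve is retained for the
#' run report. An error is raised when no grid value qualifies, which signals
#' that the replicates are inconsistent.
#'
#' @param list_a,list_b Ranked character vectors of gene ids.
#' @param population Background universe size.
#' @param p_max Maximal admissible overlap p-value (default 1e-10).
#' @param grid Candidate `top_n` values; values exceeding a list length are
#'   ignored.
#' @return An `overlap_selection` with an extra `curve` data frame.
#' @export
select_top_n <- function(list_a, list_b, population, p_max = 1e-10, grid) {
  if (missing(grid) || length(grid) == 0) stop("empty top_n grid")
  grid <- sort(unique(as.integer(grid)))
  grid <- grid[grid >= 1 & grid <= min(length(list_a), length(list_b))]
  if (length(grid) == 0) stop("no usable top_n grid value for these list lengths")
  curve <- do.call(rbind, lapply(grid, function(n) {
    sel <- overlap_top_candidates(list_a, list_b, n, population)
    data.frame(top_n = n, overlap_size = length(sel$overlap),
               p_overlap = sel$p_overlap)
  }))
  ok <- curve$p_overlap < p_max
  if (!any(ok)) {
    stop("replicates inconsistent: no top_n in the grid reaches p < ",
         format(p_max))
  }
  best <- max(curve$top_n[ok])
  sel <- overlap_top_candidates(list_a, list_b, best, population)
  sel$curve <- curve
  sel$p_max <- p_max
  sel
}

#' Cross-replicate fold-change summary
#'
#' For each gene, the arithmetic mean and sample standard deviation of its
#' fold change across the replicate pairs (the quantity plotted when final
#' differential genes are ranked by average fold change with SD error bars).
#' With a single pair the SD is reported as 0 and flagged undefined.
#'
#' @param genes Character vector of gene ids (e.g. the final overlap set).
#' @param pairs List of pairs; each pair is a list with elements `haploid`
#'   and `tetraploid`, both [count_table()] objects containing every gene.
#' @return Data frame with `gene_id`, `mean_fold`, `sd_fold`, `n_pairs`,
#'   `sd_defined`, sorted by ascending mean fold change (ties by gene id).
#' @export
summarize_de <- function(genes, pairs) {
  if (length(pairs) == 0) stop("no replicate pairs supplied")
  folds <- vapply(pairs, function(p) {
    stopifnot(inherits(p$haploid, "count_table"),
              inherits(p$tetraploid, "count_table"))
    miss <- setdiff(genes, names(p$haploid$counts))
    miss <- union(miss, setdiff(genes, names(p$tetraploid$counts)))
    if (length(miss)) stop("gene missing from a pair: ", paste(miss, collapse = ", "))
    fold_change(p$haploid$counts[genes], p$haploid$library_total,
                p$tetraploid$counts[genes], p$tetraploid$library_total)
  }, numeric(length(genes)))
  folds <- matrix(folds, nrow = length(genes))
  mean_fold <- rowMeans(folds)
  sd_fold <- if (length(pairs) > 1) apply(folds, 1, stats::sd) else rep(0, length(genes))
  out <- data.frame(gene_id = genes, mean_fold = mean_fold, sd_fold = sd_fold,
                    n_pairs = length(pairs), sd_defined = length(pairs) > 1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_fold, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
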