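#' Log-likelihood motif matrix
#'
#' A width-by-4 matrix of per-position log-likelihood scores over A, C, G, T.
#' A window's score is the sum of its per-position entries; a score of zero
#' means the window matches the background model exactly as well as the
#' motif, and the maximum score (sum of per-position maxima) is the score of
#' the consensus site and must be positive for the matrix to be usable as a
#' motif.
#'
#' Probability matrices (the usual public distribution format) are converted
#' with `score = log2(p' / background)` where `p'` regularizes each
#' probability with a small pseudo-probability so absent bases get a large
#' negative, finite score; a row equal to the background converts to zeros,
#' preserving the zero-equals-background property.
#'
#' @param scores Numeric matrix, one row per motif position, 4 columns
#'   (A, C, G, T order; column names optional).
#' @param motif_id Identifier for the motif.
#' @param type `"llr"` if `scores` already holds log-likelihoods, `"prob"`
#'   for base probabilities to be converted.
#' @param background Background base frequencies used for conversion
#'   (default uniform 0.25).
#' @param pseudo_prob Pseudo-probability mixed in before conversion
#'   (default 0.01).
#' @return An object of class `ll_matrix` with fields `motif_id`, `width`,
#'   `scores`, `max_score`.
#' @export
ll_matrix <- function(scores, motif_id, type = c("llr", "prob"),
                      background = rep(0.25, 4), pseudo_prob = 0.01) {
  type <- match.arg(type)
  scores <- as.matrix(scores)
  if (ncol(scores) != 4) stop("matrix must have 4 columns (A, C, G, T)")
  if (nrow(scores) < 1) stop("matrix must have at least one position")
  storage.mode(scores) <- "double"
  if (any(is.na(scores))) stop("missing values in matrix")
  if (type == "prob") {
    if (any(scores < 0)) stop("probability matrix with negative entries")
    rs <- rowSums(scores)
    if (any(abs(rs - 1) > 0.02)) stop("probability matrix rows must sum to 1")
    p <- (scores / rs + pseudo_prob) / (1 + 4 * pseudo_prob)
    bg <- (background + pseudo_prob) / (1 + 4 * pseudo_prob)
    scores <- log2(sweep(p, 2, bg, "/"))
  }
  colnames(scores) <- c("A", "C", "G", "T")
  max_score <- sum(apply(scores, 1, max))
  if (max_score <= 0) stop("matrix maximum score must be positive")
  structure(list(motif_id = as.character(motif_id), width = nrow(scores),
                 scores = scores, max_score = max_score),
            class = "ll_matrix")
}

#' @export
print.ll_matrix <- function(x, ...) {
  cat(sprintf("ll_matrix '%s': width %d, max score %.3f (consensus %s)\n",
              x$motif_id, x$width, x$max_score, consensus_site(x)))
  invisible(x)
}

#' Consensus site of a motif matrix
#'
#' The per-position argmax base string: the (a) sequence achieving
#' `max_score`. Ties go to the alphabetically first base.
#'
#' @param matrix An [ll_matrix()].
#' @return Character scalar of length `width`.
#' @export
consensus_site <- function(matrix) {
  stopifnot(inherits(matrix, "ll_matrix"))
  paste(c("A", "C", "G", "T")[apply(matrix$scores, 1, which.max)], collapse = "")
}

#' Read motif matrices from a simple text format
#'
#' One block per motif:
#' \preformatted{
#' >Ste12 type=llr
#' 0.5	-1.2	0.1	-0.3
#' ...
#' }
#' `type` is `llr` (default) or `prob`; probability matrices are converted as
#' described in [ll_matrix()].
#'
#' @param path Path to the motif file.
#' @param background Background base frequencies for `prob` conversion.
#' @return Named list of [ll_matrix()] objects.
#' @export
read_motif_matrices <- function(path, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no motif blocks ('>' headers) in ", path)
  ends <- c(heads[-1] - 1, length(lines))
  mats <- Map(function(h, e) {
    header <- sub("^>\\s*", "", lines[h])
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    type <- "llr"
    ty <- grep("^type=", toks, value = TRUE)
    if (length(ty)) type <- sub("^type=", "", ty[1])
    if (e < h + 1) stop("motif block '", id, "' has no rows")
    rows <- lapply(lines[(h + 1):e], function(ln) {
      as.numeric(strsplit(ln, "[\t ]+")[[1]])
    })
    if (any(vapply(rows, length, 0L) != 4)) {
      stop("motif block '", id, "' has a row without exactly 4 values")
    }
    ll_matrix(do.call(rbind, rows), motif_id = id, type = type,
              background = background)
  }, heads, ends)
  stats::setNames(mats, vapply(mats, `[[`, "", "motif_id"))
}

#' Write motif matrices in the simple text format
#'
#' @param matrices List of [ll_matrix()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_matrices <- function(matrices, path) {
  if (inherits(matrices, "ll_matrix")) matrices <- list(matrices)
  lines <- unlist(lapply(matrices, function(m) {
    c(sprintf(">%s type=llr", m$motif_id),
      apply(m$scores, 1, function(r) paste(format(r, digits = 10), collapse = "\t")))
  }))
  writeLines(lines, path)
  invisible(path)
}

# DNA string -> integer codes 1..4 for ACGT, 5 for anything else (N etc).
# Byte-level lookup keeps genome-scale scans fast.
.dna_code_lut <- local({
  lut <- rep(5L, 128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

.dna_codes <- function(sequence) {
  .dna_code_lut[utf8ToInt(sequence)]
}

# Window scores of a coded sequence under score columns `cols`
# (a width x 5 matrix whose 5th column is the per-position minimum).
.window_scores <- function(codes, cols) {
  W <- nrow(cols)
  nw <- length(codes) - W + 1
  sc <- numeric(nw)
  for (j in seq_len(W)) {
    sc <- sc + cols[j, codes[j:(j + nw - 1)]]
  }
  sc
}

.score_cols <- function(matrix) {
  cbind(matrix$scores, apply(matrix$scores, 1, min))
}

#' Best motif match score in a sequence
#'
#' The maximum, over every window of the matrix width on both strands, of the
#' summed per-position log-likelihood scores. Ambiguous bases (N) score the
#' per-position minimum, a conservative choice that cannot create spurious
#' matches.
#'
#' @param matrix An [ll_matrix()].
#' @param sequence DNA string at least as long as the matrix width.
#' @return The best window score.
#' @export
best_match_score <- function(matrix, sequence) {
  stopifnot(inherits(matrix, "ll_matrix"))
  codes <- .dna_codes(sequence)
  if (length(codes) < matrix$width) {
    stop("sequence shorter than the matrix width")
  }
  cols <- .score_cols(matrix)
  fwd <- .window_scores(codes, cols)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rc <- rev(comp[codes])
  rev_ <- .window_scores(rc, cols)
  max(fwd, rev_)
}

#' Best match scores for many sequences
#'
#' @param matrix An [ll_matrix()].
#' @param sequences Named character vector of DNA strings.
#' @return Named numeric vector of best scores.
#' @export
best_match_scores <- function(matrix, sequences) {
  vapply(sequences, function(s) best_match_score(matrix, s), numeric(1))
}

#' Call motif matches at a fractional score cutoff
#'
#' A promoter matches when its best score reaches `cutoff_fraction` times the
#' matrix maximum score (inclusive).
#'
#' @param scores Named numeric vector of best match scores.
#' @param matrix The [ll_matrix()] the scores came from.
#' @param cutoff_fraction Fraction of `max_score` in `(0, 1]`.
#' @return Named logical vector.
#' @export
call_matches <- function(scores, matrix, cutoff_fraction) {
  stopifnot(inherits(matrix, "ll_matrix"))
  if (cutoff_fraction <= 0 || cutoff_fraction > 1) {
    stop("cutoff_fraction must lie in (0, 1]")
  }
  scores >= cutoff_fraction * matrix$max_score
}

#' Binomial enrichment test for motif matches
#'
#' Upper tail `P(X >= set_matches)` for
#' `X ~ Binomial(set_size, bg_rate)`: the chance of seeing at least the
#' observed number of matching promoters in the gene set if matches occurred
#' at the genome-wide background rate.
#'
#' @param set_matches Matching promoters in the gene set.
#' @param set_size Number of promoters in the gene set.
#' @param bg_rate Background match frequency in `[0, 1]`.
#' @return Upper-tail probability.
#' @export
binomial_motif_test <- function(set_matches, set_size, bg_rate) {
  if (set_matches < 0 || set_matches > set_size) stop("inconsistent match count")
  if (bg_rate < 0 || bg_rate > 1) stop("bg_rate outside [0, 1]")
  if (set_matches == 0) return(1)
  stats::pbinom(set_matches - 1, set_size, bg_rate, lower.tail = FALSE)
}

#' The adaptive cutoff grid
#'
#' Fifteen fractions of the maximum score, 0.30 to 1.00 in steps of 0.05.
#'
#' @return Numeric vector of length 15.
#' @export
cutoff_grid <- function() seq(0.30, 1.00, by = 0.05)

#' Adaptive-cutoff motif enrichment
#'
#' Evaluates every cutoff fraction on the grid: at each cutoff the match
#' frequency in the gene set and in the background is computed and the
#' one-sided binomial enrichment p-value taken with the background frequency
#' as the null rate. The cutoff producing the most significant result is
#' returned (ties broken toward the smaller cutoff), along with the full grid
#' curve for the run report.
#'
#' @param matrix An [ll_matrix()].
#' @param set_scores Named numeric vector: best scores for the gene set's
#'   promoters.
#' @param bg_scores Named numeric vector: best scores for all promoters
#'   (the background universe).
#' @param grid Cutoff fractions (default [cutoff_grid()]).
#' @return An object of class `motif_enrichment` with the optimal cutoff's
#'   statistics and a `curve` data frame.
#' @export
optimize_cutoff <- function(matrix, set_scores, bg_scores, grid = cutoff_grid()) {
  stopifnot(inherits(matrix, "ll_matrix"))
  if (length(set_scores) == 0 || length(bg_scores) == 0) {
    stop("empty score map")
  }
  set_size <- length(set_scores)
  bg_size <- length(bg_scores)
  curve <- do.call(rbind, lapply(grid, function(cf) {
    sm <- sum(call_matches(set_scores, matrix, cf))
    bm <- sum(call_matches(bg_scores, matrix, cf))
    set_freq <- sm / set_size
    bg_freq <- bm / bg_size
    data.frame(cutoff_fraction = cf,
               set_matches = sm, set_size = set_size, set_freq = set_freq,
               bg_matches = bm, bg_size = bg_size, bg_freq = bg_freq,
               fold = if (bg_freq > 0) set_freq / bg_freq else
                 if (set_freq > 0) Inf else NA_real_,
               p_binomial = binomial_motif_test(sm, set_size, bg_freq))
  }))
  if (all(curve$set_matches == 0 & curve$bg_matches == 0)) {
    stop("no motif matches at any cutoff: nothing to test")
  }
  best <- which.min(curve$p_binomial)  # first minimum = smallest cutoff on ties
  structure(c(list(motif_id = matrix$motif_id),
              as.list(curve[best, , drop = FALSE]),
              list(curve = curve)),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("motif_enrichment '%s': cutoff %.2f, set %d/%d (%.1f%%), bg %d/%d (%.1f%%), fold %.2f, p = %.3g\n",
              x$motif_id, x$cutoff_fraction, x$set_matches, x$set_size,
              100 * x$set_freq, x$bg_matches, x$bg_size, 100 * x$bg_freq,
              x$fold, x$p_binomial))
  invisible(x)
}

#' Tabulate motif enrichment results
#'
#' @param results List of `motif_enrichment` objects (or a single one).
#' @return One data frame row per motif.
#' @export
motif_enrichment_table <- function(results) {
  if (inherits(results, "motif_enrichment")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(motif_id = r$motif_id, cutoff_fraction = r$cutoff_fraction,
               set_matches = r$set_matches, set_size = r$set_size,
               set_freq = r$set_freq, bg_matches = r$bg_matches,
               bg_size = r$bg_size, bg_freq = r$bg_freq, fold = r$fold,
               p_binomial = r$p_binomial, stringsAsFactors = FALSE)
  }))
}

#' Filter motif enrichment results
#'
#' Retains motifs most likely to be biologically relevant to the gene list:
#' enrichment p-value at most 0.005, motif present in at least 25% of the
#' set's promoters, and a set-over-background frequency fold change of at
#' least 1.5. All three bounds are inclusive.
#'
#' @param results List of `motif_enrichment` objects or a data frame from
#'   [motif_enrichment_table()].
#' @param p_max,min_set_freq,min_fold The three thresholds.
#' @return The filtered data frame.
#' @export
filter_motif_results <- function(results, p_max = 0.005, min_set_freq = 0.25,
                                 min_fold = 1.5) {
  tab <- if (is.data.frame(results)) results else motif_enrichment_table(results)
  if (is.null(tab) || nrow(tab) == 0) return(tab)
  keep <- tab$p_binomial <= p_max & tab$set_freq >= min_set_freq &
    !is.na(tab$fold) & tab$fold >= min_fold
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
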