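# Independent oracles, deliberately written as direct summations/enumerations
# and kept free of the package's own numerics.

# P(X <= k), X ~ Binomial(n, f), by explicit log-space summation of the pmf.
exact_binomial_cmf <- function(k, n, f) {
  if (k >= n) return(1)
  if (f == 0) return(1)
  if (f == 1) return(as.numeric(k >= n))
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(f) + (n - i) * log1p(-f)))
}

# P(X >= a), X ~ Hypergeometric(N, K, n), by explicit summation.
exact_hyper_tail <- function(a, n, K, N) {
  if (a == 0) return(1)
  i <- a:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# P(|A intersect B| >= m) for uniform random subsets of sizes n_a, n_b from
# 1..N, by exhaustive enumeration of B against a fixed A (exchangeability).
enum_overlap_p <- function(m, n_a, n_b, N) {
  a_set <- seq_len(n_a)
  combos <- utils::combn(N, n_b)
  mean(apply(combos, 2, function(b) length(intersect(a_set, b)) >= m))
}

# Best PWM match by brute-force window enumeration on both strands.
scan_oracle <- function(mat, sequence) {
  bases <- c("A", "C", "G", "T")
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    best <- -Inf
    W <- nrow(mat$scores)
    if (length(ch) < W) stop("short")
    for (i in 1:(length(ch) - W + 1)) {
      sc <- 0
      for (j in 1:W) {
        b <- match(ch[i + j - 1], bases)
        sc <- sc + if (is.na(b)) min(mat$scores[j, ]) else mat$scores[j, b]
      }
      best <- max(best, sc)
    }
    best
  }
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(toupper(sequence), "")[[1]])),
              collapse = "")
  max(score_one(toupper(sequence)), score_one(rc))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
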