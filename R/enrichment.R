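#' Gene-set collection over a declared background
#'
#' Term assignments are consumed as flat, pre-propagated gene sets (as
#' exported by term-finder tools); ontology DAG propagation is out of scope.
#' Genes outside the background are dropped from every set at construction.
#'
#' @param sets Named list of character vectors (term id -> gene ids).
#' @param background Character vector: the expressed-gene universe.
#' @param term_names Optional named character vector of human-readable term
#'   names (defaults to the term ids).
#' @param namespace Optional named character vector of namespace labels
#'   (e.g. "cellular_component").
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background, term_names = NULL,
                                namespace = NULL) {
  if (length(background) == 0) stop("empty background")
  if (anyDuplicated(names(sets))) stop("duplicate term ids")
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("sets must be a named list")
  }
  background <- sort(unique(background))
  sets <- lapply(sets, function(g) sort(intersect(unique(g), background)))
  ids <- names(sets)
  tn <- stats::setNames(ids, ids)
  if (!is.null(term_names)) tn[names(term_names)] <- term_names
  ns <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(namespace)) ns[names(namespace)] <- namespace
  structure(list(sets = sets, background = background,
                 term_names = tn, namespace = ns),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms over a background of %d genes\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @param background Background gene universe for the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1)
  descs <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  gene_set_collection(sets, background, term_names = descs)
}

#' Read gene sets from a two-column TSV
#'
#' Columns `term_id` and `gene_id`, one gene membership per row.
#'
#' @param path Path to the TSV (with a header row).
#' @param background Background gene universe.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets_tsv <- function(path, background) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df))) {
    stop("gene-set TSV needs columns term_id and gene_id")
  }
  gene_set_collection(split(df$gene_id, df$term_id), background)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= a)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `a` genes of an annotated class of size `K` when sampling `n` genes
#' without replacement from a universe of `N`. This single kernel drives both
#' the replicate-overlap test and gene-set enrichment. Computed in log space
#' via [stats::phyper()], stable up to genome-scale `N`.
#'
#' @param a Observed class count in the query.
#' @param n Query size.
#' @param K Class size in the background.
#' @param N Background size.
#' @return Upper-tail probability, vectorized over `a`.
#' @export
hypergeometric_tail <- function(a, n, K, N) {
  if (any(n > N) || any(K > N)) stop("inconsistent margins: n, K must not exceed N")
  if (any(a < 0) || any(a > pmin(n, K))) stop("inconsistent margins: a outside [0, min(n, K)]")
  ifelse(a == 0, 1, stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE))
}

#' Gene-set enrichment of a query list
#'
#' One row per term with at least one query member, carrying the cluster
#' frequency `a/n`, the background frequency `K/N`, the raw hypergeometric
#' upper-tail p-value and a Bonferroni-adjusted value (`p_raw` times the
#' number of terms in the collection, capped at 1). Raw p-values are the
#' primary statistic; Bonferroni is reported alongside, never substituted.
#' Query genes outside the background are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @return Data frame sorted by ascending `p_raw` (ties by term id).
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped: ",
            paste(utils::head(outside, 5), collapse = ", "))
    query <- setdiff(query, outside)
  }
  N <- length(collection$background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    a <- length(intersect(query, set))
    if (a == 0) return(NULL)
    K <- length(set)
    data.frame(term_id = id,
               term_name = unname(collection$term_names[[id]]),
               namespace = unname(collection$namespace[[id]]),
               cluster_count = a, query_size = n,
               background_count = K, background_size = N,
               cluster_pct = 100 * a / n,
               background_pct = 100 * K / N,
               p_raw = hypergeometric_tail(a, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), cluster_count = integer(0),
                      query_size = integer(0), background_count = integer(0),
                      background_size = integer(0), cluster_pct = numeric(0),
                      background_pct = numeric(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0))
    return(out)
  }
  out$p_bonferroni <- pmin(1, out$p_raw * length(collection$sets))
  out <- out[order(out$p_raw, out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
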