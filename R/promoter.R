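#' Promoter region of a gene
#'
#' The scanned promoter extends 50 bp downstream of the annotated coding
#' start (in the gene's reading direction, coding start included) and
#' upstream of the coding start to the nearest edge of the closest annotated
#' feature lying strictly upstream — any feature type counts (ORF, Ty, tRNA,
#' ...) — or 5 kb, whichever is nearer. Features that overlap the coding
#' start are skipped when looking for that upstream boundary. Minus-strand
#' genes are mirrored, and the region is clipped at the contig edges.
#'
#' @param gene_id Id of a feature of type `"gene"` in the annotation.
#' @param annotation Feature table (see [read_annotation()]).
#' @param contig_lengths Named vector of contig lengths.
#' @param max_upstream Upstream cap in bp (default 5000).
#' @param downstream Downstream extent in bp (default 50).
#' @return One-row data frame of class `promoter_region`: `gene_id`,
#'   `contig`, `start`, `end` (1-based closed, plus-strand coordinates),
#'   `strand`, `upstream_extent`, `downstream_extent`.
#' @export
extract_promoter <- function(gene_id, annotation, contig_lengths,
                             max_upstream = 5000, downstream = 50) {
  annotation <- validate_annotation(annotation)
  i <- which(annotation$gene_id == gene_id)
  if (length(i) != 1) stop("gene absent from annotation: ", gene_id)
  g <- annotation[i, ]
  if (!g$seqid %in% names(contig_lengths)) stop("unknown contig: ", g$seqid)
  L <- as.integer(contig_lengths[[g$seqid]])
  same <- annotation[-i, , drop = FALSE]
  same <- same[same$seqid == g$seqid, , drop = FALSE]
  if (g$strand == "+") {
    cs <- g$start
    # candidates lie entirely upstream; anything spanning cs is thereby skipped
    cand <- same$end[same$end < cs]
    up <- if (length(cand)) min(max_upstream, cs - max(cand)) else max_upstream
    up <- min(up, cs - 1)
    dn <- min(downstream, L - cs + 1)
    start <- cs - up
    end <- cs + dn - 1
  } else {
    cs <- g$end
    cand <- same$start[same$start > cs]
    up <- if (length(cand)) min(max_upstream, min(cand) - cs) else max_upstream
    up <- min(up, L - cs)
    dn <- min(downstream, cs)
    start <- cs - dn + 1
    end <- cs + up
  }
  if (end < start || (up <= 0 && dn <= 0)) {
    stop("zero-length promoter after clipping for gene ", gene_id)
  }
  structure(data.frame(gene_id = gene_id, contig = g$seqid,
                       start = start, end = end, strand = g$strand,
                       upstream_extent = up, downstream_extent = dn,
                       stringsAsFactors = FALSE),
            class = c("promoter_region", "data.frame"))
}

#' Promoters for all genes in an annotation
#'
#' Applies [extract_promoter()] to every feature of type `"gene"`. Genes
#' whose promoter is empty after clipping are dropped with a warning; the
#' remaining genes define the background universe for motif enrichment
#' ("all genes" = all genes with a valid promoter).
#'
#' @param annotation Feature table.
#' @param contig_lengths Named vector of contig lengths.
#' @param genes Optional subset of gene ids (default: all type-`gene`
#'   features).
#' @inheritParams extract_promoter
#' @return Data frame, one row per gene, in annotation order.
#' @export
extract_promoters <- function(annotation, contig_lengths, genes = NULL,
                              max_upstream = 5000, downstream = 50) {
  annotation <- validate_annotation(annotation)
  all_genes <- annotation$gene_id[annotation$type == "gene"]
  if (is.null(genes)) genes <- all_genes
  missing <- setdiff(genes, all_genes)
  if (length(missing)) {
    stop("gene absent from annotation: ", paste(missing, collapse = ", "))
  }
  g <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  bad_contig <- setdiff(unique(g$seqid), names(contig_lengths))
  if (length(bad_contig)) stop("unknown contig: ", paste(bad_contig, collapse = ", "))
  L <- as.integer(contig_lengths[g$seqid])
  cs <- ifelse(g$strand == "+", g$start, g$end)
  up <- integer(nrow(g))
  # vectorized boundary search on sorted feature edges; a gene's own interval
  # never qualifies (its far edge lies on the wrong side of the coding
  # start), and features spanning the coding start are excluded by the same
  # strict inequality that defines "lying strictly upstream"
  for (ctg in unique(g$seqid)) {
    feats <- annotation[annotation$seqid == ctg, , drop = FALSE]
    ends <- sort(feats$end)
    starts <- sort(feats$start)
    sel <- which(g$seqid == ctg)
    plus <- sel[g$strand[sel] == "+"]
    if (length(plus)) {
      idx <- findInterval(cs[plus] - 1L, ends)  # rightmost end < cs
      nearest <- ifelse(idx >= 1, ends[pmax(idx, 1L)], NA_integer_)
      up[plus] <- ifelse(is.na(nearest), max_upstream,
                         pmin(max_upstream, cs[plus] - nearest))
    }
    minus <- sel[g$strand[sel] == "-"]
    if (length(minus)) {
      idx <- findInterval(cs[minus], starts) + 1L  # leftmost start > cs
      nearest <- ifelse(idx <= length(starts),
                        starts[pmin(idx, length(starts))], NA_integer_)
      up[minus] <- ifelse(is.na(nearest), max_upstream,
                          pmin(max_upstream, nearest - cs[minus]))
    }
  }
  plus <- g$strand == "+"
  up <- as.integer(ifelse(plus, pmin(up, cs - 1L), pmin(up, L - cs)))
  dn <- as.integer(ifelse(plus, pmin(downstream, L - cs + 1L),
                          pmin(downstream, cs)))
  start <- ifelse(plus, cs - up, cs - dn + 1L)
  end <- ifelse(plus, cs + dn - 1L, cs + up)
  out <- data.frame(gene_id = genes, contig = g$seqid,
                    start = as.integer(start), end = as.integer(end),
                    strand = g$strand, upstream_extent = up,
                    downstream_extent = dn, stringsAsFactors = FALSE)
  valid <- out$end >= out$start &
    (out$upstream_extent > 0 | out$downstream_extent > 0)
  if (any(!valid)) {
    warning(sum(!valid), " gene(s) without a valid promoter dropped: ",
            paste(utils::head(out$gene_id[!valid], 5), collapse = ", "))
    out <- out[valid, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Promoter sequences in gene orientation
#'
#' Extracts each promoter's sequence from the genome and reverse-complements
#' minus-strand promoters, so every returned string reads in the gene's
#' direction. (Scanning is strand-symmetric, so orientation only matters for
#' bookkeeping.)
#'
#' @param promoters Data frame from [extract_promoters()].
#' @param genome Named character vector of contig sequences.
#' @return Named character vector of promoter sequences.
#' @export
promoter_sequences <- function(promoters, genome) {
  seqs <- vapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    if (!p$contig %in% names(genome)) stop("unknown contig: ", p$contig)
    s <- substr(genome[[p$contig]], p$start, p$end)
    if (p$strand == "-") s <- reverse_complement(s)
    s
  }, character(1))
  stats::setNames(seqs, promoters$gene_id)
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string (A/C/G/T/N, case preserved as upper).
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  vapply(sequence, function(s) {
    chartr("ACGTacgt", "TGCAtgca", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}
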