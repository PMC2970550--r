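#' Read a GFF3 annotation into a feature table
#'
#' Features are returned as a data frame with 1-based closed coordinates, the
#' convention of GFF3 and of the rest of this package. Every feature type is
#' retained: when promoter boundaries are resolved, any annotated feature
#' (ORF, Ty element, tRNA, ...) can serve as the first upstream feature.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `seqid`, `type`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, nrow(md))
  if ("Name" %in% names(md)) {
    ids <- ifelse(is.na(ids) | !nzchar(ids), as.character(md$Name), ids)
  }
  missing_id <- is.na(ids) | !nzchar(ids)
  ids[missing_id] <- sprintf("feature_%04d", which(missing_id))
  ann <- data.frame(
    seqid = as.character(md$seqnames),
    type = as.character(md$type),
    start = md$start,
    end = md$end,
    strand = as.character(md$strand),
    gene_id = ids,
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

#' Write a feature table as GFF3
#'
#' Deterministic formatting: identical inputs produce byte-identical files.
#'
#' @param annotation Feature data frame as returned by [read_annotation()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths, emitted as
#'   `##sequence-region` directives.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, contig_lengths = NULL) {
  annotation <- validate_annotation(annotation)
  lines <- "##gff-version 3"
  if (!is.null(contig_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(contig_lengths), as.integer(contig_lengths)))
  }
  src <- if ("source" %in% names(annotation)) annotation$source else "ploidyseq"
  lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                            annotation$seqid, src, annotation$type,
                            as.integer(annotation$start),
                            as.integer(annotation$end),
                            annotation$strand, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

validate_annotation <- function(annotation) {
  need <- c("seqid", "type", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (any(annotation$start > annotation$end)) stop("malformed feature interval")
  if (any(annotation$start < 1)) stop("feature coordinates must be 1-based positive")
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  if (anyDuplicated(annotation$gene_id)) stop("duplicate feature ids in annotation")
  annotation
}

#' Read alignment hits from a BED-like TSV
#'
#' One row per genomic hit, several rows per multiply-mapped read. Columns:
#' `read_id`, `contig`, `start`, `end`, `strand`, with 1-based closed
#' coordinates and `start < end`. A converter from SAM would populate exactly
#' these columns (read name, reference, leftmost/rightmost aligned position,
#' strand flag); SAM/BAM parsing itself is out of scope here.
#'
#' @param path Path to the TSV (with a header row).
#' @return Data frame of hits.
#' @export
read_alignment_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$start >= df$end)) stop("malformed hit interval (need start < end)")
  df
}

#' Fractional counting of multiply-mapped reads
#'
#' A read with `n` genomic hits contributes a weight of `1/n` to each feature
#' containing one of its hits; a uniquely mapped read contributes 1. A hit is
#' assigned to the feature containing its midpoint, irrespective of strand
#' (expression is counted over reads on both strands of the ORF). When
#' overlapping features both contain a midpoint the hit goes to the
#' lexicographically smallest feature id, so each hit is counted at most once
#' and total weight per read never exceeds 1.
#'
#' @param hits Data frame of alignment hits as from [read_alignment_hits()].
#' @param annotation Feature table (see [read_annotation()]).
#' @param sample_id,ploidy Labels for the resulting table.
#' @return A [count_table()] over all features in `annotation`, with
#'   `library_total` equal to the number of distinct reads.
#' @export
weight_multimapped <- function(hits, annotation, sample_id = "sample",
                               ploidy = NA_character_) {
  annotation <- validate_annotation(annotation)
  need <- c("read_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  counts <- stats::setNames(numeric(nrow(annotation)), annotation$gene_id)
  n_reads <- length(unique(hits$read_id))
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$contig), unique(annotation$seqid))
    if (length(unknown)) stop("hit on unknown contig: ", paste(unknown, collapse = ", "))
    if (any(hits$start >= hits$end)) stop("malformed hit interval (need start < end)")
    w <- 1 / table(hits$read_id)[hits$read_id]
    mid <- (hits$start + hits$end) %/% 2
    feat <- GenomicRanges::GRanges(
      annotation$seqid,
      IRanges::IRanges(annotation$start, annotation$end)
    )
    pts <- GenomicRanges::GRanges(hits$contig, IRanges::IRanges(mid, mid))
    ov <- GenomicRanges::findOverlaps(pts, feat)
    if (length(ov) > 0) {
      hit_idx <- S4Vectors::queryHits(ov)
      feat_id <- annotation$gene_id[S4Vectors::subjectHits(ov)]
      # one feature per hit: lexicographically smallest containing feature id
      ord <- order(hit_idx, feat_id)
      keep <- !duplicated(hit_idx[ord])
      hit_idx <- hit_idx[ord][keep]
      feat_id <- feat_id[ord][keep]
      inc <- tapply(as.numeric(w)[hit_idx], feat_id, sum)
      counts[names(inc)] <- counts[names(inc)] + inc
    }
  }
  count_table(counts, sample_id = sample_id,
              library_total = max(n_reads, 1), ploidy = ploidy)
}
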