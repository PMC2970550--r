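# Small in-code fixtures shared across test files.

toy_table <- function(counts, sample_id = "s", total = NULL, ploidy = NA) {
  count_table(counts, sample_id = sample_id, library_total = total,
              ploidy = ploidy)
}

# A linear toy annotation: features at given starts/ends on one contig.
toy_annotation <- function(start, end, strand = "+", type = "gene",
                           gene_id = NULL, seqid = "chrT") {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- sprintf("t%03d", seq_len(n))
  data.frame(seqid = seqid, type = rep(type, length.out = n),
             start = start, end = end,
             strand = rep(strand, length.out = n),
             gene_id = gene_id, stringsAsFactors = FALSE)
}

# Informative 8-mer motif: +2 for the consensus base, -1 otherwise.
toy_motif <- function(id = "TOY", consensus = "ACGTACGT") {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  m <- matrix(-1, nrow = length(idx), ncol = 4)
  m[cbind(seq_along(idx), idx)] <- 2
  ll_matrix(m, motif_id = id)
}
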