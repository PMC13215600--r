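# Gene model container: one transcript at a time, exons kept in transcription
# order (genomic coordinates descend along the table for minus-strand genes).

#' Construct a gene model
#'
#' A minimal single-transcript gene model: ordered exons, strand, and the CDS
#' start expressed as a transcript offset. All genomic coordinates are 1-based
#' and closed.
#'
#' @param contig contig/chromosome name.
#' @param gene_name,transcript_label gene and transcript identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons tibble with columns `start`, `end` (genomic, 1-based closed),
#'   one row per exon in transcription order.
#' @param cds_tx_start 1-based position of the first coding base in the
#'   spliced transcript.
#' @param cds_length CDS length in nucleotides (including the stop codon).
#' @return an object of class `cx_gene_model`.
#' @export
gene_model <- function(contig, gene_name, transcript_label, strand, exons,
                       cds_tx_start, cds_length) {
  cx_assert(strand %in% c("+", "-"), "`strand` must be '+' or '-'")
  exons <- as_tibble(exons)
  cx_assert(all(c("start", "end") %in% names(exons)) && nrow(exons) >= 1,
            "`exons` needs columns start, end")
  cx_assert(all(exons$end >= exons$start), "exon end < start")
  if (nrow(exons) > 1) {
    ord <- if (strand == "+") diff(exons$start) > 0 else diff(exons$start) < 0
    cx_assert(all(ord), "exons must be in transcription order for the strand")
  }
  exons$exon <- seq_len(nrow(exons))
  tx_len <- sum(exons$end - exons$start + 1)
  cx_assert(cds_tx_start >= 1 && cds_tx_start + cds_length - 1 <= tx_len,
            "CDS outside transcript")
  structure(
    list(contig = contig, gene_name = gene_name,
         transcript_label = transcript_label, strand = strand,
         exons = select(exons, "exon", "start", "end"),
         cds_tx_start = as.integer(cds_tx_start),
         cds_length = as.integer(cds_length)),
    class = "cx_gene_model")
}

#' @method print cx_gene_model
#' @export
print.cx_gene_model <- function(x, ...) {
  cat(sprintf("<cx_gene_model> %s / %s (%s strand), %d exons on %s\n",
              x$gene_name, x$transcript_label, x$strand,
              nrow(x$exons), x$contig))
  cat(sprintf("  span %d-%d, CDS tx offset %d, CDS length %d\n",
              min(x$exons$start), max(x$exons$end),
              x$cds_tx_start, x$cds_length))
  invisible(x)
}

exon_lengths <- function(gm) gm$exons$end - gm$exons$start + 1L

transcript_length <- function(gm) sum(exon_lengths(gm))

# introns in transcription order; intron i sits between exon i and exon i+1
gene_introns <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2) return(tibble(intron = integer(), start = integer(),
                                  end = integer()))
  a <- ex[-nrow(ex), ]; b <- ex[-1, ]
  tibble(intron = seq_len(nrow(ex) - 1L),
         start = pmin(a$end, b$end) + 1L,
         end = pmax(a$start, b$start) - 1L)
}

gene_span <- function(gm) c(start = min(gm$exons$start), end = max(gm$exons$end))

# transcript coordinate (1-based) of a genomic position; NA if intronic
genomic_to_tx <- function(gm, pos) {
  ex <- gm$exons
  cum <- cumsum(exon_lengths(gm))
  offs <- c(0L, cum[-length(cum)])
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      within <- if (gm$strand == "+") pos - ex$start[i] else ex$end[i] - pos
      return(offs[i] + within + 1L)
    }
  }
  NA_integer_
}

# cumulative transcript position of the last base of each exon
exon_tx_ends <- function(gm) cumsum(exon_lengths(gm))
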