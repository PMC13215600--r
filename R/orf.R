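# Transcript assembly and translation: splice exon blocks into mRNA,
# translate from the annotated start, characterise premature termination
# introduced by a cryptic-exon insertion.

# splice genomic blocks (transcription order) into a coding-strand sequence
splice_blocks <- function(genome, blocks, strand) {
  cx_assert(all(blocks$start >= 1) && all(blocks$end <= nchar(genome)),
            "block interval outside the reference")
  pieces <- substring(genome, blocks$start, blocks$end)
  if (strand == "+") paste(pieces, collapse = "")
  else paste(revcomp(pieces), collapse = "")
}

#' Splice an mRNA from an isoform block structure
#'
#' Concatenates exonic sequence in transcription order; minus-strand genes
#' are reverse-complemented block-wise so the result reads 5'->3' on the
#' coding strand.
#'
#' @param reference named character vector (the contig).
#' @param blocks tibble of genomic block intervals (`start`, `end`) in
#'   transcription order (genomic coordinates descend for minus-strand genes).
#' @param strand `"+"` or `"-"`.
#' @return the spliced mRNA sequence (character scalar).
#' @export
splice_mrna <- function(reference, blocks, strand = "+") {
  splice_blocks(unname(reference[[1]]), blocks, strand)
}

#' Translate a CDS and characterise termination
#'
#' Standard-code translation from `cds_offset` to the first stop codon. When
#' no stop is reached before the end of the sequence, `ptc` is `FALSE` and
#' `no_stop` is flagged. If the transcript's last exon-exon junction is
#' supplied, a stop ending more than 55 nt upstream of it flags the
#' transcript as a nonsense-mediated decay candidate (advisory heuristic).
#'
#' @param mrna mRNA sequence (A/C/G/T).
#' @param cds_offset 0-based offset of the first coding base.
#' @param canonical_stop_tx optional 1-based transcript position where the
#'   canonical stop codon begins; a stop strictly upstream marks `ptc`.
#' @param last_junction_tx optional 1-based transcript position of the last
#'   exon-exon junction (last base of the penultimate exon).
#' @return a `coding_prediction` list: `peptide`, `stop_codon`,
#'   `stop_codon_index` (1-based codon number), `ptc`, `no_stop`,
#'   `nmd_candidate`, `stop_tx_start`.
#' @examples
#' translate_cds("ATGAAATAG") # peptide "MK", stop TAG at codon 3
#' @export
translate_cds <- function(mrna, cds_offset = 0L, canonical_stop_tx = NULL,
                          last_junction_tx = NULL) {
  cx_assert(cds_offset >= 0 && cds_offset < nchar(mrna),
            "`cds_offset` must fall inside the sequence")
  cds <- substring(mrna, cds_offset + 1L, nchar(mrna))
  n_codon <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  bad <- grep("[^ACGT]", codons)
  code <- Biostrings::GENETIC_CODE
  aa <- character(n_codon)
  stop_at <- NA_integer_
  for (i in seq_len(n_codon)) {
    if (i %in% bad)
      rlang::abort(sprintf("non-ACGT base in codon %d ('%s')", i, codons[i]),
                   class = "crypticex_error")
    aa[i] <- code[[codons[i]]]
    if (aa[i] == "*") { stop_at <- i; break }
  }
  if (is.na(stop_at)) {
    peptide <- paste(aa[seq_len(n_codon)], collapse = "")
    pred <- list(peptide = peptide, stop_codon = NA_character_,
                 stop_codon_index = NA_integer_, ptc = FALSE, no_stop = TRUE,
                 nmd_candidate = FALSE, stop_tx_start = NA_integer_)
    return(structure(pred, class = "coding_prediction"))
  }
  peptide <- paste(aa[seq_len(stop_at - 1L)], collapse = "")
  stop_tx_start <- cds_offset + (stop_at - 1L) * 3L + 1L
  ptc <- if (!is.null(canonical_stop_tx)) stop_tx_start < canonical_stop_tx
         else FALSE
  nmd <- FALSE
  if (!is.null(last_junction_tx)) {
    stop_tx_end <- stop_tx_start + 2L
    nmd <- (last_junction_tx - stop_tx_end) > 55L
  }
  structure(list(peptide = peptide, stop_codon = codons[stop_at],
                 stop_codon_index = stop_at, ptc = ptc, no_stop = FALSE,
                 nmd_candidate = nmd, stop_tx_start = stop_tx_start),
            class = "coding_prediction")
}

#' @method print coding_prediction
#' @export
print.coding_prediction <- function(x, ...) {
  if (x$no_stop) {
    cat(sprintf("<coding_prediction> %d aa, no stop codon reached\n",
                nchar(x$peptide)))
  } else {
    cat(sprintf("<coding_prediction> %d aa, stop %s at codon %d%s%s\n",
                nchar(x$peptide), x$stop_codon, x$stop_codon_index,
                if (x$ptc) " [premature]" else "",
                if (x$nmd_candidate) " [NMD candidate]" else ""))
  }
  invisible(x)
}

#' Amino acids translated after a cryptic insertion before termination
#'
#' Compares a canonical and a novel isoform of the same gene: translates the
#' novel transcript and counts the complete codons from the first codon
#' overlapping the first novel block up to (and excluding) the stop codon.
#' Returns `NA` if translation reaches the canonical stop position without a
#' premature stop. Insertions whose length is not a multiple of 3 are
#' reported as frameshifts (attribute `frameshift`), with the count still
#' computed to the encountered stop.
#'
#' @param canonical a [gene_model()]-consistent block tibble (the canonical
#'   exons, transcription order) or `isoform_structure`.
#' @param novel an `isoform_structure` (from [map_consensus()]) or block
#'   tibble containing at least one novel block.
#' @param reference named character vector (the contig).
#' @param gene a [gene_model()].
#' @return integer count (possibly 0) or `NA`; attribute `frameshift`.
#' @export
ptc_after_insertion <- function(canonical, novel, reference, gene) {
  can_blocks <- as_blocks(canonical)
  if (inherits(novel, "isoform_structure")) {
    cx_assert(nrow(novel$novel_blocks) >= 1,
              "`novel` must contain at least one novel block")
    nov_blocks <- graft_structure(gene, novel)
    first_novel <- first_in_tx_order(novel$novel_blocks, gene$strand)
  } else {
    nov_blocks <- as_blocks(novel)
    keys <- paste(can_blocks$start, can_blocks$end)
    extra <- nov_blocks[!(paste(nov_blocks$start, nov_blocks$end) %in% keys), ]
    cx_assert(nrow(extra) >= 1, "`novel` must contain at least one novel block")
    first_novel <- first_in_tx_order(extra, gene$strand)
  }
  genome <- unname(reference[[1]])
  mrna_nov <- splice_blocks(genome, nov_blocks, gene$strand)
  mrna_can <- splice_blocks(genome, can_blocks, gene$strand)
  # transcript coordinate of the first base of the first novel block
  tx_pos <- block_tx_position(nov_blocks, first_novel, gene$strand)
  ins_len <- sum(nov_blocks$end - nov_blocks$start + 1L) -
    sum(can_blocks$end - can_blocks$start + 1L)
  frameshift <- (ins_len %% 3L) != 0L
  cds_offset <- gene$cds_tx_start - 1L
  cx_assert(tx_pos > cds_offset, "novel block lies upstream of the CDS start")
  pred <- translate_cds(mrna_nov, cds_offset)
  if (pred$no_stop) return(structure(NA_integer_, frameshift = frameshift))
  # first codon overlapping the novel block (1-based codon index in the CDS)
  first_codon <- (tx_pos - cds_offset - 1L) %/% 3L + 1L
  if (pred$stop_codon_index < first_codon)
    return(structure(NA_integer_, frameshift = frameshift))
  # is the stop premature relative to the canonical protein's stop?
  can_pred <- translate_cds(mrna_can, cds_offset)
  if (!can_pred$no_stop && !frameshift) {
    canonical_stop_in_novel <- can_pred$stop_codon_index + ins_len %/% 3L
    if (pred$stop_codon_index >= canonical_stop_in_novel)
      return(structure(NA_integer_, frameshift = frameshift))
  }
  structure(as.integer(pred$stop_codon_index - first_codon),
            frameshift = frameshift)
}

as_blocks <- function(x) {
  if (inherits(x, "cx_gene_model")) return(x$exons[, c("start", "end")])
  if (inherits(x, "isoform_structure"))
    rlang::abort("pass the gene model or a block tibble as `canonical`",
                 class = "crypticex_error")
  as_tibble(x)[, c("start", "end")]
}

# reconstruct transcription-ordered blocks from an isoform_structure
isoform_blocks <- function(structure, gene) {
  blocks <- bind_rows(
    structure$exon_intervals[, c("start", "end")],
    structure$novel_blocks[, c("start", "end")])
  if (gene$strand == "+") arrange(blocks, .data$start)
  else arrange(blocks, -.data$start)
}

first_in_tx_order <- function(blocks, strand) {
  b <- if (strand == "+") arrange(blocks, .data$start)
       else arrange(blocks, -.data$start)
  b[1, ]
}

#' Graft a mapped isoform structure onto the full gene model
#'
#' A consensus mapped with [map_consensus()] only covers the amplified region
#' (partial flanking exons). For translation, the novel blocks and boundary
#' extensions it reports are grafted onto the complete annotated exon chain:
#' extended boundaries widen the corresponding exon, novel blocks are inserted
#' at their genomic position in transcription order.
#'
#' @param gene a [gene_model()].
#' @param structure an `isoform_structure`.
#' @return block tibble (`start`, `end`) in transcription order.
#' @export
graft_structure <- function(gene, structure) {
  ex <- gene$exons[, c("start", "end")]
  if (nrow(structure$extended_boundaries)) {
    for (i in seq_len(nrow(structure$extended_boundaries))) {
      b <- structure$extended_boundaries[i, ]
      widen_low <- (gene$strand == "+") == (b$side == "5prime")
      if (widen_low) ex$start[b$exon] <- ex$start[b$exon] - b$shift
      else ex$end[b$exon] <- ex$end[b$exon] + b$shift
    }
  }
  blocks <- bind_rows(ex, structure$novel_blocks[, c("start", "end")])
  if (gene$strand == "+") arrange(blocks, .data$start)
  else arrange(blocks, -.data$start)
}

# transcript position (1-based) of the first (coding-strand) base of `block`
block_tx_position <- function(blocks, block, strand) {
  pos <- 0L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$start == block$start && b$end == block$end) return(pos + 1L)
    pos <- pos + (b$end - b$start + 1L)
  }
  rlang::abort("novel block not found in the isoform", class = "crypticex_error")
}
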