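#' HGVS intronic name for a variant
#'
#' Renders the `c.X+Y` / `c.X-Y` intronic nomenclature for a variant lying
#' strictly inside an intron of the transcript: the anchor is the cDNA
#' (coding) coordinate of the flanking exonic base on the nearer side, the
#' offset the distance in bp to the variant; the `+` form is used when the
#' upstream exon boundary is nearer or equidistant. Alleles are reported on
#' the coding strand.
#'
#' @param variant one-row tibble or list with `pos`, `ref`, `alt`
#'   (plus-strand alleles, as in a VCF).
#' @param gene a [gene_model()].
#' @param transcript_label label used in printing (defaults to the gene
#'   model's).
#' @return a list of class `cx_hgvs` with fields `transcript_label`,
#'   `anchor_cdna_pos`, `offset` (signed), `ref`, `alt`, `rendered`.
#' @examples
#' toy <- build_toy_locus(locus_spec())
#' v <- list(pos = toy$truth$variant_position, ref = toy$truth$variant_ref,
#'           alt = toy$truth$variant_alt)
#' hgvs_intronic_name(v, toy$gene)$rendered
#' @export
hgvs_intronic_name <- function(variant, gene, transcript_label = NULL) {
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  introns <- gene_introns(gene)
  hit <- which(pos >= introns$start & pos <= introns$end)
  if (length(hit) != 1) {
    rlang::abort(paste0(
      "position ", pos, " is not strictly intronic in ",
      gene$transcript_label,
      "; exonic variants need exonic HGVS nomenclature (not provided here)"),
      class = "crypticex_error")
  }
  iv <- introns[hit, ]
  if (gene$strand == "+") {
    dist_up <- pos - iv$start + 1L
    dist_down <- iv$end - pos + 1L
  } else {
    dist_up <- iv$end - pos + 1L
    dist_down <- pos - iv$start + 1L
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  tx_ends <- exon_tx_ends(gene)
  coding_of <- function(tx) tx - (gene$cds_tx_start - 1L)
  if (dist_up <= dist_down) {
    anchor <- coding_of(tx_ends[hit])
    offset <- dist_up
    rendered <- sprintf("c.%d+%d%s>%s", anchor, offset, ref, alt)
  } else {
    anchor <- coding_of(tx_ends[hit] + 1L)
    offset <- -dist_down
    rendered <- sprintf("c.%d-%d%s>%s", anchor, dist_down, ref, alt)
  }
  cx_assert(anchor >= 1,
            "anchor falls in the 5' UTR; UTR-anchored names are not supported")
  structure(list(transcript_label = transcript_label %||%
                   gene$transcript_label,
                 anchor_cdna_pos = as.integer(anchor),
                 offset = as.integer(offset), ref = ref, alt = alt,
                 rendered = rendered),
            class = "cx_hgvs")
}

#' @method print cx_hgvs
#' @export
print.cx_hgvs <- function(x, ...) {
  cat(sprintf("%s %s\n", x$transcript_label, x$rendered))
  invisible(x)
}
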