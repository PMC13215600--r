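# Synthetic toy locus with a planted deep-intronic cryptic exon. The default
# geometry mirrors the EJSCA-like study system: a five-exon gene, a G>C SNV
# 1778 bp into intron 2 sitting at the eighth base of a 92 bp cryptic exon,
# RT-PCR amplicon inserts of 306/398/541 bp, and a premature TGA after 24
# amino acids once the cryptic exon is spliced in.

#' Specify a synthetic disease locus
#'
#' Returns a validated locus specification consumed by [build_toy_locus()].
#' Defaults reproduce the standard fixture geometry used throughout the
#' package: exon 2 ends at coding position 177, the cryptic exon starts
#' 1771 bp into intron 2 so that the planted G>C variant is its eighth base
#' (HGVS c.177+1778G>C), the cryptic exon carries an in-frame TGA after 24
#' amino acids, and the downstream exon can be 5'-extended by
#' `extended_acceptor_shift` bases (541 - 398 = 143 in the fixture).
#'
#' @param contig_name reference contig name.
#' @param contig_length contig length in bp.
#' @param gene_start 1-based genomic start of exon 1 on the coding strand.
#' @param exon_lengths integer vector of exon lengths (>= 2 exons).
#' @param intron_lengths integer vector of intron lengths
#'   (`length(exon_lengths) - 1`).
#' @param strand `"+"` or `"-"`.
#' @param cds_start_exon_offset 0-based offset of the first coding base within
#'   exon 1.
#' @param utr3_in_last_exon number of 3' UTR bases in the last exon.
#' @param cryptic_exon `NULL` for a canonical-only locus, or a list with
#'   `intron_index`, `offset_into_intron` (1-based start of the exon within
#'   the intron), `length`, `variant_offset_in_exon` (1-based),
#'   `stop_after_aa`.
#' @param extended_acceptor_shift 5' extension (bp) of the exon downstream of
#'   the cryptic exon used by the longest isoform; 0 disables it.
#' @param in_frame if `TRUE`, require the cryptic exon length to be a multiple
#'   of 3 (a strictly in-frame insertion).
#' @param primer_fwd,primer_rev RT-PCR primer sequences (coding strand /
#'   reverse primer as ordered).
#' @param primer_fwd_exon,primer_fwd_offset exon index and 1-based offset
#'   within that exon of the forward primer footprint.
#' @param primer_rev_exon,primer_rev_offset likewise for the reverse primer
#'   footprint (the reverse complement of `primer_rev` on the coding strand).
#' @param n_hap_snps number of substitutions distinguishing the second
#'   canonical amplicon haplotype.
#' @param seed integer seed; the whole locus is deterministic given the spec.
#' @return a `cx_locus_spec` list.
#' @export
locus_spec <- function(contig_name = "chrT",
                       contig_length = 8000L,
                       gene_start = 1001L,
                       exon_lengths = c(120L, 117L, 100L, 80L, 150L),
                       intron_lengths = c(500L, 4000L, 400L, 350L),
                       strand = "+",
                       cds_start_exon_offset = 60L,
                       utr3_in_last_exon = 90L,
                       cryptic_exon = list(intron_index = 2L,
                                           offset_into_intron = 1771L,
                                           length = 92L,
                                           variant_offset_in_exon = 8L,
                                           stop_after_aa = 24L),
                       extended_acceptor_shift = 143L,
                       in_frame = FALSE,
                       primer_fwd = "CTTCTACACGGCCCAACACC",
                       primer_rev = "GAGCCCATTGTACCAGCCC",
                       primer_fwd_exon = 2L, primer_fwd_offset = 32L,
                       primer_rev_exon = 5L, primer_rev_offset = 61L,
                       n_hap_snps = 8L,
                       seed = 42L) {
  n_ex <- length(exon_lengths)
  cx_assert(n_ex >= 2, "need at least 2 exons")
  cx_assert(length(intron_lengths) == n_ex - 1,
            "need one intron length per exon pair")
  cx_assert(all(exon_lengths >= 1) && all(intron_lengths >= 1),
            "exon/intron lengths must be >= 1")
  cx_assert(strand %in% c("+", "-"), "`strand` must be '+' or '-'")
  gene_len <- sum(exon_lengths) + sum(intron_lengths)
  cx_assert(gene_start + gene_len - 1 <= contig_length,
            "gene does not fit on the contig")
  n_coding <- sum(exon_lengths) - cds_start_exon_offset - utr3_in_last_exon
  cx_assert(n_coding >= 6 && n_coding %% 3 == 0,
            "CDS length must be a positive multiple of 3; adjust offsets")
  if (!is.null(cryptic_exon) && cryptic_exon$length > 0) {
    ce <- cryptic_exon
    cx_assert(ce$intron_index >= 1 && ce$intron_index <= n_ex - 1,
              "cryptic exon intron index out of range")
    il <- intron_lengths[ce$intron_index]
    cx_assert(ce$offset_into_intron >= 3 &&
              ce$offset_into_intron + ce$length + 1 <= il,
              "cryptic exon (with AG/GT context) must fit inside the intron")
    cx_assert(ce$variant_offset_in_exon >= 1 &&
              ce$variant_offset_in_exon <= ce$length,
              "variant offset outside the cryptic exon")
    if (in_frame)
      cx_assert(ce$length %% 3 == 0,
                "an in-frame insertion needs a length divisible by 3")
    coding_before <- n_coding_before_intron(exon_lengths,
                                            cds_start_exon_offset,
                                            ce$intron_index)
    cx_assert(coding_before > 0,
              "cryptic exon must lie downstream of the CDS start")
    lead <- (3L - coding_before %% 3L) %% 3L
    need <- lead + 3L * ce$stop_after_aa + 3L
    if (need > ce$length)
      rlang::abort(sprintf(paste0(
        "infeasible spec: stop_after_aa = %d needs %d bp but the cryptic ",
        "exon offers only %d (stops extending into the downstream exon are ",
        "not generated)"), ce$stop_after_aa, need, ce$length),
        class = "crypticex_error")
    stop_start <- lead + 3L * ce$stop_after_aa + 1L
    cx_assert(ce$variant_offset_in_exon < stop_start ||
              ce$variant_offset_in_exon > stop_start + 2L,
              "variant must not fall inside the planted stop codon")
    if (extended_acceptor_shift > 0) {
      cx_assert(extended_acceptor_shift + 2 <=
                  il - (ce$offset_into_intron + ce$length + 2),
                "extended acceptor overlaps the cryptic exon block")
    }
  } else {
    cryptic_exon <- NULL
  }
  fp_len <- nchar(primer_fwd); rp_len <- nchar(primer_rev)
  cx_assert(fp_len >= 15 && rp_len >= 15, "primers must be >= 15 bp")
  cx_assert(primer_fwd_offset + fp_len - 1 <= exon_lengths[primer_fwd_exon],
            "forward primer footprint outside its exon")
  cx_assert(primer_rev_offset + rp_len - 1 <= exon_lengths[primer_rev_exon],
            "reverse primer footprint outside its exon")
  structure(
    list(contig_name = contig_name, contig_length = as.integer(contig_length),
         gene_start = as.integer(gene_start),
         exon_lengths = as.integer(exon_lengths),
         intron_lengths = as.integer(intron_lengths), strand = strand,
         cds_start_exon_offset = as.integer(cds_start_exon_offset),
         utr3_in_last_exon = as.integer(utr3_in_last_exon),
         cryptic_exon = cryptic_exon,
         extended_acceptor_shift =
           if (is.null(cryptic_exon)) 0L else as.integer(extended_acceptor_shift),
         in_frame = in_frame,
         primer_fwd = primer_fwd, primer_rev = primer_rev,
         primer_fwd_exon = as.integer(primer_fwd_exon),
         primer_fwd_offset = as.integer(primer_fwd_offset),
         primer_rev_exon = as.integer(primer_rev_exon),
         primer_rev_offset = as.integer(primer_rev_offset),
         n_hap_snps = as.integer(n_hap_snps),
         seed = as.integer(seed)),
    class = "cx_locus_spec")
}

# coding bases upstream of intron i (i.e. in exons 1..i)
n_coding_before_intron <- function(exon_lengths, cds_start_exon_offset, i) {
  sum(exon_lengths[seq_len(i)]) - cds_start_exon_offset
}

#' Build the synthetic toy locus
#'
#' Deterministically constructs (for a given spec and its seed) a reference
#' contig, a single-transcript gene model, and the fully recorded planted
#' truth: the genomic position and alleles of the deep-intronic SNV, the
#' cryptic exon interval flanked by AG/GT splice contexts on the coding
#' strand, the expected HGVS intronic name, the premature-stop geometry, the
#' per-genotype isoform sets, and the RT-PCR amplicon insert sequences
#' (including a second canonical haplotype).
#'
#' @param spec a [locus_spec()].
#' @return a list with elements `reference` (named character: the contig
#'   sequence), `gene` (a [gene_model()]), and `truth` (list, the planted
#'   truth).
#' @examples
#' toy <- build_toy_locus(locus_spec())
#' toy$truth$expected_hgvs
#' @export
build_toy_locus <- function(spec) {
  cx_assert(inherits(spec, "cx_locus_spec"), "`spec` must come from locus_spec()")
  with_seed(spec$seed, build_toy_locus_impl(spec))
}

build_toy_locus_impl <- function(spec) {
  n_ex <- length(spec$exon_lengths)
  L <- spec$contig_length
  contig <- rand_dna(L)

  # genomic layout on the coding ("virtual plus") strand
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- spec$gene_start
  intron_start <- integer(n_ex - 1)
  for (i in seq_len(n_ex)) {
    starts[i] <- pos; ends[i] <- pos + spec$exon_lengths[i] - 1L
    pos <- ends[i] + 1L
    if (i < n_ex) { intron_start[i] <- pos; pos <- pos + spec$intron_lengths[i] }
  }

  # coding sequence: ATG + sense codons + TAA, no internal stop
  n_coding <- sum(spec$exon_lengths) - spec$cds_start_exon_offset -
    spec$utr3_in_last_exon
  codons <- sense_codons()
  cds <- paste0("ATG",
                paste(sample(codons, n_coding / 3 - 2, replace = TRUE),
                      collapse = ""),
                "TAA")

  # distribute transcript sequence (UTR5 + CDS + UTR3) across exons
  tx_seq <- paste0(rand_dna(spec$cds_start_exon_offset), cds,
                   rand_dna(spec$utr3_in_last_exon))
  exon_seqs <- character(n_ex)
  off <- 0L
  for (i in seq_len(n_ex)) {
    exon_seqs[i] <- substring(tx_seq, off + 1L, off + spec$exon_lengths[i])
    off <- off + spec$exon_lengths[i]
  }

  # Junction disambiguation: the first base of every non-first exon must
  # differ from the donor 'G' that starts each intron, so that block
  # decomposition of spliced sequence against the genome cannot drift across
  # a splice boundary by chance micro-homology. 'C' can never create a stop.
  for (i in seq(2, n_ex)) {
    if (startsWith(exon_seqs[i], "G"))
      exon_seqs[i] <- paste0("C", substring(exon_seqs[i], 2))
  }

  # primer footprints (forward primer and reverse complement of the reverse
  # primer) overwrite their exons; the fixture phase keeps the frame stop-free
  exon_seqs[spec$primer_fwd_exon] <-
    splice_into(exon_seqs[spec$primer_fwd_exon], spec$primer_fwd_offset,
                spec$primer_fwd)
  exon_seqs[spec$primer_rev_exon] <-
    splice_into(exon_seqs[spec$primer_rev_exon], spec$primer_rev_offset,
                revcomp(spec$primer_rev))
  cds_check <- substring(paste(exon_seqs, collapse = ""),
                         spec$cds_start_exon_offset + 1L,
                         spec$cds_start_exon_offset + n_coding)
  internal <- substring(cds_check, 1, n_coding - 3)
  frames <- substring(internal, seq(1, nchar(internal) - 2, by = 3),
                      seq(3, nchar(internal), by = 3))
  cx_assert(!any(frames %in% STOP_CODONS),
            "primer footprint introduced a premature stop; move the footprint")

  # introns: canonical GT...AG, plus planted cryptic-exon and extension motifs
  intron_seqs <- vapply(spec$intron_lengths, function(l) {
    s <- rand_dna(l)
    s <- splice_into(s, 1L, "GT")
    splice_into(s, l - 1L, "AG")
  }, character(1))

  truth <- list(contig = spec$contig_name, strand = spec$strand,
                gene_start = spec$gene_start, seed = spec$seed)
  ce <- spec$cryptic_exon
  ce_seq_ref <- NULL
  if (!is.null(ce)) {
    coding_before <- n_coding_before_intron(spec$exon_lengths,
                                            spec$cds_start_exon_offset,
                                            ce$intron_index)
    lead <- (3L - coding_before %% 3L) %% 3L
    body <- paste0(strrep("C", lead),
                   paste(sample(codons, ce$stop_after_aa, replace = TRUE),
                         collapse = ""),
                   "TGA")
    tail_len <- ce$length - nchar(body)
    ce_seq_alt <- paste0(body, rand_dna(tail_len))
    # same junction-disambiguation rule as for annotated exons
    if (startsWith(ce_seq_alt, "G") && ce$variant_offset_in_exon != 1L)
      ce_seq_alt <- paste0("C", substring(ce_seq_alt, 2))
    # alt allele is C at the variant offset; reference carries G
    ce_seq_alt <- splice_into(ce_seq_alt, ce$variant_offset_in_exon, "C")
    ce_seq_ref <- splice_into(ce_seq_alt, ce$variant_offset_in_exon, "G")
    ii <- ce$intron_index
    iseq <- intron_seqs[ii]
    iseq <- splice_into(iseq, ce$offset_into_intron - 2L, "AG")
    iseq <- splice_into(iseq, ce$offset_into_intron, ce_seq_ref)
    iseq <- splice_into(iseq, ce$offset_into_intron + ce$length, "GT")
    if (spec$extended_acceptor_shift > 0) {
      ext_start <- spec$intron_lengths[ii] - spec$extended_acceptor_shift + 1L
      iseq <- splice_into(iseq, ext_start - 2L, "AG")
      if (substring(iseq, ext_start, ext_start) == "G")
        iseq <- splice_into(iseq, ext_start, "C")
    }
    intron_seqs[ii] <- iseq

    ce_gstart <- intron_start[ii] + ce$offset_into_intron - 1L
    ce_gend <- ce_gstart + ce$length - 1L
    var_pos <- ce_gstart + ce$variant_offset_in_exon - 1L
    anchor <- coding_before
    offset_up <- var_pos - intron_start[ii] + 1L
    truth$cryptic_exon_interval <- c(start = ce_gstart, end = ce_gend)
    truth$cryptic_exon_intron <- ii
    truth$variant_position <- var_pos
    truth$variant_ref_coding <- "G"
    truth$variant_alt_coding <- "C"
    truth$variant_offset_in_exon <- ce$variant_offset_in_exon
    truth$expected_hgvs <- sprintf("c.%d+%dG>C", anchor, offset_up)
    truth$expected_ptc_aa <- ce$stop_after_aa
    truth$cryptic_exon_sequence_alt <- ce_seq_alt
  }

  # assemble the contig
  cursor <- spec$gene_start
  for (i in seq_len(n_ex)) {
    contig <- splice_into(contig, cursor, exon_seqs[i])
    cursor <- cursor + spec$exon_lengths[i]
    if (i < n_ex) {
      contig <- splice_into(contig, cursor, intron_seqs[i])
      cursor <- cursor + spec$intron_lengths[i]
    }
  }

  exons <- tibble(start = starts, end = ends)
  cds_tx_start <- spec$cds_start_exon_offset + 1L

  # isoform block sets (transcription order, coding-strand coordinates)
  iso <- list(canonical = exons)
  if (!is.null(ce)) {
    ii <- spec$cryptic_exon$intron_index
    ce_iv <- tibble(start = truth$cryptic_exon_interval[["start"]],
                    end = truth$cryptic_exon_interval[["end"]])
    iso$cryptic <- bind_rows(exons[seq_len(ii), ], ce_iv,
                             exons[seq(ii + 1, n_ex), ])
    if (spec$extended_acceptor_shift > 0) {
      ext <- exons
      ext$start[ii + 1] <- ext$start[ii + 1] - spec$extended_acceptor_shift
      iso$cryptic_extended <- bind_rows(ext[seq_len(ii), ], ce_iv,
                                        ext[seq(ii + 1, n_ex), ])
    }
  }

  # minus-strand loci: reverse-complement the contig and flip coordinates
  flip <- function(tbl) {
    tibble(start = L - tbl$end + 1L, end = L - tbl$start + 1L)
  }
  if (spec$strand == "-") {
    contig <- revcomp(contig)
    exons <- flip(exons)
    iso <- lapply(iso, flip)
    if (!is.null(ce)) {
      ivl <- truth$cryptic_exon_interval
      truth$cryptic_exon_interval <- c(start = L - ivl[["end"]] + 1L,
                                       end = L - ivl[["start"]] + 1L)
      truth$variant_position <- L - truth$variant_position + 1L
    }
  }

  gm <- gene_model(spec$contig_name, "TOYG", "TOYG-201", spec$strand, exons,
                   cds_tx_start, n_coding)

  # plus-strand VCF alleles for the planted SNV
  if (!is.null(ce)) {
    truth$variant_ref <- if (spec$strand == "+") "G" else "C"
    truth$variant_alt <- if (spec$strand == "+") "C" else "G"
  }

  truth$isoforms <- iso
  truth$isoform_set_per_genotype <- if (is.null(ce)) {
    list(homref = "canonical", het = "canonical", homalt = "canonical")
  } else {
    list(homref = "canonical", het = names(iso), homalt = names(iso))
  }
  truth$canonical_mrna <- splice_blocks(contig, iso$canonical, spec$strand)

  # amplicon inserts between primer footprints, per isoform
  alt_contig <- contig
  if (!is.null(ce)) {
    vp <- truth$variant_position
    alt_contig <- splice_into(contig, vp, truth$variant_alt)
  }
  fwd <- spec$primer_fwd; rev_rc <- revcomp(spec$primer_rev)
  cut_insert <- function(genome, blocks) {
    tx <- splice_blocks(genome, blocks, spec$strand)
    f <- regexpr(fwd, tx, fixed = TRUE)
    r <- regexpr(rev_rc, tx, fixed = TRUE)
    cx_assert(f > 0 && r > f, "primer footprints not found on the isoform")
    substring(tx, f + nchar(fwd), r - 1L)
  }
  inserts <- list(canonical_a = cut_insert(contig, iso$canonical))
  if (!is.null(ce)) {
    inserts$cryptic <- cut_insert(alt_contig, iso$cryptic)
    if (!is.null(iso$cryptic_extended))
      inserts$cryptic_extended <- cut_insert(alt_contig, iso$cryptic_extended)
  }
  if (spec$n_hap_snps > 0) {
    a <- inserts$canonical_a
    pos <- sort(sample(seq(5L, nchar(a) - 4L), spec$n_hap_snps))
    b <- strsplit(a, "")[[1]]
    for (p in pos) b[p] <- sample(setdiff(BASES, b[p]), 1)
    inserts$canonical_b <- paste(b, collapse = "")
    truth$hap_snp_positions <- pos
  }
  truth$amplicon_inserts <- unlist(inserts)
  truth$amplicon_insert_lengths <- vapply(inserts, nchar, integer(1))
  truth$primers <- c(forward = spec$primer_fwd, reverse = spec$primer_rev)

  reference <- setNames(contig, spec$contig_name)
  list(reference = reference, gene = gm, truth = truth)
}
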