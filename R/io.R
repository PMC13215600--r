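# I/O boundaries. Every on-disk format follows its standard convention
# (VCF/GFF3 1-based closed, BED12 0-based half-open); in-memory tibbles are
# 1-based closed throughout.

#' Write / read FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read amplicon FASTQ
#'
#' Reads are written with a flat quality string encoding `mean_quality`
#' (default Q20); on reading, the per-read mean Phred quality is recomputed
#' from the quality string.
#'
#' @param reads tibble with columns `id`, `sequence` and optionally
#'   `mean_quality`.
#' @param path file path.
#' @return `read_amplicon_fastq()` returns a tibble `id`, `sample` (the piece
#'   of the id before the first `:`), `sequence`, `mean_quality`.
#' @export
write_fastq <- function(reads, path) {
  q <- if ("mean_quality" %in% names(reads)) reads$mean_quality else 20
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  quals <- Biostrings::BStringSet(strrep(intToUtf8(33L + as.integer(q),
                                                   multiple = TRUE),
                                         nchar(reads$sequence)))
  # QualityScaledDNAStringSet drops inherited metadata columns; that is fine
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(quals)), path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_amplicon_fastq <- function(path) {
  # the constructor notes that quality metadata columns are re-attached
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qm <- vapply(as(Biostrings::quality(x), "IntegerList"), mean, numeric(1))
  tibble(id = names(x),
         sample = sub(":.*$", "", names(x)),
         sequence = unname(as.character(x)),
         mean_quality = unname(qm))
}

#' Write / read a gene model as GFF3
#'
#' Writes `gene`, `mRNA`, `exon` and `CDS` features for the single transcript;
#' reading reconstructs the [gene_model()] from them.
#'
#' @param gene a [gene_model()].
#' @param path file path.
#' @return `read_gene_model()` returns a [gene_model()].
#' @export
write_gff3 <- function(gene, path) {
  ex <- arrange(gene$exons, .data$start)
  cds <- cds_genomic_intervals(gene)
  # GFF3 phase per CDS piece, in transcription order
  cds_tx <- if (gene$strand == "+") cds else arrange(cds, -.data$start)
  lens <- cds_tx$end - cds_tx$start + 1
  cds_tx$phase <- (3L - c(0L, cumsum(lens)[-length(lens)]) %% 3L) %% 3L
  cds <- arrange(cds_tx, .data$start)
  feats <- bind_rows(
    tibble(type = "gene", start = min(ex$start), end = max(ex$end),
           ID = gene$gene_name, Parent = NA_character_),
    tibble(type = "mRNA", start = min(ex$start), end = max(ex$end),
           ID = gene$transcript_label, Parent = gene$gene_name),
    tibble(type = "exon", start = ex$start, end = ex$end,
           ID = sprintf("%s:exon%d", gene$transcript_label,
                        order(order(if (gene$strand == "+") ex$start
                                    else -ex$start))),
           Parent = gene$transcript_label),
    tibble(type = "CDS", start = cds$start, end = cds$end,
           ID = sprintf("%s:cds", gene$transcript_label),
           Parent = gene$transcript_label, phase = cds$phase))
  gr <- GenomicRanges::GRanges(
    seqnames = gene$contig,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = gene$strand, type = feats$type, ID = feats$ID,
    Parent = ifelse(is.na(feats$Parent), "", feats$Parent),
    phase = feats$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# genomic intervals covered by the CDS (transcript offsets mapped onto exons)
cds_genomic_intervals <- function(gene) {
  lens <- exon_lengths(gene)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  cs <- gene$cds_tx_start; ce <- gene$cds_tx_start + gene$cds_length - 1L
  rows <- list()
  for (i in seq_along(lens)) {
    lo <- max(cs, starts[i]); hi <- min(ce, ends[i])
    if (lo > hi) next
    w_lo <- lo - starts[i]; w_hi <- hi - starts[i]
    g <- if (gene$strand == "+") {
      c(gene$exons$start[i] + w_lo, gene$exons$start[i] + w_hi)
    } else {
      c(gene$exons$end[i] - w_hi, gene$exons$end[i] - w_lo)
    }
    rows[[length(rows) + 1L]] <- tibble(start = g[1], end = g[2])
  }
  arrange(bind_rows(rows), .data$start)
}

#' @rdname write_gff3
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(gr))
  gene_row <- d[d$type == "gene", ]
  mrna <- d[d$type == "mRNA", ]
  cx_assert(nrow(mrna) == 1, "expected a single-transcript GFF3")
  ex <- d[d$type == "exon", ]
  strand <- as.character(mrna$strand[1])
  ex <- if (strand == "+") arrange(ex, .data$start) else arrange(ex, -.data$start)
  cds <- arrange(d[d$type == "CDS", ], .data$start)
  gm_tmp <- gene_model(as.character(mrna$seqnames[1]),
                       gene_row$ID[[1]], mrna$ID[[1]], strand,
                       tibble(start = ex$start, end = ex$end),
                       1L, 3L)
  cds_first <- if (strand == "+") min(cds$start) else max(cds$end)
  cds_tx <- genomic_to_tx(gm_tmp, cds_first)
  gene_model(gm_tmp$contig, gm_tmp$gene_name, gm_tmp$transcript_label, strand,
             gm_tmp$exons[, c("start", "end")], cds_tx,
             sum(cds$end - cds$start + 1))
}

#' Write / read spliced-read block records as BED12
#'
#' @param reads long block tibble as from [simulate_spliced_reads()].
#' @param path file path.
#' @return `read_spliced_bed()` returns the long block tibble (`read_id`,
#'   `sample`, `chrom`, `start`, `end`), coordinates 1-based closed.
#' @export
write_bed12 <- function(reads, path) {
  per_read <- reads |>
    arrange(.data$read_id, .data$start) |>
    group_by(.data$read_id, .data$sample, .data$chrom) |>
    summarise(chromStart = min(.data$start) - 1L, chromEnd = max(.data$end),
              blockCount = n(),
              blockSizes = paste(.data$end - .data$start + 1L, collapse = ","),
              blockStarts = paste(.data$start - min(.data$start),
                                  collapse = ","),
              .groups = "drop")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d\t0\t%d\t%s\t%s",
                   per_read$chrom, per_read$chromStart, per_read$chromEnd,
                   per_read$read_id, per_read$chromStart, per_read$chromEnd,
                   per_read$blockCount, per_read$blockSizes,
                   per_read$blockStarts)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_spliced_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  n_blocks <- lengths(blocks)
  flat <- as.data.frame(blocks)
  ids <- if (!is.null(names(gr))) names(gr) else gr$name
  tibble(read_id = rep(ids, n_blocks),
         sample = sub(":.*$", "", rep(ids, n_blocks)),
         chrom = rep(as.character(GenomicRanges::seqnames(gr)), n_blocks),
         start = flat$start, end = flat$end)
}

#' Write a multi-sample VCF 4.2 with SnpEff-style ANN annotations
#'
#' @param variants variant table (chrom, pos, ref, alt, gene, effect, impact).
#' @param genotypes long genotype tibble (chrom, pos, alt, sample, gt).
#' @param path file path.
#' @param contig_length optional contig length for the header.
#' @return the path, invisibly.
#' @export
write_cohort_vcf <- function(variants, genotypes, path, contig_length = NULL) {
  samples <- unique(genotypes$sample)
  gt_code <- c(homref = "0/0", het = "0/1", homalt = "1/1", missing = "./.")
  wide <- genotypes |>
    mutate(code = gt_code[.data$gt]) |>
    select("chrom", "pos", "alt", "sample", "code") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "code")
  v <- left_join(variants, wide, by = c("chrom", "pos", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_length))
      sprintf("##contig=<ID=%s,length=%d>", variants$chrom[1], contig_length),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Effect|Impact|Gene'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tANN=%s|%s|%s|%s\tGT\t%s",
                  v$chrom, v$pos, v$ref, v$alt,
                  v$alt, v$effect, v$impact, v$gene,
                  apply(as.matrix(v[, samples, drop = FALSE]), 1, paste,
                        collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read the planted truth as JSON
#' @param truth planted-truth list from [build_toy_locus()].
#' @param path file path.
#' @return `read_truth_json()` returns the truth list (tibbles restored).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$isoforms <- lapply(x$isoforms, as_tibble)
  x
}

#' Write / read cohort design and panel counts as TSV
#' @param design cohort design tibble.
#' @param path file path.
#' @return readers return tibbles / [genotype_counts()].
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  validate_design(readr::read_tsv(path, show_col_types = FALSE,
                                  col_types = "cc"))
}

#' @rdname write_design_tsv
#' @param counts a [genotype_counts()].
#' @export
write_panel_tsv <- function(counts, path) {
  readr::write_tsv(tibble(n_het = counts$n_het, n_homalt = counts$n_homalt,
                          n_total = counts$n_total), path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_panel_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, col_types = "iii")
  genotype_counts(d$n_het[1], d$n_homalt[1], d$n_total[1])
}
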