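test_that("the standard locus embodies the planted disease geometry", {
  toy <- toy_plus()
  t <- toy$truth
  expect_equal(t$expected_hgvs, "c.177+1778G>C")
  expect_equal(t$variant_offset_in_exon, 8)
  expect_equal(t$expected_ptc_aa, 24)
  # amplicon insert lengths: 306 canonical, +92 cryptic, +143 extension
  lens <- t$amplicon_insert_lengths
  expect_equal(unname(lens[c("canonical_a", "cryptic", "cryptic_extended")]),
               c(306L, 398L, 541L))
  expect_equal(unname(lens[["cryptic"]] - lens[["canonical_a"]]), 92L)
  expect_equal(unname(lens[["cryptic_extended"]] - lens[["cryptic"]]), 143L)
  # AG...GT splice context flanks the cryptic exon; ref base is G
  ref <- toy$reference[[1]]
  iv <- t$cryptic_exon_interval
  expect_equal(substring(ref, iv[["start"]] - 2, iv[["start"]] - 1), "AG")
  expect_equal(substring(ref, iv[["end"]] + 1, iv[["end"]] + 2), "GT")
  expect_equal(substring(ref, t$variant_position, t$variant_position), "G")
  # in-frame stop exactly 24 codons after the cryptic exon's first codon
  mrna <- splice_mrna(alt_reference(toy), t$isoforms$cryptic, "+")
  pred <- translate_cds(mrna, toy$gene$cds_tx_start - 1)
  expect_equal(pred$stop_codon, "TGA")
  coding_before_ce <- sum(toy$gene$exons$end[1:2] -
                            toy$gene$exons$start[1:2] + 1) -
    (toy$gene$cds_tx_start - 1)
  first_ce_codon <- coding_before_ce %/% 3 + 1
  expect_equal(pred$stop_codon_index - first_ce_codon, 24)
})

test_that("generation is deterministic and serialisations round-trip", {
  toy1 <- build_toy_locus(locus_spec())
  toy2 <- build_toy_locus(locus_spec())
  expect_identical(toy1$reference, toy2$reference)
  expect_identical(toy1$truth, toy2$truth)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fasta"); f2 <- file.path(d, "b.fasta")
  write_fasta(toy1$reference, f1); write_fasta(toy2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- file.path(d, "a.gff3"); g2 <- file.path(d, "b.gff3")
  suppressWarnings(write_gff3(toy1$gene, g1))
  suppressWarnings(write_gff3(toy2$gene, g2))
  expect_identical(readLines(g1), readLines(g2))
  # GFF3 round trip reproduces the gene model
  gm <- read_gene_model(g1)
  expect_equal(gm$exons, toy1$gene$exons)
  expect_equal(gm$strand, toy1$gene$strand)
  expect_equal(gm$cds_tx_start, toy1$gene$cds_tx_start)
  expect_equal(gm$cds_length, toy1$gene$cds_length)
  # FASTA round trip
  expect_identical(read_fasta(f1), toy1$reference)
  # truth JSON round trip preserves the geometry fields
  tj <- file.path(d, "truth.json")
  write_truth_json(toy1$truth, tj)
  t2 <- read_truth_json(tj)
  expect_equal(t2$expected_hgvs, toy1$truth$expected_hgvs)
  expect_equal(t2$variant_position, toy1$truth$variant_position)
  expect_equal(as.integer(t2$cryptic_exon_interval),
               unname(toy1$truth$cryptic_exon_interval))
  expect_equal(t2$isoforms$cryptic, toy1$truth$isoforms$cryptic)
})

test_that("a canonical-only locus has no genotype-specific isoforms", {
  toy <- build_toy_locus(locus_spec(cryptic_exon = NULL))
  sets <- toy$truth$isoform_set_per_genotype
  expect_identical(sets$homref, sets$homalt)
  expect_identical(sets$homref, "canonical")
  expect_null(toy$truth$variant_position)
})

test_that("infeasible premature-stop geometry is rejected with a message", {
  expect_error(
    locus_spec(cryptic_exon = list(intron_index = 2, offset_into_intron = 1771,
                                   length = 92, variant_offset_in_exon = 8,
                                   stop_after_aa = 40)),
    "infeasible")
  expect_error(locus_spec(exon_lengths = c(100L)), "at least 2 exons")
  expect_error(
    locus_spec(cryptic_exon = list(intron_index = 2, offset_into_intron = 1771,
                                   length = 92, variant_offset_in_exon = 100,
                                   stop_after_aa = 24)),
    "variant offset")
  expect_error(
    locus_spec(in_frame = TRUE),  # 92 is not a multiple of 3
    "divisible by 3")
})

test_that("minus-strand loci mirror the plus-strand geometry", {
  toy <- toy_minus()
  t <- toy$truth
  expect_equal(t$expected_hgvs, "c.177+1778G>C")
  # plus-strand VCF alleles are the complement of the coding-strand G>C
  expect_equal(t$variant_ref, "C")
  expect_equal(t$variant_alt, "G")
  ref <- toy$reference[[1]]
  expect_equal(substring(ref, t$variant_position, t$variant_position), "C")
  # coding-strand splice context: AG upstream of the exon in transcription
  # order is GT/AG reverse-complemented on the plus strand
  iv <- t$cryptic_exon_interval
  expect_equal(substring(ref, iv[["end"]] + 1, iv[["end"]] + 2),
               revcomp("AG"))
  expect_equal(substring(ref, iv[["start"]] - 2, iv[["start"]] - 1),
               revcomp("GT"))
  # same amplicon inserts as the plus-strand locus geometry (lengths)
  expect_equal(unname(t$amplicon_insert_lengths[c("canonical_a", "cryptic",
                                                  "cryptic_extended")]),
               c(306L, 398L, 541L))
  # translation of the cryptic isoform terminates after 24 extra aa
  ptc <- ptc_after_insertion(toy$gene, t$isoforms$cryptic,
                             alt_reference(toy), toy$gene)
  expect_equal(as.integer(ptc), 24)
})
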