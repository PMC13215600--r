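test_that("mRNA splicing concatenates blocks on the coding strand", {
  ref <- setNames("ATGTGACCCC", "c")
  blocks <- tibble::tibble(start = 1, end = 6)
  expect_equal(splice_mrna(ref, blocks, "+"), "ATGTGA")
  expect_equal(splice_mrna(ref, blocks, "-"), "TCACAT")
  toy <- toy_plus()
  expect_equal(splice_mrna(toy$reference, toy$truth$isoforms$canonical, "+"),
               toy$truth$canonical_mrna)
  tm <- toy_minus()
  expect_equal(splice_mrna(tm$reference, tm$truth$isoforms$canonical, "-"),
               tm$truth$canonical_mrna)
  expect_error(splice_mrna(ref, tibble::tibble(start = 5, end = 50), "+"),
               "outside")
})

test_that("translation follows the standard code and flags termination", {
  p1 <- translate_cds("ATGTGA")
  expect_equal(p1$peptide, "M")
  expect_equal(p1$stop_codon, "TGA")
  expect_equal(p1$stop_codon_index, 2)
  p2 <- translate_cds("ATGAAATAG")
  expect_equal(p2$peptide, "MK")
  expect_equal(p2$stop_codon, "TAG")
  expect_equal(p2$stop_codon_index, 3)
  p3 <- translate_cds("ATGAAACCC")
  expect_true(p3$no_stop)
  expect_false(p3$ptc)
  expect_error(translate_cds("ATGNNNTGA"), "non-ACGT")
  # NMD: stop more than 55 nt upstream of the last junction
  mrna <- paste0("ATGTGA", strrep("A", 100))
  expect_true(translate_cds(mrna, 0, last_junction_tx = 80)$nmd_candidate)
  expect_false(translate_cds(mrna, 0, last_junction_tx = 61)$nmd_candidate)
  # PTC relative to a canonical stop position
  expect_true(translate_cds("ATGTGA", 0, canonical_stop_tx = 10)$ptc)
})

test_that("translation agrees with the Biostrings codon table", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      n_codons <- sample(3:60, 1)
      s <- random_dna(3 * n_codons)
      mine <- translate_cds(s)
      ref <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)))
      stops <- regexpr("*", ref, fixed = TRUE)[1]
      if (stops < 0) {
        expect_true(mine$no_stop)
        expect_equal(mine$peptide, ref)
      } else {
        expect_equal(mine$peptide, substring(ref, 1, stops - 1))
        expect_equal(mine$stop_codon_index, stops)
        expect_true(mine$stop_codon %in% c("TAA", "TAG", "TGA"))
      }
    }
  })
})

test_that("amino acids after a cryptic insertion are counted to the stop", {
  toy <- toy_plus()
  altref <- alt_reference(toy)
  # planted geometry: 24 aa then TGA
  ptc <- ptc_after_insertion(toy$gene, toy$truth$isoforms$cryptic, altref,
                             toy$gene)
  expect_equal(as.integer(ptc), 24)
  expect_true(attr(ptc, "frameshift"))  # 92 bp is not a multiple of 3
  # also via the mapped consensus structure
  st <- map_consensus(unname(toy$truth$amplicon_inserts[["cryptic"]]),
                      toy$reference, toy$gene)
  expect_equal(as.integer(ptc_after_insertion(toy$gene, st, altref,
                                              toy$gene)), 24)
  # a novel block whose first codon is a stop gives 0
  ref <- setNames(paste0(strrep("C", 10), "ATGAAA", strrep("C", 30),
                         "TGACCC", strrep("C", 30), "AAATAA",
                         strrep("C", 10)), "z")
  gm <- gene_model("z", "G", "G-1", "+",
                   tibble::tibble(start = c(11, 83), end = c(16, 88)),
                   cds_tx_start = 1, cds_length = 12)
  novel <- tibble::tibble(start = c(11, 47, 83), end = c(16, 52, 88))
  p0 <- ptc_after_insertion(gm, novel, ref, gm)
  expect_equal(as.integer(p0), 0)
  # in-frame insertion without stops and no downstream PTC gives NA
  ref2 <- setNames(paste0(strrep("C", 10), "ATGAAA", strrep("C", 30),
                          "GCAGCA", strrep("C", 30), "AAATAA",
                          strrep("C", 10)), "z")
  p_na <- ptc_after_insertion(gm, novel, ref2, gm)
  expect_true(is.na(p_na))
  expect_false(attr(p_na, "frameshift"))
})

test_that("in-frame stop-free insertions splice the peptide in place", {
  withr::with_seed(55, {
    codons <- crypticex:::sense_codons()
    for (i in 1:20) {
      n1 <- sample(4:10, 1); n2 <- sample(4:10, 1); nins <- sample(2:6, 1)
      cds1 <- paste(c("ATG", sample(codons, n1, TRUE)), collapse = "")
      cds2 <- paste(c(sample(codons, n2, TRUE), "TAA"), collapse = "")
      ins <- paste(sample(codons, nins, TRUE), collapse = "")
      pad1 <- random_dna(15); pad2 <- random_dna(15); pad3 <- random_dna(15)
      genome <- paste0(pad1, cds1, pad2, ins, pad3, cds2, random_dna(10))
      e1 <- c(16, 15 + nchar(cds1))
      bi <- c(e1[2] + 16, e1[2] + 15 + nchar(ins))
      e2 <- c(bi[2] + 16, bi[2] + 15 + nchar(cds2))
      gm <- gene_model("w", "G", "G-1", "+",
                       tibble::tibble(start = c(e1[1], e2[1]),
                                      end = c(e1[2], e2[2])),
                       cds_tx_start = 1,
                       cds_length = nchar(cds1) + nchar(cds2))
      ref <- setNames(genome, "w")
      canonical <- translate_cds(splice_mrna(ref, gm$exons, "+"))
      novel_blocks <- tibble::tibble(start = c(e1[1], bi[1], e2[1]),
                                     end = c(e1[2], bi[2], e2[2]))
      novel <- translate_cds(splice_mrna(ref, novel_blocks, "+"))
      ins_aa <- translate_cds(ins)$peptide
      # peptide = canonical prefix + inserted aa + canonical suffix
      expect_equal(novel$peptide,
                   paste0(substring(canonical$peptide, 1, n1 + 1), ins_aa,
                          substring(canonical$peptide, n1 + 2,
                                    nchar(canonical$peptide))))
    }
  })
})

test_that("predictions are identical on a locus and its mirror", {
  tp <- toy_plus(); tm <- toy_minus()
  pp <- translate_cds(splice_mrna(alt_reference(tp), tp$truth$isoforms$cryptic,
                                  "+"), tp$gene$cds_tx_start - 1)
  pm <- translate_cds(splice_mrna(alt_reference(tm), tm$truth$isoforms$cryptic,
                                  "-"), tm$gene$cds_tx_start - 1)
  expect_equal(pp$peptide, pm$peptide)
  expect_equal(pp$stop_codon, pm$stop_codon)
  expect_equal(pp$stop_codon_index, pm$stop_codon_index)
})
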