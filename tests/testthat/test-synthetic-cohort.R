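test_that("causal genotypes segregate perfectly in the simulated cohort", {
  toy <- toy_plus()
  design <- cohort_design(7, 4, 32)
  variants <- simulate_candidate_variants(toy, n_decoys = 10,
                                          decoy_freq_range = c(0, 0), seed = 2)
  g <- simulate_cohort_genotypes(design, variants, q_background = 0, seed = 3)
  causal <- g |> dplyr::filter(pos == toy$truth$variant_position)
  roles <- setNames(design$role, design$sample)
  expect_equal(sum(causal$gt == "homalt"), 7)
  expect_equal(sum(causal$gt == "het"), 4)
  expect_true(all(causal$gt[roles[causal$sample] == "case"] == "homalt"))
  expect_true(all(causal$gt[roles[causal$sample] == "control"] == "homref"))
  # decoys at frequency 0: everyone homref
  decoy <- g |> dplyr::filter(pos != toy$truth$variant_position)
  expect_true(all(decoy$gt == "homref"))
  # deterministic per seed
  g2 <- simulate_cohort_genotypes(design, variants, q_background = 0, seed = 3)
  expect_identical(g, g2)
  expect_error(simulate_cohort_genotypes(cohort_design(1, 0, 0)[0, ],
                                         variants, 0, 1),
               "at least one case")
})

test_that("control heterozygosity tracks the background frequency", {
  toy <- toy_plus()
  design <- cohort_design(1, 0, 10000)
  v <- simulate_candidate_variants(toy, n_decoys = 0, seed = 1)
  g <- simulate_cohort_genotypes(design, v, q_background = 0.1, seed = 5)
  ctrl <- g |> dplyr::filter(startsWith(sample, "ctrl"))
  frac_het <- mean(ctrl$gt == "het")
  p <- 2 * 0.1 * 0.9
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac_het - p), 3 * se)
  expect_true(all(ctrl$gt != "homalt"))
})

test_that("spliced reads carry their isoform's exact block structure", {
  toy <- toy_plus()
  iso <- toy$truth$isoforms
  reads <- simulate_spliced_reads(
    toy$gene, iso,
    list(case01 = c(canonical = 0.5, cryptic = 0.5),
         ctrl01 = c(canonical = 1)),
    depth = 200, seed = 4)
  expect_equal(dplyr::n_distinct(reads$read_id[reads$sample == "ctrl01"]), 200)
  introns <- crypticex:::gene_introns(toy$gene)
  ctrl <- reads |> dplyr::filter(sample == "ctrl01")
  inside <- purrr::map2_lgl(ctrl$start, ctrl$end, function(s, e) {
    any(s >= introns$start & e <= introns$end)
  })
  expect_false(any(inside))  # canonical-only: nothing strictly intronic
  # cryptic blocks sit exactly at the planted interval, count ~ Binom(200, .5)
  iv <- toy$truth$cryptic_exon_interval
  cry <- reads |> dplyr::filter(sample == "case01", start == iv[["start"]])
  expect_true(all(cry$end == iv[["end"]]))
  expect_lt(abs(nrow(cry) - 100), 3 * sqrt(200 * 0.25))
  # BED12 round trip preserves blocks
  d <- withr::local_tempdir()
  f <- file.path(d, "reads.bed")
  write_bed12(reads, f)
  back <- read_spliced_bed(f)
  orig <- reads |> dplyr::arrange(read_id, start) |>
    dplyr::select(read_id, sample, chrom, start, end)
  back <- back |> dplyr::arrange(read_id, start)
  expect_equal(as.data.frame(back), as.data.frame(orig))
})

test_that("amplicon reads are primer-flanked isoform copies", {
  toy <- toy_plus()
  t <- toy$truth
  reads0 <- simulate_amplicon_reads(
    list(s1 = c(canonical_a = 1)), t$amplicon_inserts, t$primers,
    error_rate = 0, n_reads = 50, seed = 6)
  fwd <- t$primers[["forward"]]
  planted <- paste0(fwd, t$amplicon_inserts[["canonical_a"]],
                    revcomp(t$primers[["reverse"]]))
  seqs <- ifelse(reads0$orientation == "reverse", revcomp(reads0$sequence),
                 reads0$sequence)
  expect_true(all(seqs == planted))       # error-free reads equal the amplicon
  expect_true(all(nchar(reads0$sequence) == nchar(planted)))
  # corrupted-primer fraction produces the expected rejection count
  reads1 <- simulate_amplicon_reads(
    list(s1 = c(canonical_a = 0.5, cryptic = 0.5)), t$amplicon_inserts,
    t$primers, error_rate = 0, corrupt_primer_frac = 0.1, n_reads = 1000,
    seed = 7)
  tr <- trim_primers(reads1, t$primers)
  expect_lt(abs(sum(!tr$accepted) - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_error(simulate_amplicon_reads(list(), t$amplicon_inserts, t$primers),
               "empty mixture")
})

test_that("panel counts follow Hardy-Weinberg with optional ascertainment", {
  expect_equal(unclass(simulate_panel(500, 0, seed = 1))[c("n_het", "n_homalt")],
               list(n_het = 0L, n_homalt = 0L))
  p1 <- simulate_panel(200, 1, seed = 1, exclude_homalt = FALSE)
  expect_equal(p1$n_homalt, 200L)
  expect_equal(p1$n_het, 0L)
  # mean het count over replicates ~ 2nq(1-q)
  q <- 0.0118; n <- 1060
  hets <- vapply(1:500, function(s) simulate_panel(n, q, seed = s)$n_het,
                 integer(1))
  expected <- 2 * n * q * (1 - q)
  se_mean <- sqrt(expected * (1 - 2 * q * (1 - q))) / sqrt(500)
  expect_lt(abs(mean(hets) - expected), 3 * se_mean)
  # ascertained panels never contain hom-alt animals
  p2 <- simulate_panel(2000, 0.2, seed = 9, exclude_homalt = TRUE)
  expect_equal(p2$n_homalt, 0L)
  expect_gt(p2$n_het, 0L)
})
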