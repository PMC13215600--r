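amp_reads <- function(error_rate = 0, n_reads = 200, seed = 20,
                      corrupt = 0) {
  toy <- toy_plus()
  t <- toy$truth
  simulate_amplicon_reads(
    list(case01 = c(canonical_a = 0.2, canonical_b = 0.2, cryptic = 0.3,
                    cryptic_extended = 0.3),
         ctrl01 = c(canonical_a = 0.5, canonical_b = 0.5)),
    t$amplicon_inserts, t$primers, error_rate = error_rate,
    corrupt_primer_frac = corrupt, n_reads = n_reads, seed = seed)
}

test_that("subsampling is per-sample, order-preserving and deterministic", {
  reads <- amp_reads()
  all_kept <- subsample_reads(reads, 10000, seed = 1)
  expect_identical(all_kept, reads)
  s1 <- subsample_reads(reads, 50, seed = 2)
  s2 <- subsample_reads(reads, 50, seed = 2)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$sample)), array(c(50L, 50L)),
               ignore_attr = TRUE)
  expect_false(is.unsorted(match(s1$id, reads$id)))
  # approximate uniformity: each read selected ~ n/N of the time
  first <- reads$id[1]
  hits <- vapply(1:200, function(s) {
    first %in% subsample_reads(reads, 100, seed = s)$id[1:100]
  }, logical(1))
  p <- 100 / sum(reads$sample == reads$sample[1])
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 200))
})

test_that("exact-primer trimming recovers inserts in both orientations", {
  toy <- toy_plus()
  t <- toy$truth
  reads <- amp_reads(error_rate = 0)
  tr <- trim_primers(reads, t$primers)
  expect_true(all(tr$accepted))
  expect_true(all(tr$insert == unname(t$amplicon_inserts[tr$isoform])))
  # trimming after error-free simulation is the identity on inserts,
  # including reads emitted in reverse orientation
  expect_true(any(reads$orientation == "reverse"))
  # a single mismatch inside the forward primer rejects the read
  bad <- reads[which(reads$orientation == "forward")[1], ]
  p <- 5
  b <- substring(bad$sequence, p, p)
  bad$sequence <- paste0(substring(bad$sequence, 1, p - 1),
                         setdiff(c("A", "C", "G", "T"), b)[1],
                         substring(bad$sequence, p + 1, nchar(bad$sequence)))
  trb <- trim_primers(bad, t$primers)
  expect_false(trb$accepted)
  expect_equal(trb$reason, "no_forward_primer")
  # quality filtering only acts when quality is present
  reads$mean_quality <- c(5, rep(30, nrow(reads) - 1))
  expect_equal(nrow(filter_quality(reads, 10)), nrow(reads) - 1)
  reads$mean_quality <- NULL
  expect_equal(nrow(filter_quality(reads, 10)), nrow(reads))
})

test_that("greedy clustering matches the brute-force oracle on small sets", {
  withr::with_seed(31, {
    base1 <- random_dna(120)
    # second group at ~90% identity to the first
    base2 <- strsplit(base1, "")[[1]]
    for (p in sample(120, 12)) base2[p] <- sample(c("A","C","G","T"), 1)
    base2 <- paste(base2, collapse = "")
    mutate1 <- function(s) {
      ch <- strsplit(s, "")[[1]]
      p <- sample(length(ch), 1)
      ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    seqs <- c(vapply(1:20, function(i) mutate1(base1), character(1)),
              vapply(1:20, function(i) mutate1(base2), character(1)))
    ids <- sprintf("s1:r%02d", seq_along(seqs))
    cl <- greedy_cluster(tibble::tibble(id = ids, sample = "s1",
                                        sequence = seqs), threshold = 0.95)
    expect_equal(nrow(cl), 2)
    oracle <- oracle_greedy(seqs, ids, 0.95)
    expect_equal(unname(cl$members), unname(oracle))
    # every member reaches threshold identity to its centroid (post hoc)
    seq_of <- setNames(seqs, ids)
    for (i in seq_len(nrow(cl))) {
      cent <- seq_of[[cl$centroid_id[i]]]
      ok <- vapply(cl$members[[i]], function(id) {
        global_identity(seq_of[[id]], cent) >= 0.95
      }, logical(1))
      expect_true(all(ok))
    }
    # partition: disjoint and exhaustive
    expect_setequal(unlist(cl$members), ids)
    expect_equal(sum(cl$n_members), length(ids))
  })
  # identical reads collapse to one cluster
  same <- tibble::tibble(id = sprintf("s:%d", 1:5), sample = "s",
                         sequence = strrep("ACGT", 30))
  expect_equal(nrow(greedy_cluster(same)), 1)
})

test_that("greedy/oracle equivalence holds on random noisy mixtures", {
  toy <- toy_plus()
  t <- toy$truth
  withr::with_seed(77, {
    for (rep in 1:5) {
      iso <- sample(names(t$amplicon_inserts), 40, replace = TRUE)
      seqs <- crypticex:::mutate_seqs(unname(t$amplicon_inserts[iso]), 0.01)
      ids <- sprintf("s1:x%02d", seq_along(seqs))
      cl <- greedy_cluster(tibble::tibble(id = ids, sample = "s1",
                                          sequence = seqs), 0.98)
      oracle <- oracle_greedy(seqs, ids, 0.98)
      expect_equal(unname(cl$members), unname(oracle))
    }
  })
})

test_that("significance uses a strict per-sample fraction rule", {
  mk <- function(counts_a, counts_b) {
    structure(tibble::tibble(
      cluster_id = 0:1, centroid_id = c("a", "b"), n_members = c(
        sum(counts_a), sum(counts_b)),
      mean_length = c(100, 100),
      members = list(character(sum(counts_a)), character(sum(counts_b))),
      counts = list(as.table(counts_a), as.table(counts_b))),
      class = c("amplicon_clusters", "tbl_df", "tbl", "data.frame"),
      threshold = 0.98, centroid_seqs = c("A", "B"))
  }
  totals <- c(sA = 100, sB = 100)
  cl <- mk(c(sA = 11, sB = 0), c(sA = 10, sB = 10))
  sig <- significant_clusters(cl, totals, 0.10)
  expect_equal(sig$cluster_id, 0L)  # 11% kept, exactly 10% dropped
  # singleton noise among 1000-read samples never reaches 10%
  noise <- mk(c(sA = 1, sB = 0), c(sA = 0, sB = 1))
  expect_equal(nrow(significant_clusters(noise, c(sA = 1000, sB = 1000))), 0)
  # zero-total samples are excluded from the test
  sig2 <- significant_clusters(cl, c(totals, sC = 0), 0.10)
  expect_equal(sig2$cluster_id, 0L)
})

test_that("cluster classification separates case-only from shared", {
  inv <- amplicon_cluster_inventory(toy_plus(), error_rate = 0, seed = 33)
  expect_equal(nrow(inv$inventory), 4)
  expect_setequal(inv$inventory$class[inv$inventory$mean_length > 350],
                  "case_only")
  expect_setequal(inv$inventory$class[inv$inventory$mean_length < 350],
                  "shared")
  # degenerate: no control arm
  design <- tibble::tibble(sample = c("case01", "case02"),
                           role = c("case", "case"))
  expect_warning(classify_clusters(inv$clusters, design), "no control")
})

test_that("consensus equals the planted amplicon insert", {
  toy <- toy_plus()
  t <- toy$truth
  # error-free cluster: consensus is exactly the planted insert
  inv0 <- amplicon_cluster_inventory(toy, error_rate = 0, seed = 41)
  cons0 <- cluster_consensus(inv0$clusters, inv0$accepted, seed = 1)
  lens <- vapply(cons0$consensus, nchar, integer(1))
  expect_setequal(unname(lens), c(306L, 306L, 398L, 541L))
  expect_true(all(cons0$consensus %in% unname(t$amplicon_inserts)))
  # 1% error, 25 members: majority vote recovers the template
  for (s in 1:5) {
    inv <- amplicon_cluster_inventory(toy, seed = 100 + s)
    cons <- cluster_consensus(inv$clusters, inv$accepted, k = 25,
                              seed = 200 + s)
    big <- which(inv$inventory$n_members >= 25)
    expect_true(all(cons$consensus[big] %in% unname(t$amplicon_inserts)))
  }
  # single-member cluster: consensus is that member
  one <- tibble::tibble(id = "s:1", sample = "s", sequence = random_dna(80))
  cl1 <- greedy_cluster(one)
  c1 <- cluster_consensus(cl1, one, seed = 3)
  expect_equal(c1$consensus, one$sequence)
})

test_that("consensus mapping recovers exon structure and boundaries", {
  toy <- toy_plus()
  t <- toy$truth
  st_can <- map_consensus(unname(t$amplicon_inserts[["canonical_a"]]),
                          toy$reference, toy$gene)
  expect_equal(nrow(st_can$novel_blocks), 0)
  expect_equal(nrow(st_can$extended_boundaries), 0)
  expect_equal(st_can$exon_intervals$exon, 2:5)
  # interior exons are matched over their full annotated span
  expect_equal(st_can$exon_intervals$start[2:3], toy$gene$exons$start[3:4])
  expect_equal(st_can$exon_intervals$end[2:3], toy$gene$exons$end[3:4])
  # the second canonical haplotype (8 SNVs) maps to the same structure
  st_b <- map_consensus(unname(t$amplicon_inserts[["canonical_b"]]),
                        toy$reference, toy$gene)
  expect_equal(st_b$exon_intervals$exon, 2:5)
  expect_equal(nrow(st_b$novel_blocks), 0)
  # cryptic consensus: one novel block, boundary-exact
  st_cry <- map_consensus(unname(t$amplicon_inserts[["cryptic"]]),
                          toy$reference, toy$gene)
  iv <- t$cryptic_exon_interval
  expect_equal(nrow(st_cry$novel_blocks), 1)
  expect_equal(st_cry$novel_blocks$start, unname(iv[["start"]]))
  expect_equal(st_cry$novel_blocks$end, unname(iv[["end"]]))
  # extended consensus adds the 143 bp 5' extension of the downstream exon
  st_ext <- map_consensus(unname(t$amplicon_inserts[["cryptic_extended"]]),
                          toy$reference, toy$gene)
  expect_equal(st_ext$extended_boundaries$exon, 3)
  expect_equal(st_ext$extended_boundaries$side, "5prime")
  expect_equal(st_ext$extended_boundaries$shift, 143)
  expect_equal(st_ext$novel_blocks$start, unname(iv[["start"]]))
  # an unrelated sequence is unmappable
  withr::with_seed(5, expect_error(
    map_consensus(random_dna(300), toy$reference, toy$gene), "unmappable"))
})

test_that("predicted amplicon lengths follow the isoform structures", {
  toy <- toy_plus()
  lens <- predict_amplicon_lengths(toy$truth$isoforms, toy$reference,
                                   toy$gene, toy$truth$primers)
  expect_equal(unname(lens), c(306, 398, 541))
  expect_equal(length(predict_amplicon_lengths(list(), toy$reference,
                                               toy$gene, toy$truth$primers)), 0)
  # isoform missing the primer exons is skipped with a warning
  no_primer <- list(partial = toy$gene$exons[3:4, c("start", "end")])
  expect_warning(out <- predict_amplicon_lengths(no_primer, toy$reference,
                                                 toy$gene, toy$truth$primers),
                 "primer")
  expect_true(is.na(out[["partial"]]))
})
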