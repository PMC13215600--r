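write_test_vcf <- function(lines, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")
  writeLines(c(header, lines), path)
  path
}

test_that("VCF parsing keeps genotypes, splits multiallelics, flags lines", {
  d <- withr::local_tempdir()
  f <- write_test_vcf(c(
    "11\t6963986\t.\tC\tT\t50\tPASS\tANN=T|synonymous_variant|LOW|FADS6\tGT\t1/1\t0/1\t0/0",
    "11\t7000000\t.\tG\tT,C\t50\tPASS\t.\tGT\t1/2\t0/2\t./.",
    "11\t7000010\t.\tA\tG\t50\tPASS\t.\tGT\t0|1\t1|1\t0/0"),
    file.path(d, "a.vcf"))
  v <- parse_vcf(f)
  expect_equal(nrow(v), 4)  # multiallelic split into two records
  expect_equal(v$gt[[1]], c(s1 = "homalt", s2 = "het", s3 = "homref"))
  expect_equal(v$ann[[1]]$impact, "LOW")
  expect_equal(v$ann[[1]]$gene, "FADS6")
  # split alleles share the position; genotypes recoded per allele
  split_rows <- v[v$pos == 7000000, ]
  expect_equal(split_rows$alt, c("T", "C"))
  expect_equal(split_rows$gt[[1]], c(s1 = "het", s2 = "homref", s3 = "missing"))
  expect_equal(split_rows$gt[[2]], c(s1 = "het", s2 = "het", s3 = "missing"))
  # phased genotypes are read like unphased
  expect_equal(v$gt[[4]][["s1"]], "het")

  bad <- file.path(d, "bad.vcf")
  writeLines(c(readLines(f), "11\tnotanumber\t.\tA\tC\t1\tPASS\t.\tGT\t0/0\t0/0\t0/0"),
             bad)
  expect_error(parse_vcf(bad), "line 8")
})

test_that("ANN parsing follows the Allele|Effect|Impact|Gene layout", {
  a <- parse_ann("T|intron_variant|MODIFIER|FDXR")
  expect_equal(a$impact, "MODIFIER")
  expect_equal(a$gene, "FDXR")
  b <- parse_ann("T|synonymous_variant|LOW|FADS6,G|missense_variant|MODERATE|FDXR")
  expect_equal(nrow(b), 2)
  expect_equal(b$impact, c("LOW", "MODERATE"))
  expect_equal(nrow(parse_ann("")), 0)
  expect_equal(nrow(parse_ann(NA)), 0)
  expect_error(parse_ann("T|x|BOGUS|g"), "unknown impact")
})

test_that("allelic Fisher test equals hypergeometric enumeration", {
  expect_equal(allelic_fisher(2, 0, 0, 2), 1/3)
  expect_equal(allelic_fisher(5, 5, 5, 5), 1)
  expect_equal(allelic_fisher(14, 0, 0, 64), 1 / choose(78, 14))
  expect_equal(allelic_fisher(0, 0, 0, 0), 1)
  # oracle: stats::fisher.test on random tables with margins <= 60
  withr::with_seed(21, {
    for (i in 1:200) {
      m <- sample(0:30, 4, replace = TRUE)
      if (sum(m) == 0) next
      p_ref <- stats::fisher.test(matrix(m, 2, byrow = TRUE))$p.value
      expect_equal(allelic_fisher(m[1], m[2], m[3], m[4]), p_ref,
                   tolerance = 1e-6)
    }
  })
})

test_that("recessive segregation filter matches a brute-force predicate scan", {
  toy <- toy_plus()
  design <- cohort_design(4, 2, 10, 2)
  variants <- simulate_candidate_variants(toy, n_decoys = 60, seed = 8)
  g <- simulate_cohort_genotypes(design, variants, q_background = 0.3, seed = 9)
  d <- withr::local_tempdir()
  f <- file.path(d, "cohort.vcf")
  write_cohort_vcf(variants, g, f)
  v <- parse_vcf(f)
  # sprinkle missing genotypes deterministically
  withr::with_seed(10, {
    v$gt <- lapply(v$gt, function(x) {
      x[sample(length(x), 1)] <- ifelse(runif(1) < 0.2, "missing",
                                        x[sample(length(x), 1)])
      x
    })
  })
  for (allow in c(FALSE, TRUE)) {
    kept <- recessive_segregation_filter(v, design, allow_missing = allow)
    oracle <- vapply(v$gt, function(x) {
      ok <- TRUE
      for (i in seq_len(nrow(design))) {
        gt <- x[[design$sample[i]]]
        role <- design$role[i]
        if (role == "unknown") next
        if (gt == "missing") { if (!allow) ok <- FALSE; next }
        if (role == "case" && gt != "homalt") ok <- FALSE
        if (role == "obligate_carrier" && gt != "het") ok <- FALSE
        if (role == "control" && gt == "homalt") ok <- FALSE
      }
      ok
    }, logical(1))
    expect_equal(paste(kept$chrom, kept$pos, kept$alt),
                 paste(v$chrom, v$pos, v$alt)[oracle])
  }
  # hand cases: a het case or hom-alt control defeats the predicate
  v2 <- v[1, ]
  v2$gt[[1]][design$sample[design$role == "case"]] <- "homalt"
  v2$gt[[1]][design$sample[design$role == "obligate_carrier"]] <- "het"
  v2$gt[[1]][design$sample[design$role == "control"]] <- "homref"
  expect_equal(nrow(recessive_segregation_filter(v2, design)), 1)
  v2$gt[[1]][design$sample[design$role == "case"][1]] <- "het"
  expect_equal(nrow(recessive_segregation_filter(v2, design)), 0)
  v2$gt[[1]][design$sample[design$role == "case"][1]] <- "homalt"
  v2$gt[[1]][design$sample[design$role == "control"][1]] <- "homalt"
  expect_equal(nrow(recessive_segregation_filter(v2, design)), 0)
})

test_that("impact and cross-population filters are idempotent and ordered", {
  tbl <- ejsca_region_variants_synthetic(77, seed = 3)
  v <- tbl$variants
  v$ann <- purrr::pmap(v[, c("alt", "gene", "effect", "impact")],
                       function(alt, gene, effect, impact) {
                         tibble::tibble(allele = alt, gene = gene,
                                        effect = effect, impact = impact)
                       })
  kept <- impact_filter(v, c("HIGH", "MODERATE"))
  expect_true(all(kept$impact %in% c("HIGH", "MODERATE")))
  expect_identical(impact_filter(v), v)  # all four classes = identity
  expect_identical(impact_filter(kept, c("HIGH", "MODERATE")), kept)
  expect_false(is.unsorted(match(paste(kept$pos, kept$alt),
                                 paste(v$pos, v$alt))))

  ex <- cross_population_exclude(v, tbl$observations, "QuarterHorse")
  expect_equal(nrow(ex), 9)
  expect_false(any(ex$synthetic))
  expect_identical(cross_population_exclude(ex, tbl$observations,
                                            "QuarterHorse"), ex)
  # observation in the home breed does not exclude; absent variants kept
  own <- tibble::tibble(chrom = v$chrom[1], pos = v$pos[1], alt = v$alt[1],
                        breed = "QuarterHorse")
  expect_equal(nrow(cross_population_exclude(v[1, ], own, "QuarterHorse")), 1)
  expect_equal(nrow(cross_population_exclude(v[1, ],
                                             own[0, ], "QuarterHorse")), 1)
})

test_that("candidate region spans the published variant table", {
  region <- define_candidate_region(ejsca_candidate_variants())
  expect_equal(region$chrom, "11")
  expect_equal(region$start, 6963986)
  expect_equal(region$end, 7045999)
  expect_equal(region$span, 82013)
  one <- define_candidate_region(tibble::tibble(chrom = "1", pos = 5))
  expect_equal(one$span, 0)
  two <- define_candidate_region(tibble::tibble(chrom = "1", pos = c(7, 8)))
  expect_equal(two$span, 1)
  expect_error(define_candidate_region(
    tibble::tibble(chrom = c("1", "2"), pos = c(1, 2))), "multiple chromosomes")
})

test_that("HGVS intronic names anchor to the nearer exon boundary", {
  toy <- toy_plus()
  t <- toy$truth
  h <- hgvs_intronic_name(list(pos = t$variant_position, ref = t$variant_ref,
                               alt = t$variant_alt), toy$gene)
  expect_equal(h$rendered, "c.177+1778G>C")
  expect_equal(h$anchor_cdna_pos, 177)
  expect_equal(h$offset, 1778)
  # small hand-built gene: exon1 [101,160] (cds from 121), exon2 [1161,1220]
  gm <- gene_model("c", "G", "G-1", "+",
                   tibble::tibble(start = c(101, 1161), end = c(160, 1220)),
                   cds_tx_start = 21, cds_length = 99)
  # 1 bp after exon 1 (cDNA ends at 60 - 20 = 40)
  h1 <- hgvs_intronic_name(list(pos = 161, ref = "A", alt = "T"), gm)
  expect_equal(h1$rendered, "c.40+1A>T")
  # 5 bp before exon 2 (first coding base of exon 2 is c.41)
  h2 <- hgvs_intronic_name(list(pos = 1156, ref = "G", alt = "A"), gm)
  expect_equal(h2$rendered, "c.41-5G>A")
  expect_error(hgvs_intronic_name(list(pos = 150, ref = "A", alt = "T"), gm),
               "exonic")
  # minus strand: alleles are complemented onto the coding strand
  tm <- toy_minus()$truth
  hm <- hgvs_intronic_name(list(pos = tm$variant_position, ref = tm$variant_ref,
                                alt = tm$variant_alt), toy_minus()$gene)
  expect_equal(hm$rendered, "c.177+1778G>C")
})
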