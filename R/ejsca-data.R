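# Published summary data for the EJSCA (equine juvenile spinocerebellar
# ataxia) mapping study that this package's methods are modelled on, plus a
# synthetic stand-in for the study's full 77-variant association table.

#' The nine EJSCA candidate variants
#'
#' The nine single-nucleotide variants associated with equine juvenile
#' spinocerebellar ataxia by whole-genome sequencing of Quarter Horses
#' (EquCab3.0, chromosome 11), spanning *FADS6*, *FDXR*, *GRIN2C* and
#' *TMEM104*. These are the variants left after recessive segregation,
#' allelic association at p < 1e-11, and exclusion of alleles observed in
#' other breeds; the *FDXR* intronic variant at chr11:6973334 (G>C,
#' *FDXR-203* c.177+1778G>C) is the disease variant.
#'
#' @return tibble: `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`, `impact`,
#'   `p_allelic`.
#' @export
ejsca_candidate_variants <- function() {
  tibble(
    chrom = "11",
    pos = c(6963986L, 6973334L, 6973640L, 6976294L, 6976720L,
            6991960L, 7024027L, 7025248L, 7045999L),
    ref = c("C", "G", "T", "C", "C", "A", "C", "C", "C"),
    alt = c("T", "C", "C", "T", "T", "G", "T", "T", "G"),
    gene = c("FADS6", "FDXR", "FDXR", "FDXR", "FDXR",
             "GRIN2C", "TMEM104", "TMEM104", "TMEM104"),
    effect = c("synonymous_variant", rep("intron_variant", 8)),
    impact = c("LOW", rep("MODIFIER", 8)),
    p_allelic = 2.99e-12)
}

#' Synthetic stand-in for the EJSCA 77-variant association table
#'
#' The study's full supplementary table of 77 associated variants is not
#' redistributable here, so this builds a synthetic equivalent: the nine
#' published candidate variants plus `n_total - 9` synthetic decoy SNVs drawn
#' uniformly over the published 82 kb candidate region, each decoy marked as
#' observed in at least one other breed. Applying
#' [cross_population_exclude()] to it therefore reproduces the published
#' filtering outcome (9 of 77 retained) on synthetic positions.
#'
#' @param n_total total number of variants (>= 9).
#' @param seed integer seed.
#' @return list with `variants` (tibble, column `synthetic` flags decoys) and
#'   `observations` (tibble `chrom`, `pos`, `alt`, `breed` of cross-breed
#'   sightings).
#' @export
ejsca_region_variants_synthetic <- function(n_total = 77, seed = 1L) {
  real <- mutate(ejsca_candidate_variants(), synthetic = FALSE)
  cx_assert(n_total >= nrow(real), "`n_total` must be at least 9")
  n_decoy <- n_total - nrow(real)
  with_seed(seed, {
    pos <- sample(setdiff(seq(min(real$pos), max(real$pos)), real$pos),
                  n_decoy)
    ref <- sample(BASES, n_decoy, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
    decoys <- tibble(
      chrom = "11", pos = sort(pos), ref = ref, alt = unname(alt),
      gene = sample(c("FADS6", "FDXR", "GRIN2C", "TMEM104"), n_decoy,
                    replace = TRUE),
      effect = sample(c("intron_variant", "missense_variant",
                        "synonymous_variant"), n_decoy, replace = TRUE,
                      prob = c(0.8, 0.1, 0.1)))
    decoys$impact <- dplyr::case_when(
      decoys$effect == "missense_variant" ~ "MODERATE",
      decoys$effect == "synonymous_variant" ~ "LOW",
      TRUE ~ "MODIFIER")
    decoys$p_allelic <- 2.99e-12
    decoys$synthetic <- TRUE
    obs <- tibble(chrom = decoys$chrom, pos = decoys$pos, alt = decoys$alt,
                  breed = sample(c("Arabian", "Thoroughbred", "Standardbred"),
                                 n_decoy, replace = TRUE))
    list(variants = arrange(bind_rows(real, decoys), .data$pos),
         observations = obs)
  })
}
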