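# Cohort, read and panel simulators. Every generator takes one integer seed
# and leaves the caller's RNG stream untouched.

#' Define a case/carrier/control cohort
#'
#' @param n_case,n_carrier,n_control,n_unknown cohort arm sizes. Carriers are
#'   obligate carriers (parents of affected individuals under recessive
#'   inheritance); unknowns are excluded from segregation predicates and
#'   association counts.
#' @return a tibble with columns `sample`, `role`.
#' @export
cohort_design <- function(n_case = 7, n_carrier = 4, n_control = 32,
                          n_unknown = 0) {
  cx_assert(n_case >= 1, "a cohort needs at least one case")
  tibble(
    sample = c(sprintf("case%02d", seq_len(n_case)),
               sprintf("carrier%02d", seq_len0(n_carrier)),
               sprintf("ctrl%02d", seq_len0(n_control)),
               sprintf("unk%02d", seq_len0(n_unknown))),
    role = c(rep("case", n_case), rep("obligate_carrier", n_carrier),
             rep("control", n_control), rep("unknown", n_unknown)))
}

seq_len0 <- function(n) if (n == 0) integer() else seq_len(n)

validate_design <- function(design) {
  cx_assert(all(c("sample", "role") %in% names(design)),
            "design needs columns sample, role")
  cx_assert(all(design$role %in%
                  c("case", "obligate_carrier", "control", "unknown")),
            "unknown role in design")
  cx_assert(sum(design$role == "case") >= 1, "design needs at least one case")
  cx_assert(!anyDuplicated(design$sample), "duplicate sample names")
  invisible(design)
}

#' Simulate a candidate-variant table for a toy locus
#'
#' Produces the planted causal SNV plus `n_decoys` decoy SNVs scattered over
#' the contig, each with a population alternate-allele frequency and a
#' SnpEff-style annotation (gene, effect, impact).
#'
#' @param toy output of [build_toy_locus()].
#' @param n_decoys number of decoy variants.
#' @param decoy_freq_range range of decoy alternate-allele frequencies.
#' @param seed integer seed.
#' @return tibble with columns chrom, pos, ref, alt, causal, alt_freq, gene,
#'   effect, impact.
#' @export
simulate_candidate_variants <- function(toy, n_decoys = 50,
                                        decoy_freq_range = c(0.05, 0.4),
                                        seed = 1L) {
  truth <- toy$truth
  contig <- toy$gene$contig
  ref_seq <- unname(toy$reference[[1]])
  with_seed(seed, {
    pos <- sort(sample(seq_len(nchar(ref_seq)), n_decoys))
    if (!is.null(truth$variant_position))
      pos <- setdiff(pos, truth$variant_position)
    ref <- if (length(pos)) substring(ref_seq, pos, pos) else character()
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
    decoys <- tibble(
      chrom = contig, pos = pos, ref = ref, alt = unname(alt),
      causal = FALSE,
      alt_freq = runif(length(pos), decoy_freq_range[1], decoy_freq_range[2]),
      gene = sample(c("TOYG", "NBRG1", "NBRG2"), length(pos), replace = TRUE),
      effect = sample(c("intron_variant", "synonymous_variant",
                        "missense_variant", "intergenic_region"),
                      length(pos), replace = TRUE))
    decoys$impact <- dplyr::case_when(
      decoys$effect == "missense_variant" ~ "MODERATE",
      decoys$effect == "synonymous_variant" ~ "LOW",
      TRUE ~ "MODIFIER")
    causal <- if (is.null(truth$variant_position)) NULL else
      tibble(chrom = contig, pos = truth$variant_position,
             ref = truth$variant_ref, alt = truth$variant_alt,
             causal = TRUE, alt_freq = NA_real_, gene = "TOYG",
             effect = "intron_variant", impact = "MODIFIER")
    out <- arrange(bind_rows(causal, decoys), .data$pos)
    cx_assert(nrow(out) >= 1, "no variants to simulate")
    out
  })
}

#' Simulate cohort genotypes
#'
#' The causal variant segregates perfectly: cases are homozygous alternate,
#' obligate carriers heterozygous, controls carry the alternate allele at the
#' background frequency `q_background` with hom-alt genotypes excluded (a
#' rare, fully penetrant recessive allele); unknowns are drawn at
#' `q_background` without constraint. Decoy variants are drawn independently
#' for every sample from Hardy-Weinberg at their own `alt_freq`.
#'
#' @param design a [cohort_design()] tibble.
#' @param variants variant table as from [simulate_candidate_variants()].
#' @param q_background background alternate-allele frequency in controls for
#'   the causal variant (in `[0, 0.5]`).
#' @param seed integer seed.
#' @return long tibble: `chrom`, `pos`, `alt`, `sample`, `gt` (one of homref,
#'   het, homalt, missing).
#' @export
simulate_cohort_genotypes <- function(design, variants, q_background = 0.012,
                                      seed = 1L) {
  validate_design(design)
  cx_assert(q_background >= 0 && q_background <= 0.5,
            "`q_background` must be in [0, 0.5]")
  with_seed(seed, {
    res <- purrr::pmap(variants, function(chrom, pos, ref, alt, causal,
                                          alt_freq, ...) {
      gt <- if (isTRUE(causal)) {
        draw_causal_gt(design$role, q_background)
      } else {
        draw_hwe_gt(nrow(design), alt_freq)
      }
      tibble(chrom = chrom, pos = pos, alt = alt, sample = design$sample,
             gt = gt)
    })
    bind_rows(res)
  })
}

draw_hwe_gt <- function(n, q) {
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  c("homref", "het", "homalt")[sample.int(3, n, replace = TRUE, prob = p)]
}

draw_causal_gt <- function(roles, q) {
  vapply(roles, function(r) {
    switch(r,
      case = "homalt",
      obligate_carrier = "het",
      control = {
        # Hardy-Weinberg conditional on not hom-alt
        if (q == 0) "homref"
        else if (runif(1) < 2 * q * (1 - q) / (1 - q^2)) "het" else "homref"
      },
      unknown = draw_hwe_gt(1, q))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate spliced-read block records
#'
#' Each simulated read covers the full exon chain of its source isoform, so
#' its block structure equals the isoform's exon intervals (the idealised
#' output of a spliced aligner collapsed to block evidence).
#'
#' @param gene a [gene_model()] (provides contig and strand).
#' @param isoforms named list of block tibbles (`start`, `end`), as recorded
#'   in the planted truth.
#' @param weights_per_sample named list: sample -> named non-negative weights
#'   over isoform names.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return long tibble: `read_id`, `sample`, `isoform`, `chrom`, `start`,
#'   `end` (one row per block).
#' @export
simulate_spliced_reads <- function(gene, isoforms, weights_per_sample,
                                   depth = 100, seed = 1L) {
  cx_assert(length(weights_per_sample) >= 1, "need at least one sample")
  for (w in weights_per_sample) {
    cx_assert(all(w >= 0) && sum(w) > 0 && all(names(w) %in% names(isoforms)),
              "weights must be non-negative over known isoforms")
  }
  with_seed(seed, {
    out <- purrr::imap(weights_per_sample, function(w, s) {
      pick <- sample(names(w), depth, replace = TRUE, prob = w)
      purrr::imap_dfr(setNames(pick, seq_along(pick)), function(iso, i) {
        blocks <- arrange(isoforms[[iso]], .data$start)
        tibble(read_id = sprintf("%s:r%04d", s, as.integer(i)), sample = s,
               isoform = iso, chrom = gene$contig,
               start = blocks$start, end = blocks$end)
      })
    })
    bind_rows(out)
  })
}

#' Simulate long-read amplicon FASTQ records
#'
#' Reads are `forward primer + insert + reverse-complement(reverse primer)`,
#' with i.i.d. substitution errors applied to the insert. A configurable
#' fraction of reads carries a single-base corruption inside a primer
#' footprint (to exercise exact-primer rejection), and each read is emitted
#' in forward or reverse orientation with equal probability.
#'
#' @param mixtures named list: sample -> named fractions over insert names
#'   (each summing to 1).
#' @param inserts named character vector of insert sequences (from the
#'   planted truth).
#' @param primers named character vector `c(forward=, reverse=)`.
#' @param error_rate per-base substitution probability on the insert.
#' @param corrupt_primer_frac fraction of reads with a corrupted primer base.
#' @param n_reads reads per sample.
#' @param seed integer seed.
#' @return tibble: `id`, `sample`, `isoform`, `orientation`, `sequence`,
#'   `mean_quality`.
#' @export
simulate_amplicon_reads <- function(mixtures, inserts, primers,
                                    error_rate = 0.01,
                                    corrupt_primer_frac = 0,
                                    n_reads = 1000, seed = 1L) {
  cx_assert(length(mixtures) >= 1, "empty mixture")
  for (m in mixtures) {
    cx_assert(length(m) >= 1 && abs(sum(m) - 1) < 1e-8 &&
                all(names(m) %in% names(inserts)),
              "each mixture must sum to 1 over known inserts")
  }
  fwd <- unname(primers[["forward"]])
  rev_rc <- revcomp(unname(primers[["reverse"]]))
  with_seed(seed, {
    out <- purrr::imap(mixtures, function(m, s) {
      iso <- sample(names(m), n_reads, replace = TRUE, prob = m)
      ins <- mutate_seqs(unname(inserts[iso]), error_rate)
      reads <- paste0(fwd, ins, rev_rc)
      corrupt <- runif(n_reads) < corrupt_primer_frac
      if (any(corrupt)) {
        reads[corrupt] <- vapply(reads[corrupt], corrupt_primer_base,
                                 character(1), fwd_len = nchar(fwd),
                                 rev_len = nchar(rev_rc))
      }
      flipped <- runif(n_reads) < 0.5
      reads[flipped] <- revcomp(reads[flipped])
      tibble(id = sprintf("%s:%s:a%05d", s, iso, seq_len(n_reads)),
             sample = s, isoform = iso,
             orientation = ifelse(flipped, "reverse", "forward"),
             sequence = reads, mean_quality = 20)
    })
    bind_rows(out)
  })
}

# i.i.d. substitutions at `rate` on each sequence
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# flip one base inside a randomly chosen primer footprint
corrupt_primer_base <- function(read, fwd_len, rev_len) {
  L <- nchar(read)
  p <- if (runif(1) < 0.5) sample.int(fwd_len, 1) else L - sample.int(rev_len, 1) + 1L
  b <- substring(read, p, p)
  splice_into(read, p, sample(setdiff(BASES, b), 1))
}

#' Simulate a carrier-screening genotyping panel
#'
#' Genotypes are drawn from Hardy-Weinberg proportions at allele frequency
#' `q`. With `exclude_homalt`, hom-alt draws are redrawn conditional on not
#' being hom-alt, emulating ascertainment of presumed-unaffected animals for
#' a fully penetrant recessive disease.
#'
#' @param n panel size.
#' @param q disease-allele frequency.
#' @param seed integer seed.
#' @param exclude_homalt redraw hom-alt genotypes?
#' @return a [genotype_counts()] object.
#' @export
simulate_panel <- function(n, q, seed = 1L, exclude_homalt = FALSE) {
  cx_assert(n >= 1, "panel size must be >= 1")
  cx_assert(q >= 0 && q <= 1, "`q` must be a frequency")
  with_seed(seed, {
    gt <- draw_hwe_gt(n, q)
    if (exclude_homalt && q < 1) {
      idx <- which(gt == "homalt")
      if (length(idx))
        gt[idx] <- ifelse(runif(length(idx)) < 2 * q * (1 - q) / (1 - q^2),
                          "het", "homref")
    }
    genotype_counts(n_het = sum(gt == "het"), n_homalt = sum(gt == "homalt"),
                    n_total = n)
  })
}
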