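# End-to-end orchestration: simulate -> segregate -> cryptic -> amplicon ->
# translate -> allele frequency, with a manifest and a reproducible report.

#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end run. Defaults are
#' the package's standard study conditions: a 7/4/32 case/carrier/control
#' WGS cohort, RNA evidence for 5 cases and 6 controls, amplicon sequencing
#' of 2 cases and 4 controls at 1,000 reads per sample with 1% substitution
#' error, 98% clustering identity, the strict >10% per-sample significance
#' rule, 25-member consensus subsamples, and a 1,060-animal screening panel
#' at q = 0.0118.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; each stage derives its own stream from it.
#' @param locus a [locus_spec()].
#' @param design a [cohort_design()] tibble.
#' @param q_background control-arm background allele frequency of the causal
#'   variant.
#' @param n_decoys decoy variants in the cohort VCF.
#' @param obs_other_breed_frac fraction of decoys recorded as observed in
#'   other breeds in the external-observation table.
#' @param p_threshold allelic association p-value cutoff.
#' @param impacts impact classes retained by the impact screen.
#' @param home_breed breed label for cross-population exclusion.
#' @param rnaseq_depth spliced reads per RNA sample.
#' @param rnaseq_cases,rnaseq_controls RNA cohort sizes (taken from the top of
#'   each arm).
#' @param amplicon_cases,amplicon_controls amplicon cohort sizes.
#' @param amplicon_reads amplicon reads per sample.
#' @param error_rate amplicon per-base substitution rate.
#' @param corrupt_primer_frac fraction of amplicon reads with a corrupted
#'   primer base.
#' @param case_mixture,control_mixture named isoform-mixture fractions for the
#'   amplicon arms (over the planted insert names).
#' @param subsample_n amplicon subsampling depth per sample.
#' @param identity clustering identity threshold.
#' @param sig_frac significance fraction (strict `>`).
#' @param consensus_k consensus subsample size.
#' @param min_case_reads,max_control_fraction cryptic-exon call thresholds.
#' @param classify_min_reads per-sample occupancy for cluster classification.
#' @param panel_n,panel_q screening-panel size and allele frequency.
#' @return a `cx_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("crypticex_run_"),
                            seed = 1L,
                            locus = locus_spec(),
                            design = cohort_design(),
                            q_background = 0.012,
                            n_decoys = 50,
                            obs_other_breed_frac = 0.9,
                            p_threshold = 1e-11,
                            impacts = c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                            home_breed = "QuarterHorse",
                            rnaseq_depth = 200,
                            rnaseq_cases = 5, rnaseq_controls = 6,
                            amplicon_cases = 2, amplicon_controls = 4,
                            amplicon_reads = 1000,
                            error_rate = 0.01,
                            corrupt_primer_frac = 0.02,
                            case_mixture = c(canonical_a = 0.2,
                                             canonical_b = 0.2,
                                             cryptic = 0.3,
                                             cryptic_extended = 0.3),
                            control_mixture = c(canonical_a = 0.5,
                                                canonical_b = 0.5),
                            subsample_n = 100000,
                            identity = 0.98,
                            sig_frac = 0.10,
                            consensus_k = 25,
                            min_case_reads = 10,
                            max_control_fraction = 0.05,
                            classify_min_reads = 5,
                            panel_n = 1060, panel_q = 0.0118) {
  validate_design(design)
  cx_assert(all(c(identity, sig_frac, max_control_fraction) > 0) &&
              all(c(identity, sig_frac, max_control_fraction) <= 1),
            "fractional thresholds must be in (0, 1]")
  cx_assert(p_threshold > 0 && p_threshold <= 1,
            "`p_threshold` must be in (0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "cx_config")
}

#' Run the full pipeline
#'
#' Executes all stages in order, writing per-stage artifacts and a manifest
#' under `config$out_dir`. Reruns with an identical configuration are
#' byte-identical. A stage failure halts the run with the stage name and
#' cause; artifacts written so far are retained.
#'
#' @param config a [pipeline_config()].
#' @return a `cx_report` list with sections `candidates`, `region`, `hgvs`,
#'   `cryptic_calls`, `variant_offset`, `clusters`, `consensus`,
#'   `coding`, `allele_frequency`, `truth`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cx_assert(inherits(config, "cx_config"), "`config` must be a pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, params, outputs = character()) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage,
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
      outputs = paste(outputs, collapse = ";"))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   class = "crypticex_stage_error")
    })
  }
  p <- function(f) file.path(config$out_dir, f)

  ## stage 1: simulate -----------------------------------------------------
  sim <- run_stage("simulate", {
    toy <- build_toy_locus(config$locus)
    variants <- simulate_candidate_variants(toy, config$n_decoys,
                                            seed = derive_seed(config$seed, 1))
    genotypes <- simulate_cohort_genotypes(config$design, variants,
                                           config$q_background,
                                           seed = derive_seed(config$seed, 2))
    obs <- with_seed(derive_seed(config$seed, 3), {
      d <- filter(variants, !.data$causal)
      seen <- runif(nrow(d)) < config$obs_other_breed_frac
      tibble(chrom = d$chrom[seen], pos = d$pos[seen], alt = d$alt[seen],
             breed = sample(c("BreedA", "BreedB", "BreedC"), sum(seen),
                            replace = TRUE))
    })
    rna_samples <- c(
      head(config$design$sample[config$design$role == "case"],
           config$rnaseq_cases),
      head(config$design$sample[config$design$role == "control"],
           config$rnaseq_controls))
    iso <- toy$truth$isoforms
    w_case <- if (length(iso) > 1) {
      c(canonical = 0.5, cryptic = 0.3, cryptic_extended = 0.2)[names(iso)]
    } else c(canonical = 1)
    weights <- lapply(setNames(rna_samples, rna_samples), function(s) {
      if (startsWith(s, "case")) w_case else c(canonical = 1)
    })
    reads_rna <- simulate_spliced_reads(toy$gene, iso, weights,
                                        depth = config$rnaseq_depth,
                                        seed = derive_seed(config$seed, 4))
    amp_samples <- c(
      head(config$design$sample[config$design$role == "case"],
           config$amplicon_cases),
      head(config$design$sample[config$design$role == "control"],
           config$amplicon_controls))
    inserts <- toy$truth$amplicon_inserts
    mixtures <- lapply(setNames(amp_samples, amp_samples), function(s) {
      m <- if (startsWith(s, "case")) config$case_mixture else
        config$control_mixture
      m[names(m) %in% names(inserts)] / sum(m[names(m) %in% names(inserts)])
    })
    reads_amp <- simulate_amplicon_reads(
      mixtures, inserts, toy$truth$primers, config$error_rate,
      config$corrupt_primer_frac, config$amplicon_reads,
      seed = derive_seed(config$seed, 5))
    panel <- simulate_panel(config$panel_n, config$panel_q,
                            seed = derive_seed(config$seed, 6),
                            exclude_homalt = TRUE)
    toy$truth$panel_counts <- list(n_het = panel$n_het,
                                   n_homalt = panel$n_homalt,
                                   n_total = panel$n_total)
    write_fasta(toy$reference, p("reference.fasta"))
    write_gff3(toy$gene, p("gene.gff3"))
    write_cohort_vcf(variants, genotypes, p("cohort.vcf"),
                     contig_length = config$locus$contig_length)
    readr::write_tsv(obs, p("external_observations.tsv"))
    write_design_tsv(config$design, p("design.tsv"))
    write_bed12(reads_rna, p("spliced_reads.bed"))
    write_fastq(reads_amp, p("amplicons.fastq"))
    write_panel_tsv(panel, p("panel.tsv"))
    write_truth_json(toy$truth, p("truth.json"))
    note("simulate", list(seed = config$seed,
                          q_background = config$q_background,
                          n_decoys = config$n_decoys),
         c("reference.fasta", "gene.gff3", "cohort.vcf", "spliced_reads.bed",
           "amplicons.fastq", "panel.tsv", "truth.json"))
    list(toy = toy, panel = panel, obs = obs)
  })
  toy <- sim$toy

  ## stage 2: segregation + association ------------------------------------
  seg <- run_stage("segregate", {
    v <- parse_vcf(p("cohort.vcf"))
    v <- association_test(v, config$design)
    v <- filter(v, .data$p_allelic < config$p_threshold)
    v <- recessive_segregation_filter(v, config$design)
    v <- impact_filter(v, config$impacts)
    v <- cross_population_exclude(v, sim$obs, config$home_breed)
    region <- if (nrow(v)) define_candidate_region(v) else
      tibble(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
             span = NA_integer_, n_variants = 0L)
    candidates <- v |>
      mutate(gene = purrr::map_chr(.data$ann, function(a) {
               if (nrow(a)) a$gene[1] else NA_character_
             }),
             effect = purrr::map_chr(.data$ann, function(a) {
               if (nrow(a)) a$effect[1] else NA_character_
             }),
             impact = purrr::map_chr(.data$ann, function(a) {
               if (nrow(a)) a$impact[1] else NA_character_
             })) |>
      select("chrom", "pos", "ref", "alt", "gene", "effect", "impact",
             "p_allelic")
    readr::write_tsv(candidates, p("candidates.tsv"))
    hg <- purrr::map(seq_len(nrow(candidates)), function(i) {
      tryCatch(hgvs_intronic_name(candidates[i, ], toy$gene)$rendered,
               error = function(e) NA_character_)
    })
    candidates$hgvs <- unlist(hg)
    jsonlite::write_json(region, p("candidate_region.json"),
                         auto_unbox = TRUE, digits = NA)
    note("segregate", list(p_threshold = config$p_threshold,
                           impacts = config$impacts,
                           home_breed = config$home_breed),
         c("candidates.tsv", "candidate_region.json"))
    list(candidates = candidates, region = region)
  })

  ## stage 3: cryptic-exon calling ------------------------------------------
  cry <- run_stage("cryptic", {
    reads <- read_spliced_bed(p("spliced_reads.bed"))
    profiles <- intron_coverage(reads, toy$gene)
    calls <- call_cryptic_exons(profiles, config$design, toy$gene,
                                config$min_case_reads,
                                config$max_control_fraction)
    offset <- if (nrow(calls) && nrow(seg$candidates)) {
      locate_variant_in_exon(calls[1, ], list(pos = seg$candidates$pos[1]),
                             toy$gene$strand)
    } else NA_integer_
    readr::write_tsv(calls, p("cryptic_calls.tsv"))
    note("cryptic", list(min_case_reads = config$min_case_reads,
                         max_control_fraction = config$max_control_fraction),
         "cryptic_calls.tsv")
    list(profiles = profiles, calls = calls, offset = offset)
  })

  ## stage 4: amplicon isoforms ----------------------------------------------
  amp <- run_stage("amplicon", {
    reads <- read_amplicon_fastq(p("amplicons.fastq"))
    reads <- filter_quality(reads, 10)
    reads <- subsample_reads(reads, config$subsample_n,
                             seed = derive_seed(config$seed, 7))
    trimmed <- trim_primers(reads, toy$truth$primers)
    accepted <- trimmed |> filter(.data$accepted) |>
      mutate(sequence = .data$insert)
    totals <- table(accepted$sample)
    clusters <- greedy_cluster(accepted, config$identity)
    sig <- significant_clusters(clusters, totals, config$sig_frac)
    sig <- classify_clusters(sig, config$design, config$classify_min_reads)
    cons <- cluster_consensus(sig, accepted, config$consensus_k,
                              seed = derive_seed(config$seed, 8))
    structures <- purrr::map(cons$consensus, function(cs) {
      tryCatch(map_consensus(cs, toy$reference, toy$gene),
               error = function(e) NULL)
    })
    inv <- sig |>
      as_tibble() |>
      select("cluster_id", "n_members", "mean_length", "class") |>
      mutate(consensus_length = nchar(cons$consensus),
             novel_blocks = purrr::map_int(structures, function(s) {
               if (is.null(s)) NA_integer_ else nrow(s$novel_blocks)
             }))
    readr::write_tsv(inv, p("cluster_inventory.tsv"))
    write_fasta(setNames(cons$consensus,
                         sprintf("cluster%d", cons$cluster_id)),
                p("consensus.fasta"))
    lengths_pred <- predict_amplicon_lengths(toy$truth$isoforms,
                                             toy$reference, toy$gene,
                                             toy$truth$primers)
    note("amplicon", list(subsample_n = config$subsample_n,
                          identity = config$identity,
                          sig_frac = config$sig_frac,
                          consensus_k = config$consensus_k),
         c("cluster_inventory.tsv", "consensus.fasta"))
    list(trimmed = trimmed, inventory = inv, clusters = sig,
         consensus = cons, structures = structures,
         predicted_lengths = lengths_pred)
  })

  ## stage 5: translation ----------------------------------------------------
  orf <- run_stage("translate", {
    case_idx <- which(amp$inventory$class == "case_only" &
                        amp$inventory$novel_blocks > 0)
    if (length(case_idx) == 0) {
      note("translate", list(skipped = "no case-only novel structure"))
      list(ptc_aa = NA_integer_, prediction = NULL)
    } else {
      st <- amp$structures[[case_idx[1]]]
      ptc <- ptc_after_insertion(toy$gene, st, toy$reference, toy$gene)
      full <- graft_structure(toy$gene, st)
      mrna <- splice_mrna(toy$reference, full, toy$gene$strand)
      lens <- full$end - full$start + 1L
      last_junction <- sum(lens) - lens[length(lens)]
      can_pred <- translate_cds(toy$truth$canonical_mrna,
                                toy$gene$cds_tx_start - 1L)
      pred <- translate_cds(mrna, toy$gene$cds_tx_start - 1L,
                            canonical_stop_tx = can_pred$stop_tx_start,
                            last_junction_tx = last_junction)
      jsonlite::write_json(
        list(ptc_aa_after_insertion = as.integer(ptc),
             frameshift = attr(ptc, "frameshift"),
             stop_codon = pred$stop_codon, ptc = pred$ptc,
             nmd_candidate = pred$nmd_candidate,
             peptide = pred$peptide),
        p("coding_prediction.json"), auto_unbox = TRUE, digits = NA)
      note("translate", list(), "coding_prediction.json")
      list(ptc_aa = as.integer(ptc), prediction = pred)
    }
  })

  ## stage 6: allele frequency ------------------------------------------------
  af <- run_stage("allelefreq", {
    est <- allele_frequency(read_panel_tsv(p("panel.tsv")))
    jsonlite::write_json(list(f = est$f, se = est$se,
                              n_het = est$counts$n_het,
                              n_homalt = est$counts$n_homalt,
                              n_total = est$counts$n_total),
                         p("allele_frequency.json"), auto_unbox = TRUE,
                         digits = NA)
    note("allelefreq", list(panel_n = config$panel_n,
                            panel_q = config$panel_q),
         "allele_frequency.json")
    est
  })

  report <- structure(
    list(candidates = seg$candidates, region = seg$region,
         hgvs = seg$candidates$hgvs[!is.na(seg$candidates$hgvs)],
         cryptic_calls = cry$calls, variant_offset = cry$offset,
         clusters = amp$inventory, consensus = amp$consensus,
         predicted_lengths = amp$predicted_lengths,
         ptc_aa = orf$ptc_aa, coding = orf$prediction,
         allele_frequency = af, truth = toy$truth,
         manifest = bind_rows(manifest), config = config),
    class = "cx_report")
  jsonlite::write_json(report_summary(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)), p("report.txt"))
  report
}

# flat, JSON-serialisable summary of a report
report_summary <- function(r) {
  list(
    n_candidates = nrow(r$candidates),
    candidates = as.list(r$candidates[, c("chrom", "pos", "ref", "alt",
                                          "p_allelic")]),
    region = as.list(r$region),
    hgvs = r$hgvs,
    n_cryptic_calls = nrow(r$cryptic_calls),
    cryptic_interval = if (nrow(r$cryptic_calls))
      c(r$cryptic_calls$start[1], r$cryptic_calls$end[1]) else NULL,
    variant_offset_in_exon = r$variant_offset,
    cluster_classes = as.list(table(r$clusters$class)),
    consensus_lengths = nchar(r$consensus$consensus),
    ptc_aa_after_insertion = r$ptc_aa,
    allele_frequency = r$allele_frequency$f,
    allele_frequency_se = r$allele_frequency$se)
}

#' @method print cx_report
#' @export
print.cx_report <- function(x, ...) {
  cat("== crypticex pipeline report ==\n")
  cat(sprintf("Candidate variants after filtering: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) {
    cat(sprintf("  top: %s:%d %s>%s (p = %.3g)%s\n",
                x$candidates$chrom[1], x$candidates$pos[1],
                x$candidates$ref[1], x$candidates$alt[1],
                x$candidates$p_allelic[1],
                if (length(x$hgvs)) paste0("  HGVS ", x$hgvs[1]) else ""))
  }
  cat(sprintf("Candidate region: %s:%d-%d (span %d bp, %d variants)\n",
              x$region$chrom, x$region$start, x$region$end, x$region$span,
              x$region$n_variants))
  cat(sprintf("Cryptic exon calls: %d", nrow(x$cryptic_calls)))
  if (nrow(x$cryptic_calls))
    cat(sprintf(" [%d-%d, case support %d, variant at base %s]",
                x$cryptic_calls$start[1], x$cryptic_calls$end[1],
                x$cryptic_calls$case_read_support[1],
                format(x$variant_offset)))
  cat("\n")
  cls <- table(x$clusters$class)
  cat(sprintf("Significant clusters: %d (%s)\n", nrow(x$clusters),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  cat(sprintf("Consensus lengths: %s\n",
              paste(sort(nchar(x$consensus$consensus)), collapse = ", ")))
  if (!is.na(x$ptc_aa))
    cat(sprintf("Premature stop %d aa after the cryptic insertion (%s)%s\n",
                x$ptc_aa, x$coding$stop_codon,
                if (isTRUE(x$coding$nmd_candidate)) ", NMD candidate" else ""))
  cat(sprintf("Allele frequency: %.4f (SE %.4f) from %d het / %d genotyped\n",
              x$allele_frequency$f, x$allele_frequency$se,
              x$allele_frequency$counts$n_het,
              x$allele_frequency$counts$n_total))
  invisible(x)
}
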