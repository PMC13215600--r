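# Cryptic-exon calling from spliced-read block evidence: intronic coverage
# profiles, case-vs-control support contrast, and variant localisation.

#' Intronic coverage profiles from spliced-read blocks
#'
#' For each intron of the gene model, merges the maximal intervals covered by
#' read blocks lying strictly inside the intron and counts supporting reads
#' per sample. A read is junction-supporting for an interval if it also
#' carries at least one block overlapping an annotated exon.
#'
#' @param reads long block tibble (`read_id`, `sample`, `chrom`, `start`,
#'   `end`), e.g. from [read_spliced_bed()] or [simulate_spliced_reads()].
#' @param gene a [gene_model()] with at least two exons.
#' @return tibble: `intron`, `start`, `end`, `sample`, `n_reads`,
#'   `n_junction_reads` (one row per merged interval and sample).
#' @export
intron_coverage <- function(reads, gene) {
  cx_assert(nrow(gene$exons) >= 2, "gene model needs at least 2 exons")
  introns <- gene_introns(gene)
  ex <- gene$exons
  reads <- filter(reads, .data$chrom == gene$contig)
  has_exon_block <- reads |>
    mutate(exonic = purrr::map2_lgl(.data$start, .data$end, function(s, e) {
      any(s <= ex$end & e >= ex$start)
    })) |>
    group_by(.data$read_id) |>
    summarise(junction = any(.data$exonic), .groups = "drop")
  out <- purrr::pmap(introns, function(intron, start, end) {
    i_start <- start; i_end <- end
    inside <- filter(reads, .data$start >= i_start, .data$end <= i_end)
    if (nrow(inside) == 0) return(NULL)
    merged <- merge_intervals(inside[, c("start", "end")])
    purrr::pmap(merged, function(start, end) {
      s0 <- start; e0 <- end
      hits <- filter(inside, .data$start >= s0, .data$end <= e0) |>
        left_join(has_exon_block, by = "read_id") |>
        distinct(.data$read_id, .data$sample, .data$junction)
      hits |>
        group_by(.data$sample) |>
        summarise(n_reads = n(), n_junction_reads = sum(.data$junction),
                  .groups = "drop") |>
        mutate(intron = intron, start = s0, end = e0, .before = 1)
    }) |> bind_rows()
  })
  bind_rows(out)
}

#' Call cryptic exons from intronic coverage profiles
#'
#' Emits a call for each merged intronic interval whose summed case support
#' reaches `min_case_reads` and whose control/case support ratio does not
#' exceed `max_control_fraction`. Boundaries are the merged-coverage bounds;
#' junction support is reported but not required.
#'
#' @param profiles output of [intron_coverage()].
#' @param design cohort design tibble.
#' @param gene a [gene_model()] (names the gene in the calls).
#' @param min_case_reads minimum summed case read support.
#' @param max_control_fraction maximum control/case support ratio.
#' @return tibble of calls: `gene`, `intron_index`, `chrom`, `start`, `end`,
#'   `case_read_support`, `control_read_support`, `junction_supported`.
#' @export
call_cryptic_exons <- function(profiles, design, gene, min_case_reads = 10,
                               max_control_fraction = 0.05) {
  validate_design(design)
  empty <- tibble(gene = character(), intron_index = integer(),
                  chrom = character(), start = integer(), end = integer(),
                  case_read_support = integer(),
                  control_read_support = integer(),
                  junction_supported = logical())
  if (is.null(profiles) || nrow(profiles) == 0) return(empty)
  roles <- setNames(design$role, design$sample)
  calls <- profiles |>
    mutate(role = roles[.data$sample]) |>
    group_by(.data$intron, .data$start, .data$end) |>
    summarise(
      case_read_support = sum(.data$n_reads[.data$role == "case"]),
      control_read_support = sum(.data$n_reads[.data$role == "control"]),
      junction_supported = sum(.data$n_junction_reads[.data$role == "case"]) > 0,
      .groups = "drop") |>
    filter(.data$case_read_support >= min_case_reads,
           .data$control_read_support <=
             max_control_fraction * .data$case_read_support) |>
    mutate(chrom = gene$contig, gene = gene$gene_name, .before = 1) |>
    select("gene", "intron", "chrom", dplyr::everything()) |>
    rename(intron_index = "intron")
  if (nrow(calls) == 0) empty else calls
}

#' Locate a variant within a called cryptic exon
#'
#' Offset of the variant from the coding-strand 5' end of the call interval
#' (1-based), or `NA` if the variant lies outside the interval. On
#' minus-strand genes the 5' end is the higher genomic coordinate, so "eighth
#' base pair" is well-defined on either strand.
#'
#' @param call one-row call tibble from [call_cryptic_exons()] (fields
#'   `start`, `end`).
#' @param variant list/row with `pos`.
#' @param strand coding strand of the gene (`"+"` or `"-"`).
#' @return integer offset or `NA`.
#' @export
locate_variant_in_exon <- function(call, variant, strand = "+") {
  pos <- variant$pos
  if (pos < call$start || pos > call$end) return(NA_integer_)
  if (strand == "+") as.integer(pos - call$start + 1L)
  else as.integer(call$end - pos + 1L)
}
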