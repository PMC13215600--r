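# Recessive-model variant prioritisation: VCF/ANN parsing, the allelic Fisher
# exact test, segregation predicates, impact and cross-population filters,
# candidate-region definition.

#' Parse a multi-sample VCF into a variant tibble
#'
#' Reads a VCF 4.2 with per-sample GT (and optionally SnpEff-style ANN INFO).
#' Multiallelic sites are split into one record per alternate allele, with
#' genotypes recoded per split allele (dosage of that allele; any `.` in GT
#' yields `missing`). Malformed headers or rows raise an error naming the
#' offending line.
#'
#' @param path path to a VCF file.
#' @return tibble with columns `chrom`, `pos`, `ref`, `alt`, `ann` (list of
#'   annotation tibbles) and `gt` (list of named genotype-class vectors).
#' @export
parse_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  cx_assert(length(hdr) == 1,
            sprintf("malformed VCF %s: no #CHROM header line", path))
  for (i in seq_along(lines)) {
    if (i <= hdr) next
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10 || is.na(suppressWarnings(as.integer(f[2]))))
      rlang::abort(sprintf("malformed VCF row at line %d of %s", i, path),
                   class = "crypticex_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  info <- vcfR::extract.info(v, element = "ANN")
  samples <- colnames(gt_mat)
  out <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    anns <- parse_ann(if (is.null(info) || is.na(info[i])) "" else info[i])
    purrr::map(seq_along(alts), function(k) {
      gts <- recode_gt_for_allele(gt_mat[i, ], k)
      ann_k <- if (nrow(anns)) anns[anns$allele == alts[k] |
                                      !nzchar(anns$allele), , drop = FALSE]
               else anns
      tibble(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = alts[k],
             ann = list(ann_k), gt = list(setNames(gts, samples)))
    }) |> bind_rows()
  })
  bind_rows(out)
}

# genotype class of allele k (1-based alt index) from a diploid GT string
recode_gt_for_allele <- function(gt, k) {
  vapply(gt, function(g) {
    if (is.na(g)) return("missing")
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(al == ".") || length(al) != 2) return("missing")
    d <- sum(al == as.character(k))
    c("homref", "het", "homalt")[d + 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a SnpEff-style ANN INFO field
#'
#' Entries are comma-separated; subfields pipe-delimited in the order
#' `Allele|Effect|Impact|Gene`.
#'
#' @param info_field the ANN value (without the `ANN=` key); `""` or `NA`
#'   yields an empty table.
#' @return tibble with columns `allele`, `gene`, `effect`, `impact`.
#' @export
parse_ann <- function(info_field) {
  empty <- tibble(allele = character(), gene = character(),
                  effect = character(), impact = character())
  if (is.null(info_field) || length(info_field) == 0 ||
      is.na(info_field) || !nzchar(info_field)) return(empty)
  entries <- strsplit(info_field, ",", fixed = TRUE)[[1]]
  out <- purrr::map(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    cx_assert(length(f) >= 4, sprintf("malformed ANN entry '%s'", e))
    cx_assert(f[3] %in% c("HIGH", "MODERATE", "LOW", "MODIFIER"),
              sprintf("unknown impact '%s' in ANN entry", f[3]))
    tibble(allele = f[1], gene = f[4], effect = f[2], impact = f[3])
  })
  bind_rows(out)
}

#' Two-sided allelic Fisher exact test
#'
#' Exact two-sided p for a 2x2 allele-count table (case alt/ref vs control
#' alt/ref), computed by full hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (ties within relative tolerance
#' 1e-12 are included). An all-zero table returns 1 by convention.
#'
#' @param case_alt,case_ref,ctrl_alt,ctrl_ref non-negative allele counts.
#' @return the two-sided p value.
#' @examples
#' allelic_fisher(2, 0, 0, 2) # 1/3
#' @export
allelic_fisher <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  counts <- c(case_alt, case_ref, ctrl_alt, ctrl_ref)
  cx_assert(all(counts >= 0) && all(counts == floor(counts)),
            "allele counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) return(1)
  m1 <- case_alt + case_ref          # case alleles
  k_alt <- case_alt + ctrl_alt       # alt alleles overall
  ks <- max(0, m1 - (n - k_alt)):min(m1, k_alt)
  probs <- stats::dhyper(ks, k_alt, n - k_alt, m1)
  p_obs <- stats::dhyper(case_alt, k_alt, n - k_alt, m1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Allelic association over a cohort
#'
#' Computes the case-vs-control allele-count table and two-sided Fisher exact
#' p for every variant. Only samples with role `case` or `control` enter the
#' table; missing genotypes are excluded from the margins.
#'
#' @param variants variant tibble from [parse_vcf()].
#' @param design cohort design tibble.
#' @return the variant tibble with columns `case_alt`, `case_ref`,
#'   `ctrl_alt`, `ctrl_ref`, `p_allelic` added.
#' @export
association_test <- function(variants, design) {
  validate_design(design)
  cases <- design$sample[design$role == "case"]
  ctrls <- design$sample[design$role == "control"]
  dose <- c(homref = 0, het = 1, homalt = 2)
  counts <- purrr::map(variants$gt, function(g) {
    gc <- g[cases]; gk <- g[ctrls]
    gc <- gc[gc != "missing"]; gk <- gk[gk != "missing"]
    tibble(case_alt = sum(dose[gc]), case_ref = 2 * length(gc) - sum(dose[gc]),
           ctrl_alt = sum(dose[gk]), ctrl_ref = 2 * length(gk) - sum(dose[gk]))
  }) |> bind_rows()
  out <- bind_cols(variants, counts)
  out$p_allelic <- purrr::pmap_dbl(counts, allelic_fisher)
  out
}

#' Recessive segregation filter
#'
#' Keeps a variant iff every case is hom-alt, every obligate carrier is het,
#' and no control is hom-alt. Samples with missing genotypes fail the
#' predicate unless `allow_missing`; samples with role `unknown` are ignored.
#'
#' @param variants variant tibble from [parse_vcf()].
#' @param design cohort design tibble.
#' @param allow_missing treat missing genotypes as compatible?
#' @return the filtered variant tibble (order preserved).
#' @export
recessive_segregation_filter <- function(variants, design,
                                         allow_missing = FALSE) {
  validate_design(design)
  keep <- purrr::map_lgl(variants$gt, segregates_recessive, design = design,
                         allow_missing = allow_missing)
  variants[keep, , drop = FALSE]
}

segregates_recessive <- function(g, design, allow_missing = FALSE) {
  ok <- function(samples, want, forbid = NULL) {
    x <- g[samples]
    if (!allow_missing && any(x == "missing")) return(FALSE)
    x <- x[x != "missing"]
    if (!is.null(forbid)) return(!any(x %in% forbid))
    all(x == want)
  }
  ok(design$sample[design$role == "case"], "homalt") &&
    ok(design$sample[design$role == "obligate_carrier"], "het") &&
    ok(design$sample[design$role == "control"], NULL, forbid = "homalt")
}

#' Filter variants by predicted impact
#'
#' Keeps a variant iff any of its annotations has an impact in `allowed`.
#' Idempotent and order-preserving.
#'
#' @param variants variant tibble from [parse_vcf()].
#' @param allowed character vector of impact classes to keep.
#' @return the filtered variant tibble.
#' @export
impact_filter <- function(variants,
                          allowed = c("HIGH", "MODERATE", "LOW", "MODIFIER")) {
  cx_assert(all(allowed %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")),
            "`allowed` must be impact classes")
  keep <- purrr::map_lgl(variants$ann, function(a) {
    nrow(a) > 0 && any(a$impact %in% allowed)
  })
  variants[keep, , drop = FALSE]
}

#' Exclude variants observed in other populations
#'
#' Keeps a variant iff its (chrom, pos, alt) key is observed in no breed
#' other than `home_breed` in the external observation table. Variants absent
#' from the table are kept. Idempotent and order-preserving.
#'
#' @param variants variant tibble.
#' @param external_observations tibble with columns `chrom`, `pos`, `alt`,
#'   `breed` (may be empty).
#' @param home_breed the study breed; observations in it do not exclude.
#' @return the filtered variant tibble.
#' @export
cross_population_exclude <- function(variants, external_observations,
                                     home_breed) {
  if (is.null(external_observations) || nrow(external_observations) == 0)
    return(variants)
  other <- external_observations |>
    filter(.data$breed != home_breed) |>
    mutate(key = paste(.data$chrom, .data$pos, .data$alt, sep = ":"))
  keys <- paste(variants$chrom, variants$pos, variants$alt, sep = ":")
  variants[!(keys %in% other$key), , drop = FALSE]
}

#' Candidate region spanned by associated variants
#'
#' @param variants variant tibble on a single chromosome.
#' @return one-row tibble: `chrom`, `start`, `end`, `span` (`end - start`),
#'   `n_variants`.
#' @export
define_candidate_region <- function(variants) {
  cx_assert(nrow(variants) >= 1, "need at least one variant")
  cx_assert(length(unique(variants$chrom)) == 1,
            "variants span multiple chromosomes; partition before calling")
  tibble(chrom = variants$chrom[1],
         start = min(variants$pos), end = max(variants$pos),
         span = max(variants$pos) - min(variants$pos),
         n_variants = nrow(variants))
}
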