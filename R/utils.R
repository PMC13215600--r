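# Shared low-level helpers. Genomic intervals are 1-based and closed
# throughout the package (the IRanges/GFF/VCF convention); BED12, which is
# 0-based half-open, is converted at its I/O boundary only.

cx_assert <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg, class = "crypticex_error")
  invisible(TRUE)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic random DNA under the current RNG state
rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# all 61 sense codons (no stops); used when a reading frame must stay open
sense_codons <- function() {
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, STOP_CODONS)
}

# Merge overlapping/adjacent closed intervals. `tbl` has columns start, end.
merge_intervals <- function(tbl) {
  if (nrow(tbl) == 0) return(tibble(start = integer(), end = integer()))
  tbl <- dplyr::arrange(tbl, .data$start, .data$end)
  out_s <- tbl$start[1]; out_e <- tbl$end[1]
  res_s <- integer(); res_e <- integer()
  if (nrow(tbl) > 1) {
    for (i in 2:nrow(tbl)) {
      if (tbl$start[i] <= out_e + 1L) {
        out_e <- max(out_e, tbl$end[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- tbl$start[i]; out_e <- tbl$end[i]
      }
    }
  }
  tibble(start = c(res_s, out_s), end = c(res_e, out_e))
}

# substring by 1-based closed interval
subseq_chr <- function(seq, start, end) substring(seq, start, end)

# overwrite a 1-based closed interval of `seq` with `piece`
splice_into <- function(seq, start, piece) {
  end <- start + nchar(piece) - 1L
  cx_assert(start >= 1 && end <= nchar(seq), "replacement outside sequence")
  paste0(substring(seq, 1L, start - 1L), piece,
         substring(seq, end + 1L, nchar(seq)))
}

# Seeded evaluation that never touches the global RNG stream.
with_seed <- function(seed, code) {
  cx_assert(is.numeric(seed) && length(seed) == 1 && !is.na(seed),
            "`seed` must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed for stage `k` from a master seed, staying < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483587)
}

gt_levels <- c("homref", "het", "homalt", "missing")

gt_from_string <- function(gt) {
  # unphased or phased diploid GT string -> genotype class
  g <- gsub("\\|", "/", gt)
  dplyr::case_when(
    g %in% c("0/0") ~ "homref",
    g %in% c("0/1", "1/0") ~ "het",
    g %in% c("1/1") ~ "homalt",
    TRUE ~ "missing"
  )
}
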