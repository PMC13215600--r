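# broom-style tidiers for the package's result objects.

#' Tidy an allele-frequency estimate
#' @param x an `af_estimate`.
#' @param ... unused.
#' @return one-row tibble: `estimate`, `std.error`, `n_het`, `n_homalt`,
#'   `n_total`.
#' @export
tidy.af_estimate <- function(x, ...) {
  tibble(estimate = x$f, std.error = x$se, n_het = x$counts$n_het,
         n_homalt = x$counts$n_homalt, n_total = x$counts$n_total)
}

#' @rdname tidy.af_estimate
#' @export
glance.af_estimate <- function(x, ...) {
  tibble(f = x$f, se = x$se, n = x$counts$n_total,
         carriers = x$counts$n_het + x$counts$n_homalt)
}

#' Tidy an amplicon cluster set
#' @param x an `amplicon_clusters` object.
#' @param ... unused.
#' @return tibble with one row per cluster and sample:
#'   `cluster_id`, `sample`, `n_reads`, plus cluster-level columns.
#' @export
tidy.amplicon_clusters <- function(x, ...) {
  purrr::map2_dfr(x$cluster_id, x$counts, function(id, ct) {
    tibble(cluster_id = id, sample = names(ct), n_reads = as.integer(ct))
  }) |>
    left_join(as_tibble(x)[, intersect(c("cluster_id", "n_members",
                                         "mean_length", "class"), names(x))],
              by = "cluster_id")
}

#' @rdname tidy.amplicon_clusters
#' @export
glance.amplicon_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x), n_reads = sum(x$n_members),
         threshold = attr(x, "threshold"),
         largest = if (nrow(x)) max(x$n_members) else 0L)
}

#' Tidy a coding prediction
#' @param x a `coding_prediction`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.coding_prediction <- function(x, ...) {
  tibble(peptide_length = nchar(x$peptide), stop_codon = x$stop_codon,
         stop_codon_index = x$stop_codon_index, ptc = x$ptc,
         no_stop = x$no_stop, nmd_candidate = x$nmd_candidate)
}

#' Glance at a pipeline report
#' @param x a `cx_report`.
#' @param ... unused.
#' @return one-row tibble with the headline results.
#' @export
glance.cx_report <- function(x, ...) {
  cls <- table(x$clusters$class)
  tibble(n_candidates = nrow(x$candidates),
         region_span = x$region$span,
         n_cryptic_calls = nrow(x$cryptic_calls),
         variant_offset = x$variant_offset,
         shared_clusters = as.integer(cls["shared"] %|0|% 0L),
         case_only_clusters = as.integer(cls["case_only"] %|0|% 0L),
         ptc_aa = x$ptc_aa,
         allele_frequency = x$allele_frequency$f)
}

`%|0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
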