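# ggplot2 visualisations for the main result types.

#' Plot per-sample cluster occupancy
#'
#' Bar panel of the fraction of each sample's reads held by each cluster,
#' with the significance fraction drawn as a dashed line.
#'
#' @param object an `amplicon_clusters` object (ideally classified).
#' @param per_sample_totals named totals used for fractions; defaults to the
#'   cluster-derived totals.
#' @param sig_frac significance fraction to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.amplicon_clusters <- function(object, per_sample_totals = NULL,
                                       sig_frac = 0.10, ...) {
  d <- tidy(object)
  totals <- per_sample_totals %||%
    setNames(tapply(d$n_reads, d$sample, sum), unique(d$sample))
  d$fraction <- d$n_reads / as.numeric(totals[d$sample])
  d$cluster <- factor(d$cluster_id)
  mapping <- if ("class" %in% names(d)) {
    ggplot2::aes(x = .data$cluster, y = .data$fraction, fill = .data$class)
  } else {
    ggplot2::aes(x = .data$cluster, y = .data$fraction)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = sig_frac, linetype = "dashed") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "cluster", y = "fraction of sample reads",
                  title = "Amplicon cluster occupancy") +
    ggplot2::theme_minimal()
}

#' Plot intronic coverage profiles with cryptic-exon calls
#'
#' @param profiles output of [intron_coverage()].
#' @param calls optional calls from [call_cryptic_exons()].
#' @param gene optional [gene_model()] for exon context.
#' @return a ggplot object.
#' @export
plot_intron_coverage <- function(profiles, calls = NULL, gene = NULL) {
  p <- ggplot2::ggplot(profiles) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$sample, yend = .data$sample,
                                       linewidth = .data$n_reads),
                          lineend = "butt") +
    ggplot2::labs(x = "genomic position", y = NULL,
                  linewidth = "reads",
                  title = "Intronic expressed blocks") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_vline(xintercept = c(calls$start, calls$end),
                                 linetype = "dotted")
  }
  if (!is.null(gene)) {
    ex <- gene$exons
    p <- p + ggplot2::annotate("rect", xmin = ex$start, xmax = ex$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}

#' Plot a coding prediction as a peptide schematic
#'
#' @param object a `coding_prediction`.
#' @param insertion_aa_start optional 1-based codon index where the inserted
#'   amino acids begin (shaded).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coding_prediction <- function(object, insertion_aa_start = NULL, ...) {
  n <- nchar(object$peptide)
  d <- tibble(x = seq_len(n))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = 1)) +
    ggplot2::geom_tile(height = 0.3, fill = "grey70") +
    ggplot2::labs(x = "codon", y = NULL,
                  title = sprintf("Peptide (%d aa)%s", n,
                                  if (object$ptc) " - premature stop" else "")) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(insertion_aa_start)) {
    p <- p + ggplot2::annotate("rect", xmin = insertion_aa_start - 0.5,
                               xmax = n + 0.5, ymin = 0.8, ymax = 1.2,
                               alpha = 0.3, fill = "red")
  }
  if (!object$no_stop) {
    p <- p + ggplot2::annotate("text", x = n + 1, y = 1,
                               label = object$stop_codon, size = 3)
  }
  p
}
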