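# Population allele-frequency estimation from carrier-screening counts, and
# the comparative threshold-cycle (2^-ddCt) fold-change.

#' Genotype counts from a screening panel
#'
#' @param n_het number of heterozygous individuals (one disease allele).
#' @param n_homalt number of homozygous-alternate individuals.
#' @param n_total panel size.
#' @return a `genotype_counts` list.
#' @export
genotype_counts <- function(n_het, n_homalt, n_total) {
  cx_assert(n_total >= 0 && n_het >= 0 && n_homalt >= 0,
            "counts must be non-negative")
  cx_assert(n_het + n_homalt <= n_total,
            "carriers cannot outnumber the panel")
  structure(list(n_het = as.integer(n_het), n_homalt = as.integer(n_homalt),
                 n_total = as.integer(n_total)),
            class = "genotype_counts")
}

#' @method print genotype_counts
#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %d het + %d hom-alt of %d genotyped\n",
              x$n_het, x$n_homalt, x$n_total))
  invisible(x)
}

#' Disease-allele frequency from genotype counts
#'
#' The allele-counting estimator `f = (n_het + 2 n_homalt) / (2 n_total)`,
#' with binomial standard error `sqrt(f (1 - f) / (2 n_total))`. (The SE is
#' the square root of the allele-count binomial variance; the estimate's
#' metadata also records the raw variance `f(1-f)/(2n)` for reference.)
#'
#' @param counts a [genotype_counts()] (or list with `n_het`, `n_homalt`,
#'   `n_total`).
#' @return an `af_estimate` list: `f`, `se`, `counts`, `meta`.
#' @examples
#' est <- allele_frequency(genotype_counts(25, 0, 1060))
#' round(est$f, 3) # 0.012
#' @export
allele_frequency <- function(counts) {
  cx_assert(counts$n_total >= 1, "panel size must be >= 1")
  f <- (counts$n_het + 2 * counts$n_homalt) / (2 * counts$n_total)
  se <- sqrt(f * (1 - f) / (2 * counts$n_total))
  structure(list(f = f, se = se, counts = counts,
                 meta = list(se_definition = "sqrt(f(1-f)/(2n))",
                             variance_no_radical = f * (1 - f) /
                               (2 * counts$n_total))),
            class = "af_estimate")
}

#' Standard error of an allele-frequency estimate
#'
#' @param estimate an `af_estimate` from [allele_frequency()].
#' @return the binomial standard error.
#' @export
allele_frequency_se <- function(estimate) {
  cx_assert(inherits(estimate, "af_estimate"),
            "`estimate` must come from allele_frequency()")
  estimate$se
}

#' @method print af_estimate
#' @export
print.af_estimate <- function(x, ...) {
  cat(sprintf("<af_estimate> f = %.4g (SE %.3g) from %d het + %d hom-alt / %d\n",
              x$f, x$se, x$counts$n_het, x$counts$n_homalt, x$counts$n_total))
  invisible(x)
}

#' Fold change by the comparative threshold-cycle method
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)`;
#' fold change = `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl threshold
#'   cycles (target and reference gene, case and control group).
#' @return the fold change (numeric scalar).
#' @examples
#' ddct_fold_change(25, 20, 25, 20) # 1
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  cx_assert(all(is.finite(cts)) && all(cts > 0),
            "threshold cycles must be finite and positive")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
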