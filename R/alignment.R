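#' Global sequence identity
#'
#' Fraction of identical columns in an optimal global (Needleman-Wunsch)
#' alignment of two sequences under the fixed scoring scheme match = +1,
#' mismatch = -1, gap column = -2. Gap columns count against identity, so
#' `global_identity("ACGT", "ACG")` is 3/4. The measure is symmetric.
#'
#' This exact, reproducible definition stands in for the word-based identity
#' heuristics of common clustering tools; it is the primitive behind
#' [greedy_cluster()].
#'
#' @param a,b non-empty DNA strings.
#' @return a single numeric identity in `[0, 1]`.
#' @examples
#' global_identity("ACGT", "ACGT") # 1
#' global_identity("ACGT", "ACGA") # 0.75
#' @export
global_identity <- function(a, b) {
  cx_assert(is.character(a) && length(a) == 1 && nzchar(a) &&
            is.character(b) && length(b) == 1 && nzchar(b),
            "`a` and `b` must be single non-empty sequences")
  .cx_align_global(a, b)$identity
}

# full alignment record (score, identity, aligned strings)
align_global <- function(a, b) .cx_align_global(a, b)

# banded threshold decision used on the clustering hot path; exact for the
# question "is identity >= thr" (see src/align.cpp for the band argument)
identity_at_least <- function(a, b, thr) .cx_identity_ge(a, b, thr)
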