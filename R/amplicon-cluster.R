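# Long-read amplicon analysis: subsampling, exact-primer trimming, greedy
# global-identity clustering, the per-sample significance rule, and
# case/control cluster classification.

#' Subsample reads per sample
#'
#' Draws `min(n, available)` reads uniformly without replacement within each
#' sample, preserving the original row order of the selected reads.
#'
#' @param reads tibble with a `sample` column.
#' @param n maximum reads per sample.
#' @param seed integer seed.
#' @return the subsampled tibble.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  cx_assert(n >= 1, "`n` must be >= 1")
  with_seed(seed, {
    keep <- reads |>
      mutate(.row = row_number()) |>
      group_by(.data$sample) |>
      dplyr::group_map(function(d, key) {
        if (nrow(d) <= n) d$.row else sort(sample(d$.row, n))
      })
    reads[sort(unlist(keep)), , drop = FALSE]
  })
}

#' Drop reads below a mean-quality threshold
#'
#' Reads without a `mean_quality` column (or with `NA`) are kept: quality
#' filtering only applies where quality information exists.
#'
#' @param reads read tibble.
#' @param min_quality minimum mean Phred quality.
#' @return the filtered tibble.
#' @export
filter_quality <- function(reads, min_quality = 10) {
  if (!"mean_quality" %in% names(reads)) return(reads)
  filter(reads, is.na(.data$mean_quality) |
                  .data$mean_quality >= min_quality)
}

#' Exact-primer trimming
#'
#' A read is accepted iff the forward primer occurs exactly at its 5' end and
#' the reverse complement of the reverse primer exactly at its 3' end, in
#' either read orientation (reverse-orientation reads are reverse-complemented
#' first). Accepted reads yield the insert between the primers, oriented
#' forward; others are rejected with a reason code (`no_forward_primer`,
#' `no_reverse_primer`). Rejection is a value, not an error.
#'
#' @param reads tibble with columns `id`, `sample`, `sequence`.
#' @param primers named character vector `c(forward=, reverse=)`.
#' @return the input tibble with columns `accepted`, `reason`, `insert`
#'   added (insert is `NA` for rejected reads).
#' @export
trim_primers <- function(reads, primers) {
  fwd <- unname(primers[["forward"]])
  rev_rc <- revcomp(unname(primers[["reverse"]]))
  seqs <- reads$sequence
  fwd_ok <- startsWith(seqs, fwd)
  flipped <- !fwd_ok
  if (any(flipped)) {
    rc <- revcomp(seqs[flipped])
    use <- startsWith(rc, fwd)
    seqs[flipped][use] <- rc[use]
    fwd_ok[flipped] <- use
  }
  rev_ok <- fwd_ok & endsWith(seqs, rev_rc)
  insert <- ifelse(rev_ok,
                   substring(seqs, nchar(fwd) + 1L,
                             nchar(seqs) - nchar(rev_rc)),
                   NA_character_)
  reads |>
    mutate(accepted = rev_ok,
           reason = dplyr::case_when(rev_ok ~ NA_character_,
                                     !fwd_ok ~ "no_forward_primer",
                                     TRUE ~ "no_reverse_primer"),
           insert = insert)
}

#' Greedy identity-threshold clustering
#'
#' Reads are sorted by length descending (ties by id ascending); each read
#' joins the first existing cluster whose centroid identity (see
#' [global_identity()]) reaches `threshold`, else founds a new cluster with
#' itself as centroid. Clusters are numbered in creation order. A length
#' pre-screen skips centroid comparisons that cannot reach the threshold
#' (identity is at most the length ratio).
#'
#' @param inserts tibble with columns `id`, `sample`, `sequence` (trimmed
#'   inserts, e.g. the accepted rows of [trim_primers()]).
#' @param threshold minimum global identity to the cluster centroid.
#' @return an `amplicon_clusters` object: a tibble with one row per cluster
#'   (`cluster_id`, `centroid_id`, `n_members`, `mean_length`, `members`
#'   list-col, `counts` list-col of per-sample counts) plus attributes.
#' @export
greedy_cluster <- function(inserts, threshold = 0.98) {
  cx_assert(nrow(inserts) >= 1, "need at least one read")
  cx_assert(threshold > 0 && threshold <= 1, "`threshold` must be in (0, 1]")
  ord <- order(-nchar(inserts$sequence), inserts$id)
  ids <- inserts$id[ord]
  seqs <- inserts$sequence[ord]
  samples <- inserts$sample[ord]
  lens <- nchar(seqs)
  assign <- .cx_greedy_assign(seqs, threshold)
  cent_seq <- seqs[!duplicated(assign)]
  members <- split(ids, assign)
  member_samples <- split(samples, assign)
  member_lens <- split(lens, assign)
  k <- length(members)
  tbl <- tibble(
    cluster_id = seq_len(k) - 1L,
    centroid_id = vapply(seq_len(k), function(ci) {
      ids[which(assign == ci)[1]]
    }, character(1)),
    n_members = lengths(members),
    mean_length = vapply(member_lens, mean, numeric(1)),
    members = unname(members),
    counts = unname(lapply(member_samples, function(s) table(s)))
  )
  structure(tbl, class = c("amplicon_clusters", class(tbl)),
            threshold = threshold,
            centroid_seqs = cent_seq)
}

#' @method print amplicon_clusters
#' @export
print.amplicon_clusters <- function(x, ...) {
  cat(sprintf("<amplicon_clusters> %d clusters over %d reads (identity >= %s)\n",
              nrow(x), sum(x$n_members), format(attr(x, "threshold"))))
  NextMethod()
}

# per-sample count matrix (clusters x samples)
cluster_count_matrix <- function(clusters, samples = NULL) {
  samples <- samples %||%
    sort(unique(unlist(lapply(clusters$counts, names))))
  m <- matrix(0L, nrow(clusters), length(samples),
              dimnames = list(clusters$cluster_id, samples))
  for (i in seq_len(nrow(clusters))) {
    ct <- clusters$counts[[i]]
    m[i, names(ct)] <- as.integer(ct)
  }
  m
}

#' Significant clusters under the per-sample fraction rule
#'
#' Keeps a cluster iff it holds strictly more than `fraction` of at least one
#' sample's total reads. Totals are the post-trim per-sample read counts;
#' samples with zero total are excluded from the test.
#'
#' @param clusters an `amplicon_clusters` object.
#' @param per_sample_totals named integer vector of post-trim totals.
#' @param fraction significance fraction (strict `>`).
#' @return the filtered `amplicon_clusters` object.
#' @export
significant_clusters <- function(clusters, per_sample_totals, fraction = 0.10) {
  totals <- per_sample_totals[per_sample_totals > 0]
  m <- cluster_count_matrix(clusters, names(totals))
  frac <- sweep(m, 2, as.numeric(totals), "/")
  keep <- apply(frac, 1, max) > fraction
  out <- clusters[keep, , drop = FALSE]
  attr(out, "threshold") <- attr(clusters, "threshold")
  attr(out, "centroid_seqs") <- attr(clusters, "centroid_seqs")[keep]
  out
}

#' Classify clusters by cohort arm
#'
#' A cluster is `case_only` iff every control sample holds fewer than
#' `min_reads` of its reads and at least one case holds at least `min_reads`;
#' `control_only` symmetrically; otherwise `shared`. With an empty control
#' arm every cluster is (degenerately) case-only and a warning is raised.
#'
#' @param clusters an `amplicon_clusters` object (typically post
#'   [significant_clusters()]).
#' @param design cohort design tibble.
#' @param min_reads occupancy threshold per sample.
#' @return the cluster tibble with a `class` column added.
#' @export
classify_clusters <- function(clusters, design, min_reads = 5) {
  validate_design(design)
  cases <- design$sample[design$role == "case"]
  ctrls <- design$sample[design$role == "control"]
  if (length(ctrls) == 0)
    rlang::warn("no control samples: every cluster will be case_only")
  cls <- vapply(clusters$counts, function(ct) {
    cc <- setNames(rep(0L, length(cases)), cases)
    kk <- setNames(rep(0L, length(ctrls)), ctrls)
    common_c <- intersect(names(ct), cases)
    common_k <- intersect(names(ct), ctrls)
    cc[common_c] <- as.integer(ct[common_c])
    kk[common_k] <- as.integer(ct[common_k])
    if (all(kk < min_reads) && any(cc >= min_reads)) "case_only"
    else if (all(cc < min_reads) && any(kk >= min_reads)) "control_only"
    else "shared"
  }, character(1))
  out <- mutate(clusters, class = cls)
  attr(out, "threshold") <- attr(clusters, "threshold")
  attr(out, "centroid_seqs") <- attr(clusters, "centroid_seqs")
  out
}

#' One-shot amplicon cluster inventory for a toy locus
#'
#' Convenience composition of the amplicon chain on a simulated cohort:
#' simulate reads from per-arm isoform mixtures, trim primers exactly,
#' greedy-cluster the inserts, apply the per-sample significance rule, and
#' classify clusters by cohort arm.
#'
#' @param toy output of [build_toy_locus()].
#' @param case_mixture,control_mixture named isoform-mixture fractions (over
#'   the planted insert names).
#' @param n_cases,n_controls amplicon cohort arm sizes.
#' @param n_reads reads per sample.
#' @param error_rate per-base substitution rate on the insert.
#' @param corrupt_primer_frac fraction of reads with a corrupted primer base.
#' @param threshold clustering identity threshold.
#' @param sig_frac significance fraction (strict `>`).
#' @param min_reads per-sample occupancy for classification.
#' @param seed integer seed.
#' @return list: `inventory` (tibble `cluster_id`, `n_members`,
#'   `mean_length`, `class`), `clusters` (classified significant
#'   `amplicon_clusters`), `accepted` (trimmed reads), `totals`.
#' @export
amplicon_cluster_inventory <- function(toy,
                                       case_mixture = c(canonical_a = 0.2,
                                                        canonical_b = 0.2,
                                                        cryptic = 0.3,
                                                        cryptic_extended = 0.3),
                                       control_mixture = c(canonical_a = 0.5,
                                                           canonical_b = 0.5),
                                       n_cases = 2, n_controls = 4,
                                       n_reads = 1000, error_rate = 0.01,
                                       corrupt_primer_frac = 0,
                                       threshold = 0.98, sig_frac = 0.10,
                                       min_reads = 5, seed = 1L) {
  samples <- c(sprintf("case%02d", seq_len(n_cases)),
               sprintf("ctrl%02d", seq_len(n_controls)))
  design <- tibble(sample = samples,
                   role = rep(c("case", "control"), c(n_cases, n_controls)))
  inserts <- toy$truth$amplicon_inserts
  mixtures <- lapply(setNames(samples, samples), function(s) {
    m <- if (startsWith(s, "case")) case_mixture else control_mixture
    m <- m[names(m) %in% names(inserts)]
    m / sum(m)
  })
  reads <- simulate_amplicon_reads(mixtures, inserts, toy$truth$primers,
                                   error_rate, corrupt_primer_frac, n_reads,
                                   seed = seed)
  trimmed <- trim_primers(reads, toy$truth$primers)
  accepted <- trimmed |> filter(.data$accepted) |>
    mutate(sequence = .data$insert)
  totals <- table(accepted$sample)
  cl <- greedy_cluster(accepted, threshold)
  sig <- significant_clusters(cl, totals, sig_frac)
  sig <- classify_clusters(sig, design, min_reads)
  inventory <- as_tibble(sig)[, c("cluster_id", "n_members", "mean_length",
                                  "class")]
  list(inventory = inventory, clusters = sig, accepted = accepted,
       totals = totals)
}
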