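# Cluster consensus via a star multiple alignment around the centroid, block
# decomposition of consensus sequences against the reference, and amplicon
# length prediction.

#' Majority consensus of a cluster
#'
#' Subsamples up to `k` members, star-aligns them to the cluster centroid
#' (pairwise optimal global alignments merged on centroid coordinates), and
#' takes the per-column majority symbol. Ties are broken in favour of the
#' centroid's symbol (consensus stays in A/C/G/T); columns where gaps hold a
#' strict majority are deleted. With i.i.d. substitution errors well below
#' 50% per column, the consensus converges to the true template.
#'
#' @param clusters an `amplicon_clusters` object.
#' @param inserts the trimmed read tibble the clusters were built from
#'   (columns `id`, `sequence`).
#' @param k members to subsample per cluster.
#' @param seed integer seed.
#' @return tibble: `cluster_id`, `consensus`, `n_used`, `support` (list-col:
#'   per-column fraction of members agreeing with the consensus symbol).
#' @export
cluster_consensus <- function(clusters, inserts, k = 25, seed = 1L) {
  seq_of <- setNames(inserts$sequence, inserts$id)
  cents <- attr(clusters, "centroid_seqs")
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
      ids <- clusters$members[[i]]
      use <- if (length(ids) > k) sort(sample(seq_along(ids), k)) else
        seq_along(ids)
      seqs <- unname(seq_of[ids[use]])
      cons <- star_consensus(cents[[i]], seqs)
      tibble(cluster_id = clusters$cluster_id[i], consensus = cons$sequence,
             n_used = length(seqs), support = list(cons$support))
    })
    bind_rows(rows)
  })
}

# star MSA around `center`; returns majority consensus and per-column support
star_consensus <- function(center, seqs) {
  if (length(seqs) == 1 && identical(seqs[[1]], center))
    return(list(sequence = center,
                support = rep(1, nchar(center))))
  n_center <- nchar(center)
  # per member: symbols at center positions, and insertions keyed by the
  # center position they follow (0 = before the first center base)
  aligned <- lapply(seqs, function(s) {
    al <- align_global(s, center)
    am <- strsplit(al$aligned_a, "")[[1]]
    ac <- strsplit(al$aligned_b, "")[[1]]
    at_center <- character(n_center)
    ins <- vector("list", n_center + 1L)
    p <- 0L
    buf <- character()
    for (j in seq_along(ac)) {
      if (ac[j] == "-") {
        buf <- c(buf, am[j])
      } else {
        if (length(buf)) { ins[[p + 1L]] <- buf; buf <- character() }
        p <- p + 1L
        at_center[p] <- am[j]
      }
    }
    if (length(buf)) ins[[p + 1L]] <- buf
    list(at_center = at_center, ins = ins)
  })
  n_mem <- length(aligned)
  ins_len <- integer(n_center + 1L)
  for (a in aligned) {
    l <- lengths(a$ins)
    ins_len <- pmax(ins_len, l)
  }
  # assemble the column matrix: insertions after position p, then base p+1
  cols <- list(); cent_sym <- character()
  for (p in 0:n_center) {
    if (ins_len[p + 1L] > 0) {
      for (q in seq_len(ins_len[p + 1L])) {
        cols[[length(cols) + 1L]] <- vapply(aligned, function(a) {
          v <- a$ins[[p + 1L]]
          if (q <= length(v)) v[q] else "-"
        }, character(1))
        cent_sym <- c(cent_sym, "-")
      }
    }
    if (p < n_center) {
      cols[[length(cols) + 1L]] <- vapply(aligned, function(a) {
        a$at_center[p + 1L]
      }, character(1))
      cent_sym <- c(cent_sym, substring(center, p + 1L, p + 1L))
    }
  }
  out <- character(); support <- numeric()
  for (j in seq_along(cols)) {
    tab <- table(cols[[j]])
    gaps <- if ("-" %in% names(tab)) tab[["-"]] else 0L
    if (2L * gaps > n_mem) next
    tab_b <- tab[names(tab) != "-"]
    top <- names(tab_b)[tab_b == max(tab_b)]
    sym <- if (cent_sym[j] %in% top) cent_sym[j] else sort(top)[1]
    out <- c(out, sym)
    support <- c(support, as.integer(tab_b[[sym]]) / n_mem)
  }
  list(sequence = paste(out, collapse = ""), support = support)
}

#' Map a consensus sequence onto the gene's genomic span
#'
#' Decomposes the consensus into maximal collinear matches against the coding
#' strand of the gene's genomic span (seed-and-extend with exact 18-mers,
#' junctions of up to 2 mismatched bases merged into one block), then labels
#' each block: blocks overlapping annotated exons are canonical exon
#' intervals, intronic blocks are novel, and a canonical block extending past
#' its exon's annotated bounds is reported in `extended_boundaries` with the
#' shift in bp.
#'
#' @param consensus a consensus DNA string (>= 50 bp).
#' @param reference named character vector (the contig).
#' @param gene a [gene_model()].
#' @param seed_size exact seed length for block anchoring.
#' @return an object of class `isoform_structure`: list with
#'   `exon_intervals`, `novel_blocks`, `extended_boundaries` tibbles (genomic,
#'   1-based closed) and `placed_fraction`.
#' @export
map_consensus <- function(consensus, reference, gene, seed_size = 18L) {
  cx_assert(nchar(consensus) >= 50, "consensus too short to map (>= 50 bp)")
  span <- gene_span(gene)
  target <- subseq_chr(unname(reference[[1]]), span[["start"]], span[["end"]])
  if (gene$strand == "-") target <- revcomp(target)
  blocks <- decompose_blocks(consensus, target, seed_size)
  placed <- sum(blocks$c_end - blocks$c_start + 1L)
  frac <- placed / nchar(consensus)
  if (frac < 0.8)
    rlang::abort(sprintf(
      "unmappable consensus: only %.0f%% of bases placed", 100 * frac),
      class = "crypticex_error")
  # target coordinates -> genomic
  g <- if (gene$strand == "+") {
    tibble(start = span[["start"]] + blocks$t_start - 1L,
           end = span[["start"]] + blocks$t_end - 1L)
  } else {
    tibble(start = span[["end"]] - blocks$t_end + 1L,
           end = span[["end"]] - blocks$t_start + 1L)
  }
  ex <- gene$exons
  hit_exon <- purrr::map_int(seq_len(nrow(g)), function(i) {
    ov <- which(g$start[i] <= ex$end & g$end[i] >= ex$start)
    if (length(ov) == 0) NA_integer_ else ov[which.max(
      pmin(g$end[i], ex$end[ov]) - pmax(g$start[i], ex$start[ov]))]
  })
  exon_rows <- list(); novel_rows <- list(); ext_rows <- list()
  for (i in seq_len(nrow(g))) {
    if (is.na(hit_exon[i])) {
      novel_rows[[length(novel_rows) + 1L]] <- g[i, ]
      next
    }
    e <- ex[hit_exon[i], ]
    exon_rows[[length(exon_rows) + 1L]] <-
      mutate(g[i, ], exon = e$exon, .before = 1)
    lo_shift <- e$start - g$start[i]
    hi_shift <- g$end[i] - e$end
    if (lo_shift > 0)
      ext_rows[[length(ext_rows) + 1L]] <- tibble(
        exon = e$exon,
        side = if (gene$strand == "+") "5prime" else "3prime",
        shift = lo_shift)
    if (hi_shift > 0)
      ext_rows[[length(ext_rows) + 1L]] <- tibble(
        exon = e$exon,
        side = if (gene$strand == "+") "3prime" else "5prime",
        shift = hi_shift)
  }
  structure(
    list(exon_intervals = if (length(exon_rows)) bind_rows(exon_rows) else
           tibble(exon = integer(), start = integer(), end = integer()),
         novel_blocks = if (length(novel_rows)) bind_rows(novel_rows) else
           tibble(start = integer(), end = integer()),
         extended_boundaries = if (length(ext_rows)) bind_rows(ext_rows) else
           tibble(exon = integer(), side = character(), shift = integer()),
         placed_fraction = frac),
    class = "isoform_structure")
}

#' @method print isoform_structure
#' @export
print.isoform_structure <- function(x, ...) {
  cat(sprintf("<isoform_structure> %d canonical blocks, %d novel, %d extended (%.0f%% placed)\n",
              nrow(x$exon_intervals), nrow(x$novel_blocks),
              nrow(x$extended_boundaries), 100 * x$placed_fraction))
  invisible(x)
}

# Greedy collinear block decomposition: exact seeds, maximal extension with a
# budget of <= `max_junction` substitution mismatches per block (each accepted
# mismatch must be backed by a run of >= 4 exact matches beyond it, so blocks
# never drift past their true boundary), plus merging of collinear neighbours
# across short substitution junctions.
decompose_blocks <- function(query, target, seed_size, max_junction = 2L) {
  qlen <- nchar(query); tlen <- nchar(target)
  ch_q <- strsplit(query, "")[[1]]
  ch_t <- strsplit(target, "")[[1]]
  raw <- list()
  c_cur <- 1L; t_min <- 1L
  while (c_cur + seed_size - 1L <= qlen) {
    seed <- substring(query, c_cur, c_cur + seed_size - 1L)
    hit <- find_from(target, seed, t_min)
    if (hit < 0) { c_cur <- c_cur + 1L; next }
    budget <- max_junction
    # extend right, stepping over isolated substitutions
    cl <- c_cur + seed_size - 1L; tl <- hit + seed_size - 1L
    repeat {
      while (cl < qlen && tl < tlen && ch_q[cl + 1L] == ch_t[tl + 1L]) {
        cl <- cl + 1L; tl <- tl + 1L
      }
      if (budget == 0L || cl + 1L >= qlen || tl + 1L >= tlen) break
      run <- 0L
      while (cl + 2L + run <= qlen && tl + 2L + run <= tlen &&
             ch_q[cl + 2L + run] == ch_t[tl + 2L + run]) run <- run + 1L
      if (run < 4L && !(cl + 2L + run > qlen)) break
      if (run < 1L) break
      cl <- cl + 1L; tl <- tl + 1L; budget <- budget - 1L
    }
    # extend left over previously unplaced bases, same mismatch rule
    cs <- c_cur; ts <- hit
    floor_c <- if (length(raw)) raw[[length(raw)]]$c_end + 1L else 1L
    floor_t <- if (length(raw)) raw[[length(raw)]]$t_end + 1L else 1L
    repeat {
      while (cs > floor_c && ts > floor_t && ch_q[cs - 1L] == ch_t[ts - 1L]) {
        cs <- cs - 1L; ts <- ts - 1L
      }
      if (budget == 0L || cs - 1L <= floor_c || ts - 1L <= floor_t) break
      run <- 0L
      while (cs - 2L - run >= floor_c && ts - 2L - run >= floor_t &&
             ch_q[cs - 2L - run] == ch_t[ts - 2L - run]) run <- run + 1L
      at_floor <- (cs - 2L - run < floor_c) || (ts - 2L - run < floor_t)
      if (run < 4L && !at_floor) break
      if (run < 1L) break
      cs <- cs - 1L; ts <- ts - 1L; budget <- budget - 1L
    }
    raw[[length(raw) + 1L]] <- list(c_start = cs, c_end = cl,
                                    t_start = ts, t_end = tl)
    c_cur <- cl + 1L; t_min <- tl + 1L
  }
  cx_assert(length(raw) > 0,
            "unmappable consensus: no anchor match against the reference")
  # merge collinear neighbours across short substitution junctions
  merged <- list(raw[[1]])
  for (b in raw[-1]) {
    last <- merged[[length(merged)]]
    gap_c <- b$c_start - last$c_end - 1L
    gap_t <- b$t_start - last$t_end - 1L
    if (gap_c == gap_t && gap_c >= 0L && gap_c <= max_junction) {
      last$c_end <- b$c_end; last$t_end <- b$t_end
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- b
    }
  }
  bind_rows(lapply(merged, as_tibble))
}

find_from <- function(target, pattern, from) {
  hit <- regexpr(pattern, substring(target, from), fixed = TRUE)[1]
  if (hit < 0) -1L else hit + from - 1L
}

#' Predicted amplicon lengths per isoform
#'
#' For each isoform block structure, splices the transcript from the
#' reference, locates the exact primer footprints, and returns the insert
#' length between them (the post-trim amplicon length). Isoforms missing a
#' primer footprint are skipped with a warning (`NA` in the result).
#'
#' @param isoforms named list of block tibbles (`start`, `end`, transcription
#'   order).
#' @param reference named character vector (the contig).
#' @param gene a [gene_model()] (for the strand).
#' @param primers named character vector `c(forward=, reverse=)`.
#' @return named numeric vector of insert lengths.
#' @export
predict_amplicon_lengths <- function(isoforms, reference, gene, primers) {
  if (length(isoforms) == 0) return(setNames(numeric(), character()))
  fwd <- unname(primers[["forward"]])
  rev_rc <- revcomp(unname(primers[["reverse"]]))
  vapply(isoforms, function(blocks) {
    tx <- splice_blocks(unname(reference[[1]]), blocks, gene$strand)
    f <- regexpr(fwd, tx, fixed = TRUE)[1]
    r <- regexpr(rev_rc, tx, fixed = TRUE)[1]
    if (f < 0 || r <= f) {
      rlang::warn("isoform lacks a primer footprint; skipped")
      return(NA_real_)
    }
    as.numeric(r - (f + nchar(fwd)))
  }, numeric(1))
}
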