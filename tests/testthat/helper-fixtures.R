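# Shared fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

toy_plus <- function() fixture("toy_plus", function() build_toy_locus(locus_spec()))
toy_minus <- function() fixture("toy_minus", function() {
  build_toy_locus(locus_spec(strand = "-"))
})

# reference with the alternate (cryptic-activating) allele substituted in
alt_reference <- function(toy) {
  ref <- toy$reference
  s <- unname(ref[[1]])
  v <- toy$truth$variant_position
  out <- paste0(substring(s, 1, v - 1), toy$truth$variant_alt,
                substring(s, v + 1, nchar(s)))
  setNames(out, names(ref))
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

# independent greedy clustering oracle: direct transcription of the rule,
# using the exported full-DP identity only
oracle_greedy <- function(seqs, ids, threshold) {
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  cent <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- 0L
    for (ci in seq_along(cent)) {
      if (global_identity(seqs[i], seqs[cent[ci]]) >= threshold) {
        placed <- ci; break
      }
    }
    if (placed == 0L) { cent <- c(cent, i); placed <- length(cent) }
    assign[i] <- placed
  }
  split(ids, assign)
}
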