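# Shared fixtures and independent oracles used across test files.

# Build a population_state from a plain matrix.
state_of <- function(m, generation = 0L) {
  population_state(matrix(as.integer(m), nrow = nrow(m)), generation)
}

# Naive re-scan of a stored state history: recomputes, with simple loops
# independent of the package's tracker, the per-generation LLC size, the
# per-locus minima, each locus's first-fixation generation and the overall
# first fixation time. History is a list of count matrices, one per
# generation (generation index = position in the list).
brute_rescan <- function(history) {
  g <- ncol(history[[1]])
  first_fix <- rep(NA_integer_, g)
  llc <- integer(length(history))
  minima_last <- integer(g)
  for (t in seq_along(history)) {
    m <- history[[t]]
    n_free <- 0L
    for (j in seq_len(nrow(m))) {
      if (all(m[j, ] == 0L)) n_free <- n_free + 1L
    }
    llc[t] <- n_free
    for (i in seq_len(g)) {
      mn <- min(m[, i])
      minima_last[i] <- mn
      if (mn >= 1L && is.na(first_fix[i])) first_fix[i] <- t
    }
  }
  list(llc = llc,
       first_fixation_generation = first_fix,
       fixed_mutation_count = minima_last,
       text = if (all(is.na(first_fix))) NA_integer_
              else min(first_fix, na.rm = TRUE))
}
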