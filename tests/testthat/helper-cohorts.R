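# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

small_cohort <- function(seed = 11, n_a = 10, n_b = 10, n_genes = 30,
                         dropout = 0, dispersion = 0.3, ...) {
  simulate_cohort(
    generate_codeset(n_genes, 0),
    sim_params(n_group_a = n_a, n_group_b = n_b, dropout_prob = dropout,
               dispersion = dispersion, seed = seed, ...)
  )
}

# Brute-force pair search, independent of tsp_search's vectorized path:
# plain double loop over pairs using pair_score only.
brute_force_tsp <- function(values, labels) {
  G <- nrow(values)
  best <- NULL
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      s <- pair_score(values[i, ], values[j, ], labels)$score
      if (is.null(best) || s > best$score + 1e-12) {
        best <- list(pair = rownames(values)[c(i, j)], score = s)
      }
    }
  }
  best
}

# Hand-built count_matrix over an explicit codeset, for normalization
# arithmetic checks.
manual_cm <- function(counts, classes, conc = NULL) {
  cs <- data.frame(
    probe_name = rownames(counts), probe_class = classes,
    concentration = if (is.null(conc)) NA_real_ else conc,
    stringsAsFactors = FALSE)
  class(cs) <- c("codeset", "data.frame")
  count_matrix(counts, cs)
}
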