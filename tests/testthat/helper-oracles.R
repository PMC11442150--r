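# Independent brute-force oracles used across the suite.

# Enrichment walk, materialising P_hit and P_miss at every position i.
# Deliberately naive (quadratic); must agree with the cumulative-sum
# implementation to 1e-12. Ties in |P_hit - P_miss| resolve to the
# earliest position (strict > comparison).
es_bruteforce <- function(ranking, signature_genes, alpha = 0.25) {
  ord <- ranking$ord
  N <- length(ord)
  hit <- ord %in% signature_genes
  NG <- sum(hit)
  stopifnot(NG > 0L, NG < N)
  rank_at_pos <- N:1
  denom <- sum(abs(rank_at_pos[hit])^alpha)
  best <- NA_real_
  best_abs <- -Inf
  for (i in seq_len(N)) {
    p_hit <- sum(abs(rank_at_pos[seq_len(i)][hit[seq_len(i)]])^alpha) / denom
    p_miss <- sum(!hit[seq_len(i)]) / (N - NG)
    d <- p_hit - p_miss
    if (abs(d) > best_abs) {
      best_abs <- abs(d)
      best <- d
    }
  }
  best
}

# AUROC by exhaustive (positive, negative) pair counting, 0.5 per tie.
auroc_pairs <- function(scores_pos, scores_neg) {
  tot <- 0
  for (p in scores_pos) for (n in scores_neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(scores_pos) * length(scores_neg))
}

# small shared simulated cohort (fast; used by several module tests)
tiny_cohort <- function(seed = 42L, effect_size = 3) {
  simulate_cohort(sim_config(n_genes = 300L, n_cells = 60L,
                             program_size = 30L,
                             effect_size = effect_size,
                             n_positive_drugs = 2L,
                             n_negative_drugs = 6L,
                             reversal_strength = 1,
                             seed = seed))
}

tiny_truth <- function(positives, pool, seed = 1L) {
  sample_negatives(positives, pool, seed = seed)
}
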