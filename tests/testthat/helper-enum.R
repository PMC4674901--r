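# Brute-force enumeration oracle: under the gene-by-gene model the set of
# deleted genes after k deletions is a uniformly random k-subset, so the
# exact run-length law follows from enumerating all choose(n, k)
# placements on the n-cycle.

# Signature string of a run-length multiset, e.g. "1+2".
run_signature <- function(lens) paste(sort(lens), collapse = "+")

# Exact distribution over run-length-multiset signatures, plus the exact
# per-placement mean and variance of the number of runs of each length.
enum_circular_subsets <- function(n, k) {
  combs <- utils::combn(n, k)
  m <- ncol(combs)
  sigs <- character(m)
  counts <- matrix(0L, nrow = m, ncol = k)  # runs of length l per placement
  for (j in seq_len(m)) {
    lens <- circ_single_runs(n, combs[, j])
    sigs[j] <- run_signature(lens)
    for (l in lens) counts[j, l] <- counts[j, l] + 1L
  }
  list(
    n_placements = m,
    sig_prob = table(sigs) / m,
    mean_runs = colMeans(counts),                  # E[# runs of length l]
    var_runs = apply(counts, 2, stats::var) * (m - 1) / m)
}
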