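# Run-length tallies: empirical estimates of psi_t (single-copy run
# lengths) and rho_t (double-copy run lengths).

#' Construct a run-length tally
#'
#' Counts of maximal single-copy runs (estimating the run-length
#' distribution psi_t) and double-copy runs (estimating rho_t) by length.
#' Counts are stored as dense integer vectors indexed by run length.
#'
#' @param single_lengths Integer vector of single-copy run lengths.
#' @param double_lengths Integer vector of double-copy run lengths.
#' @param n_genes Genome size `N` the runs were observed on.
#' @return An object of class `run_length_tally` with fields `single`,
#'   `double` (counts by length), `n_genes` and `deleted_count`.
#' @export
run_length_tally <- function(single_lengths, double_lengths, n_genes) {
  check_number(n_genes, "n_genes", min = 1, integerish = TRUE)
  single_lengths <- as.integer(single_lengths)
  double_lengths <- as.integer(double_lengths)
  tab <- function(x) {
    if (length(x) == 0L) integer(0) else tabulate(x, nbins = max(x))
  }
  structure(
    list(single = tab(single_lengths), double = tab(double_lengths),
         n_genes = as.integer(n_genes),
         deleted_count = sum(single_lengths)),
    class = "run_length_tally")
}

#' @export
print.run_length_tally <- function(x, ...) {
  cat("Run-length tally on N =", x$n_genes, "genes;",
      x$deleted_count, "deleted (1 - theta =",
      sprintf("%.3f)\n", x$deleted_count / x$n_genes))
  cat("  single-copy runs:", sum(x$single), " double-copy runs:",
      sum(x$double), "\n")
  invisible(x)
}

#' Counts-by-length vector of one run type
#' @param tally A [run_length_tally()].
#' @param run_type `"single"` or `"double"`.
#' @return Integer vector; element `l` is the number of runs of length `l`.
#' @export
tally_counts <- function(tally, run_type = c("single", "double")) {
  stopifnot(inherits(tally, "run_length_tally"))
  run_type <- match.arg(run_type)
  tally[[run_type]]
}

# Maximal-run lengths of a logical vector, honouring circular wrap.
run_lengths_logical <- function(x, circular) {
  n <- length(x)
  if (circular) {
    b <- which(x != x[c(n, seq_len(n - 1L))])[1L]
    if (is.na(b)) {
      r <- list(values = x[1L], lengths = n)
    } else {
      rot <- if (b == 1L) x else x[c(b:n, 1:(b - 1L))]
      r <- rle(rot)
    }
  } else {
    r <- rle(x)
  }
  list(single = r$lengths[r$values], double = r$lengths[!r$values])
}

#' Decompose a genome state into maximal runs
#'
#' @param state A [genome_state()].
#' @return A [run_length_tally()].  On a circular genome the run lengths of
#'   both types sum to `n_genes`; on a linear genome terminal runs are
#'   included as ordinary runs.
#' @export
extract_runs <- function(state) {
  stopifnot(inherits(state, "genome_state"))
  r <- run_lengths_logical(state$copies == 1L,
                           circular = state$topology == "circular")
  run_length_tally(r$single, r$double, state$n_genes)
}

#' Empirical mean double-copy run length
#'
#' The mean of the double-copy run-length distribution rho_t, written
#' nu_t; it decreases as fractionation proceeds and parameterises all the
#' analytic overlap probabilities.
#'
#' @param tally A [run_length_tally()].
#' @return Mean double-run length, or `NaN` if there are no double runs.
#' @export
mean_double_run <- function(tally) {
  stopifnot(inherits(tally, "run_length_tally"))
  counts <- tally$double
  if (sum(counts) == 0L) return(NaN)
  sum(seq_along(counts) * counts) / sum(counts)
}
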