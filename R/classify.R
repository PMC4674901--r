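# Kolmogorov-Smirnov classification of run-length samples onto the mu
# grid ("binning" estimator mu_hat).

# D between a counts-by-length vector and reference cumulative(s); ref may
# be a vector or a matrix with one column per candidate mu.  Both step
# functions are compared on all integers up to the longer support; beyond
# their own maximum both cumulatives are 1.
ks_counts_vs_cum <- function(counts, ref) {
  total <- sum(counts)
  ref <- as.matrix(ref)
  L <- max(length(counts), nrow(ref))
  samp <- cumsum(pad_right(counts, L)) / total
  if (nrow(ref) < L) {
    ref <- rbind(ref, matrix(1, L - nrow(ref), ncol(ref)))
  }
  apply(abs(ref - samp), 2, max)
}

#' Kolmogorov-Smirnov distance between a sample and a reference
#'
#' `D = max_l |Fhat_sample(l) - F_ref(l)|` over integer run lengths `l`,
#' each cumulative being the proportion of runs of length `<= l`.
#'
#' @param sample_tally A [run_length_tally()] with at least one run of
#'   `run_type`.
#' @param reference_cum Numeric reference cumulative over `l = 1, 2, ...`
#'   (e.g. from [reference_cumulative()]); 1 beyond its last element.
#' @param run_type `"single"` or `"double"`.
#' @return The KS distance `D` in `[0, 1]`.
#' @examples
#' tal <- run_length_tally(c(1, 3), c(4, 4), 12)
#' ks_distance(tal, cumsum(rep(0.25, 4)))  # sample {1,3} vs uniform on 1..4
#' @export
ks_distance <- function(sample_tally, reference_cum,
                        run_type = c("single", "double")) {
  run_type <- match.arg(run_type)
  counts <- tally_counts(sample_tally, run_type)
  if (sum(counts) == 0L) {
    stop("sample has no ", run_type, "-copy runs; classification undefined",
         call. = FALSE)
  }
  if (!is.numeric(reference_cum) || length(reference_cum) == 0L) {
    stop("`reference_cum` must be a non-empty numeric cumulative",
         call. = FALSE)
  }
  unname(ks_counts_vs_cum(counts, reference_cum))
}

classify_counts <- function(counts, mat, mu_values) {
  D <- ks_counts_vs_cum(counts, mat)
  hits <- which(D == min(D))
  list(distances = stats::setNames(D, sprintf("%.6g", mu_values)),
       mu_hat = mu_values[hits[1L]], tie = length(hits) > 1L)
}

#' Classify a run-length sample onto the mu grid
#'
#' Computes the KS distance between the sample cumulative and the
#' reference cumulative of every candidate `mu` at the sample's
#' `(N, 1 - theta)`, and assigns the sample to the bin with minimal
#' distance.  Exact ties are broken toward the smallest `mu`
#' (conservative toward the gene-by-gene model) and flagged.
#'
#' @param sample_tally A [run_length_tally()].
#' @param library A [build_reference()] result covering the cell.
#' @param n_genes,one_minus_theta Grid cell the sample was observed at.
#' @param run_type `"single"` or `"double"`.
#' @return An object of class `classification_result` with fields
#'   `distances` (named by candidate mu), `mu_hat`, `tie`, `n_genes`,
#'   `one_minus_theta`, `run_type`.
#' @export
classify_sample <- function(sample_tally, library, n_genes, one_minus_theta,
                            run_type = c("single", "double")) {
  run_type <- match.arg(run_type)
  counts <- tally_counts(sample_tally, run_type)
  if (sum(counts) == 0L) {
    stop("sample has no ", run_type, "-copy runs; classification undefined",
         call. = FALSE)
  }
  mat <- ref_cell_matrix(library, n_genes, one_minus_theta, run_type)
  res <- classify_counts(counts, mat, library$mu_values)
  structure(
    c(res, list(n_genes = as.integer(n_genes),
                one_minus_theta = one_minus_theta, run_type = run_type)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("mu_hat = %g (D = %.4f%s) at N = %d, 1 - theta = %.3f [%s runs]\n",
              x$mu_hat, min(x$distances), if (x$tie) ", tie" else "",
              x$n_genes, x$one_minus_theta, x$run_type))
  invisible(x)
}
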