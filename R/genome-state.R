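#' Post-WGD genome copy state
#'
#' Represents the per-position copy status of the `N` duplicated genes at
#' some time after the whole genome doubling: each gene is either still
#' `double` (both homeologous copies retained) or `single` (one copy
#' deleted by fractionation).  The initial state (t = 0) is all-double.
#'
#' The default topology is circular, which removes end effects exactly;
#' the model's assumption is that `N` is large enough for ends not to
#' matter, and a cycle realises that without ad-hoc boundary rules.
#' Linear chromosomes are supported for completeness.
#'
#' @param n_genes Number of duplicated genes `N` (`>= 2`).
#' @param singles Integer positions (1-based) already single-copy.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `genome_state` with fields `n_genes`,
#'   `copies` (integer vector of 2s and 1s) and `topology`.
#' @examples
#' g <- genome_state(12, singles = c(3, 4, 5, 9))
#' extract_runs(g)
#' @export
genome_state <- function(n_genes, singles = integer(0),
                         topology = c("circular", "linear")) {
  check_number(n_genes, "n_genes", min = 2, integerish = TRUE)
  topology <- match.arg(topology)
  n_genes <- as.integer(n_genes)
  singles <- as.integer(singles)
  if (anyDuplicated(singles) || any(singles < 1L | singles > n_genes)) {
    stop("`singles` must be distinct positions in 1..", n_genes, call. = FALSE)
  }
  if (length(singles) == n_genes) {
    stop("degenerate all-single state: no double-copy genes remain",
         call. = FALSE)
  }
  copies <- rep(2L, n_genes)
  copies[singles] <- 1L
  structure(list(n_genes = n_genes, copies = copies, topology = topology),
            class = "genome_state")
}

#' @export
print.genome_state <- function(x, ...) {
  cat("Genome state:", x$n_genes, "duplicated genes (", x$topology, ")\n")
  cat("  single-copy:", deleted_count(x),
      sprintf("(1 - theta = %.3f)\n", deleted_count(x) / x$n_genes))
  invisible(x)
}

#' Number of single-copy genes in a state
#' @param state A [genome_state()].
#' @return Integer count of positions with one remaining copy.
#' @export
deleted_count <- function(state) {
  stopifnot(inherits(state, "genome_state"))
  sum(state$copies == 1L)
}

#' Apply one deletion event with skipping
#'
#' Scans from `start` in increasing position order (wrapping on a circular
#' genome) and converts double-copy genes to single-copy until `a` have
#' been converted (or, on a linear genome, the chromosome end is reached).
#' Already-single-copy genes encountered along the way are skipped: the
#' excised fragment is no longer visible to the deletion process, so a
#' later event that lands near an existing run simply extends it.
#'
#' @param state A [genome_state()] with at least one double-copy gene.
#' @param start Start position; must currently be double-copy (the process
#'   samples starts among doubled genes only).
#' @param a Requested event length (the sampled geometric variate).
#' @return A list with the updated `state` and the `event`, an object of
#'   class `deletion_event` with fields `start`, `requested_length`,
#'   `converted` (positions changed, in scan order) and `overlapped_runs`
#'   (the number `q` of distinct pre-existing single-copy runs the event
#'   skipped through, i.e. absorbed into the new run).
#' @export
apply_deletion_event <- function(state, start, a) {
  stopifnot(inherits(state, "genome_state"))
  n <- state$n_genes
  check_number(start, "start", min = 1, max = n, integerish = TRUE)
  check_number(a, "a", min = 1, integerish = TRUE)
  if (all(state$copies == 1L)) {
    stop("no double-copy genes remain", call. = FALSE)
  }
  if (state$copies[start] != 2L) {
    stop("`start` must be a double-copy position (starts are sampled among ",
         "doubled genes)", call. = FALSE)
  }
  ord <- if (state$topology == "circular") {
    ((start - 1L) + 0:(n - 1L)) %% n + 1L
  } else {
    start:n
  }
  is_double <- state$copies[ord] == 2L
  quota <- min(a, sum(is_double))
  last <- which(cumsum(is_double) == quota)[1L]
  window <- seq_len(last)
  converted <- ord[window][is_double[window]]
  # skipped singles strictly inside the span; the window ends on a
  # conversion so trailing ("touching") runs are not counted
  gaps <- rle(is_double[window])
  overlapped <- sum(!gaps$values)
  state$copies[converted] <- 1L
  event <- structure(
    list(start = as.integer(start), requested_length = as.integer(a),
         converted = as.integer(converted),
         overlapped_runs = as.integer(overlapped)),
    class = "deletion_event")
  list(state = state, event = event)
}

#' @export
print.deletion_event <- function(x, ...) {
  cat("Deletion event: start", x$start, "requested", x$requested_length,
      "converted", length(x$converted), "overlapped_runs", x$overlapped_runs,
      "\n")
  invisible(x)
}
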