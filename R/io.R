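# Plain-text interchange: per-gene copy-state tracks and run-length
# summaries, so observed post-WGD genomes can be brought in for
# classification and simulation output can be inspected outside R.

#' Write a per-gene copy-state track
#'
#' TSV with a header and columns `position` (1-based), optionally
#' `gene_id`, and `copies` (2 = still duplicated, 1 = fractionated).
#'
#' @param state A [genome_state()].
#' @param path Output file.
#' @param gene_ids Optional character vector of `n_genes` identifiers.
#' @return `path`, invisibly.
#' @export
write_copy_state_track <- function(state, path, gene_ids = NULL) {
  stopifnot(inherits(state, "genome_state"))
  df <- data.frame(position = seq_len(state$n_genes))
  if (!is.null(gene_ids)) {
    stopifnot(length(gene_ids) == state$n_genes)
    df$gene_id <- as.character(gene_ids)
  }
  df$copies <- state$copies
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene copy-state track
#'
#' @param path TSV written by [write_copy_state_track()] (or by hand, for
#'   an observed genome): columns `position` and `copies`, `gene_id`
#'   optional.  Positions must be exactly `1..N`.
#' @param topology Topology to interpret the track under.
#' @return A [genome_state()].
#' @export
read_copy_state_track <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  df <- read.delim(path)
  if (!all(c("position", "copies") %in% names(df))) {
    stop("track must have columns `position` and `copies`", call. = FALSE)
  }
  n <- nrow(df)
  if (!setequal(df$position, seq_len(n))) {
    stop("`position` must cover 1..", n, " exactly", call. = FALSE)
  }
  if (!all(df$copies %in% c(1L, 2L))) {
    stop("`copies` must be 1 or 2", call. = FALSE)
  }
  genome_state(n, singles = df$position[df$copies == 1L],
               topology = topology)
}

#' Write a trajectory run-length summary
#'
#' TSV with one row per (checkpoint, run type, length): columns
#' `one_minus_theta`, `run_type`, `length`, `count`.
#'
#' @param trajectory A [simulate_fractionation()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_summary <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "fractionation_trajectory"))
  rows <- list()
  for (chk in trajectory$checkpoints) {
    for (rt in c("single", "double")) {
      counts <- chk$tally[[rt]]
      keep <- which(counts > 0L)
      if (length(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          one_minus_theta = chk$one_minus_theta, run_type = rt,
          length = keep, count = counts[keep])
      }
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a run-length tally from a summary TSV
#'
#' Accepts the [write_trajectory_summary()] format restricted to one
#' checkpoint (or any TSV with columns `run_type`, `length`, `count`).
#'
#' @param path Input TSV.
#' @param n_genes Genome size the runs were observed on; default: sum of
#'   `length * count` over both run types.
#' @return A [run_length_tally()].
#' @export
read_run_length_tally <- function(path, n_genes = NULL) {
  df <- read.delim(path)
  if (!all(c("run_type", "length", "count") %in% names(df))) {
    stop("tally file must have columns `run_type`, `length`, `count`",
         call. = FALSE)
  }
  if ("one_minus_theta" %in% names(df) &&
      length(unique(df$one_minus_theta)) > 1L) {
    stop("file holds several checkpoints; filter to one before reading ",
         "a tally", call. = FALSE)
  }
  expand <- function(rt) {
    sub <- df[df$run_type == rt, , drop = FALSE]
    rep(sub$length, sub$count)
  }
  single <- expand("single")
  double <- expand("double")
  if (is.null(n_genes)) n_genes <- sum(single) + sum(double)
  run_length_tally(single, double, n_genes)
}
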