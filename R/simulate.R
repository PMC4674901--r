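#' Simulate the fractionation process
#'
#' Starting from an all-double genome of `n_genes` duplicated genes,
#' repeatedly (i) chooses a start uniformly among the currently
#' double-copy genes, (ii) draws a length `a` from the geometric deletion
#' law, and (iii) converts the next `a` double-copy genes in scan order to
#' single-copy, skipping genes that are already single-copy.  Run-length
#' tallies are recorded at each requested deleted proportion `1 - theta`.
#'
#' By default the final event before each checkpoint is truncated so that
#' the deleted count lands exactly on `round((1 - theta) * N)`, making the
#' recorded tallies conditional on an exact deleted fraction (the
#' convention used for the reference grids).  `truncate = FALSE` instead
#' records the state at the first event that reaches or crosses each
#' checkpoint.
#'
#' @param n_genes Genome size `N` (`>= 2`).
#' @param model A [geometric_deletion_model()] or a numeric `mu >= 1`.
#' @param checkpoints Strictly increasing deleted proportions `1 - theta`,
#'   each in (0, 1); they must map to distinct deleted counts that leave
#'   at least one double-copy gene.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param seed Integer seed; identical `(parameters, seed)` give
#'   bit-identical trajectories.  `NULL` uses (and advances) the current
#'   RNG stream.
#' @param keep_events Retain the full event log and per-checkpoint
#'   event-id snapshots (needed by [run_composition()]).
#' @param truncate Truncate the final event of each leg (see above).
#' @return An object of class `fractionation_trajectory`: a list with the
#'   simulation parameters, a `checkpoints` list (each element holding
#'   `one_minus_theta`, `deleted_count`, `n_events`, the
#'   [run_length_tally()] `tally`, and with `keep_events` the per-position
#'   `event_ids`), and with `keep_events` an `events` data frame with
#'   columns `start`, `requested_length`, `n_converted`, `overlapped_runs`.
#' @examples
#' tr <- simulate_fractionation(100, 1.5, checkpoints = c(0.2, 0.5), seed = 1)
#' tr$checkpoints[[1]]$tally
#' @export
simulate_fractionation <- function(n_genes, model, checkpoints,
                                   topology = c("circular", "linear"),
                                   seed = NULL, keep_events = FALSE,
                                   truncate = TRUE) {
  check_number(n_genes, "n_genes", min = 2, integerish = TRUE)
  model <- as_deletion_model(model)
  topology <- match.arg(topology)
  if (length(checkpoints) < 1L || !is.numeric(checkpoints)) {
    stop("`checkpoints` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(checkpoints <= 0) || any(checkpoints >= 1)) {
    stop("`checkpoints` (deleted proportions 1 - theta) must lie strictly ",
         "in (0, 1)", call. = FALSE)
  }
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop("`checkpoints` must be strictly increasing", call. = FALSE)
  }
  targets <- as.integer(round(checkpoints * n_genes))
  if (any(targets < 1L)) {
    stop("checkpoint too small: round((1 - theta) * N) must be >= 1",
         call. = FALSE)
  }
  if (any(targets >= n_genes)) {
    stop("checkpoint too large: it would delete every gene", call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("checkpoints map to duplicate deleted counts at N = ", n_genes,
         call. = FALSE)
  }

  res <- with_seed(seed, sim_fractionation_cpp(
    as.integer(n_genes), model$mu, targets,
    circular = topology == "circular",
    truncate = truncate, keep_events = keep_events))

  chk <- vector("list", length(checkpoints))
  for (i in seq_along(checkpoints)) {
    chk[[i]] <- list(
      one_minus_theta = checkpoints[i],
      deleted_count = res$deleted[i],
      n_events = res$n_events[i],
      tally = run_length_tally(res$single_runs[[i]], res$double_runs[[i]],
                               n_genes))
    if (keep_events) chk[[i]]$event_ids <- res$event_ids[[i]]
  }
  events <- NULL
  if (keep_events) {
    events <- data.frame(start = res$ev_start,
                         requested_length = res$ev_requested,
                         n_converted = res$ev_converted,
                         overlapped_runs = res$ev_overlapped)
  }
  structure(
    list(n_genes = as.integer(n_genes), mu = model$mu, topology = topology,
         seed = seed, one_minus_theta = checkpoints, truncate = truncate,
         checkpoints = chk, events = events),
    class = "fractionation_trajectory")
}

#' @export
print.fractionation_trajectory <- function(x, ...) {
  cat("Fractionation trajectory: N =", x$n_genes, " mu =", x$mu,
      paste0("(", x$topology, ")\n"))
  cat("  checkpoints at 1 - theta =",
      paste(format(x$one_minus_theta), collapse = ", "), "\n")
  if (!is.null(x$events)) cat("  event log:", nrow(x$events), "events\n")
  invisible(x)
}

# Index of the checkpoint matching a deleted proportion (within fp noise).
checkpoint_index <- function(trajectory, one_minus_theta) {
  i <- which(abs(trajectory$one_minus_theta - one_minus_theta) < 1e-8)
  if (length(i) != 1L) {
    stop("trajectory has no checkpoint at 1 - theta = ", one_minus_theta,
         call. = FALSE)
  }
  i
}

#' Run-length tally at a trajectory checkpoint
#' @param trajectory A [simulate_fractionation()] result.
#' @param one_minus_theta One of the trajectory's checkpoint proportions.
#' @return The [run_length_tally()] recorded there.
#' @export
trajectory_tally <- function(trajectory, one_minus_theta) {
  stopifnot(inherits(trajectory, "fractionation_trajectory"))
  trajectory$checkpoints[[checkpoint_index(trajectory, one_minus_theta)]]$tally
}
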