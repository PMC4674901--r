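#' Event composition of single-copy runs
#'
#' For each maximal single-copy run present at a checkpoint, reports how
#' many deletion events contributed converted genes to it and the mean
#' requested length of those events.  Because skipped genes lie between a
#' single event's conversions, each event's contribution is contiguous at
#' the time of the event and stays inside one run thereafter, so every
#' event belongs to exactly one run.
#'
#' Under the gene-by-gene model (`mu = 1`) a run of length `l` is always
#' built from `l` events of length 1.  Under segmental models the events
#' found in runs built from many events tend to be the longer ones — long
#' events overlap existing runs more often — which is the signature
#' non-independence that frustrates a closed-form run-length law.
#'
#' @param trajectory A [simulate_fractionation()] result with
#'   `keep_events = TRUE`.
#' @param one_minus_theta Checkpoint to inspect.
#' @return A data frame with one row per single-copy run: `run_length`,
#'   `n_events`, `mean_event_length` (mean requested length of the
#'   constituent events).
#' @export
run_composition <- function(trajectory, one_minus_theta) {
  stopifnot(inherits(trajectory, "fractionation_trajectory"))
  if (is.null(trajectory$events)) {
    stop("trajectory has no event log; rerun simulate_fractionation() with ",
         "keep_events = TRUE", call. = FALSE)
  }
  i <- checkpoint_index(trajectory, one_minus_theta)
  evid <- trajectory$checkpoints[[i]]$event_ids
  single <- evid > 0L
  n <- trajectory$n_genes
  circular <- trajectory$topology == "circular"

  # walk positions starting at a run boundary so wrap-around runs are whole
  ord <- seq_len(n)
  if (circular) {
    b <- which(single != single[c(n, seq_len(n - 1L))])[1L]
    if (!is.na(b) && b > 1L) ord <- c(b:n, 1:(b - 1L))
  }
  r <- rle(single[ord])
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  req <- trajectory$events$requested_length

  keep <- which(r$values)
  out <- data.frame(run_length = integer(length(keep)),
                    n_events = integer(length(keep)),
                    mean_event_length = numeric(length(keep)))
  for (j in seq_along(keep)) {
    pos <- ord[starts[keep[j]]:ends[keep[j]]]
    ids <- unique(evid[pos])
    out$run_length[j] <- length(pos)
    out$n_events[j] <- length(ids)
    out$mean_event_length[j] <- mean(req[ids])
  }
  out[order(out$run_length), , drop = FALSE]
}
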