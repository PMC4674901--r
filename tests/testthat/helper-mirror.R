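# Pure-R mirror of the compiled fractionation event loop.  Uses the same
# RNG draw order (u1 = start index among doubles in position order,
# u2 = geometric length by inversion, drawn even when mu = 1), so with the
# same seed it must reproduce simulate_fractionation() bit-identically.
# Serves as the independent step-by-step reference for the skipping rule.
mirror_simulate <- function(n_genes, mu, checkpoints,
                            topology = "circular", seed = NULL,
                            truncate = TRUE) {
  n <- as.integer(n_genes)
  circular <- topology == "circular"
  targets <- as.integer(round(checkpoints * n))
  if (!is.null(seed)) set.seed(seed)
  single <- logical(n)
  evid <- integer(n)
  deleted <- 0L
  k <- n
  evcount <- 0L
  ev_start <- integer(0); ev_req <- numeric(0)
  ev_conv <- integer(0); ev_over <- integer(0)
  chk <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    target <- targets[ti]
    while (deleted < target) {
      evcount <- evcount + 1L
      u1 <- runif(1)
      idx <- min(floor(u1 * k), k - 1)
      pos <- which(!single)[idx + 1]
      u2 <- runif(1)
      if (mu <= 1) {
        a <- 1
      } else {
        a <- 1 + floor(log(1 - u2) / log(1 - 1 / mu))
        if (!is.finite(a) || a < 1 || a > 2147483647) a <- 2147483647
      }
      quota <- a
      if (truncate) quota <- min(quota, target - deleted)
      quota <- min(quota, k)
      converted <- 0L; overlapped <- 0L; in_gap <- FALSE
      i <- pos
      while (converted < quota) {
        if (!single[i]) {
          single[i] <- TRUE
          evid[i] <- evcount
          converted <- converted + 1L
          in_gap <- FALSE
        } else if (!in_gap) {
          overlapped <- overlapped + 1L
          in_gap <- TRUE
        }
        i <- i + 1L
        if (i > n) {
          if (circular) i <- 1L else break
        }
      }
      deleted <- deleted + converted
      k <- k - converted
      ev_start <- c(ev_start, pos)
      ev_req <- c(ev_req, a)
      ev_conv <- c(ev_conv, converted)
      ev_over <- c(ev_over, overlapped)
      if (!truncate && deleted >= target) break
    }
    chk[[ti]] <- list(singles = which(single), deleted = deleted,
                      event_ids = evid, n_events = evcount)
  }
  list(checkpoints = chk,
       events = data.frame(start = ev_start, requested_length = ev_req,
                           n_converted = ev_conv,
                           overlapped_runs = ev_over))
}

# Independent circular run-length extraction from a set of single-copy
# positions (adjacency grouping, no rle / no package code).
circ_single_runs <- function(n, singles) {
  k <- length(singles)
  if (k == 0L) return(integer(0))
  if (k == n) return(n)
  s <- sort(singles)
  grp <- cumsum(c(TRUE, diff(s) > 1L))
  lens <- as.integer(table(grp))
  # merge runs adjacent across the wrap
  if (length(lens) > 1L && s[1] == 1L && s[k] == n) {
    lens[1] <- lens[1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  sort(lens)
}
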