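test_that("trajectories are deterministic given seed and parameters", {
  a <- simulate_fractionation(120, 1.7, checkpoints = c(0.2, 0.6),
                              seed = 77, keep_events = TRUE)
  b <- simulate_fractionation(120, 1.7, checkpoints = c(0.2, 0.6),
                              seed = 77, keep_events = TRUE)
  expect_identical(a, b)
  c <- simulate_fractionation(120, 1.7, checkpoints = c(0.2, 0.6),
                              seed = 78, keep_events = TRUE)
  expect_false(identical(a$events, c$events))
})

test_that("checkpoint parameters are validated", {
  expect_error(simulate_fractionation(50, 1, checkpoints = numeric(0)),
               "non-empty")
  expect_error(simulate_fractionation(50, 1, checkpoints = c(0.2, 0.2)),
               "strictly increasing")
  expect_error(simulate_fractionation(50, 1, checkpoints = c(0.5, 1)),
               "\\(0, 1\\)")
  expect_error(simulate_fractionation(50, 1, checkpoints = 0),
               "\\(0, 1\\)")
  expect_error(simulate_fractionation(50, 1, checkpoints = 0.995),
               "every gene")
  expect_error(simulate_fractionation(50, 1, checkpoints = 0.001),
               ">= 1")
  expect_error(simulate_fractionation(1, 1, checkpoints = 0.5), ">= 2")
  expect_error(simulate_fractionation(50, 0.5, checkpoints = 0.5), ">= 1")
})

test_that("gene-by-gene deletion never overlaps and lands exactly", {
  tr <- simulate_fractionation(60, 1, checkpoints = 0.5, seed = 3,
                               keep_events = TRUE)
  expect_equal(nrow(tr$events), 30)  # round(0.5 * 60) events of length 1
  expect_true(all(tr$events$requested_length == 1))
  expect_true(all(tr$events$n_converted == 1))
  expect_true(all(tr$events$overlapped_runs == 0))
  expect_equal(tr$checkpoints[[1]]$deleted_count, 30L)

  # N = 4, 1 - theta = 0.25: exactly one gene single
  tr4 <- simulate_fractionation(4, 1, checkpoints = 0.25, seed = 5)
  expect_equal(trajectory_tally(tr4, 0.25)$single, 1L)
})

test_that("compiled trajectories match the pure-R mirror bit for bit", {
  set.seed(2024)
  cases <- expand.grid(mu = c(1, 1.4, 2.4, 3.5),
                       topology = c("circular", "linear"),
                       truncate = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    n <- sample(12:80, 1)
    seed <- sample.int(1e6, 1)
    chks <- c(0.25, 0.5, 0.8)
    tr <- simulate_fractionation(n, cases$mu[i], chks,
                                 topology = cases$topology[i], seed = seed,
                                 keep_events = TRUE,
                                 truncate = cases$truncate[i])
    mir <- mirror_simulate(n, cases$mu[i], chks,
                           topology = cases$topology[i], seed = seed,
                           truncate = cases$truncate[i])
    expect_equal(tr$events, mir$events)
    for (ci in seq_along(chks)) {
      expect_identical(tr$checkpoints[[ci]]$deleted_count,
                       mir$checkpoints[[ci]]$deleted)
      expect_identical(tr$checkpoints[[ci]]$event_ids,
                       mir$checkpoints[[ci]]$event_ids)
      # tallies agree with independent extraction from the mirror state
      if (cases$topology[i] == "circular") {
        s <- tally_counts(tr$checkpoints[[ci]]$tally, "single")
        expect_equal(rep(seq_along(s), s),
                     circ_single_runs(n, mir$checkpoints[[ci]]$singles))
      }
    }
  }
})

test_that("checkpoint truncation lands exactly; first-crossing may overshoot", {
  tr <- simulate_fractionation(200, 2.4, checkpoints = seq(0.1, 0.9, 0.2),
                               seed = 9)
  got <- vapply(tr$checkpoints, `[[`, integer(1), "deleted_count")
  expect_equal(got, as.integer(round(seq(0.1, 0.9, 0.2) * 200)))

  trf <- simulate_fractionation(200, 2.4, checkpoints = seq(0.1, 0.9, 0.2),
                                seed = 9, truncate = FALSE)
  gotf <- vapply(trf$checkpoints, `[[`, integer(1), "deleted_count")
  expect_true(all(gotf >= round(seq(0.1, 0.9, 0.2) * 200)))
  expect_true(!is.unsorted(gotf))
})

test_that("conservation and monotone fractionation hold along trajectories", {
  chks <- seq(0.1, 0.9, 0.1)
  for (seed in 1:5) {
    tr <- simulate_fractionation(150, 2, chks, seed = seed)
    for (chk in tr$checkpoints) {
      s <- chk$tally$single
      d <- chk$tally$double
      expect_equal(sum(seq_along(s) * s) + sum(seq_along(d) * d), 150)
    }
    del <- vapply(tr$checkpoints, `[[`, integer(1), "deleted_count")
    expect_true(!is.unsorted(del, strictly = TRUE))
  }
})

test_that("mean double-copy run length nu_t decreases as deletion proceeds", {
  chks <- seq(0.1, 0.9, 0.1)
  nu <- matrix(0, nrow = 40, ncol = length(chks))
  set.seed(31)
  for (r in 1:40) {
    tr <- simulate_fractionation(300, 1.6, chks)
    nu[r, ] <- vapply(tr$checkpoints,
                      function(chk) mean_double_run(chk$tally), numeric(1))
  }
  expect_true(all(diff(colMeans(nu)) < 0))
})

test_that("mu = 1 run-length law matches the exact subset-enumeration oracle", {
  # N = 6 circular, 2 deleted: quick version of the brute-force check
  oracle <- enum_circular_subsets(6, 2)
  reps <- 20000
  sigs <- character(reps)
  set.seed(606)
  for (r in seq_len(reps)) {
    tal <- trajectory_tally(
      simulate_fractionation(6, 1, checkpoints = 2 / 6), 2 / 6)
    s <- tally_counts(tal, "single")
    sigs[r] <- run_signature(rep(seq_along(s), s))
  }
  emp <- table(factor(sigs, levels = names(oracle$sig_prob))) / reps
  for (cat in names(oracle$sig_prob)) {
    p <- as.numeric(oracle$sig_prob[cat])
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(emp[cat] - p), 3 * se)
  }
})

test_that("empirical no-overlap fraction tracks p0 as runs shorten", {
  # p0 counts events that fall strictly inside a double run; an event
  # with overlapped_runs = 0 may additionally "touch" a run boundary
  # without skipping, so the empirical fraction sits above p0 by the
  # touching probability, which is O((mu + 1) / nu_t): both start-at-
  # first-gene and end-at-last-gene involve hitting ~1 position out of
  # the ~nu_t in the run.  Test the decline and those two-sided bounds.
  mu <- 2
  chks <- seq(0.1, 0.4, 0.1)
  pred <- obs <- nus <- matrix(NA_real_, nrow = 30, ncol = length(chks) - 1)
  set.seed(88)
  for (r in 1:30) {
    tr <- simulate_fractionation(900, mu, chks, keep_events = TRUE)
    nev <- vapply(tr$checkpoints, `[[`, integer(1), "n_events")
    nu <- vapply(tr$checkpoints,
                 function(chk) mean_double_run(chk$tally), numeric(1))
    for (ci in seq_len(length(chks) - 1)) {
      ev <- tr$events$overlapped_runs[(nev[ci] + 1):nev[ci + 1]]
      obs[r, ci] <- mean(ev == 0)
      nus[r, ci] <- mean(nu[ci:(ci + 1)])
      pred[r, ci] <- p0_discrete_closed(overlap_params(mu, nus[r, ci]))
    }
  }
  mo <- colMeans(obs)
  mp <- colMeans(pred)
  expect_true(all(diff(mo) < 0))           # declines as nu_t shrinks
  expect_true(all(mo > mp - 0.03))         # touching only inflates it
  expect_true(all(mo - mp < (mu + 1) / colMeans(nus) + 0.05))
})
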