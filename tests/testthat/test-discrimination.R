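# Small grids keep these unit checks fast; the paper-scale study runs in
# the acceptance suite.

small_lib <- build_reference(mu_values = c(1, 1.5, 2.4), n_genes = 120,
                             one_minus_theta = c(0.2, 0.5, 0.9),
                             replicates = 40, seed = 501)

test_that("reference libraries are deterministic and well-formed", {
  again <- build_reference(mu_values = c(1, 1.5, 2.4), n_genes = 120,
                           one_minus_theta = c(0.2, 0.5, 0.9),
                           replicates = 40, seed = 501)
  expect_identical(small_lib$cum, again$cum)

  for (rt in c("single", "double")) {
    for (omt in c(0.2, 0.5, 0.9)) {
      for (mu in c(1, 1.5, 2.4)) {
        cum <- reference_cumulative(small_lib, mu, 120, omt, rt)
        expect_true(all(diff(cum) >= -1e-12))   # non-decreasing
        expect_equal(cum[length(cum)], 1)       # reaches 1
      }
    }
  }
})

test_that("pigeonhole: double runs at 1 - theta = 0.9 are short", {
  lib <- build_reference(mu_values = 1, n_genes = 100,
                         one_minus_theta = 0.9, replicates = 1,
                         run_type = "double", seed = 8)
  cum <- reference_cumulative(lib, 1, 100, 0.9, "double")
  expect_lte(length(cum), 10)  # only 10 double-copy genes remain
})

test_that("segmental deletion fattens the single-run tail", {
  lib <- build_reference(mu_values = c(1, 2.4), n_genes = 900,
                         one_minus_theta = 0.2, replicates = 50,
                         run_type = "single", seed = 13)
  f1 <- reference_cumulative(lib, 1, 900, 0.2, "single")
  f24 <- reference_cumulative(lib, 2.4, 900, 0.2, "single")
  expect_lt(f24[1], f1[1])  # fewer length-1 runs under mu = 2.4
})

test_that("KS distance agrees with enumerated step functions", {
  # sample runs {1, 3} vs uniform reference on {1,2,3,4}: D = 0.25
  tal <- run_length_tally(c(1, 3), c(4, 4), 12)
  expect_equal(ks_distance(tal, cumsum(rep(0.25, 4))), 0.25)
  # identical cumulatives: D = 0
  expect_equal(ks_distance(tal, c(0.5, 0.5, 1)), 0)
  # disjoint supports: D = 1
  ones <- run_length_tally(rep(1, 5), 15, 20)
  expect_equal(ks_distance(ones, c(rep(0, 9), 1)), 1)
  # sample with no runs of the requested type errors
  nod <- run_length_tally(c(2, 2), integer(0), 20)
  expect_error(ks_distance(nod, c(0.5, 1), run_type = "double"),
               "no double-copy runs")
  expect_true(all(ks_distance(tal, c(0.1, 0.2, 0.9, 1)) >= 0))
})

test_that("a pooled reference sample classifies to its own bin with D = 0", {
  # replaying the library's RNG stream reproduces the mu = 1 cell's
  # replicates; their pooled runs are exactly the reference counts
  lens <- list(single = integer(0), double = integer(0))
  set.seed(501)
  for (r in 1:40) {
    tr <- simulate_fractionation(120, 1, c(0.2, 0.5, 0.9))
    tal <- trajectory_tally(tr, 0.5)
    for (rt in c("single", "double")) {
      cnt <- tally_counts(tal, rt)
      lens[[rt]] <- c(lens[[rt]], rep(seq_along(cnt), cnt))
    }
  }
  pooled <- run_length_tally(lens$single, lens$double, 120)
  cl <- classify_sample(pooled, small_lib, 120, 0.5, "single")
  expect_equal(cl$mu_hat, 1)
  expect_equal(unname(cl$distances["1"]), 0)
  expect_false(cl$tie)
})

test_that("exact ties break toward the smallest mu and are flagged", {
  lib <- small_lib
  # duplicate the mu = 1 column so two candidates are identical
  for (key in names(lib$cum$single)) {
    lib$cum$single[[key]][, 2] <- lib$cum$single[[key]][, 1]
    lib$cum$double[[key]][, 2] <- lib$cum$double[[key]][, 1]
  }
  tr <- simulate_fractionation(120, 1, 0.5, seed = 77)
  cl <- classify_sample(trajectory_tally(tr, 0.5), lib, 120, 0.5)
  expect_true(cl$tie)
  expect_equal(cl$mu_hat, 1)
  expect_equal(unname(cl$distances["1"]), unname(cl$distances["1.5"]))
})

test_that("missing grid cells are reported by name", {
  tal <- run_length_tally(c(1, 2), c(3, 4), 10)
  expect_error(classify_sample(tal, small_lib, 999, 0.5), "N = 999")
  expect_error(classify_sample(tal, small_lib, 120, 0.35),
               "1 - theta = 0.35")
  slib <- build_reference(mu_values = 1, n_genes = 50,
                          one_minus_theta = 0.5, replicates = 2,
                          run_type = "single", seed = 1)
  expect_error(classify_sample(tal, slib, 50, 0.5, "double"),
               "no double-run")
})

test_that("assessment tabulates proper frequency distributions", {
  expect_warning(
    a <- assess_discrimination(true_mu = c(1, 2.4), n_genes = 120,
                               one_minus_theta = c(0.2, 0.5),
                               samples_per_cell = 40, library = small_lib,
                               run_type = "single", seed = 501),
    "library seed")
  a <- assess_discrimination(true_mu = c(1, 2.4), n_genes = 120,
                             one_minus_theta = c(0.2, 0.5),
                             samples_per_cell = 40, library = small_lib,
                             run_type = "single", seed = 733)
  sums <- tapply(a$freq, paste(a$true_mu, a$one_minus_theta), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # widely separated generating mu are recovered as the modal bin
  for (mu in c(1, 2.4)) {
    cell <- a[a$true_mu == mu & a$one_minus_theta == 0.2, ]
    expect_equal(cell$mu_hat[which.max(cell$freq)], mu)
  }
})

test_that("run-type comparison requires matching grids and is 0 on itself", {
  a <- assess_discrimination(true_mu = 1, n_genes = 120,
                             one_minus_theta = c(0.2, 0.5),
                             samples_per_cell = 20, library = small_lib,
                             run_type = c("single", "double"), seed = 9)
  cmp <- compare_run_types(a, a)
  expect_equal(nrow(cmp), 2)
  expect_true(all(is.finite(cmp$diff)))
  same <- compare_run_types(
    a[a$run_type == "single", ], a[a$run_type == "single", ])
  expect_true(all(same$diff == 0))
  b <- assess_discrimination(true_mu = 1, n_genes = 120,
                             one_minus_theta = 0.2,
                             samples_per_cell = 20, library = small_lib,
                             run_type = "double", seed = 10)
  expect_error(compare_run_types(a, b), "different")
})
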