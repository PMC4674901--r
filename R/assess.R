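# Discrimination error assessment: how often does the KS binning
# estimator recover the generating mu, and how often does it confuse a
# segmental process with the gene-by-gene model?

#' Assess discrimination error rates
#'
#' For each `(true mu, N)` cell, simulates `samples_per_cell` fresh
#' trajectories of the deletion process, observes each at every requested
#' deleted proportion (one trajectory followed across all its
#' checkpoints), classifies it by minimal KS distance against the
#' reference library, and tabulates the frequency of each estimate
#' `mu_hat`.  The frequency of `mu_hat = 1` is the quantity of interest
#' for the functional-vs-structural question: at true `mu = 1` it is one
#' minus the type-I error of the test of the gene-by-gene model.
#'
#' @param true_mu Generating mean deletion lengths to test.
#' @param n_genes Genome sizes (must be in the library grid).
#' @param one_minus_theta Checkpoints; default all library checkpoints.
#' @param samples_per_cell Fresh trajectories per `(true mu, N)` cell.
#' @param library A [build_reference()] result.  Build it with a seed
#'   independent of `seed`.
#' @param run_type Run type(s) to classify on: `"single"`, `"double"` or
#'   both; the same trajectories are reused for each type, as in the
#'   comparison of the two approaches.
#' @param seed Integer seed for the test samples.
#' @return An object of class `error_assessment`: a data frame with
#'   columns `run_type`, `true_mu`, `n_genes`, `one_minus_theta`,
#'   `mu_hat`, `count`, `freq` (all candidate bins present, frequencies
#'   summing to 1 per cell), with the study parameters in attributes.
#' @export
assess_discrimination <- function(true_mu, n_genes,
                                  one_minus_theta = NULL,
                                  samples_per_cell = 300,
                                  library,
                                  run_type = c("single", "double"),
                                  seed = NULL) {
  stopifnot(inherits(library, "reference_library"))
  run_type <- match.arg(run_type, several.ok = TRUE)
  if (!all(run_type %in% library$run_type)) {
    stop("library lacks run type(s): ",
         paste(setdiff(run_type, library$run_type), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(one_minus_theta)) one_minus_theta <- library$one_minus_theta
  check_number(samples_per_cell, "samples_per_cell", min = 1,
               integerish = TRUE)
  if (!is.null(seed) && !is.null(library$seed) &&
      identical(as.integer(seed), as.integer(library$seed))) {
    warning("test seed equals the library seed; samples are not ",
            "independent of the reference", call. = FALSE)
  }
  for (omt in one_minus_theta) {
    if (!any(abs(library$one_minus_theta - omt) < 1e-8)) {
      stop("library has no checkpoint at 1 - theta = ", omt, call. = FALSE)
    }
  }
  n_genes <- as.integer(n_genes)
  if (!all(n_genes %in% library$n_genes)) {
    stop("library has no cells at N = ",
         paste(setdiff(n_genes, library$n_genes), collapse = ", "),
         call. = FALSE)
  }
  mu_values <- library$mu_values
  nmu <- length(mu_values)

  rows <- list()
  with_seed(seed, {
    for (N in n_genes) {
      targets <- as.integer(round(one_minus_theta * N))
      mats <- lapply(run_type, function(rt) {
        lapply(one_minus_theta, function(omt) {
          ref_cell_matrix(library, N, omt, rt)
        })
      })
      names(mats) <- run_type
      for (mu in true_mu) {
        # counts[[rt]][[ci]] tallies mu_hat bins over samples
        bins <- lapply(run_type, function(rt) {
          lapply(seq_along(one_minus_theta), function(ci) integer(nmu))
        })
        names(bins) <- run_type
        for (s in seq_len(samples_per_cell)) {
          res <- sim_fractionation_cpp(N, mu, targets,
                                       circular =
                                         library$topology == "circular",
                                       truncate = TRUE, keep_events = FALSE)
          for (ci in seq_along(one_minus_theta)) {
            for (rt in run_type) {
              lens <- res[[paste0(rt, "_runs")]][[ci]]
              counts <- tabulate(lens, nbins = max(lens))
              cl <- classify_counts(counts, mats[[rt]][[ci]], mu_values)
              j <- which(mu_values == cl$mu_hat)
              bins[[rt]][[ci]][j] <- bins[[rt]][[ci]][j] + 1L
            }
          }
        }
        for (rt in run_type) {
          for (ci in seq_along(one_minus_theta)) {
            rows[[length(rows) + 1L]] <- data.frame(
              run_type = rt, true_mu = mu, n_genes = N,
              one_minus_theta = one_minus_theta[ci], mu_hat = mu_values,
              count = bins[[rt]][[ci]],
              freq = bins[[rt]][[ci]] / samples_per_cell)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("error_assessment", "data.frame"),
            mu_values = mu_values, samples_per_cell = samples_per_cell,
            seed = seed, topology = library$topology)
}

#' Frequency of mu_hat = 1 per cell
#'
#' The summary plotted against `1 - theta` in the discrimination study:
#' how often a sample is assigned to the gene-by-gene bin.
#'
#' @param assessment An [assess_discrimination()] result.
#' @param run_type Restrict to one run type (default: all present).
#' @return Data frame with columns `run_type`, `true_mu`, `n_genes`,
#'   `one_minus_theta`, `freq_mu1`.
#' @export
mu1_frequency <- function(assessment, run_type = NULL) {
  stopifnot(inherits(assessment, "error_assessment"))
  d <- as.data.frame(assessment)
  if (!is.null(run_type)) d <- d[d$run_type %in% run_type, , drop = FALSE]
  d <- d[abs(d$mu_hat - 1) < 1e-8, , drop = FALSE]
  out <- d[, c("run_type", "true_mu", "n_genes", "one_minus_theta")]
  out$freq_mu1 <- d$freq
  rownames(out) <- NULL
  out
}

#' Compare double-copy against single-copy classification
#'
#' Per-cell difference in the frequency of `mu_hat = 1` between
#' classification on double-copy runs (cumulatives `G`) and on
#' single-copy runs (cumulatives `F`) from the same simulations.  The
#' double-copy approach systematically favours `mu = 1` at small deleted
#' proportions and disfavours it at large ones, correct or not.
#'
#' @param assessment_single An [assess_discrimination()] result holding
#'   single-run classifications (if it holds both types, its single-run
#'   rows are used).
#' @param assessment_double Likewise for double-run classifications.
#' @return Data frame with columns `true_mu`, `n_genes`,
#'   `one_minus_theta`, `freq_mu1_single`, `freq_mu1_double`, `diff`
#'   (double minus single).
#' @export
compare_run_types <- function(assessment_single, assessment_double) {
  pick <- function(a, want) {
    types <- unique(a$run_type)
    rt <- if (want %in% types) want else if (length(types) == 1L) types else
      stop("assessment holds ", paste(types, collapse = "+"),
           " runs; cannot select ", want, call. = FALSE)
    mu1_frequency(a, rt)
  }
  s <- pick(assessment_single, "single")
  d <- pick(assessment_double, "double")
  key <- function(x) paste(x$true_mu, x$n_genes, x$one_minus_theta)
  if (!identical(sort(key(s)), sort(key(d)))) {
    stop("assessments cover different (true mu, N, 1 - theta) grids",
         call. = FALSE)
  }
  if (!identical(attr(assessment_single, "samples_per_cell"),
                 attr(assessment_double, "samples_per_cell"))) {
    stop("assessments use different sample counts", call. = FALSE)
  }
  m <- match(key(s), key(d))
  out <- s[, c("true_mu", "n_genes", "one_minus_theta")]
  out$freq_mu1_single <- s$freq_mu1
  out$freq_mu1_double <- d$freq_mu1[m]
  out$diff <- out$freq_mu1_double - out$freq_mu1_single
  rownames(out) <- NULL
  out
}
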