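# Reference run-length cumulatives F_{mu,N,1-theta} (single-copy runs)
# and G_{mu,N,1-theta} (double-copy runs) estimated by simulation on a
# parameter grid, against which observed samples are classified.

ref_key <- function(n_genes, one_minus_theta) {
  sprintf("N%d|t%.4f", as.integer(n_genes), one_minus_theta)
}

mu_col <- function(mu_values, mu) {
  i <- which(abs(mu_values - mu) < 1e-8)
  if (length(i) != 1L) return(NA_integer_)
  i
}

#' Build a reference cumulative library
#'
#' For every `(mu, N)` pair, simulates `replicates` fractionation
#' trajectories observed at all requested deleted proportions `1 - theta`
#' and turns the run-length counts into empirical cumulative
#' distributions over run length `l` — the reference cumulatives
#' `F_{mu,N,1-theta}` (single-copy runs) and `G_{mu,N,1-theta}`
#' (double-copy runs).  Defaults reproduce the full study grid:
#' `mu = 1.0 .. 2.4` by 0.1, `N = 100 .. 900` by 100, `1 - theta =
#' 0.1 .. 0.9` by 0.1.
#'
#' `pooling = "pool"` (default) pools run counts across replicates before
#' normalising — run-weighted averaging, stable when individual trials
#' contain few runs.  `pooling = "average"` instead averages each trial's
#' relative length frequencies.
#'
#' @param mu_values Candidate mean deletion lengths (each `>= 1`).
#' @param n_genes Genome sizes `N`.
#' @param one_minus_theta Deleted proportions, strictly increasing in
#'   (0, 1).
#' @param replicates Trajectories per `(mu, N)` cell (`>= 1`).
#' @param run_type Which run types to tabulate: `"single"`, `"double"` or
#'   both (default).
#' @param topology Passed to the simulator.
#' @param seed Integer seed; same seed, same library.
#' @param pooling `"pool"` or `"average"` (see above).
#' @return An object of class `reference_library`.
#' @export
build_reference <- function(mu_values = seq(1, 2.4, by = 0.1),
                            n_genes = seq(100, 900, by = 100),
                            one_minus_theta = seq(0.1, 0.9, by = 0.1),
                            replicates = 300,
                            run_type = c("single", "double"),
                            topology = c("circular", "linear"),
                            seed = NULL,
                            pooling = c("pool", "average")) {
  run_type <- match.arg(run_type, several.ok = TRUE)
  topology <- match.arg(topology)
  pooling <- match.arg(pooling)
  check_number(replicates, "replicates", min = 1, integerish = TRUE)
  if (any(mu_values < 1) || is.unsorted(mu_values, strictly = TRUE)) {
    stop("`mu_values` must be strictly increasing and all >= 1",
         call. = FALSE)
  }
  if (any(one_minus_theta <= 0) || any(one_minus_theta >= 1) ||
      is.unsorted(one_minus_theta, strictly = TRUE)) {
    stop("`one_minus_theta` must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  n_genes <- as.integer(n_genes)

  cum <- with_seed(seed, {
    out <- list()
    for (rt in run_type) out[[rt]] <- list()
    for (N in n_genes) {
      targets <- as.integer(round(one_minus_theta * N))
      stopifnot(all(targets >= 1L), all(targets < N),
                !anyDuplicated(targets))
      # acc[[rt]][[ci]] is an N x n_mu matrix of (possibly weighted) counts
      acc <- lapply(run_type, function(rt) {
        lapply(seq_along(one_minus_theta), function(ci) {
          matrix(0, nrow = N, ncol = length(mu_values))
        })
      })
      names(acc) <- run_type
      for (mi in seq_along(mu_values)) {
        for (rep in seq_len(replicates)) {
          res <- sim_fractionation_cpp(N, mu_values[mi], targets,
                                       circular = topology == "circular",
                                       truncate = TRUE, keep_events = FALSE)
          for (ci in seq_along(one_minus_theta)) {
            for (rt in run_type) {
              lens <- res[[paste0(rt, "_runs")]][[ci]]
              if (length(lens)) {
                cnt <- tabulate(lens, nbins = N)
                if (pooling == "average") cnt <- cnt / sum(cnt)
                acc[[rt]][[ci]][, mi] <- acc[[rt]][[ci]][, mi] + cnt
              }
            }
          }
        }
      }
      for (ci in seq_along(one_minus_theta)) {
        for (rt in run_type) {
          m <- acc[[rt]][[ci]]
          tot <- colSums(m)
          if (any(tot == 0)) {
            bad <- mu_values[tot == 0][1]
            stop("reference cell (mu = ", bad, ", N = ", N,
                 ", 1 - theta = ", one_minus_theta[ci], ", ", rt,
                 ") has zero runs", call. = FALSE)
          }
          cm <- apply(m, 2, cumsum)
          cm <- sweep(cm, 2, tot, "/")
          lmax <- max(which(rowSums(m) > 0))
          cm <- cm[seq_len(lmax), , drop = FALSE]
          colnames(cm) <- sprintf("%.6g", mu_values)
          out[[rt]][[ref_key(N, one_minus_theta[ci])]] <- cm
        }
      }
    }
    out
  })

  structure(
    list(mu_values = as.numeric(mu_values), n_genes = n_genes,
         one_minus_theta = as.numeric(one_minus_theta),
         replicates = as.integer(replicates), run_type = run_type,
         topology = topology, seed = seed, pooling = pooling, cum = cum),
    class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("Reference cumulative library (", paste(x$run_type, collapse = " + "),
      " runs)\n", sep = "")
  cat("  mu grid:", length(x$mu_values), "values in [",
      min(x$mu_values), ",", max(x$mu_values), "]\n")
  cat("  N:", paste(x$n_genes, collapse = ", "), "\n")
  cat("  1 - theta:", paste(format(x$one_minus_theta), collapse = ", "), "\n")
  cat("  replicates:", x$replicates, " pooling:", x$pooling,
      " seed:", if (is.null(x$seed)) "none" else x$seed, "\n")
  invisible(x)
}

ref_cell_matrix <- function(library, n_genes, one_minus_theta, run_type) {
  stopifnot(inherits(library, "reference_library"))
  if (!run_type %in% library$run_type) {
    stop("library holds no ", run_type, "-run cumulatives", call. = FALSE)
  }
  omt <- library$one_minus_theta[
    which(abs(library$one_minus_theta - one_minus_theta) < 1e-8)[1]]
  key <- ref_key(n_genes, omt)
  m <- library$cum[[run_type]][[key]]
  if (is.na(omt) || is.null(m)) {
    stop("library has no cell at (N = ", n_genes, ", 1 - theta = ",
         one_minus_theta, ", ", run_type, ")", call. = FALSE)
  }
  m
}

#' Look up one reference cumulative
#'
#' @param library A [build_reference()] result.
#' @param mu,n_genes,one_minus_theta Grid coordinates of the cell.
#' @param run_type `"single"` or `"double"`.
#' @return Numeric vector: `P(run length <= l)` for `l = 1, 2, ...` up to
#'   the largest length observed in that cell (1 thereafter).
#' @export
reference_cumulative <- function(library, mu, n_genes, one_minus_theta,
                                 run_type = c("single", "double")) {
  run_type <- match.arg(run_type)
  m <- ref_cell_matrix(library, n_genes, one_minus_theta, run_type)
  i <- mu_col(library$mu_values, mu)
  if (is.na(i)) {
    stop("library has no cell at mu = ", mu, " (N = ", n_genes,
         ", 1 - theta = ", one_minus_theta, ", ", run_type, ")",
         call. = FALSE)
  }
  m[, i]
}

#' Serialise a reference library to TSV + JSON
#'
#' Writes one TSV per run type (columns `mu`, `n_genes`,
#' `one_minus_theta`, `length`, `cum_prob`; rows stop at the first length
#' where the cumulative reaches 1) plus a `library.json` sidecar with the
#' grid, replicate count, seed and pooling mode.
#'
#' @param library A [build_reference()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_library <- function(library, dir) {
  stopifnot(inherits(library, "reference_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rt in library$run_type) {
    rows <- list()
    for (N in library$n_genes) {
      for (omt in library$one_minus_theta) {
        m <- library$cum[[rt]][[ref_key(N, omt)]]
        for (i in seq_along(library$mu_values)) {
          v <- m[, i]
          lmax <- which(v >= 1 - 1e-12)[1]
          if (is.na(lmax)) lmax <- length(v)
          rows[[length(rows) + 1L]] <- data.frame(
            mu = library$mu_values[i], n_genes = N, one_minus_theta = omt,
            length = seq_len(lmax), cum_prob = v[seq_len(lmax)])
        }
      }
    }
    tab <- do.call(rbind, rows)
    write.table(tab, file.path(dir, paste0("reference_", rt, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(mu_values = library$mu_values, n_genes = library$n_genes,
               one_minus_theta = library$one_minus_theta,
               replicates = library$replicates, run_type = library$run_type,
               topology = library$topology, seed = library$seed,
               pooling = library$pooling,
               package_version = as.character(packageVersion("fractionator")))
  jsonlite::write_json(meta, file.path(dir, "library.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a serialised reference library
#'
#' @param dir Directory written by [write_reference_library()].
#' @return A `reference_library` equivalent to the one written (cumulative
#'   values restored to full precision as printed).
#' @export
read_reference_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "library.json"),
                              simplifyVector = TRUE)
  cum <- list()
  for (rt in meta$run_type) {
    tab <- read.delim(file.path(dir, paste0("reference_", rt, ".tsv")))
    cum[[rt]] <- list()
    for (N in meta$n_genes) {
      for (omt in meta$one_minus_theta) {
        sel <- tab$n_genes == N & abs(tab$one_minus_theta - omt) < 1e-8
        sub <- tab[sel, , drop = FALSE]
        lmax <- max(sub$length)
        m <- matrix(1, nrow = lmax, ncol = length(meta$mu_values),
                    dimnames = list(NULL, sprintf("%.6g", meta$mu_values)))
        for (i in seq_along(meta$mu_values)) {
          s <- sub[abs(sub$mu - meta$mu_values[i]) < 1e-8, , drop = FALSE]
          m[s$length, i] <- s$cum_prob
          if (max(s$length) < lmax) m[(max(s$length) + 1):lmax, i] <- 1
        }
        cum[[rt]][[ref_key(N, omt)]] <- m
      }
    }
  }
  structure(
    list(mu_values = meta$mu_values, n_genes = as.integer(meta$n_genes),
         one_minus_theta = meta$one_minus_theta,
         replicates = meta$replicates, run_type = meta$run_type,
         topology = meta$topology, seed = meta$seed, pooling = meta$pooling,
         cum = cum),
    class = "reference_library")
}
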