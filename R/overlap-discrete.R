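# Overlap probabilities for the discrete deletion process.
#
# A new deletion event overlaps q pre-existing single-copy runs; q = 0
# means the event falls strictly inside a double-copy run without touching
# either end, creating a new run.  All probabilities depend only on the
# deletion-length law gamma (geometric, mean mu) and the double-copy
# run-length law rho_t (geometric, mean nu_t).

#' Overlap-probability parameters
#'
#' Bundles the mean deletion-event length `mu` and the current mean
#' double-copy run length `nu` (nu_t, which decreases as fractionation
#' proceeds).  In the discrete model both laws are geometric on
#' \{1, 2, ...\}; in the continuous analogue they are exponential.
#'
#' @param mu Mean deletion length (`>= 1` for the discrete model; any
#'   positive value is accepted here because the continuous model allows
#'   `mu < 1`, and the discrete operations check their own stricter
#'   domains).
#' @param nu Mean double-copy run length (`> 0`; discrete operations
#'   require `nu > 1` since a geometric mean cannot be below 1 and runs of
#'   mean length 1 have no interior).
#' @return An object of class `overlap_params`.
#' @export
overlap_params <- function(mu, nu) {
  check_number(mu, "mu", min = 0, strict_min = TRUE)
  check_number(nu, "nu", min = 0, strict_min = TRUE)
  structure(list(mu = as.numeric(mu), nu = as.numeric(nu)),
            class = "overlap_params")
}

as_overlap_params <- function(params) {
  if (inherits(params, "overlap_params")) return(params)
  if (is.list(params) && all(c("mu", "nu") %in% names(params))) {
    return(overlap_params(params$mu, params$nu))
  }
  stop("`params` must be an overlap_params object (or a list with mu, nu)",
       call. = FALSE)
}

check_discrete_params <- function(params) {
  params <- as_overlap_params(params)
  if (params$mu < 1) {
    stop("discrete model requires `mu` >= 1 (got ", params$mu, ")",
         call. = FALSE)
  }
  if (params$nu <= 1) {
    stop("discrete model requires `nu` > 1 (got ", params$nu, ")",
         call. = FALSE)
  }
  params
}

#' p0 by direct truncated summation (oracle)
#'
#' Evaluates the triple-sum definition of the probability that a deletion
#' event falls within a double-copy run without deleting the gene at
#' either end:
#' `p0 = (1/nu) * sum_{l>2} rho(l) * sum_{j=2}^{l-1} sum_{a=1}^{l-j} gamma(a)`,
#' where `j` indexes the start of the event inside a run of length `l` and
#' `a` the event length.  The inner double sum collapses to partial
#' geometric sums, `S(l) = (l-1) G(l-2) - A(l-2)` with `G`/`A` the partial
#' zeroth/first moments of `gamma`, so only the outer sum over `l` is
#' truncated: it stops once the remaining tail mass of `l * rho(l) / nu`
#' drops below `tail_tol`.
#'
#' This is the slow-but-transparent route kept as an independent check on
#' the closed form [p0_discrete_closed()].
#'
#' @param params An [overlap_params()] with `mu >= 1`, `nu > 1`.
#' @param tail_tol Truncation tolerance on the neglected tail mass
#'   (`0 < tail_tol <= 1e-6`).
#' @param max_terms Hard cap on the number of outer-sum terms.
#' @return The probability `p0` in `[0, 1]`.
#' @export
p0_discrete_sum <- function(params, tail_tol = 1e-12, max_terms = 1e7) {
  params <- check_discrete_params(params)
  check_number(tail_tol, "tail_tol", min = 0, max = 1e-6, strict_min = TRUE)
  mu <- params$mu
  nu <- params$nu
  qn <- 1 - 1 / nu
  # tail mass of l * rho(l) / nu beyond L is qn^L * (L + nu) / nu
  L <- 16
  while (qn^L * (L + nu) / nu >= tail_tol) {
    L <- L * 2
    if (L > max_terms) {
      stop("outer sum did not converge within the cap of ", max_terms,
           " terms (max_terms); tail mass still ",
           format(qn^(L / 2) * (L / 2 + nu) / nu), call. = FALSE)
    }
  }
  l <- 3:L
  qm <- 1 - 1 / mu
  G <- 1 - qm^(l - 2)                    # P(X <= l - 2)
  A <- mu - qm^(l - 2) * ((l - 2) + mu)  # sum_{a <= l-2} a * gamma(a)
  S <- (l - 1) * G - A
  rho <- (1 / nu) * qn^(l - 1)
  sum(rho * S) / nu
}

#' p0 in closed form
#'
#' The triple sum of [p0_discrete_sum()] reduces, via the geometric
#' distribution with mean `zeta` of [zeta_mean()], to
#' `p0 = (nu - 1)^2 / ((mu + nu - 1) * nu)`.
#'
#' @inheritParams p0_discrete_sum
#' @return The probability `p0` in `[0, 1]`.
#' @examples
#' p0_discrete_closed(overlap_params(1, 2))  # 0.25
#' @export
p0_discrete_closed <- function(params) {
  params <- check_discrete_params(params)
  (params$nu - 1)^2 / ((params$mu + params$nu - 1) * params$nu)
}

#' p0 large-nu approximation
#'
#' Early in the process, while the mean double-copy run length `nu_t` is
#' still large (order 10^3 to 10^4), `p0 ~ (nu / (mu + nu)) (1 - 1/nu)`:
#' only slightly below 1, then declining rapidly as `nu_t` shrinks.
#'
#' @inheritParams p0_discrete_sum
#' @return The approximate probability.
#' @export
p0_discrete_approx <- function(params) {
  params <- check_discrete_params(params)
  (params$nu / (params$mu + params$nu)) * (1 - 1 / params$nu)
}

#' Mean of the reduced geometric law zeta
#'
#' The cross terms of the `p0` sum involve products of the two geometric
#' survival factors, which combine into a single geometric distribution
#' with mean `zeta` given by `1 - 1/zeta = (1 - 1/mu)(1 - 1/nu)`.
#'
#' @param params An [overlap_params()] with `mu >= 1`, `nu >= 1`.
#' @return An object of class `zeta_reduction` with field `zeta`
#'   (`1 <= zeta <= min(mu, nu)`).
#' @export
zeta_mean <- function(params) {
  params <- as_overlap_params(params)
  if (params$mu < 1 || params$nu < 1) {
    stop("`zeta_mean` requires mu >= 1 and nu >= 1", call. = FALSE)
  }
  z <- 1 / (1 - (1 - 1 / params$mu) * (1 - 1 / params$nu))
  structure(list(zeta = z, mu = params$mu, nu = params$nu),
            class = "zeta_reduction")
}

#' @export
print.zeta_reduction <- function(x, ...) {
  cat(sprintf("zeta = %.6g (mu = %g, nu = %g)\n", x$zeta, x$mu, x$nu))
  invisible(x)
}
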