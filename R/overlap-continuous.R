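# Continuous analogue: chromosomes are long line segments, deletion
# lengths are exponential with mean mu (density f) and the undeleted
# segment lengths are exponential with mean nu_t (density sigma_t).  Here
# the number q of pre-existing single-copy runs overlapped by a new event
# has an exact geometric law.

check_continuous_params <- function(params) {
  params <- as_overlap_params(params)
  if (params$mu <= 0 || params$nu <= 0) {
    stop("continuous model requires mu > 0 and nu > 0", call. = FALSE)
  }
  params
}

#' Overlap-count probabilities, continuous model (closed form)
#'
#' In the continuous model the probability that a deletion event overlaps
#' exactly `q` pre-existing single-copy runs is geometric on
#' `q = 0, 1, ...` with parameter `mu / (mu + nu)`:
#' `p_q = (nu / (mu + nu)) * (mu / (mu + nu))^q`.
#' At `q = 0` this is `nu / (mu + nu)`, echoing the large-nu form of the
#' discrete `p0`.
#'
#' @param params An [overlap_params()]; any `mu > 0` is allowed (point
#'   deletions `mu -> 0` always fall inside a segment).
#' @param q Non-negative integer overlap count (vectorised).
#' @return `P(overlap = q)` for each element of `q`.
#' @examples
#' pq_continuous(overlap_params(1, 3), 0:3)
#' @export
pq_continuous <- function(params, q) {
  params <- check_continuous_params(params)
  if (length(q) < 1L || any(!is.finite(q)) || any(q < 0 | q != floor(q))) {
    stop("`q` must contain non-negative integers", call. = FALSE)
  }
  mu <- params$mu
  nu <- params$nu
  (nu / (mu + nu)) * (mu / (mu + nu))^q
}

#' Overlap-count probabilities by nested quadrature (oracle)
#'
#' Evaluates the defining nested integrals of the continuous model
#' numerically: for `q = 0`, the chance that an event starting uniformly
#' inside an undeleted segment of (length-biased) exponential length ends
#' before the segment does; for `q = 1`, that it runs past the segment end
#' but terminates inside the next undeleted segment.  The innermost
#' integral of the exponential length density `f` is taken via its exact
#' CDF ([stats::pexp()]); the remaining one (q = 0) or three (q = 1)
#' integrals over segment lengths and the start position use adaptive
#' quadrature on the semi-infinite ranges.
#'
#' Kept as an independent numerical check on [pq_continuous()].
#'
#' @inheritParams pq_continuous
#' @param q 0 or 1 (the integral forms spelled out by the model).
#' @param quadrature_tol Relative tolerance passed to the quadrature.
#' @return The probability `p_q`.
#' @export
pq_continuous_oracle <- function(params, q, quadrature_tol = 1e-8) {
  params <- check_continuous_params(params)
  check_number(q, "q", min = 0, max = 1, integerish = TRUE)
  check_number(quadrature_tol, "quadrature_tol", min = 0, max = 1e-2,
               strict_min = TRUE)
  mu <- params$mu
  nu <- params$nu
  tol <- quadrature_tol / 10
  quad <- function(f, lower, upper) {
    r <- tryCatch(
      stats::integrate(f, lower, upper, rel.tol = tol, abs.tol = tol,
                       stop.on.error = TRUE),
      error = function(e) stop("quadrature failed to reach tolerance ",
                               quadrature_tol, ": ", conditionMessage(e),
                               call. = FALSE))
    r$value
  }
  if (q == 0) {
    # p0 = int_l (l sigma(l) / nu) int_x (1/l) int_{y<=l-x} f(y) dy dx dl
    inner <- function(l) {
      vapply(l, function(li) {
        if (li <= 0) return(0)
        quad(function(x) stats::pexp(li - x, rate = 1 / mu), 0, li) / li
      }, numeric(1))
    }
    quad(function(l) l * stats::dexp(l, rate = 1 / nu) / nu * inner(l),
         0, Inf)
  } else {
    # p1 = (1/nu) int_l int_z sigma(l) sigma(z)
    #        int_{x=0}^{l} [F(l - x + z) - F(l - x)] dx dz dl
    x_int <- function(l, z) {
      quad(function(x) {
        stats::pexp(l - x + z, rate = 1 / mu) -
          stats::pexp(l - x, rate = 1 / mu)
      }, 0, l)
    }
    z_int <- function(l) {
      vapply(l, function(li) {
        quad(function(z) {
          vapply(z, function(zi) {
            stats::dexp(zi, rate = 1 / nu) * x_int(li, zi)
          }, numeric(1))
        }, 0, Inf)
      }, numeric(1))
    }
    quad(function(l) stats::dexp(l, rate = 1 / nu) * z_int(l), 0, Inf) / nu
  }
}
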