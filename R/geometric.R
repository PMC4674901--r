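#' Geometric deletion-length model
#'
#' The number of genes excised by one deletion event is geometric on
#' \{1, 2, 3, ...\} with mean `mu`: `P(X = a) = (1/mu) (1 - 1/mu)^(a-1)`.
#' `mu = 1` is the degenerate gene-by-gene ("functional") model in which
#' every event deletes exactly one gene; `mu > 1` is the segmental
#' ("structural") model.
#'
#' @param mu Mean deletion-event length in genes; must be `>= 1`.
#' @return An object of class `geometric_deletion_model`.
#' @examples
#' m <- geometric_deletion_model(2)
#' deletion_length_pmf(m, 1)  # 0.5
#' @export
geometric_deletion_model <- function(mu) {
  check_number(mu, "mu", min = 1)
  structure(list(mu = as.numeric(mu)), class = "geometric_deletion_model")
}

as_deletion_model <- function(model) {
  if (inherits(model, "geometric_deletion_model")) return(model)
  if (is.numeric(model) && length(model) == 1L) {
    return(geometric_deletion_model(model))
  }
  stop("`model` must be a geometric_deletion_model or a single numeric mu",
       call. = FALSE)
}

#' @export
print.geometric_deletion_model <- function(x, ...) {
  cat("Geometric deletion-length model: mu =", x$mu,
      if (x$mu == 1) "(gene-by-gene)" else "(segmental)", "\n")
  invisible(x)
}

#' Probability mass function of the deletion length
#'
#' @param model A [geometric_deletion_model()] (or a numeric `mu`).
#' @param a Vector of lengths (positive integers).
#' @return `P(X = a)` for each element of `a`.
#' @export
deletion_length_pmf <- function(model, a) {
  model <- as_deletion_model(model)
  if (any(a < 1 | a != floor(a))) {
    stop("`a` must contain positive integers", call. = FALSE)
  }
  mu <- model$mu
  # 0^0 = 1 handles mu = 1 at a = 1
  (1 / mu) * (1 - 1 / mu)^(a - 1)
}

#' Sample deletion-event lengths
#'
#' Draws from the geometric length law on \{1, 2, ...\} with mean `mu`.
#' With `mu = 1` the draw is deterministically 1.
#'
#' @inheritParams deletion_length_pmf
#' @param n Number of draws.
#' @return Integer vector of `n` sampled lengths, each `>= 1`.
#' @export
sample_deletion_length <- function(model, n = 1) {
  model <- as_deletion_model(model)
  check_number(n, "n", min = 1, integerish = TRUE)
  1L + stats::rgeom(n, prob = 1 / model$mu)
}
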