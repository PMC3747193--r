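#' Birth-death rate parameters
#'
#' Container for per-lineage speciation (`b`) and extinction (`d`) rates of a
#' constant-rate birth-death process, in units of events per lineage per
#' million years. The derived quantities `r = b - d` (net diversification
#' rate) and `eps = d / b` (relative extinction fraction) are stored
#' alongside.
#'
#' @param b Speciation rate (> 0), per lineage per Myr.
#' @param d Extinction rate (>= 0), per lineage per Myr.
#' @return An object of class `bd_params`: a list with elements `b`, `d`,
#'   `r`, `eps`.
#' @examples
#' bd_params(0.2, 0.1)
#' bd_params_rel(r = 0.1, eps = 0.5)
#' @export
bd_params <- function(b, d = 0) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(d), length(d) == 1L)
  if (!is.finite(b) || b <= 0) stop("speciation rate b must be > 0")
  if (!is.finite(d) || d < 0) stop("extinction rate d must be >= 0")
  structure(list(b = b, d = d, r = b - d, eps = d / b), class = "bd_params")
}

#' @rdname bd_params
#' @param r Net diversification rate `b - d` (> 0), per lineage per Myr.
#' @param eps Relative extinction fraction `d / b`, in `[0, 1)`.
#' @export
bd_params_rel <- function(r, eps = 0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.numeric(eps), length(eps) == 1L)
  if (!is.finite(r) || r <= 0) stop("net diversification rate r must be > 0")
  if (!is.finite(eps) || eps < 0 || eps >= 1) stop("eps must lie in [0, 1)")
  bd_params(b = r / (1 - eps), d = r * eps / (1 - eps))
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf(
    "birth-death rates: b = %.6g, d = %.6g  (r = %.6g, eps = %.6g) per Myr\n",
    x$b, x$d, x$r, x$eps))
  invisible(x)
}

#' Extinction and descendant-count kernels of the birth-death process
#'
#' For a single lineage alive `t` Myr before the present, `alpha` is the
#' probability that it leaves no extant descendant, and `beta` is the
#' geometric parameter of its descendant-count distribution: conditional on
#' survival the number of extant descendants is geometric with success
#' probability `1 - beta`. With `rho = exp(r t)`,
#' `alpha = d (rho - 1) / (b rho - d)` and
#' `beta = b (rho - 1) / (b rho - d)`; the critical case `b = d` uses the
#' limit `alpha = beta = b t / (1 + b t)`.
#'
#' @param t Ages in Myr (vectorised, all >= 0).
#' @param params A [bd_params] object.
#' @return A two-column matrix with columns `alpha` and `beta`, both in
#'   `[0, 1)` and strictly increasing in `t`.
#' @examples
#' bd_alpha_beta(10, bd_params(0.2, 0.1))
#' @export
bd_alpha_beta <- function(t, params) {
  stopifnot(inherits(params, "bd_params"), is.numeric(t))
  if (any(t < 0)) stop("negative t")
  b <- params$b
  d <- params$d
  if (abs(b - d) <= 1e-12 * b) {
    ab <- b * t / (1 + b * t)
    return(cbind(alpha = ab, beta = ab))
  }
  r <- b - d
  E <- exp(-r * t)
  beta <- -expm1(-r * t) / (1 - (d / b) * E)
  cbind(alpha = (d / b) * beta, beta = beta)
}

#' Probability of a clade's extant species richness
#'
#' Probability that a single lineage of stem age `t` has exactly `n` extant
#' descendant species under a constant-rate birth-death process:
#' `P(0) = alpha` and `P(n) = (1 - alpha) (1 - beta) beta^(n-1)` for
#' `n >= 1`. With `conditional = TRUE` the distribution is conditioned on
#' survival to the present (divides by `1 - alpha`, and `P(0)` becomes 0).
#'
#' @param n Non-negative integer richness values (vectorised).
#' @param t Stem age in Myr (scalar, >= 0).
#' @param params A [bd_params] object.
#' @param conditional Condition on survival of the lineage?
#' @return Probabilities, one per element of `n`; they sum to one over
#'   `n >= 0` (unconditional) or `n >= 1` (conditional).
#' @examples
#' prob_richness(0:5, 10, bd_params(0.2, 0.1))
#' @export
prob_richness <- function(n, t, params, conditional = FALSE) {
  stopifnot(is.numeric(n), all(n >= 0), all(n == round(n)),
            is.numeric(t), length(t) == 1L, t >= 0)
  ab <- bd_alpha_beta(t, params)
  a <- ab[1L, "alpha"]
  be <- ab[1L, "beta"]
  p <- ifelse(n == 0, a, (1 - a) * (1 - be) * be^(pmax(n - 1, 0)))
  if (conditional) p <- ifelse(n == 0, 0, p / (1 - a))
  unname(p)
}

#' Log-likelihood of branching ages under the reconstructed birth-death
#' process
#'
#' Conditioned (Nee-form) log-likelihood of the ordered branching ages of a
#' fully resolved ultrametric tree under constant rates. With `a = eps`
#' and branching ages `x_2 >= ... >= x_N` (the first being the root age),
#' \deqn{\ln L = \ln(N-1)! + (N-2)\ln r + r \sum_{i=3}^{N} x_i +
#'   N \ln(1-a) - 2 \sum_{i=2}^{N} \ln(e^{r x_i} - a).}
#' Parameter values outside the admissible region (`r <= 0` or `eps >= 1`)
#' return `-Inf` rather than raising an error, so optimisers can probe them.
#'
#' @param ages Branching ages in Myr (at least two; order irrelevant).
#' @param params A [bd_params] object.
#' @return A finite log-likelihood, or `-Inf` outside the admissible region.
#' @examples
#' loglik_resolved(c(2, 1), bd_params(0.5, 0))
#' @export
loglik_resolved <- function(ages, params) {
  stopifnot(inherits(params, "bd_params"), is.numeric(ages))
  if (length(ages) < 2L) stop("need at least 2 branching ages (>= 3 tips)")
  r <- params$r
  a <- params$eps
  if (r <= 0 || a >= 1) return(-Inf)
  x <- sort(ages, decreasing = TRUE)
  N <- length(x) + 1L
  # log(exp(r x) - a) written as r x + log1p(-a exp(-r x)) for stability
  lfactorial(N - 1) + (N - 2) * log(r) + r * sum(x[-1L]) + N * log1p(-a) -
    2 * sum(r * x + log1p(-a * exp(-r * x)))
}
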