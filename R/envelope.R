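# Expected clade diversity through time and confidence envelopes under a
# constant-rate birth-death process, with the net-diversification
# estimators that invert them (Magallon-Sanderson method-of-moments).

.beta_re <- function(t, r, eps) {
  # geometric parameter under the (r, eps) parameterisation, stable in t
  E <- exp(-r * t)
  -expm1(-r * t) / (1 - eps * E)
}

#' Net diversification rate from standing richness and clade age
#'
#' Method-of-moments estimator of `r = b - d` given an extant species count
#' `n`, a clade age `t` (Ma), and an assumed relative extinction fraction
#' `eps`. For a stem-age clade
#' \deqn{\hat r = \ln[n (1-\epsilon) + \epsilon] / t,}
#' and for a crown-age clade
#' \deqn{\hat r = \frac{1}{t}\left\{\ln\left[\frac{n}{2}(1-\epsilon^2) +
#'   2\epsilon + \frac{1-\epsilon}{2}
#'   \sqrt{n (n\epsilon^2 - 8\epsilon + 2 n \epsilon + n)}\right] -
#'   \ln 2\right\}.}
#' At `eps = 0` these reduce to `ln(n)/t` and `ln(n/2)/t`.
#'
#' @param n Extant richness (>= 1 for stem, >= 2 for crown).
#' @param t Clade age in Ma (> 0).
#' @param eps Relative extinction fraction in `[0, 1)`.
#' @param mode `"crown"` or `"stem"`.
#' @return Estimated net diversification rate, per lineage per Myr.
#' @examples
#' estimate_r(1638, 81, eps = 0, mode = "crown")    # 0.0828
#' estimate_r(1638, 81, eps = 0.9, mode = "crown")  # 0.062
#' @export
estimate_r <- function(n, t, eps = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  stopifnot(t > 0, eps >= 0, eps < 1, n >= 1)
  if (mode == "stem") {
    arg <- n * (1 - eps) + eps
    if (arg <= 0) stop("clade too small for this eps")
    return(log(arg) / t)
  }
  if (n < 2) stop("crown estimator needs n >= 2")
  disc <- n * (n * eps^2 - 8 * eps + 2 * n * eps + n)
  if (disc < 0) stop("clade too small for this eps")
  arg <- (n / 2) * (1 - eps^2) + 2 * eps + ((1 - eps) / 2) * sqrt(disc)
  if (arg <= 0) stop("clade too small for this eps")
  (log(arg) - log(2)) / t
}

#' Expected species richness of a surviving clade
#'
#' Mean extant diversity at age `t` of a clade evolving at net rate `r`
#' with relative extinction `eps`, conditioned on survival: `1/(1 - beta)`
#' from a stem lineage, `2/(1 - beta)` from a crown pair (each root lineage
#' conditioned on leaving descendants), with `beta` the geometric parameter
#' of [bd_alpha_beta]. At `t = 0` this is 1 (stem) or 2 (crown).
#'
#' @param t Clade ages in Ma (vectorised, >= 0).
#' @inheritParams estimate_r
#' @return Expected species counts, increasing in `t` and `r`.
#' @examples
#' expected_richness(81, 0.0828, 0, "crown")  # about 1638
#' @export
expected_richness <- function(t, r, eps = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  stopifnot(all(t >= 0), r > 0, eps >= 0, eps < 1)
  be <- .beta_re(t, r, eps)
  (if (mode == "crown") 2 else 1) / (1 - be)
}

#' Confidence bounds on clade richness given age
#'
#' Equal-tailed confidence interval for the extant species count of a
#' surviving clade of age `t` under rates `(r, eps)`. The clade-size law is
#' geometric from a stem lineage, `P(N = n) = (1-beta) beta^(n-1)`, and a
#' sum of two survival-conditioned geometrics from a crown pair,
#' `P(N = n) = (n-1) (1-beta)^2 beta^(n-2)`. Bounds invert the integer CDF
#' exactly: the lower bound is the largest `n` with `CDF(n-1) <= (1-level)/2`
#' and the upper bound the smallest `n` with `CDF(n) >= 1 - (1-level)/2`
#' (slightly conservative, as for any discrete law).
#'
#' @param t Clade ages in Ma (vectorised, >= 0).
#' @inheritParams estimate_r
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A matrix with columns `lower` and `upper` (integer counts).
#' @examples
#' confidence_bounds(23, 0.0828, 0, "crown")
#' @export
confidence_bounds <- function(t, r, eps = 0, mode = c("crown", "stem"),
                              level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(all(t >= 0), r > 0, eps >= 0, eps < 1, level > 0, level < 1)
  lo_q <- (1 - level) / 2
  hi_q <- 1 - lo_q
  base <- if (mode == "crown") 2L else 1L
  out <- matrix(base, nrow = length(t), ncol = 2L,
                dimnames = list(NULL, c("lower", "upper")))
  be <- .beta_re(t, r, eps)
  for (i in seq_along(t)) {
    if (be[i] <= 0) next
    p <- 1 - be[i]
    if (mode == "stem") {
      # N - 1 ~ geometric(p); CDF(n) = pgeom(n - 1, p)
      up <- stats::qgeom(hi_q, p) + 1L
      ks <- stats::qgeom(lo_q, p)
      if (stats::pgeom(ks, p) <= lo_q) ks <- ks + 1L
      lo <- ks + 1L  # largest n with pgeom(n - 2, p) <= lo_q
    } else {
      # N - 2 ~ nbinom(2, p); CDF(n) = pnbinom(n - 2, 2, p)
      up <- stats::qnbinom(hi_q, 2, p) + 2L
      ks <- stats::qnbinom(lo_q, 2, p)
      if (stats::pnbinom(ks, 2, p) <= lo_q) ks <- ks + 1L
      lo <- ks + 2L  # largest n with pnbinom(n - 3, 2, p) <= lo_q
    }
    out[i, ] <- c(max(lo, base), max(up, base))
  }
  out
}

#' Richness envelope through time
#'
#' Expected diversity and confidence bounds evaluated on an age grid —
#' the plot data for clade-age-versus-richness envelope figures.
#'
#' @inheritParams confidence_bounds
#' @param t_max Oldest age on the grid, Ma (default 100).
#' @param step Grid resolution, Ma (default 1).
#' @return A data.frame (class `envelope_table`) with columns `t`, `lower`,
#'   `expected`, `upper`; the generating `(r, eps, mode, level)` are
#'   attached as attributes.
#' @export
envelope_table <- function(r, eps = 0, mode = c("crown", "stem"),
                           level = 0.95, t_max = 100, step = 1) {
  mode <- match.arg(mode)
  t <- seq(0, t_max, by = step)
  bounds <- confidence_bounds(t, r, eps, mode, level)
  out <- data.frame(t = t, lower = bounds[, "lower"],
                    expected = expected_richness(t, r, eps, mode),
                    upper = bounds[, "upper"])
  attr(out, "params") <- list(r = r, eps = eps, mode = mode, level = level)
  class(out) <- c("envelope_table", "data.frame")
  out
}

#' Published envelope parameter presets
#'
#' The three `(r, eps)` combinations used for the cichlid richness
#' envelopes: a low-extinction and a high-extinction family-wide rate
#' estimated from total cichlid richness and crown age, and the background
#' rate from the shift analysis.
#'
#' @return Named list of lists with elements `r` and `eps`:
#'   `low` (r = 0.0828, eps = 0), `high` (r = 0.062, eps = 0.9),
#'   `background` (r = 0.069, eps = 0.41).
#' @export
envelope_presets <- function() {
  list(low = list(r = 0.0828, eps = 0),
       high = list(r = 0.062, eps = 0.9),
       background = list(r = 0.069, eps = 0.41))
}

#' Classify clades against a richness envelope
#'
#' Compares each clade's standing richness with the confidence bounds at
#' its age: `below`, `within`, or `above`. When HPD age bounds are present
#' the classification is recomputed at both endpoints and flagged
#' `ambiguous` if the endpoints disagree — a clade is only unambiguously
#' exceptional when it falls outside the envelope across its whole
#' credible age range. Records without richness are skipped with a
#' warning.
#'
#' @param clades A clade table (see [read_clade_table]).
#' @inheritParams confidence_bounds
#' @return A data.frame: name, age, age_lo, age_hi, richness, lower,
#'   upper, class, ambiguous.
#' @export
assess_clades <- function(clades, r, eps = 0, level = 0.95) {
  clades <- validate_clades(clades)
  skip <- is.na(clades$richness)
  if (any(skip))
    warning("skipping clades without richness: ",
            paste(clades$name[skip], collapse = ", "))
  clades <- clades[!skip, , drop = FALSE]
  cls_at <- function(t, n, mode) {
    b <- confidence_bounds(t, r, eps, mode, level)
    ifelse(n < b[, "lower"], "below", ifelse(n > b[, "upper"], "above", "within"))
  }
  out <- clades[c("name", "age", "age_lo", "age_hi", "richness")]
  out$lower <- NA_integer_
  out$upper <- NA_integer_
  out$class <- NA_character_
  out$ambiguous <- FALSE
  for (i in seq_len(nrow(clades))) {
    mode <- clades$mode[i]
    b <- confidence_bounds(clades$age[i], r, eps, mode, level)
    out$lower[i] <- b[1L, "lower"]
    out$upper[i] <- b[1L, "upper"]
    out$class[i] <- cls_at(clades$age[i], clades$richness[i], mode)
    if (!is.na(clades$age_lo[i]) && !is.na(clades$age_hi[i])) {
      c_lo <- cls_at(clades$age_lo[i], clades$richness[i], mode)
      c_hi <- cls_at(clades$age_hi[i], clades$richness[i], mode)
      out$ambiguous[i] <- c_lo != c_hi
    }
  }
  rownames(out) <- NULL
  out
}
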