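# Combined likelihood of a chronogram with unresolved terminal clades.
#
# The reconstructed-process density factorises over branches: with
# q(t) = (1 - alpha(t)) (1 - beta(t)), a reconstructed branch from age t1
# down to age t2 contributes q(t1)/q(t2), every internal (non-root)
# bifurcation contributes b, and conditioning on survival of the two root
# lineages divides by (1 - alpha(root age)) once per root edge. A pendant
# branch subtending an unresolved clade of richness n and stem age t1 is
# replaced by the probability of that clade's richness: P(n | t1) under
# the default root-only conditioning (the exact joint density; for a
# single rate class with all richness 1 this IS loglik_resolved), or the
# survival-conditioned P(n | t1) / (1 - alpha(t1)) under the optional
# "root+tips" convention, where each tip clade additionally conditions on
# its own survival. The latter cancels every tip's survival factor and
# leaves the likelihood with a degenerate supremum plateau on the
# r -> 0, eps -> 1 boundary, so it is not the default.
#
# Every term depends on the rates of exactly one class, so the likelihood
# is separable across classes and each class can be maximised on its own.

.LOGR_LO <- -16
.LOGR_HI <- 3
.LEPS_LO <- -35
.LEPS_HI <- 35

# Precompute everything the likelihood needs from a tree + richness.
bd_terms <- function(tree, richness = NULL) {
  tree <- as_chronogram(tree)
  n <- if (is.null(richness) || is.data.frame(richness)) {
    match_richness(tree, richness)
  } else {
    stats::setNames(as.integer(richness[tree$tip.label]), tree$tip.label)
  }
  if (anyNA(n)) stop("richness missing for some tips")
  n_tip <- length(tree$tip.label)
  age <- node_ages(tree)
  root <- n_tip + 1L
  edge <- tree$edge  # cladewise: parents precede children
  child <- edge[, 2L]
  parent <- edge[, 1L]
  int <- child > n_tip
  tip_edge <- !int
  po <- .postorder_nodes(tree)
  list(tree = tree, n_tip = n_tip, root = root, age = age,
       edge_parent = parent, edge_child = child,
       int_child = child[int], int_t1 = age[parent[int]], int_t2 = age[child[int]],
       tip_id = child[tip_edge], tip_t = age[parent[tip_edge]],
       tip_n = as.numeric(n[child[tip_edge]]),
       root_children = child[parent == root], root_age = age[root],
       po_rank = stats::setNames(seq_along(po), po),
       const = lfactorial(n_tip - 1))
}

# Most-recent-shift class of every node; 0 = base class. `shifts` are node
# numbers; a shift node's own subtending edge belongs to its new class.
.node_classes <- function(terms, shifts) {
  n_all <- terms$n_tip + terms$tree$Nnode
  cls <- integer(n_all)
  if (length(shifts)) {
    sh <- match(seq_len(n_all), shifts, nomatch = 0L)
    for (i in seq_along(terms$edge_parent)) {
      v <- terms$edge_child[i]
      cls[v] <- if (sh[v] > 0L) sh[v] else cls[terms$edge_parent[i]]
    }
  }
  cls
}

# Split the term table into per-class data lists keyed "0", "1", ...
# tip_cond: condition each tip clade on its own survival (in addition to
# the root conditioning) instead of using the exact joint density.
# slice_age: when the unresolved tips come from cutting the tree at a
# fixed age, the geometric richness factor is evaluated at that age (the
# exact marginal density of the sliced data); NULL = stem-age convention.
.class_data <- function(terms, shifts, tip_cond = FALSE, slice_age = NULL) {
  cls <- .node_classes(terms, shifts)
  lapply(stats::setNames(0:length(shifts), 0:length(shifts)), function(k) {
    ei <- which(cls[terms$int_child] == k)
    ti <- which(cls[terms$tip_id] == k)
    ci <- which(cls[terms$root_children] == k)
    t1 <- terms$int_t1[ei]; t2 <- terms$int_t2[ei]
    tt <- terms$tip_t[ti];  tn <- terms$tip_n[ti]
    ct <- rep.int(terms$root_age, length(ci))
    bt <- if (is.null(slice_age)) tt else rep.int(slice_age, length(ti))
    ts <- c(t1, t2, tt, ct, bt)
    m <- length(ei)
    list(ts = ts, m = m, ntip = length(ti), ncond = length(ci),
         i1 = seq_len(m), i2 = m + seq_len(m),
         it = 2L * m + seq_along(ti), ic = 2L * m + length(ti) + seq_along(ci),
         ib = 2L * m + length(ti) + length(ci) + seq_along(ti),
         tn1 = tn - 1, tt = tt, bt = bt,
         rsum = sum(t1) - sum(t2) + sum(tt),
         tip_cond = tip_cond,
         key = paste(c(if (tip_cond) "tc" else "rc",
                       if (is.null(slice_age)) "stem" else
                         sprintf("sl%.12g", slice_age), ei, -1L, ti, -2L, ci),
                     collapse = ","))
  })
}

# Negative log-likelihood of one class at par = (log r, logit eps).
.class_nll <- function(par, dat) {
  lr <- min(max(par[1L], .LOGR_LO), .LOGR_HI)
  le <- min(max(par[2L], .LEPS_LO), .LEPS_HI)
  r <- exp(lr)
  eps <- stats::plogis(le)
  l1me <- log1p(-eps)
  E <- exp(-r * dat$ts)
  g <- log1p(-eps * E)
  ll <- -r * dat$rsum
  if (dat$m) {
    ll <- ll + dat$m * (lr - l1me) - 2 * sum(g[dat$i1]) + 2 * sum(g[dat$i2])
  }
  if (dat$ntip) {
    gt <- g[dat$it]
    surv <- if (dat$tip_cond) 1 else 2  # "root": tips keep their (1 - alpha)
    ll <- ll + surv * (dat$ntip * l1me - sum(gt)) +
      sum(dat$tn1 * (log(-expm1(-r * dat$bt)) - g[dat$ib]))
  }
  if (dat$ncond) ll <- ll - dat$ncond * l1me + sum(g[dat$ic])
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Deterministic per-class maximisation: fixed 3x3 start grid over
# (log r, logit eps), Nelder-Mead from the best three starts, BFGS polish.
.fit_class <- function(dat, extra_starts = NULL) {
  if (dat$m == 0L && dat$ntip == 0L && dat$ncond == 0L) {
    return(list(logr = NA_real_, logiteps = NA_real_, r = NA_real_,
                eps = NA_real_, b = NA_real_, d = NA_real_, lnL = 0,
                boundary = TRUE, empty = TRUE))
  }
  grid <- as.matrix(expand.grid(lr = log(c(0.02, 0.1, 0.5)),
                                le = stats::qlogis(c(0.05, 0.5, 0.95))))
  if (!is.null(extra_starts)) grid <- rbind(grid, extra_starts)
  vals <- apply(grid, 1L, .class_nll, dat = dat)
  ord <- order(vals)[seq_len(min(3L, nrow(grid)))]
  best <- NULL
  for (i in ord) {
    fit <- stats::optim(grid[i, ], .class_nll, dat = dat, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  pol <- tryCatch(
    stats::optim(best$par, .class_nll, dat = dat, method = "BFGS",
                 control = list(maxit = 100L, reltol = 1e-12)),
    error = function(e) best)
  if (pol$value <= best$value) best <- pol
  lr <- min(max(best$par[1L], .LOGR_LO), .LOGR_HI)
  le <- min(max(best$par[2L], .LEPS_LO), .LEPS_HI)
  r <- exp(lr)
  eps <- stats::plogis(le)
  list(logr = lr, logiteps = le, r = r, eps = eps,
       b = r / (1 - eps), d = r * eps / (1 - eps), lnL = -best$value,
       boundary = (lr <= .LOGR_LO + 1e-6 || lr >= .LOGR_HI - 1e-6 ||
                     eps <= 1e-6 || le >= .LEPS_HI - 0.1),
       empty = FALSE)
}

# Fit every class of a shift configuration; memoised on the class's term
# membership so unchanged classes are never re-optimised during a search.
.fit_partition <- function(terms, shifts, cache = NULL, extra_starts = NULL,
                           tip_cond = FALSE, slice_age = NULL) {
  cd <- .class_data(terms, shifts, tip_cond, slice_age)
  fits <- vector("list", length(cd))
  for (k in seq_along(cd)) {
    key <- cd[[k]]$key
    hit <- if (!is.null(cache)) cache[[key]] else NULL
    if (!is.null(hit)) {
      fits[[k]] <- hit
    } else {
      fits[[k]] <- .fit_class(cd[[k]], extra_starts = extra_starts)
      if (!is.null(cache)) cache[[key]] <- fits[[k]]
    }
  }
  names(fits) <- names(cd)
  fits
}

.model_from_fits <- function(terms, shifts, fits) {
  lnL <- sum(vapply(fits, `[[`, 0, "lnL")) + terms$const
  k <- 2L + 3L * length(shifts)
  structure(list(
    shifts = shifts,
    shift_ids = node_ids(terms$tree)[shifts],
    class_fits = fits,
    params = lapply(fits, function(f)
      if (isTRUE(f$empty)) NULL else bd_params(f$b, f$d)),
    lnL = lnL, k = k, AIC = 2 * k - 2 * lnL,
    n_tip = terms$n_tip,
    boundary = any(vapply(fits, `[[`, TRUE, "boundary"))
  ), class = "shift_model")
}

#' Combined log-likelihood of a chronogram with tip richness counts
#'
#' Total log-likelihood of the resolved internal structure (reconstructed
#' birth-death process, conditioned on survival of the two root lineages)
#' plus, for every tip, the survival-conditioned probability of its
#' unresolved clade's richness at its stem age (the age of the node its
#' subtending edge attaches to). Each branch, node, and tip term is
#' evaluated under the rate class assigned to it by `shifts`: an element
#' belongs to the class of the most recent shift node on its rootward path
#' (the shift node itself included), or to the base class.
#'
#' @param tree A `chronogram`.
#' @param richness A richness data.frame (see [read_richness]), or `NULL`
#'   for a fully resolved tree (all tips richness 1).
#' @param params A [bd_params] object (base class), or a list of
#'   `bd_params` of length `length(shifts) + 1` (base first).
#' @param shifts Integer node numbers of shift points (possibly empty).
#' @param condition Survival conditioning convention. `"root"` (default)
#'   conditions once on survival of the two root lineages and uses the
#'   exact joint density of backbone and richness counts; with all tip
#'   richness 1 and a single class it equals [loglik_resolved] exactly.
#'   `"root+tips"` additionally conditions every tip clade on its own
#'   survival (the MEDUSA-flavour convention); note its maximum sits on a
#'   degenerate high-turnover boundary ridge for fully resolved trees.
#' @param backbone_age Collapse age of a time-sliced backbone, in Ma.
#'   Unresolved tips created by cutting a resolved tree at a fixed age
#'   (see [collapse_to_backbone]) carry, by construction, no reconstructed
#'   split above the cut; the exact marginal density then evaluates the
#'   geometric richness factor at the cut age rather than at the stem age.
#'   The default `NULL` is the stem-age convention appropriate for
#'   taxonomy-defined unresolved clades (tribes, subfamilies); the two
#'   conventions coincide for tips of richness 1.
#' @return Log-likelihood (scalar).
#' @export
loglik_combined <- function(tree, richness = NULL, params, shifts = integer(0),
                            condition = c("root", "root+tips"),
                            backbone_age = NULL) {
  condition <- match.arg(condition)
  terms <- bd_terms(tree, richness)
  if (inherits(params, "bd_params")) params <- list(params)
  if (length(params) != length(shifts) + 1L)
    stop("need one bd_params per rate class (base first)")
  cd <- .class_data(terms, shifts, tip_cond = condition == "root+tips",
                    slice_age = backbone_age)
  ll <- terms$const
  for (k in seq_along(cd)) {
    p <- params[[k]]
    ll <- ll - .class_nll(c(log(p$r), stats::qlogis(p$eps)), cd[[k]])
  }
  ll
}

#' Maximum-likelihood birth-death rates for a shift configuration
#'
#' Estimates per-class `(r, eps)` by maximising [loglik_combined] in the
#' transformed space `(log r, logit eps)`, deterministically (fixed 3x3
#' start grid, Nelder-Mead, quasi-Newton polish; no randomness). Estimates
#' pinned against the admissible-region limits are flagged as boundary
#' estimates (e.g. `eps` driven to 0 on pure-birth data).
#'
#' @inheritParams loglik_combined
#' @return A `shift_model`: rate class fits, `lnL`, parameter count
#'   `k = 2 + 3 * n_shifts`, and `AIC = 2k - 2 lnL`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1.5,(C:2,D:2):0.5);")
#' fit_bd(tr)
#' @export
fit_bd <- function(tree, richness = NULL, shifts = integer(0),
                   condition = c("root", "root+tips"), backbone_age = NULL) {
  condition <- match.arg(condition)
  terms <- bd_terms(tree, richness)
  fits <- .fit_partition(terms, shifts, tip_cond = condition == "root+tips",
                         slice_age = backbone_age)
  .model_from_fits(terms, shifts, fits)
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("birth-death shift model: %d shift(s), lnL = %.4f, k = %d, AIC = %.4f\n",
              length(x$shifts), x$lnL, x$k, x$AIC))
  for (k in seq_along(x$class_fits)) {
    f <- x$class_fits[[k]]
    lab <- if (k == 1L) "base" else paste0("shift @ ", x$shift_ids[k - 1L])
    if (isTRUE(f$empty)) {
      cat(sprintf("  %-24s (empty class)\n", lab))
    } else {
      cat(sprintf("  %-24s r = %.5f, eps = %.4f%s\n", lab, f$r, f$eps,
                  if (f$boundary) "  [boundary]" else ""))
    }
  }
  invisible(x)
}
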