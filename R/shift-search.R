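# Stepwise-AIC search over diversification-rate shift points.
#
# Forward phase: every non-root node is a candidate shift; the candidate
# giving the lowest AIC is accepted if it undercuts the current model's AIC
# by at least the cutoff. Backward phase: shifts whose removal costs less
# than the cutoff are eliminated, cheapest first, refitting after each
# removal. All rate classes are refit at every candidate evaluation; since
# the likelihood is separable across classes this is done per class with
# memoisation, which yields identical optima.

.AIC_SLACK <- 1e-9

#' Candidate shift points of a chronogram
#'
#' Every node except the root: all tips (a shift confined to a single
#' unresolved clade) and all non-root internal nodes — `2N - 2` candidates
#' for an `N`-tip binary tree. A shift at the root would be the base model
#' itself.
#'
#' @param tree A `chronogram`.
#' @return Integer vector of node numbers.
#' @export
candidate_shift_points <- function(tree) {
  tree <- as_chronogram(tree)
  n_tip <- length(tree$tip.label)
  setdiff(seq_len(n_tip + tree$Nnode), n_tip + 1L)
}

# Evaluate adding shift `s` to `model`; returns the augmented shift_model.
.eval_add <- function(terms, model, s, cache, tip_cond, slice_age = NULL) {
  shifts <- c(model$shifts, s)
  old_cls <- .node_classes(terms, model$shifts)
  donor <- model$class_fits[[old_cls[s] + 1L]]
  extra <- if (!isTRUE(donor$empty)) c(donor$logr, donor$logiteps) else NULL
  fits <- .fit_partition(terms, shifts, cache = cache, extra_starts = extra,
                         tip_cond = tip_cond, slice_age = slice_age)
  .model_from_fits(terms, shifts, fits)
}

#' One forward step of the stepwise-AIC shift search
#'
#' Evaluates every candidate node not already a shift, each with all rate
#' classes refit at their maximum-likelihood values, and accepts the
#' best-AIC augmented model if it improves on the current AIC by at least
#' `cutoff`. AIC ties (within 1e-9) are broken towards the smallest
#' postorder node rank, making the step deterministic.
#'
#' @param model A `shift_model` (see [fit_bd]).
#' @param tree,richness As in [fit_bd].
#' @param cutoff Positive AIC improvement required to accept a shift
#'   (default 4, a common threshold for AIC significance).
#' @param condition Survival conditioning convention (see
#'   [loglik_combined]).
#' @param backbone_age Collapse age for time-sliced backbones (see
#'   [loglik_combined]); `NULL` for the stem-age convention.
#' @return The accepted augmented `shift_model`, or the input model with
#'   attribute `accepted = FALSE` when no candidate clears the cutoff.
#' @export
step_forward <- function(model, tree, richness = NULL, cutoff = 4,
                         condition = c("root", "root+tips"),
                         backbone_age = NULL) {
  condition <- match.arg(condition)
  terms <- bd_terms(tree, richness)
  .step_forward(terms, model, cutoff, cache = new.env(parent = emptyenv()),
                tip_cond = condition == "root+tips", slice_age = backbone_age)
}

.step_forward <- function(terms, model, cutoff, cache, tip_cond = FALSE,
                          slice_age = NULL) {
  stopifnot(cutoff > 0)
  cand <- setdiff(candidate_shift_points(terms$tree), model$shifts)
  best <- NULL
  best_rank <- Inf
  for (s in cand) {
    m <- .eval_add(terms, model, s, cache, tip_cond, slice_age)
    rank_s <- terms$po_rank[[as.character(s)]]
    if (is.null(best) || m$AIC < best$AIC - .AIC_SLACK ||
        (m$AIC < best$AIC + .AIC_SLACK && rank_s < best_rank)) {
      best <- m
      best_rank <- rank_s
    }
  }
  if (!is.null(best) && best$AIC <= model$AIC - cutoff + .AIC_SLACK) {
    attr(best, "accepted") <- TRUE
    best
  } else {
    attr(model, "accepted") <- FALSE
    model
  }
}

#' Backward elimination of weakly supported shift points
#'
#' Repeatedly removes the shift whose removal increases AIC the least
#' (refitting the remaining classes after each removal) for as long as that
#' increase is below `cutoff`; a shift is kept only if dropping it would
#' cost at least the cutoff. A model with no shifts is returned unchanged.
#'
#' @inheritParams step_forward
#' @return A `shift_model` with zero or more shifts removed.
#' @export
step_backward <- function(model, tree, richness = NULL, cutoff = 4,
                          condition = c("root", "root+tips"),
                          backbone_age = NULL) {
  condition <- match.arg(condition)
  terms <- bd_terms(tree, richness)
  .step_backward(terms, model, cutoff, cache = new.env(parent = emptyenv()),
                 tip_cond = condition == "root+tips",
                 slice_age = backbone_age)$model
}

.step_backward <- function(terms, model, cutoff, cache, tip_cond = FALSE,
                           slice_age = NULL) {
  stopifnot(cutoff > 0)
  removed <- list()
  while (length(model$shifts) > 0L) {
    best <- NULL
    best_rank <- Inf
    for (j in seq_along(model$shifts)) {
      shifts <- model$shifts[-j]
      fits <- .fit_partition(terms, shifts, cache = cache, tip_cond = tip_cond,
                             slice_age = slice_age)
      m <- .model_from_fits(terms, shifts, fits)
      rank_j <- terms$po_rank[[as.character(model$shifts[j])]]
      if (is.null(best) || m$AIC < best$AIC - .AIC_SLACK ||
          (m$AIC < best$AIC + .AIC_SLACK && rank_j < best_rank)) {
        best <- m
        best_rank <- rank_j
        dropped <- model$shifts[j]
      }
    }
    if (best$AIC - model$AIC < cutoff - .AIC_SLACK) {
      removed <- c(removed, list(list(node = dropped, model = best)))
      model <- best
    } else {
      break
    }
  }
  list(model = model, removed = removed)
}

#' Stepwise-AIC search for diversification-rate shifts
#'
#' Fits the constant-rate birth-death model (2 parameters), then adds shift
#' points forward while each addition lowers AIC by at least `cutoff` (each
#' shift adds two rates and one location parameter, so a one-shift model
#' has 5 parameters), then runs backward elimination. The whole procedure
#' is deterministic and invariant to tip relabelling and Newick rotation
#' (trees are canonicalised on input).
#'
#' @inheritParams step_forward
#' @param cutoff AIC improvement threshold (default 4). `Inf` disables the
#'   search and returns the constant-rate model.
#' @param max_shifts Safety cap on the number of forward additions.
#' @return A `search_report`: `steps` (data.frame: step, action, node, lnL,
#'   k, AIC), `const_model`, `final_model`, `delta_aic` (constant-rate AIC
#'   minus final AIC), `cutoff`, and the canonical `tree`.
#' @export
run_search <- function(tree, richness = NULL, cutoff = 4, max_shifts = 25L,
                       condition = c("root", "root+tips"),
                       backbone_age = NULL) {
  condition <- match.arg(condition)
  tip_cond <- condition == "root+tips"
  terms <- bd_terms(tree, richness)
  cache <- new.env(parent = emptyenv())
  const <- .model_from_fits(terms, integer(0),
                            .fit_partition(terms, integer(0), cache = cache,
                                           tip_cond = tip_cond,
                                           slice_age = backbone_age))
  steps <- data.frame(step = 0L, action = "start", node = NA_character_,
                      lnL = const$lnL, k = const$k, AIC = const$AIC,
                      stringsAsFactors = FALSE)
  model <- const
  ids <- node_ids(terms$tree)
  if (is.finite(cutoff)) {
    while (length(model$shifts) < max_shifts) {
      nxt <- .step_forward(terms, model, cutoff, cache, tip_cond, backbone_age)
      if (!isTRUE(attr(nxt, "accepted"))) break
      model <- nxt
      steps <- rbind(steps, data.frame(
        step = nrow(steps), action = "add",
        node = ids[model$shifts[length(model$shifts)]],
        lnL = model$lnL, k = model$k, AIC = model$AIC,
        stringsAsFactors = FALSE))
    }
    bw <- .step_backward(terms, model, cutoff, cache, tip_cond, backbone_age)
    for (rem in bw$removed) {
      steps <- rbind(steps, data.frame(
        step = nrow(steps), action = "remove", node = ids[rem$node],
        lnL = rem$model$lnL, k = rem$model$k, AIC = rem$model$AIC,
        stringsAsFactors = FALSE))
    }
    model <- bw$model
  }
  structure(list(steps = steps, const_model = const, final_model = model,
                 delta_aic = const$AIC - model$AIC, cutoff = cutoff,
                 tree = terms$tree),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf(
    "stepwise-AIC shift search (cutoff %.3g)\nconstant-rate model: k = %d, AIC = %.4f\n",
    x$cutoff, x$const_model$k, x$const_model$AIC))
  cat(sprintf("final model: %d shift(s), k = %d, AIC = %.4f (delta AIC = %.4f)\n",
              length(x$final_model$shifts), x$final_model$k,
              x$final_model$AIC, x$delta_aic))
  if (length(x$final_model$shifts))
    cat("shift nodes:", paste(x$final_model$shift_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a search report
#'
#' Writes the step table as TSV and the full report (steps, per-class
#' rates, AICs) as JSON.
#'
#' @param report A `search_report` from [run_search].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_search_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "search_steps.tsv")
  utils::write.table(report$steps, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fm <- report$final_model
  js <- file.path(dir, "search_report.json")
  jsonlite::write_json(list(
    cutoff = report$cutoff,
    constant_rate = list(lnL = report$const_model$lnL, k = report$const_model$k,
                         AIC = report$const_model$AIC),
    final = list(lnL = fm$lnL, k = fm$k, AIC = fm$AIC,
                 shifts = as.list(fm$shift_ids),
                 classes = lapply(fm$class_fits, function(f)
                   list(r = f$r, eps = f$eps, b = f$b, d = f$d,
                        boundary = f$boundary))),
    delta_aic = report$delta_aic,
    steps = report$steps), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
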