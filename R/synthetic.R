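# Forward (Gillespie) simulation of the linear birth-death process:
# complete trees pruned of extinct lineages, optional implanted rate
# shifts, and collapse of a reconstructed tree to a backbone of unresolved
# clades carrying richness counts. These generators emulate the structure
# the analysis assumes — constant rates within rate classes — and serve as
# the Monte-Carlo cross-check of the analytic kernels.

#' Simulation configuration
#'
#' @param b,d Base speciation and extinction rates, per lineage per Myr.
#' @param duration Run length in Myr (crown/stem age of the simulation);
#'   exactly one of `duration` and `n_tips` must be given.
#' @param n_tips Target number of surviving tips; the present is drawn
#'   uniformly within the waiting interval after the target is reached, so
#'   the returned tree is ultrametric with positive pendant edges.
#' @param seed Integer seed; all randomness of [simulate_tree] flows from
#'   it and the caller's RNG state is left untouched.
#' @param start `"crown"` (two initial lineages, the default: ages are
#'   crown ages) or `"stem"` (one initial lineage).
#' @param shift Optional implanted rate shift: a list with elements `b`,
#'   `d`, `age_min`, `age_max` and optionally `size_min`, `size_max`. After
#'   the base simulation, the oldest internal node whose age falls in the
#'   window and whose clade size is within the range is selected
#'   (deterministically) and its subtree regrown under the shifted rates;
#'   regrown tips are labelled with prefix `"s"`.
#' @param max_reject Abort after this many rejected replicates (survival or
#'   selection conditions unreachable).
#' @return A `sim_config` list.
#' @export
sim_config <- function(b, d = 0, duration = NULL, n_tips = NULL, seed,
                       start = c("crown", "stem"), shift = NULL,
                       max_reject = 1000L) {
  start <- match.arg(start)
  stopifnot(b > 0, d >= 0, is.numeric(seed), length(seed) == 1L)
  if (is.null(duration) == is.null(n_tips))
    stop("give exactly one stopping rule: duration or n_tips")
  if (!is.null(n_tips)) stopifnot(n_tips >= 2)
  if (!is.null(shift)) {
    stopifnot(is.list(shift), shift$b > 0, shift$d >= 0,
              shift$age_min > 0, shift$age_max >= shift$age_min)
    if (is.null(shift$size_min)) shift$size_min <- 1L
    if (is.null(shift$size_max)) shift$size_max <- Inf
  }
  structure(list(b = b, d = d, duration = duration, n_tips = n_tips,
                 seed = as.integer(seed), start = start, shift = shift,
                 max_reject = as.integer(max_reject)),
            class = "sim_config")
}

# Gillespie forward pass; returns lineage records or NULL when every
# lineage dies before the stopping rule is met.
.gillespie <- function(b, d, duration = NULL, n_stop = NULL, start_n) {
  cap <- 1024L
  parent <- integer(cap)   # parent lineage index (0 = root of simulation)
  t0 <- numeric(cap)       # birth time (forward, 0 at start)
  t1 <- numeric(cap)       # end time (split/death/present)
  kids <- integer(cap)     # 0 tip, 2 split
  n_lin <- start_n
  alive <- seq_len(start_n)
  t0[alive] <- 0
  now <- 0
  tot <- b + d
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    if (!is.null(n_stop) && n_alive >= n_stop) {
      dt <- stats::rexp(1L, tot * n_alive)
      duration <- now + stats::runif(1L) * dt
      break
    }
    dt <- stats::rexp(1L, tot * n_alive)
    if (!is.null(duration) && now + dt >= duration) break
    now <- now + dt
    i <- alive[sample.int(n_alive, 1L)]
    t1[i] <- now
    if (stats::runif(1L) < b / tot) {
      kids[i] <- 2L
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap
        length(t1) <- cap; length(kids) <- cap
      }
      new <- n_lin + 1:2
      parent[new] <- i
      t0[new] <- now
      t1[new] <- 0
      kids[new] <- 0L
      n_lin <- n_lin + 2L
      alive <- c(alive[alive != i], new)
    } else {
      alive <- alive[alive != i]
    }
  }
  t1[alive] <- duration
  idx <- seq_len(n_lin)
  list(parent = parent[idx], t0 = t0[idx], t1 = t1[idx], kids = kids[idx],
       duration = duration, extant = idx %in% alive)
}

# Build the complete phylo from Gillespie records, prune extinct tips,
# return a chronogram (or NULL if fewer than 2 survivors).
.records_to_tree <- function(rec, start_n, tip_prefix = "t") {
  n_lin <- length(rec$parent)
  is_tip <- rec$kids == 0L
  n_tip <- sum(is_tip)
  if (n_tip < 2L) return(NULL)
  # node numbering: tips 1..n_tip, then internals; crown start adds a root
  node_of <- integer(n_lin)
  node_of[is_tip] <- seq_len(n_tip)
  internal <- which(!is_tip)
  extra_root <- start_n == 2L
  node_of[internal] <- n_tip + (if (extra_root) 1L else 0L) + seq_along(internal)
  n_node <- length(internal) + if (extra_root) 1L else 0L
  edge <- matrix(0L, n_lin - if (extra_root) 0L else 1L, 2L)
  elen <- numeric(nrow(edge))
  k <- 0L
  for (i in seq_len(n_lin)) {
    p <- rec$parent[i]
    if (p == 0L && !extra_root) next  # stem start: initial lineage is the root edge
    k <- k + 1L
    from <- if (p == 0L) n_tip + 1L else node_of[p]
    edge[k, ] <- c(from, node_of[i])
    elen[k] <- rec$t1[i] - if (p == 0L) 0 else rec$t1[p]
  }
  phy <- structure(list(edge = edge[seq_len(k), , drop = FALSE],
                        edge.length = elen[seq_len(k)],
                        tip.label = paste0(tip_prefix, seq_len(n_tip)),
                        Nnode = n_node),
                   class = "phylo")
  phy <- ape::read.tree(text = .newick_text(phy))
  extinct <- paste0(tip_prefix, which(!rec$extant[is_tip]))
  if (length(extinct)) {
    if (n_tip - length(extinct) < 2L) return(NULL)
    phy <- ape::drop.tip(phy, extinct)
  }
  if (is.null(phy) || length(phy$tip.label) < 2L) return(NULL)
  as_chronogram(phy)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a reconstructed birth-death chronogram
#'
#' Forward Gillespie simulation of the linear birth-death process from a
#' crown pair (or a single stem lineage), pruned of extinct lineages;
#' rejection-resamples until at least two lineages survive. Deterministic
#' given the config seed. With an implanted shift, the selected subtree is
#' regrown under the shifted rates from the selected node's age (as a
#' crown clade, both daughters surviving) and its tips labelled with
#' prefix `"s"`.
#'
#' @param config A [sim_config].
#' @return A `chronogram`; the realised shift node's age is attached as
#'   attribute `shift_age` when a shift was implanted.
#' @examples
#' tr <- simulate_tree(sim_config(b = 0.3, d = 0.1, duration = 10, seed = 1))
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    start_n <- if (config$start == "crown") 2L else 1L
    tree <- NULL
    for (trial in seq_len(config$max_reject)) {
      rec <- .gillespie(config$b, config$d, config$duration, config$n_tips,
                        start_n)
      if (is.null(rec)) next
      tree <- .records_to_tree(rec, start_n)
      if (is.null(tree)) next
      if (is.null(config$shift)) return(tree)
      grafted <- .implant_shift(tree, config$shift, config$max_reject)
      if (!is.null(grafted)) return(grafted)
      tree <- NULL
    }
    stop("stopping rule unreachable: all replicates rejected")
  })
}

# Regrow the subtree of a deterministically selected node under shifted
# rates. Selection: oldest internal node with age in [age_min, age_max]
# and clade size in [size_min, size_max]; ties broken by node number.
.implant_shift <- function(tree, shift, max_reject) {
  n_tip <- length(tree$tip.label)
  age <- node_ages(tree)
  sizes <- .clade_sizes(tree)
  cand <- which(seq_along(age) > n_tip &
                  age >= shift$age_min & age <= shift$age_max &
                  sizes >= shift$size_min & sizes <= shift$size_max)
  cand <- setdiff(cand, n_tip + 1L)  # never the root
  if (!length(cand)) return(NULL)
  node <- cand[order(-age[cand], cand)][1L]
  a_v <- age[node]
  sub <- NULL
  for (i in seq_len(max_reject)) {
    rec <- .gillespie(shift$b, shift$d, duration = a_v, n_stop = NULL,
                      start_n = 2L)
    if (is.null(rec)) next
    s <- .records_to_tree(rec, 2L, tip_prefix = "s")
    if (is.null(s)) next
    if (abs(max(node_ages(s)) - a_v) > 1e-9 * a_v) next  # a root lineage died out
    sub <- s
    break
  }
  if (is.null(sub)) return(NULL)
  tips_below <- .tips_below(tree, node)
  rep_tip <- sort(tree$tip.label[tips_below])[1L]
  pruned <- if (length(tips_below) > 1L)
    ape::drop.tip(tree, setdiff(tree$tip.label[tips_below], rep_tip)) else tree
  class(pruned) <- "phylo"
  grafted <- ape::bind.tree(pruned, sub,
                            where = which(pruned$tip.label == rep_tip),
                            position = a_v)
  grafted <- ape::drop.tip(grafted, rep_tip)
  out <- as_chronogram(grafted)
  attr(out, "shift_age") <- a_v
  out
}

.tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= n_tip) acc <- c(acc, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  acc
}

.clade_sizes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  sizes <- c(rep.int(1L, n_tip), integer(tree$Nnode))
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e))) sizes[e[i, 1L]] <- sizes[e[i, 1L]] + sizes[e[i, 2L]]
  sizes
}

#' Collapse a resolved chronogram to a backbone with richness counts
#'
#' Every lineage crossing `cut_age` becomes an unresolved backbone tip
#' whose richness is the number of descendant tips in the original tree
#' (total richness is conserved exactly). The surviving tip keeps the
#' lexicographically smallest label of its clade; its pendant edge runs to
#' the present from the attachment node, matching the stem-age convention
#' of the combined likelihood.
#'
#' @param tree A `chronogram`.
#' @param cut_age Collapse age in Ma, strictly between 0 and the root age.
#' @return A list with elements `tree` (the backbone `chronogram`) and
#'   `richness` (data.frame `tip`, `n_species`).
#' @export
collapse_to_backbone <- function(tree, cut_age) {
  tree <- as_chronogram(tree)
  age <- node_ages(tree)
  root_age <- max(age)
  if (cut_age <= 0 || cut_age >= root_age)
    stop("cut_age must lie strictly between 0 and the root age")
  cross <- which(age[tree$edge[, 1L]] > cut_age & age[tree$edge[, 2L]] <= cut_age)
  keep <- character(0)
  count <- integer(0)
  drop <- character(0)
  for (i in cross) {
    below <- .tips_below(tree, tree$edge[i, 2L])
    labs <- sort(tree$tip.label[below])
    keep <- c(keep, labs[1L])
    count <- c(count, length(below))
    if (length(labs) > 1L) drop <- c(drop, labs[-1L])
  }
  backbone <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  backbone <- as_chronogram(backbone)
  list(tree = backbone,
       richness = data.frame(tip = keep, n_species = count,
                             stringsAsFactors = FALSE)[order(keep), ])
}

#' Monte-Carlo clade sizes under the birth-death process
#'
#' Forward count-level Gillespie simulation of the number of extant
#' descendants of one lineage (stem) or a crown pair after `t` Myr; the
#' independent oracle for [prob_richness], [expected_richness] and
#' [confidence_bounds]. Crown replicates can be conditioned on survival of
#' both root lineages (the conditioning under which the crown clade-size
#' law holds).
#'
#' @param n_rep Number of replicates to return.
#' @param b,d Speciation and extinction rates.
#' @param t Duration in Myr.
#' @param mode `"stem"` or `"crown"`.
#' @param condition_survival Drop replicates whose lineage(s) died out
#'   (both lineages must survive in crown mode).
#' @param seed Integer seed (caller's RNG state untouched).
#' @return Integer vector of clade sizes (length `n_rep` when
#'   conditioning, else exactly `n_rep` unconditioned replicates).
#' @export
simulate_clade_sizes <- function(n_rep, b, d, t, mode = c("stem", "crown"),
                                 condition_survival = FALSE, seed) {
  mode <- match.arg(mode)
  stopifnot(b > 0, d >= 0, t >= 0)
  .with_seed(seed, {
    draw <- function(m) .sim_counts(m, b, d, t)
    if (mode == "stem" && !condition_survival) return(draw(n_rep))
    out <- integer(0)
    while (length(out) < n_rep) {
      m <- max(1000L, ceiling((n_rep - length(out)) * 1.5))
      if (mode == "stem") {
        x <- draw(m)
        out <- c(out, x[x > 0L])
      } else {
        x1 <- draw(m)
        x2 <- draw(m)
        if (condition_survival) {
          ok <- x1 > 0L & x2 > 0L
          out <- c(out, (x1 + x2)[ok])
        } else {
          return((x1 + x2)[seq_len(n_rep)])
        }
      }
    }
    out[seq_len(n_rep)]
  })
}

# vectorised count-level Gillespie: one lineage per replicate at t = 0
.sim_counts <- function(n_rep, b, d, t_end) {
  n <- rep.int(1L, n_rep)
  tt <- numeric(n_rep)
  active <- rep.int(TRUE, n_rep)
  tot <- b + d
  pb <- b / tot
  while (any(active)) {
    idx <- which(active)
    dt <- stats::rexp(length(idx), tot * n[idx])
    tt[idx] <- tt[idx] + dt
    done <- tt[idx] >= t_end
    ev <- idx[!done]
    if (length(ev)) {
      birth <- stats::runif(length(ev)) < pb
      n[ev] <- n[ev] + ifelse(birth, 1L, -1L)
      active[ev[n[ev] == 0L]] <- FALSE
    }
    active[idx[done]] <- FALSE
  }
  n
}
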