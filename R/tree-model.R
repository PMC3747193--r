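#' @importFrom ape read.tree write.tree drop.tip bind.tree is.binary
#'   node.depth.edgelength Ntip Nnode
NULL

.ULTRA_RTOL <- 1e-6

#' Read an ultrametric chronogram from Newick
#'
#' Parses a single Newick tree with branch lengths in millions of years and
#' validates it as a chronogram: rooted, strictly binary, all branch lengths
#' positive, and ultrametric to a relative tolerance of 1e-6 of the root
#' age. Residual root-to-tip deviations within tolerance (rounding noise in
#' relaxed-clock exports) are removed by snapping every tip to age exactly
#' zero, so downstream age arithmetic is exact. The tree is put into a
#' canonical orientation (children ordered by their smallest descendant tip
#' label), which makes node numbering deterministic; internal node labels
#' are preserved.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An object of classes `chronogram` and `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("invalid Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("invalid Newick: no tree parsed")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree per file")
    phy <- phy[[1L]]
  }
  as_chronogram(phy)
}

#' Validate and canonicalise a phylogeny as a chronogram
#'
#' @param phy A `phylo` object (or an existing `chronogram`, returned after
#'   re-validation).
#' @return A `chronogram` (see [read_newick]).
#' @export
as_chronogram <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stop("fewer than 2 tips")
  nkids <- tabulate(phy$edge[, 1L], nbins = n_tip + phy$Nnode)
  if (any(nkids[-seq_len(n_tip)] != 2L)) stop("non-binary tree")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("invalid edge: missing branch length")
  if (any(phy$edge.length <= 0)) stop("invalid edge: zero or negative branch length")
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(n_tip)])
  if (root_age <= 0) stop("invalid edge: root age must be > 0")
  dev <- abs(depth[seq_len(n_tip)] - root_age) / root_age
  if (any(dev > .ULTRA_RTOL)) {
    worst <- which.max(dev)
    stop(sprintf("not a chronogram: tip '%s' deviates from ultrametricity by %.3g (relative)",
                 phy$tip.label[worst], dev[worst]))
  }
  # snap tips to age exactly 0: recompute edge lengths from node ages
  age <- root_age - depth
  age[seq_len(n_tip)] <- 0
  phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  if (any(phy$edge.length <= 0))
    stop("invalid edge: branch length collapsed to zero under ultrametric snapping")
  phy <- .canonicalise(phy)
  class(phy) <- c("chronogram", "phylo")
  phy
}

# Deterministic orientation: children of every node ordered by the smallest
# tip label in their subtree; node numbering then follows from re-reading
# the canonical Newick text.
.canonicalise <- function(phy) {
  out <- ape::read.tree(text = .newick_text(phy))
  class(out) <- "phylo"
  out
}

.newick_text <- function(phy) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  has_lab <- !is.null(phy$node.label)
  rec <- function(node, len) {
    sub <- if (node <= n_tip) {
      list(txt = phy$tip.label[node], key = phy$tip.label[node])
    } else {
      parts <- lapply(kids[[as.character(node)]], function(i)
        rec(phy$edge[i, 2L], phy$edge.length[i]))
      keys <- vapply(parts, `[[`, "", "key")
      o <- order(keys, method = "radix")
      lab <- if (has_lab) phy$node.label[node - n_tip] else ""
      if (is.na(lab)) lab <- ""
      list(txt = paste0("(", paste(vapply(parts, `[[`, "", "txt")[o],
                                   collapse = ","), ")", lab),
           key = min(keys))
    }
    if (!is.null(len)) sub$txt <- paste0(sub$txt, ":", sprintf("%.15g", len))
    sub
  }
  paste0(rec(root, NULL)$txt, ";")
}

#' Serialise a chronogram to Newick text
#'
#' Writes branch lengths at full double precision (15 significant digits) so
#' that a read/write round trip preserves node ages to better than 1e-9.
#' Children are emitted in canonical order (see [read_newick]).
#'
#' @param tree A `chronogram` (or any binary ultrametric `phylo`).
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (length(tree$tip.label) < 2L) stop("fewer than 2 tips")
  txt <- .newick_text(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Node ages of a chronogram
#'
#' @param tree A `chronogram`.
#' @return Numeric vector of ages in Myr indexed by node number (tips
#'   `1..N` first, all exactly 0, then internal nodes).
#' @export
node_ages <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(n_tip)]) - depth
  age[seq_len(n_tip)] <- 0
  age
}

#' Branching ages of a chronogram
#'
#' Ages of the `N - 1` internal nodes, sorted in weakly decreasing order;
#' the first element is the root age. This is the input to
#' [loglik_resolved].
#'
#' @param tree A `chronogram` with at least 2 tips.
#' @return Numeric vector of length `N - 1`.
#' @examples
#' branching_ages(read_newick("((A:1,B:1):1,C:2);"))  # 2, 1
#' @export
branching_ages <- function(tree) {
  age <- node_ages(tree)
  sort(age[-seq_len(length(tree$tip.label))], decreasing = TRUE)
}

#' Deterministic node identifiers
#'
#' Tips are identified by their labels; internal nodes by their Newick node
#' label when present, otherwise by `node_<i>` where `i` is the node's
#' position in the canonical postorder traversal.
#'
#' @param tree A `chronogram`.
#' @return Character vector indexed by node number.
#' @export
node_ids <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- .postorder_nodes(tree)
  ids <- character(n_all)
  ids[seq_len(n_tip)] <- tree$tip.label
  for (v in (n_tip + 1L):n_all) {
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - n_tip] else ""
    if (is.na(lab) || !nzchar(lab)) lab <- sprintf("node_%d", match(v, po))
    ids[v] <- lab
  }
  ids
}

# postorder sequence over all nodes (tips included)
.postorder_nodes <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  c(e[, 2L][!duplicated(e[, 2L])], length(tree$tip.label) + 1L)
}

#' Read a tip richness table
#'
#' Two-column UTF-8 TSV with header `tip<TAB>n_species` mapping each tip
#' label of the accompanying chronogram to its count of valid extant
#' species (an integer >= 1). Consistency with a particular tree is checked
#' separately at pipeline assembly (see [match_richness]).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `tip` (character) and `n_species`
#'   (integer).
#' @export
read_richness <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  if (!identical(names(tab)[1:2], c("tip", "n_species")))
    stop("richness table must have header 'tip\tn_species'")
  if (nrow(tab) == 0L) stop("no records")
  validate_richness(tab)
}

#' @rdname read_richness
#' @param tab A data.frame with columns `tip` and `n_species`.
#' @export
validate_richness <- function(tab) {
  if (nrow(tab) == 0L) stop("no records")
  if (anyDuplicated(tab$tip)) stop("duplicate tip in richness table: ",
                                   tab$tip[duplicated(tab$tip)][1L])
  n <- tab$n_species
  if (anyNA(n) || any(n != round(n)) || any(n < 1))
    stop("richness counts must be integers >= 1")
  tab$n_species <- as.integer(n)
  tab[c("tip", "n_species")]
}

#' Align a richness table with a chronogram's tips
#'
#' @param tree A `chronogram`.
#' @param richness A richness data.frame ([read_richness]), or `NULL` for
#'   all-ones (a fully resolved tree).
#' @return Integer vector of counts ordered as `tree$tip.label`.
#' @export
match_richness <- function(tree, richness = NULL) {
  tips <- tree$tip.label
  if (is.null(richness)) return(stats::setNames(rep.int(1L, length(tips)), tips))
  richness <- validate_richness(richness)
  miss <- setdiff(tips, richness$tip)
  if (length(miss)) stop("tips missing from richness table: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(richness$tip, tips)
  if (length(extra)) stop("richness entries absent from tree: ",
                          paste(extra, collapse = ", "))
  stats::setNames(richness$n_species[match(tips, richness$tip)], tips)
}

#' Read a clade table
#'
#' TSV with header `name age age_lo age_hi richness mode`, one row per
#' clade: mean age in Ma, optional 95% HPD bounds, optional extant species
#' count, and whether the age is a crown or a stem age. A mean age falling
#' outside its own HPD interval is reported with a warning but kept
#' verbatim (published tables occasionally contain such inconsistencies).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the six columns above.
#' @export
read_clade_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "age", "age_lo", "age_hi", "richness", "mode")
  if (!all(need %in% names(tab)))
    stop("clade table must have header 'name age age_lo age_hi richness mode'")
  validate_clades(tab[need])
}

#' @rdname read_clade_table
#' @param tab A data.frame with the clade-table columns.
#' @export
validate_clades <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  if (anyNA(tab$age) || any(tab$age <= 0)) stop("clade ages must be > 0")
  if (!all(tab$mode %in% c("crown", "stem"))) stop("mode must be 'crown' or 'stem'")
  has_hpd <- !is.na(tab$age_lo) & !is.na(tab$age_hi)
  if (any(has_hpd & tab$age_lo > tab$age_hi)) stop("age_lo exceeds age_hi")
  bad <- has_hpd & (tab$age < tab$age_lo | tab$age > tab$age_hi)
  if (any(bad))
    warning("mean age outside its HPD interval (kept verbatim): ",
            paste(tab$name[bad], collapse = ", "))
  rich <- tab$richness
  if (any(!is.na(rich) & (rich != round(rich) | rich < 1)))
    stop("clade richness must be integer >= 1 when present")
  tab
}

#' Tip labels of the clade descending from a node
#'
#' @param tree A `chronogram`.
#' @param node A node number, or a node identifier as produced by
#'   [node_ids].
#' @return Character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  tree <- as_chronogram(tree)
  if (is.character(node)) {
    node <- match(node, node_ids(tree))
    if (is.na(node)) stop("unknown node id")
  }
  tree$tip.label[.tips_below(tree, node)]
}
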