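# Shared fixtures built in code.

# A backbone dataset with an implanted diversification-rate speed-up:
# base crown clade grown at b = 0.05 (pure birth) for 70 Myr, one internal
# node aged 6-9 Ma regrown at b = 0.4, then collapsed at 3 Ma into
# unresolved tips carrying richness. Replicates are conditioned on the
# shifted clade spanning at least `min_shift_tips` species; shifted-clade
# tips carry the label prefix "s".
sim_shifted_backbone <- function(seed, min_shift_tips = 20L, cut_age = 3) {
  shift_spec <- list(b = 0.4, d = 0, age_min = 6, age_max = 9)
  for (k in 0:99) {
    tr <- simulate_tree(sim_config(b = 0.05, d = 0, duration = 70,
                                   seed = seed + 100000L * k,
                                   shift = shift_spec))
    if (sum(startsWith(tr$tip.label, "s")) >= min_shift_tips) {
      bb <- collapse_to_backbone(tr, cut_age)
      bb$cut_age <- cut_age
      return(bb)
    }
  }
  stop("no replicate with a large enough shifted clade")
}

# Is the node (given by its node_ids() identifier) inside the implanted
# clade, i.e. are all its descendant tips shifted-clade tips?
node_inside_shift <- function(tree, id) {
  all(startsWith(clade_tips(tree, id), "s"))
}

richness_df <- function(tree, counts = 1L) {
  data.frame(tip = tree$tip.label, n_species = counts,
             stringsAsFactors = FALSE)
}
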