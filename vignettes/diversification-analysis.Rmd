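---
title: "Detecting diversification-rate shifts and exceptional clade richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversification-rate shifts and exceptional clade richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divshift)
```

## The question

Some clades hold vastly more species than their close relatives: among
cichlid fishes, the African subfamily Pseudocrenilabrinae holds over a
thousand valid species while its Malagasy relatives hold a few dozen.
Two non-exclusive explanations exist: the species-rich clade diversified
*faster* (a rate shift somewhere in its history), or it is simply
*older* (more time to accumulate species at a common rate). `divshift`
implements both halves of that test on a time-calibrated phylogeny
(a *chronogram*, branch lengths in Myr) whose tips may stand for whole
unresolved clades carrying only an extant species count:

1. a **stepwise-AIC search for diversification-rate shifts** under a
   birth--death model whose likelihood combines the resolved backbone
   with the taxonomic richness of its unresolved tips, and
2. **expected-richness confidence envelopes** through time, which
   classify each clade as species-poorer, -richer, or as expected given
   its age under stated net diversification and relative extinction
   rates.

## The model

Lineages speciate at rate $b$ and go extinct at rate $d$ (per lineage
per Myr), with net diversification $r = b - d$ and relative extinction
$\epsilon = d/b$. For one lineage alive $t$ Myr ago, with
$\rho = e^{rt}$,

$$\alpha(t) = \frac{d(\rho - 1)}{b\rho - d}, \qquad
  \beta(t) = \frac{b(\rho - 1)}{b\rho - d},$$

where $\alpha$ is the probability of total extinction and, conditional
on survival, the number of extant descendants is geometric with
parameter $\beta$: $P(n) = (1-\alpha)(1-\beta)\beta^{n-1}$. The critical
case $b = d$ uses the limit $\alpha = \beta = bt/(1+bt)$. All kernels
are evaluated in numerically stable forms (in terms of $e^{-rt}$ with
`log1p`/`expm1`), so ages up to hundreds of Myr and rates spanning
$10^{-7}$–$20$ per Myr are safe.

### Likelihood of a backbone with unresolved tips

The reconstructed-process density factorises over branches: writing
$q(t) = (1-\alpha(t))(1-\beta(t))$, a resolved branch from age $t_1$
down to $t_2$ contributes $q(t_1)/q(t_2)$, every non-root bifurcation
contributes $b$, and each pendant lineage of stem age $t_s$ subtending
an unresolved clade of $n$ species contributes $P(n \mid t_s)$. The
whole observation is conditioned once on survival of the two root
lineages (the Nee conditioning) and carries the usual $(N-1)!$
labelled-histories constant. For a fully resolved tree (all tips
richness 1) this is *exactly* the classical conditioned likelihood of
the branching ages,

$$\ln L = \ln(N-1)! + (N-2)\ln r + r\sum_{i=3}^{N} x_i
  + N \ln(1-\epsilon) - 2\sum_{i=2}^{N}\ln\!\left(e^{r x_i} - \epsilon\right),$$

which `loglik_resolved()` evaluates directly and `loglik_combined()`
reproduces to machine precision (a property the test suite checks).

Two conventions deserve comment, both decided here after numerical
analysis and both switchable:

* **Survival conditioning** (`condition`). An alternative convention
  conditions every unresolved tip clade on its own survival *in
  addition* to the root conditioning. That cancels each tip's survival
  factor $(1-\alpha(t_s))$, and the resulting likelihood has a
  degenerate supremum: a plateau on the boundary $r \to 0$,
  $\epsilon \to 1$ (infinite turnover) whose value exceeds the interior
  optimum on fully resolved trees, so the optimizer runs off the
  admissible region. The default `"root"` is the exact joint density
  and has no such pathology; `"root+tips"` is provided for
  compatibility with implementations that use the per-tip conditioning.

* **Stem-age versus slice semantics** (`backbone_age`). For
  taxonomy-defined unresolved clades (tribes, subfamilies) the pendant
  term $P(n \mid t_s)$ at the stem age is the correct marginal: every
  split of the stem lineage is, by definition, internal to the clade.
  Data produced by *cutting a resolved tree at a fixed age* are subtly
  different: a slice-defined pendant has, by construction, no
  reconstructed split above the cut, and fitting such data with the
  stem-age term inflates $\hat r$ by 20--25% regardless of tree size.
  The exact marginal for sliced data only changes the geometric factor,
  $\beta(t_s)^{n-1} \to \beta(t_{\mathrm{cut}})^{n-1}$; passing
  `backbone_age = cut` selects it, and simulation-based tests that
  generate data with `collapse_to_backbone()` do so. The two forms
  coincide for richness-1 tips. Empirical backbones assembled from
  taxonomy should keep the default.

### Rate estimation

`fit_bd()` maximises the likelihood per rate class in
$(\log r, \operatorname{logit} \epsilon)$ space: a fixed $3\times3$
start grid ($r \in \{0.02, 0.1, 0.5\}$,
$\epsilon \in \{0.05, 0.5, 0.95\}$), Nelder--Mead from the best three
starts, then a BFGS polish, with box clamps at
$\log r \in [-16, 3]$ and $|\operatorname{logit}\epsilon| \le 35$.
There is no randomness anywhere in fitting: the same input yields
bitwise-identical output. Estimates effectively pinned against a limit
(e.g. $\hat\epsilon \to 0$ on pure-birth data, where the extinction
rate sits on its boundary) carry a `boundary` flag. On small trees the
profile in $\epsilon$ is notoriously flat and its maximum may sit at
$\epsilon \to 1$ with $r \to 0$ — a known ridge of the conditioned
birth--death likelihood, reported honestly rather than masked.

## The shift search

Every node except the root — including tips, so a shift confined to a
single unresolved clade is admissible — is a candidate shift point
(`candidate_shift_points()`, $2N-2$ candidates). An element of the tree
belongs to the rate class of the most recent shift node on its rootward
path (the shift node's own subtending edge included), else to the base
class. Because every likelihood term depends on exactly one class's
parameters, the likelihood is separable: refitting all classes at every
candidate evaluation (the convention adopted here, which avoids
order-of-addition artifacts) is implemented as per-class refits with
memoisation and is mathematically identical to a joint refit.

The forward phase (`step_forward()`) accepts the best-AIC candidate if
it undercuts the current AIC by at least the cutoff (default 4, a
common threshold for AIC significance); parameter counts follow
$k = 2 + 3 \times \text{shifts}$ — two rates for the base model, and
two rates plus one location per shift, so a one-shift model has 5
parameters. The backward phase (`step_backward()`) repeatedly removes
the shift whose removal costs the least AIC whenever that cost is below
the same cutoff — the symmetric-cutoff reading of backward elimination,
chosen so that a shift is kept if and only if keeping it is supported
at the same evidence threshold as adding it. AIC ties (within $10^{-9}$)
are broken toward the smallest postorder node rank, and trees are
canonicalised on input (children ordered by smallest descendant label),
so the whole search is deterministic and invariant to tip relabelling
and Newick rotation.

```{r search-demo}
bb <- collapse_to_backbone(
  simulate_tree(sim_config(b = 0.12, d = 0, duration = 35, seed = 7)),
  cut_age = 4)
run_search(bb$tree, bb$richness, cutoff = 4, backbone_age = 4)
```

```{r search-files, eval = FALSE}
# the same analysis from files, writing TSV/JSON reports and a manifest:
rep <- cmd_shift("tree.nwk", "richness.tsv", cutoff = 4, out = "results/")
```

## Expected richness given age

`estimate_r()` is the method-of-moments estimator of $r$ from a
standing richness and a clade age at an assumed $\epsilon$: for a stem
clade $\hat r t = \ln[n(1-\epsilon) + \epsilon]$, and for a crown clade
the closed form obtained by inverting the mean clade size conditioned
on clade survival, $E[N] = 2/[(1-\beta)(1+\alpha)]$ (the test suite
verifies this inversion to $10^{-6}$, and the $\epsilon = 0$ reductions
$\ln(n)/t$ and $\ln(n/2)/t$ to $10^{-9}$). With the bundled cichlid
inputs — $n = 16 + 15 + 1081 + 526 = 1638$ valid species, crown age 81
Ma — it gives $r = 0.0828$ per Myr at $\epsilon = 0$ and $r = 0.062$ at
$\epsilon = 0.9$:

```{r estimator}
estimate_r(1638, 81, eps = 0, mode = "crown")
estimate_r(1638, 81, eps = 0.9, mode = "crown")
```

`expected_richness()` and `confidence_bounds()` describe the clade-size
law of a *surviving* clade: geometric from a stem lineage, and the sum
of two survival-conditioned geometrics (a size-2 negative binomial)
from a crown pair, each root lineage conditioned on leaving
descendants. Bounds invert the integer CDF exactly — the lower bound is
the largest $n$ with $F(n-1) \le (1-\ell)/2$, the upper the smallest
$n$ with $F(n) \ge 1-(1-\ell)/2$ — rather than solving a continuous
relaxation; the difference from implementations that do is at most one
species, and the discrete inversion makes the interval conservative the
way any discrete equal-tailed interval is (empirical coverage in
simulation is 0.95 within Monte-Carlo error, a test the suite runs).
Note one asymmetry inherited from the source method: the crown
*estimator* inverts the clade-survival mean, while the *envelope* law
conditions on both root lineages surviving; at $\epsilon = 0$ the two
conditionings coincide.

`assess_clades()` classifies each clade at its mean age as `below`,
`within`, or `above` the envelope, re-classifies at both HPD endpoints
when an age interval is available, and flags the clade `ambiguous` when
the endpoint classifications disagree — so "unambiguously exceptional"
means outside the envelope across the whole credible age range.

```{r envelope}
fx <- suppressWarnings(cichlid_fixture())
r <- estimate_r(sum(fx$richness$n_species), 81, eps = 0, mode = "crown")
head(envelope_table(r, 0, "crown", t_max = 30), 4)
```

## The synthetic-data generators

`simulate_tree()` is a forward Gillespie simulation of the linear
birth--death process — crown-started (two lineages) by default to match
crown-age semantics, stem-started on request — pruned of extinct
lineages and rejection-resampled until at least two lineages survive.
Stopping is by duration or by a target tip count (in the latter case
the present is drawn uniformly inside the waiting interval after the
target is reached, keeping pendant edges positive). All randomness
derives from the single config seed and the caller's RNG state is
restored afterwards. Rate shifts are implanted by deterministically
selecting the oldest internal node in a requested age window (and clade
size range) and regrowing its subtree under the shifted rates as a
crown clade of exactly that age; regrown tips carry an `"s"` label
prefix so tests can identify the true shifted clade.
`collapse_to_backbone()` turns a resolved simulation into an
unresolved-clade dataset by cutting at a fixed age, conserving total
richness exactly. `simulate_clade_sizes()` is an independent
count-level Gillespie simulator used as the Monte-Carlo oracle for the
analytic kernels — the two generators cross-validate each other and the
closed forms in the test suite (total-variation distance below 0.01 at
$10^5$ replicates).

What the generators emulate is the *statistical* structure the analysis
assumes: constant rates within classes, complete and exact taxon
counts, error-free ultrametric node ages. Real chronograms violate all
three (rate heterogeneity beyond discrete shifts, taxonomic lumping,
calibration uncertainty), so passing simulation tests demonstrates
correctness of the machinery, not robustness of the biology.

## Study conditions used by the simulation tests

The test suite fixes these scenarios (chosen once, as conditions a
practitioner would call realistic for a family-level fish phylogeny):

* **Shift recovery**: base crown clade at $b = 0.05$, $d = 0$ grown for
  70 Myr (roughly 40--100 extant tips); one node aged 6--9 Ma regrown at
  $b = 0.4$; replicates conditioned on the shifted clade spanning at
  least 20 species; collapsed at 3 Ma. Over 100 replicates the first
  accepted shift falls inside the true clade in at least 90% and the
  final model has exactly one shift in at least 80%.
* **False-positive control**: 100 pure-birth trees ($b = 0.2$, 100
  tips, richness 1); a forward step at cutoff 4 accepts a shift in at
  most 10% of replicates. The cutoff is a selection heuristic, not a
  sized test, so this is an operating characteristic, not a guaranteed
  error rate.
* **Parameter recovery**: 100 trees at $b = 0.2$, $d = 0.1$ grown for
  45 Myr and collapsed at 5 Ma (about 100 backbone tips); the mean
  $\hat r$ is within 10% of the true $0.1$.
* **Envelope coverage**: $10^4$ crown clades at $r = 0.08$,
  $\epsilon = 0.5$, $t = 40$, conditioned on both root lineages
  surviving; the 95% bounds cover $0.95 \pm 0.01$ of them.

* **Kernel oracle**: the analytic clade-size law is compared with
  $10^5$ forward count-level simulations at four $(b, d, t)$
  combinations (supercritical, pure-birth, and critical $b = d$),
  requiring total-variation distance below 0.01. The grid points are
  chosen so that the Monte-Carlo noise floor of the empirical TV —
  approximately $\tfrac12\sqrt{2/(\pi n)}\sum_k \sqrt{p_k}$, which
  grows with the width of the distribution's support — stays near
  0.006 or less; at, say, $\beta = 0.95$ the floor itself would exceed
  the tolerance and the comparison would be uninformative at this
  sample size.

These sizes keep the full suite within a practical runtime while
leaving Monte-Carlo error well inside each tolerance.

## Numerical choices and degenerate inputs

* Ultrametricity is validated to a relative tolerance of $10^{-6}$ of
  the root age (relaxed-clock exports carry rounding noise); residual
  deviations are removed by snapping tips to age exactly zero, and
  anything worse is an error, never silently renormalised.
* Trees must be strictly binary and rooted with positive branch
  lengths; polytomies are rejected at read time.
* Optimisation tolerances: Nelder--Mead relative tolerance $10^{-10}$,
  BFGS polish $10^{-12}$, AIC comparisons at $10^{-9}$ slack.
* Degenerate classes (e.g. a shift on a single richness-1 tip) have a
  likelihood supremum on the boundary; they are fitted deterministically
  and flagged, and the AIC penalty makes them uncompetitive.
* `b = d` is handled by series limits in the kernels, not excluded.
* A clade table whose mean age falls outside its own HPD interval (one
  such row exists in the bundled cichlid data) is kept verbatim with a
  warning: published tables are treated as data, not corrected.

## Known limitations

* Rates are constant within classes: no time-varying or
  diversity-dependent models.
* Richness enters only through terminal unresolved clades; there is no
  general sampling-fraction mechanism.
* The stepwise search is greedy; it returns one model, not a posterior
  over shift configurations, and AIC-based selection with many
  correlated candidates has no guaranteed error rate.
* AICc is deliberately not used; parameter counts follow the
  $2 + 3k$ convention throughout.
* Exact reproduction of a published shift analysis requires the exact
  backbone node ages of the original chronogram; where those are not
  available the package's simulation-based checks stand in.
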