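test_that("alpha/beta kernels match closed forms and the simulation oracle", {
  p <- bd_params(0.1, 0)
  expect_equal(unname(bd_alpha_beta(0, p)[1, ]), c(0, 0))
  expect_equal(unname(bd_alpha_beta(10, p)[1, ]),
               c(0, 1 - exp(-1)), tolerance = 1e-12)

  # frozen Monte-Carlo oracle values (1e5 forward simulations of the
  # linear birth-death process at b = 0.2, d = 0.1, t = 10)
  ab <- bd_alpha_beta(10, bd_params(0.2, 0.1))
  expect_equal(unname(ab[1, "alpha"]), 0.3873, tolerance = 2e-4)
  expect_equal(unname(ab[1, "beta"]), 0.7746, tolerance = 2e-4)
  x <- simulate_clade_sizes(2e4, 0.2, 0.1, 10, mode = "stem", seed = 7)
  expect_equal(mean(x == 0), unname(ab[1, "alpha"]), tolerance = 0.012)

  # critical case b = d uses the series limit
  abc <- bd_alpha_beta(5, bd_params(0.2, 0.2))
  expect_equal(unname(abc[1, "alpha"]), 1 / 2)
  expect_equal(unname(abc[1, "beta"]), 1 / 2)

  # strictly increasing in t, within [0, 1)
  tt <- seq(0, 50, by = 0.5)
  ab <- bd_alpha_beta(tt, bd_params(0.3, 0.25))
  expect_true(all(diff(ab[, "alpha"]) > 0))
  expect_true(all(diff(ab[, "beta"]) > 0))
  expect_true(all(ab >= 0 & ab < 1))
  expect_error(bd_alpha_beta(-1, p), "negative t")
})

test_that("clade-size law is a proper distribution matching the simulator", {
  p <- bd_params(0.2, 0.1)
  # pure birth: P(1) = exp(-b t)
  expect_equal(prob_richness(1, 10, bd_params(0.1, 0)), exp(-1),
               tolerance = 1e-12)
  # geometric tail: sum over n >= 1 equals 1 - alpha, total mass 1
  a <- bd_alpha_beta(10, p)[1, "alpha"]
  expect_equal(sum(prob_richness(1:5000, 10, p)), unname(1 - a),
               tolerance = 1e-10)
  expect_equal(sum(prob_richness(0:5000, 10, p)), 1, tolerance = 1e-10)
  expect_equal(sum(prob_richness(1:5000, 10, p, conditional = TRUE)), 1,
               tolerance = 1e-10)

  # total-variation distance to the forward-simulation oracle
  x <- simulate_clade_sizes(2e4, 0.2, 0.1, 10, mode = "stem", seed = 11)
  nmax <- max(x)
  emp <- tabulate(x + 1L, nbins = nmax + 1L) / length(x)
  thr <- prob_richness(0:nmax, 10, p)
  tv <- 0.5 * sum(abs(emp - thr)) + 0.5 * (1 - sum(thr))
  expect_lt(tv, 0.015)
})

test_that("resolved-tree likelihood matches an independent evaluation", {
  # Yule, x = (2, 1), b = 0.5: term-by-term oracle of the displayed formula
  x <- c(2, 1)
  b <- 0.5
  N <- 3
  oracle <- lfactorial(N - 1) + (N - 2) * log(b) + b * sum(x[-1]) +
    N * log(1 - 0) - 2 * sum(log(exp(b * x) - 0))
  expect_equal(loglik_resolved(x, bd_params(b, 0)), oracle, tolerance = 1e-12)

  # general rates, independent naive evaluation without the stable forms
  p <- bd_params(0.23, 0.11)
  a <- p$eps
  r <- p$r
  x <- c(7.2, 5.5, 3.1, 1.4)
  N <- 5
  naive <- lfactorial(N - 1) + (N - 2) * log(r) + r * sum(x[-1]) +
    N * log(1 - a) - 2 * sum(log(exp(r * x) - a))
  expect_equal(loglik_resolved(x, p), naive, tolerance = 1e-10)

  # permutation invariance and admissible-region signalling
  expect_identical(loglik_resolved(x, p), loglik_resolved(rev(x), p))
  expect_identical(loglik_resolved(x, bd_params(0.1, 0.2)), -Inf)
  expect_error(loglik_resolved(2, p), "at least 2")

  # finite on simulated trees (with at least 3 surviving tips)
  for (i in 1:20) {
    tr <- simulate_tree(sim_config(b = 0.2, d = 0.1, duration = 25,
                                   seed = 400 + i))
    if (length(tr$tip.label) < 3L) next
    expect_true(is.finite(loglik_resolved(branching_ages(tr),
                                          bd_params(0.2, 0.1))))
  }
})

test_that("combined likelihood reduces to the resolved form and handles richness", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  p <- bd_params(0.2, 0.1)
  # all richness 1, single class: exact joint density equals the Nee form
  expect_equal(loglik_combined(tr, NULL, p),
               loglik_resolved(c(2, 1), p), tolerance = 1e-12)
  # the per-tip conditioning variant differs by the tip survival constants
  a_tip <- bd_alpha_beta(c(1, 1, 2), p)[, "alpha"]
  expect_equal(loglik_combined(tr, NULL, p, condition = "root+tips"),
               loglik_resolved(c(2, 1), p) - sum(log(1 - a_tip)),
               tolerance = 1e-12)
  # a richness-n tip multiplies in beta(stem age)^(n-1)
  rich <- data.frame(tip = c("A", "B", "C"), n_species = c(4L, 1L, 1L))
  be <- unname(bd_alpha_beta(1, p)[1, "beta"])
  expect_equal(loglik_combined(tr, rich, p),
               loglik_combined(tr, NULL, p) + 3 * log(be), tolerance = 1e-12)
  # pure birth, single tip clade of richness 1 at stem age t: term exp(-b t)
  pb <- bd_params(0.25, 0)
  expect_equal(loglik_combined(tr, NULL, pb),
               loglik_resolved(c(2, 1), pb), tolerance = 1e-12)
  # relabelling tips leaves the likelihood unchanged
  tr2 <- tr
  tr2$tip.label <- c("X", "Y", "Z")[match(tr$tip.label, c("A", "B", "C"))]
  rich2 <- transform(rich, tip = c("X", "Y", "Z")[match(rich$tip, c("A", "B", "C"))])
  expect_equal(loglik_combined(as_chronogram(tr2), rich2, p),
               loglik_combined(tr, rich, p), tolerance = 1e-12)
  expect_error(loglik_combined(tr, rich[1:2, ], p), "missing")
})

test_that("fit_bd is deterministic, flags boundaries, and respects nesting", {
  tr <- simulate_tree(sim_config(b = 0.25, d = 0.05, duration = 25, seed = 42))
  f1 <- fit_bd(tr)
  f2 <- fit_bd(tr)
  expect_identical(f1, f2)
  expect_identical(f1$k, 2L)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$lnL, tolerance = 1e-9)

  # pure-birth data: extinction estimate pinned at the boundary, flagged
  yule <- simulate_tree(sim_config(b = 0.3, d = 0, n_tips = 120, seed = 2))
  fy <- fit_bd(yule)
  expect_lt(fy$class_fits[[1]]$eps, 1e-4)
  expect_true(fy$class_fits[[1]]$boundary)

  # adding a rate class at the ML never lowers the likelihood
  cand <- candidate_shift_points(tr)
  deep <- cand[cand > length(tr$tip.label)][1]
  f_shift <- fit_bd(tr, shifts = deep)
  expect_gte(f_shift$lnL, f1$lnL - 1e-6)
  expect_identical(f_shift$k, 5L)
})

test_that("fitted rates recover the truth on simulated data", {
  # resolved Yule trees: ML b-hat close to the generating rate
  bs <- vapply(1:40, function(i) {
    tr <- simulate_tree(sim_config(b = 0.3, d = 0, n_tips = 200,
                                   seed = 2000 + i))
    fit_bd(tr)$class_fits[[1]]$b
  }, 0)
  expect_equal(mean(bs), 0.3, tolerance = 0.1)

  # backbone + richness: r-hat bias shrinks as the backbone grows
  rhat <- function(dur, n, seed0) {
    vapply(seq_len(n), function(i) {
      tr <- simulate_tree(sim_config(b = 0.2, d = 0.1, duration = dur,
                                     seed = seed0 + i))
      bb <- collapse_to_backbone(tr, 5)
      fit_bd(bb$tree, bb$richness, backbone_age = 5)$class_fits[[1]]$r
    }, 0)
  }
  small <- rhat(38, 15, 7000)   # ~50-tip backbones
  large <- rhat(45, 15, 8000)   # ~100-tip backbones
  expect_lt(abs(mean(large) - 0.1), abs(mean(small) - 0.1) + 0.02)
  expect_equal(mean(large), 0.1, tolerance = 0.2)
})
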