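test_that("net-diversification estimators match closed forms", {
  # family-wide cichlid rates: n = 16 + 15 + 1081 + 526 species, crown 81 Ma
  expect_lt(abs(estimate_r(1638, 81, 0, "crown") - 0.0828), 5e-5)
  expect_lt(abs(estimate_r(1638, 81, 0.9, "crown") - 0.062), 5e-4)

  # eps = 0 reductions
  expect_equal(estimate_r(100, 20, 0, "stem"), log(100) / 20, tolerance = 1e-12)
  expect_equal(estimate_r(100, 20, 0, "crown"), log(50) / 20, tolerance = 1e-12)
  expect_equal(estimate_r(2, 37, 0, "crown"), 0, tolerance = 1e-12)
  expect_error(estimate_r(1, 10, 0, "crown"), "n >= 2")
  expect_error(estimate_r(10, 0, 0, "stem"))
})

test_that("estimator and expected richness are mutual inverses", {
  # at eps = 0, both directions, crown and stem, to 1e-9
  for (n in c(10, 250, 1638)) {
    for (t in c(23, 81)) {
      rc <- estimate_r(n, t, 0, "crown")
      expect_equal(expected_richness(t, rc, 0, "crown"), n, tolerance = 1e-9)
      rs <- estimate_r(n, t, 0, "stem")
      expect_equal(expected_richness(t, rs, 0, "stem"), n, tolerance = 1e-9)
    }
  }
  # stem inversion is exact at any eps; crown-with-extinction inverts the
  # clade-survival mean 2 / ((1 - beta)(1 + alpha))
  rs <- estimate_r(500, 40, 0.7, "stem")
  expect_equal(expected_richness(40, rs, 0.7, "stem"), 500, tolerance = 1e-6)
  rc <- estimate_r(1638, 81, 0.9, "crown")
  ab <- bd_alpha_beta(81, bd_params_rel(rc, 0.9))
  expect_equal(unname(2 / ((1 - ab[1, "beta"]) * (1 + ab[1, "alpha"]))), 1638,
               tolerance = 1e-6)
})

test_that("expected richness behaves like a conditioned clade-size mean", {
  expect_equal(expected_richness(0, 0.1, 0, "crown"), 2)
  expect_equal(expected_richness(0, 0.1, 0, "stem"), 1)
  expect_equal(expected_richness(log(819) / 0.0828, 0.0828, 0, "crown"),
               1638, tolerance = 1e-6)
  tt <- seq(0, 80, by = 1)
  en <- expected_richness(tt, 0.08, 0.41, "crown")
  expect_true(all(diff(en) > 0))
  # Monte-Carlo conditional mean of surviving crown clades
  x <- simulate_clade_sizes(4000, b = 0.2, d = 0.1, t = 30, mode = "crown",
                            condition_survival = TRUE, seed = 21)
  expect_equal(mean(x), expected_richness(30, 0.1, 0.5, "crown"),
               tolerance = 0.05)
})

test_that("confidence bounds invert the integer clade-size CDF exactly", {
  expect_equal(unname(confidence_bounds(0, 0.1, 0, "crown")[1, ]), c(2, 2))
  expect_equal(unname(confidence_bounds(0, 0.1, 0, "stem")[1, ]), c(1, 1))

  # brute-force pmf check (crown law: (n-1)(1-beta)^2 beta^(n-2))
  r <- 0.0828
  eps <- 0.41
  t <- 30
  be <- unname(bd_alpha_beta(t, bd_params_rel(r, eps))[1, "beta"])
  n <- 2:20000
  pmf <- (n - 1) * (1 - be)^2 * be^(n - 2)
  cdf <- cumsum(pmf)
  b <- confidence_bounds(t, r, eps, "crown")
  lo <- b[1, "lower"]
  up <- b[1, "upper"]
  expect_lte(if (lo > 2) cdf[lo - 1 - 1] else 0, 0.025)
  expect_gt(cdf[lo - 1], 0.025)
  expect_gte(cdf[up - 1], 0.975)
  expect_lt(cdf[up - 2], 0.975)
  expect_equal(cdf[2 - 1], (1 - be)^2, tolerance = 1e-12)
  # stem law: geometric
  bs <- confidence_bounds(t, r, eps, "stem")
  bes <- be
  expect_lte(bs[1, "lower"], bs[1, "upper"])

  # bounds widen with t and with eps at fixed r*t
  tt <- seq(1, 100, by = 1)
  bb <- confidence_bounds(tt, 0.0828, 0, "crown")
  expect_true(all(diff(bb[, "upper"]) >= 0))
  expect_true(all(diff(bb[, "lower"]) >= 0))
  w0 <- diff(confidence_bounds(40, 0.1, 0, "crown")[1, ])
  w9 <- diff(confidence_bounds(80, 0.05, 0.9, "crown")[1, ])  # same r*t
  expect_gt(w9, w0)
})

test_that("envelope coverage matches its nominal level in simulation", {
  x <- simulate_clade_sizes(3000, b = 0.16, d = 0.08, t = 40, mode = "crown",
                            condition_survival = TRUE, seed = 33)
  b <- confidence_bounds(40, 0.08, 0.5, "crown")
  cov <- mean(x >= b[1, "lower"] & x <= b[1, "upper"])
  expect_equal(cov, 0.95, tolerance = 0.02)
})

test_that("envelope tables carry bounds, means, and generating parameters", {
  env <- envelope_table(0.0828, 0, "crown", t_max = 100, step = 1)
  expect_identical(nrow(env), 101L)
  expect_equal(env$t[1], 0)
  expect_equal(unname(unlist(env[1, c("lower", "expected", "upper")])),
               c(2, 2, 2))
  expect_true(all(env$lower <= env$expected & env$expected <= env$upper))
  expect_true(all(diff(env$upper) >= 0))
  ps <- attr(env, "params")
  expect_equal(ps$r, 0.0828)
  expect_identical(ps$mode, "crown")

  pr <- envelope_presets()
  expect_equal(pr$low, list(r = 0.0828, eps = 0))
  expect_equal(pr$high, list(r = 0.062, eps = 0.9))
  expect_equal(pr$background, list(r = 0.069, eps = 0.41))
})

test_that("clades are classified against the envelope with HPD ambiguity", {
  r <- 0.0828
  # build deterministic cases straight from the bounds
  b23 <- confidence_bounds(23, r, 0, "crown")
  clades <- data.frame(
    name = c("rich", "poor", "typical", "straddle", "noHPD"),
    age = c(23, 60, 40, 23, 30),
    age_lo = c(17, 48, 31, 17, NA),
    age_hi = c(31, 72, 49, 31, NA),
    richness = NA_integer_,
    mode = "crown", stringsAsFactors = FALSE)
  b60 <- confidence_bounds(60, r, 0, "crown")
  b40 <- confidence_bounds(40, r, 0, "crown")
  b17 <- confidence_bounds(17, r, 0, "crown")
  b31 <- confidence_bounds(31, r, 0, "crown")
  clades$richness <- c(b31[1, "upper"] + 1L,          # above across whole HPD
                       max(2L, b60[1, "lower"] - 1L), # below at mean age
                       round(expected_richness(40, r, 0, "crown")),
                       b31[1, "upper"],               # above at 17, within at 31
                       10L)
  out <- assess_clades(clades, r, eps = 0, level = 0.95)
  expect_identical(out$class[out$name == "rich"], "above")
  expect_false(out$ambiguous[out$name == "rich"])
  expect_identical(out$class[out$name == "poor"], "below")
  expect_identical(out$class[out$name == "typical"], "within")
  expect_true(out$ambiguous[out$name == "straddle"])
  expect_false(out$ambiguous[out$name == "noHPD"])

  # records without richness are skipped with a warning
  clades$richness[2] <- NA_integer_
  expect_warning(out2 <- assess_clades(clades, r, 0), "poor")
  expect_identical(nrow(out2), 4L)

  # a clade simulated with a much faster rate classifies above
  x <- simulate_clade_sizes(60, b = 3 * r, d = 0, t = 40, mode = "crown",
                            condition_survival = TRUE, seed = 5)
  cl <- data.frame(name = paste0("c", seq_along(x)), age = 40,
                   age_lo = NA_real_, age_hi = NA_real_,
                   richness = x, mode = "crown", stringsAsFactors = FALSE)
  res <- assess_clades(cl, r, 0)
  expect_gt(mean(res$class == "above"), 0.5)
})
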