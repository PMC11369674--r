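test_that("the Wald ratio follows its closed form", {
  w <- mr_wald_ratio(0.5, 0.25, 0.1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(mr_wald_ratio(0.5, 0, 0.1)$beta, 0)
  expect_equal(mr_wald_ratio(-0.5, -0.25, 0.1)$beta, 0.5)
  expect_error(mr_wald_ratio(0, 0.1, 0.1), "degenerate")
})

test_that("IVW is exact under a shared ratio and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.4)
  pair <- mrmediate:::pair_from_vectors(bx, rep(0.01, 3), 0.3 * bx,
                                        c(0.01, 0.02, 0.015))
  fit <- mr_ivw(pair, model = "fixed")
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$Q, 0, tolerance = 1e-20)
  expect_equal(fit$Q_pvalue, 1)

  for (seed in 1:6) {
    f <- random_fixture(seed)
    est <- mr_ivw(fixture_pair(f), model = "fixed")
    orc <- oracle_ivw(f$bx, f$by, f$sy)
    expect_equal(est$beta, orc$beta, tolerance = 1e-12)
    expect_equal(est$se, orc$se_fixed, tolerance = 1e-12)
    expect_equal(est$Q, orc$q, tolerance = 1e-10)
    # closed meta-analytic form equals the regression formulation
    expect_equal(est$beta,
                 sum(f$by * f$bx / f$sy^2) / sum(f$bx^2 / f$sy^2),
                 tolerance = 1e-14)
  }
})

test_that("duplicating every variant leaves the fixed IVW estimate unchanged", {
  f <- random_fixture(3)
  p1 <- fixture_pair(f)
  p2 <- mrmediate:::pair_from_vectors(rep(f$bx, 2), rep(f$sx, 2),
                                      rep(f$by, 2), rep(f$sy, 2))
  expect_equal(mr_ivw(p2, model = "fixed")$beta,
               mr_ivw(p1, model = "fixed")$beta, tolerance = 1e-14)
})

test_that("the random-effects model never reports less than the nominal SE", {
  for (seed in 1:5) {
    f <- random_fixture(seed, n = 10)
    fixed <- mr_ivw(fixture_pair(f), model = "fixed")
    rand <- mr_ivw(fixture_pair(f), model = "random_multiplicative")
    expect_equal(rand$beta, fixed$beta)
    expect_gte(rand$se, fixed$se)
    expect_equal(rand$se, fixed$se * sqrt(max(1, fixed$Q / fixed$Q_df)),
                 tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact affine structure", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  pair <- mrmediate:::pair_from_vectors(bx, rep(0.01, 4), 0.1 + 0.3 * bx,
                                        rep(0.02, 4))
  eg <- mr_egger(pair)
  expect_equal(eg$intercept$beta, 0.1, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)

  pair0 <- mrmediate:::pair_from_vectors(bx, rep(0.01, 4), 0.3 * bx,
                                         rep(0.02, 4))
  expect_equal(mr_egger(pair0)$intercept$beta, 0, tolerance = 1e-12)
  expect_error(mr_egger(mrmediate:::pair_from_vectors(bx[1:2], rep(0.01, 2),
                                                      bx[1:2], rep(0.01, 2))),
               "at least 3")
})

test_that("MR-Egger matches the weighted-regression oracle on noisy fixtures", {
  for (seed in 1:6) {
    f <- random_fixture(seed, n = 9)
    eg <- mr_egger(fixture_pair(f))
    orc <- oracle_egger(f$bx, f$by, f$sy)
    expect_equal(eg$slope$beta, orc$slope, tolerance = 1e-12)
    expect_equal(eg$intercept$beta, orc$intercept, tolerance = 1e-12)
    expect_equal(eg$slope$se, orc$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$se, orc$se_intercept, tolerance = 1e-10)
  }
})

test_that("constant directional pleiotropy lands in the Egger intercept", {
  bx <- c(0.12, 0.2, 0.33, 0.41, 0.5)
  by <- 0.25 * bx
  delta <- 0.07
  p0 <- mrmediate:::pair_from_vectors(bx, rep(0.01, 5), by, rep(0.02, 5))
  p1 <- mrmediate:::pair_from_vectors(bx, rep(0.01, 5), by + delta,
                                      rep(0.02, 5))
  e0 <- mr_egger(p0); e1 <- mr_egger(p1)
  expect_equal(e1$intercept$beta, e0$intercept$beta + delta, tolerance = 1e-12)
  expect_equal(e1$slope$beta, e0$slope$beta, tolerance = 1e-12)
})

test_that("median estimators reproduce textbook cases", {
  # plain median with equal weights
  bx <- rep(1, 3)
  p <- mrmediate:::pair_from_vectors(bx, rep(0.01, 3), c(1, 2, 9),
                                     rep(0.1, 3))
  expect_equal(mr_weighted_median(p, n_boot = 100, seed = 1)$beta, 2)
  p2 <- mrmediate:::pair_from_vectors(rep(1, 3), rep(0.01, 3), c(3, 1, 2),
                                      rep(0.1, 3))
  expect_equal(mr_simple_median(p2, n_boot = 100, seed = 1)$beta, 2)
  # even count: midpoint convention (4 variants, two ratio groups)
  p3 <- mrmediate:::pair_from_vectors(rep(1, 4), rep(0.01, 4), c(1, 1, 3, 3),
                                      rep(0.1, 4))
  expect_equal(mr_simple_median(p3, n_boot = 100, seed = 1)$beta, 2)
})

test_that("weighted median matches the cumulative-weight oracle", {
  for (seed in 1:6) {
    f <- random_fixture(seed, n = 5)
    est <- mr_weighted_median(fixture_pair(f), n_boot = 100, seed = 2)
    orc <- oracle_weighted_median(f$by / f$bx, f$bx^2 / f$sy^2)
    expect_equal(est$beta, orc, tolerance = 1e-12)
    sm <- mr_simple_median(fixture_pair(f), n_boot = 100, seed = 2)
    expect_equal(sm$beta, oracle_weighted_median(f$by / f$bx, rep(1, 5)),
                 tolerance = 1e-12)
  }
})

test_that("equal weights make the weighted and simple medians coincide", {
  bx <- rep(0.2, 5)
  by <- c(0.02, 0.05, 0.04, 0.09, 0.01)
  p <- mrmediate:::pair_from_vectors(bx, rep(0.01, 5), by, rep(0.02, 5))
  expect_equal(mr_weighted_median(p, n_boot = 100, seed = 5)$beta,
               mr_simple_median(p, n_boot = 100, seed = 5)$beta)
})

test_that("bootstrap SEs are seed-reproducible and shrink with input SEs", {
  f <- random_fixture(8)
  p <- fixture_pair(f)
  a <- mr_weighted_median(p, n_boot = 200, seed = 42)
  b <- mr_weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(p, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c_$se))

  # consistency: identical ratios, vanishing SEs -> estimate r, SE -> 0
  bx <- c(0.1, 0.2, 0.3)
  tiny <- mrmediate:::pair_from_vectors(bx, rep(1e-8, 3), 0.4 * bx,
                                        rep(1e-8, 3))
  est <- mr_weighted_median(tiny, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.4, tolerance = 1e-6)
  expect_lt(est$se, 1e-5)
})

test_that("all estimators are invariant to per-variant allele recoding", {
  f <- random_fixture(12, n = 7)
  p1 <- fixture_pair(f)
  flip <- rep(c(-1, 1), length.out = 7)
  p2 <- mrmediate:::pair_from_vectors(f$bx * flip, f$sx, f$by * flip, f$sy)
  expect_equal(mr_ivw(p2, model = "fixed")$beta,
               mr_ivw(p1, model = "fixed")$beta, tolerance = 1e-12)
  expect_equal(mr_egger(p2)$slope$beta, mr_egger(p1)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(p2)$intercept$beta, mr_egger(p1)$intercept$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(p2, n_boot = 100, seed = 3)$beta,
               mr_weighted_median(p1, n_boot = 100, seed = 3)$beta,
               tolerance = 1e-12)
  expect_equal(mr_simple_median(p2, n_boot = 100, seed = 3)$beta,
               mr_simple_median(p1, n_boot = 100, seed = 3)$beta,
               tolerance = 1e-12)
})

test_that("estimates report odds ratios consistent with their betas", {
  f <- random_fixture(2)
  fit <- mr_fit(fixture_pair(f), seed = 6, n_boot = 100)
  for (est in fit$estimates) {
    expect_equal(est$or, exp(est$beta))
    expect_equal(est$ci_low, exp(est$beta - 1.96 * est$se))
    expect_equal(est$ci_high, exp(est$beta + 1.96 * est$se))
    expect_true(est$pvalue > 0 && est$pvalue <= 1)
  }
  tab <- as.data.frame(fit)
  expect_true(all(c("exposure", "outcome", "method", "n_snp", "beta", "se",
                    "pvalue", "or", "ci_low", "ci_high") %in% names(tab)))
})

test_that("a single instrument delegates to the Wald ratio", {
  p <- mrmediate:::pair_from_vectors(0.5, 0.01, 0.25, 0.1)
  fit <- mr_fit(p)
  expect_named(fit$estimates, "wald")
  expect_equal(fit$estimates$wald$beta, 0.5)
})
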