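test_that("survival aggregation: means, SEM, order invariance", {
  recs <- structure(data.frame(
    animal_id = c("a1", "a2"), arm = "control", eye = "e1",
    age_pn = 30, position_deg = 10, cones_per_100um = c(2, 4)),
    class = c("cone_counts", "data.frame"))
  s <- aggregate_survival(recs)
  expect_equal(s$mean_density, 3)
  expect_equal(s$sem, 1)  # sd(c(2,4))/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(s$n, 2)

  one <- recs[1, ]
  expect_warning(s1 <- aggregate_survival(one), "SEM")
  expect_equal(s1$sem, 0)

  shuffled <- recs[2:1, ]
  expect_equal(aggregate_survival(shuffled), s)
  expect_error(aggregate_survival(recs[0, ]), "nonempty")
})

test_that("decay fitting recovers closed-form intercepts and flags degenerate fits", {
  ages <- c(26, 30, 37, 45, 60, 90)
  noiseless <- simulate_survival(list(decay_model(5.541, 0.05832)), ages,
                                 n_eyes = 2, seed = 1)
  fit <- fit_decay(aggregate_survival(noiseless), "control")
  expect_equal(fit$a, 5.541, tolerance = 1e-10)
  expect_equal(fit$b, 0.05832, tolerance = 1e-10)
  expect_equal(fit$x_intercept, 5.541 / 0.05832, tolerance = 1e-10)  # 95.01
  expect_equal(fit$r2, 1)
  # threshold shifts the intercept: (a - log2 theta) / b
  fit2 <- fit_decay(aggregate_survival(noiseless), "control", theta = 2)
  expect_equal(fit2$x_intercept, (5.541 - 1) / 0.05832, tolerance = 1e-10)

  flat <- simulate_survival(list(decay_model(4, 0)), ages, n_eyes = 1, seed = 2)
  ffit <- fit_decay(aggregate_survival(flat), "control")
  expect_false(ffit$intercept_defined)
  expect_true(is.na(ffit$x_intercept))
  expect_error(intercept_delay(ffit, fit), "defined")

  single <- simulate_survival(list(decay_model(4, 0.1)), 30, n_eyes = 3, seed = 3)
  expect_error(fit_decay(aggregate_survival(single), "control"), "2 distinct ages")
})

test_that("intercept delay: symmetry and the treated-vs-control subtraction", {
  ages <- c(26, 30, 37, 45, 60, 90)
  mk <- function(a) fit_decay(aggregate_survival(
    simulate_survival(list(decay_model(a, 0.05832)), ages, n_eyes = 1,
                      seed = 1)), "control")
  fc <- mk(5.541)  # intercept 95.01
  ft <- mk(4.606)  # intercept 78.98
  expect_equal(intercept_delay(fc, fc), 0)
  d <- intercept_delay(fc, ft)
  expect_equal(round(d), 16)
  expect_equal(d, (5.541 - 4.606) / 0.05832, tolerance = 1e-10)
  expect_equal(intercept_delay(ft, fc), d)  # absolute value symmetric
  expect_equal(intercept_delay(fc, ft, signed = TRUE), -d)
})

test_that("x-intercept is equivariant under time translation", {
  ages <- c(26, 30, 37, 45, 60, 90)
  recs <- simulate_survival(list(decay_model(5, 0.05, 0.1)), ages,
                            n_eyes = 4, seed = 7)
  f0 <- fit_decay(aggregate_survival(recs), "control")
  shifted <- recs
  shifted$age_pn <- shifted$age_pn + 10
  f1 <- fit_decay(aggregate_survival(shifted), "control")
  expect_equal(f1$x_intercept, f0$x_intercept + 10, tolerance = 1e-8)
})

test_that("fitted decay parameters recover generator values under noise", {
  ages <- c(26, 30, 37, 45, 60, 90)
  ok <- vapply(1:200, function(i) {
    recs <- simulate_survival(list(decay_model(5.541, 0.05832, 0.1)), ages,
                              n_eyes = 6, seed = i)
    f <- fit_decay(aggregate_survival(recs), "control")
    abs(f$a - 5.541) / 5.541 < 0.05 && abs(f$b - 0.05832) / 0.05832 < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("per-animal survival ratios: pairing, averaging, undefined control", {
  recs <- structure(data.frame(
    animal_id = rep(c("m1", "m2"), each = 4),
    arm = rep(c("treated", "treated", "control", "control"), 2),
    eye = rep(c("R", "R", "L", "L"), 2),
    age_pn = 30,
    position_deg = rep(c(-10, 10), 4),
    cones_per_100um = c(4, 4, 2, 2,   6, 6, 6, 6)),
    class = c("cone_counts", "data.frame"))
  sr <- survival_ratio(recs)
  expect_equal(sr$log2_ratio[sr$animal_id == "m1"], 1)   # log2(4/2)
  expect_equal(sr$log2_ratio[sr$animal_id == "m2"], 0)   # treated = control

  zero <- recs
  zero$cones_per_100um[zero$arm == "control" & zero$animal_id == "m1"] <- 0
  expect_warning(srz <- survival_ratio(zero), "zero control")
  expect_true(is.na(srz$log2_ratio[srz$animal_id == "m1"]))
})

test_that("Hedges' g: hand-computed value, antisymmetry, degenerate groups", {
  expect_equal(hedges_g(c(1, 2, 3), c(3, 4, 5)), 1.6, tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hedges_g(c(3, 4, 5), c(1, 2, 3)), -1.6, tolerance = 1e-12)
  expect_equal(hedges_g(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_warning(g_inf <- hedges_g(c(2, 2), c(3, 3)), "infinite")
  expect_identical(g_inf, Inf)
})

test_that("shared-control estimation: nulls, determinism, CI sanity", {
  ctrl <- withr::with_seed(61, rnorm(12))
  res <- shared_control_estimation(ctrl, list(same = ctrl, shift = ctrl + 3),
                                   n_boot = 500, n_perm = 199, seed = 5)
  same <- res[res$comparison == "same", ]
  expect_equal(same$hedges_g, 0)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)
  expect_gt(same$p_perm, 0.5)
  shift <- res[res$comparison == "shift", ]
  expect_gt(shift$hedges_g, 2)
  expect_true(shift$ci_low <= shift$hedges_g && shift$hedges_g <= shift$ci_high)
  expect_lt(shift$p_perm, 0.05)
  # +1-smoothed permutation p never reaches 0
  expect_gte(shift$p_perm, 1 / 200)

  rerun <- shared_control_estimation(ctrl, list(same = ctrl, shift = ctrl + 3),
                                     n_boot = 500, n_perm = 199, seed = 5)
  expect_identical(res, rerun)
  # per-group substreams: dropping one group leaves the other unchanged
  solo <- shared_control_estimation(ctrl, list(same = ctrl),
                                    n_boot = 500, n_perm = 199, seed = 5)
  expect_equal(solo$ci_low, res$ci_low[res$comparison == "same"])
})

test_that("shared-control estimation recovers the population effect size", {
  # N(0,1) vs N(1,1), n = 20: population Hedges-corrected value ~ 0.98
  gs <- vapply(1:200, function(i) {
    withr::with_seed(1000 + i, {
      a <- rnorm(20)
      b <- rnorm(20, 1)
    })
    hedges_g(a, b)
  }, numeric(1))
  expect_lt(abs(mean(gs) - 0.98), 0.1)
})

test_that("permutation p values are uniform under the null", {
  ps <- vapply(1:1000, function(i) {
    withr::with_seed(3000 + i, {
      a <- rnorm(10)
      b <- rnorm(10)
    })
    res <- shared_control_estimation(a, list(g = b), n_boot = 2,
                                     n_perm = 199, seed = i)
    res$p_perm
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
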