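test_that("generation is deterministic in the seed", {
  cfg <- make_preset("interaction_demo")
  t1 <- generate(cfg)
  t2 <- generate(cfg)
  expect_identical(t1$records, t2$records)
  t3 <- generate(cfg, seed = 999)
  expect_false(identical(t1$records, t3$records))
})

test_that("factor and interaction specs are centered", {
  fs <- factor_spec("f", c(0.2, 0.8), c(-2, 1))
  expect_equal(sum(fs$p * fs$effects), 0, tolerance = 1e-12)

  fa <- factor_spec("a", c(0.3, 0.7), c(1, -1))
  fb <- factor_spec("b", c(0.5, 0.25, 0.25), c(0, 1, -1))
  is_ <- interaction_spec(fa, fb, matrix(rnorm(6), 2, 3))
  expect_equal(as.numeric(fa$p %*% is_$cross), rep(0, 3), tolerance = 1e-12)
  expect_equal(as.numeric(is_$cross %*% fb$p), rep(0, 2), tolerance = 1e-12)
})

test_that("expected_q gives the planted variance share", {
  expect_equal(expected_q(factor_spec("f", c(0.5, 0.5), c(-1, 1)), 1), 0.5)
  expect_equal(expected_q(factor_spec("f", c(0.5, 0.5), 0), 1), 0)

  # Monte-Carlo oracle for an asymmetric spec
  fs <- factor_spec("f", c(0.2, 0.8), c(-2, 0.5))
  target <- expected_q(fs, 1)
  cfg <- synth_config(200000, seed = 77, factors = list(fs),
                      noise = noise_gaussian(1), base_mean = 50)
  tab <- generate(cfg)
  qhat <- compute_q(tab$records$injuries, stratify(tab, "f"))$q
  expect_equal(qhat, target, tolerance = 0.01)
})

test_that("moment matching hits feasible targets and rejects infeasible ones", {
  p <- fit_discrete_moments(0:4, 1.2, 0.9)
  s <- 0:4
  expect_equal(sum(p * s), 1.2, tolerance = 1e-6)
  expect_equal(sqrt(sum(p * s^2) - 1.2^2), 0.9, tolerance = 1e-5)
  expect_true(all(p > 0))

  expect_error(fit_discrete_moments(0:2, 0.48, 0.301), "infeasible")
  expect_error(fit_discrete_moments(0:2, 5, 1), "outside the open support")
  # two-point support: variance is determined by the mean
  expect_equal(fit_discrete_moments(c(1, 2), 1.25,
                                    sqrt(0.25 * 0.75)), c(0.75, 0.25),
               tolerance = 1e-9)
  expect_error(fit_discrete_moments(c(1, 2), 1.25, 0.9), "two-point")
})

test_that("a zero-effect configuration plants no heterogeneity", {
  fs <- factor_spec("f", rep(1, 4), 0)
  cfg <- synth_config(2000, seed = 31, factors = list(fs),
                      noise = noise_gaussian(1), base_mean = 10)
  tab <- generate(cfg)
  qr <- compute_q(tab$records$injuries, stratify(tab, "f"))
  expect_lt(qr$q, 0.01)
})

test_that("gaussian outcomes are truncated at zero, poisson are integer", {
  fs <- factor_spec("f", c(0.5, 0.5), c(-1, 1))
  tg <- generate(synth_config(500, seed = 2, factors = list(fs),
                              noise = noise_gaussian(3), base_mean = 0.5))
  expect_true(all(tg$records$injuries >= 0))
  expect_true(any(tg$records$injuries == 0))

  tp <- generate(synth_config(500, seed = 2, factors = list(fs),
                              noise = noise_poisson(), base_mean = 2))
  expect_true(all(tp$records$injuries == round(tp$records$injuries)))
  expect_equal(mean(tp$records$injuries), 2, tolerance = 0.2)
})

test_that("the calibration preset reproduces the published structure", {
  cfg <- make_preset("shenzhen_like")
  tab <- generate(cfg)
  expect_equal(nrow(tab$records), 3250L)
  expect_equal(names(tab$coding), names(shenzhen_codings()))
  for (fn in names(tab$coding)) {
    expect_true(all(tab$records[[fn]] %in% tab$coding[[fn]]$codes))
  }
  sp <- split_groups(tab)
  # table-wide fatality mean calibrated to 0.48
  expect_equal(mean(tab$records$fatalities), 0.48, tolerance = 0.05)
  # group-1 conditional severity: SD pinned to 0.301 by the preset design
  expect_equal(sd(sp$group1$records$fatalities), 0.301, tolerance = 0.1)
  # group-2 injury moments matched to (1.41, 1.055)
  expect_equal(mean(sp$group2$records$injuries), 1.41, tolerance = 0.05)
  expect_equal(sd(sp$group2$records$injuries), 1.055, tolerance = 0.1)
  expect_true(all(sp$group2$records$injuries >= 1))
})

test_that("group-level moment fidelity is stable across seeds", {
  cfg <- make_preset("shenzhen_like")
  p2 <- (1 - sqrt(1 - 4 * 0.301^2)) / 2
  cond_target <- 1 + p2
  means <- vapply(1:5, function(s) {
    sp <- split_groups(generate(cfg, seed = s))
    c(mean(sp$group1$records$fatalities), mean(sp$group2$records$injuries))
  }, numeric(2))
  expect_equal(mean(means[1, ]), cond_target, tolerance = 0.02 / cond_target)
  expect_equal(mean(means[2, ]), 1.41, tolerance = 0.03 / 1.41)
})

test_that("the interaction preset plants nonlinear enhancement", {
  tab <- generate(make_preset("interaction_demo"))
  ir <- interaction_detector(tab$records$injuries,
                             stratify(tab, "factor_a"),
                             stratify(tab, "factor_b"))
  expect_equal(ir$type, "Enhance, nonlinear")
  expect_gt(ir$q_ab, 0.2)
})

test_that("the spatial preset clusters the outcome in space", {
  tab <- generate(make_preset("spatial_demo"))
  expect_equal(nrow(tab$records), 800L)
  qz <- compute_q(tab$records$injuries, stratify(tab, "zones"))
  expect_gt(qz$q, 0.5)
})

test_that("zone tilts shift category frequencies between zones", {
  cfg <- make_preset("shenzhen_like")
  tab <- generate(cfg)
  rec <- tab$records
  # road_type category 1 is up-tilted in eastern zones, down in the center
  f_center <- mean(rec$road_type[rec$zones == 1] == 1)
  f_east <- mean(rec$road_type[rec$zones == 4] == 1)
  expect_gt(f_east, f_center)
})
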