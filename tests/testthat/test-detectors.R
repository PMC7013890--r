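test_that("compute_q matches the hand variance decomposition", {
  qr <- compute_q(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(qr$sst, 5)
  expect_equal(qr$ssw, 1)
  expect_equal(qr$q, 0.8)
  expect_equal(qr$per_stratum$mean, c(1.5, 3.5))
  expect_equal(qr$per_stratum$n, c(2L, 2L))

  # equal stratum means and variances: nothing explained
  expect_equal(compute_q(c(1, 2, 1, 2), c("A", "A", "B", "B"))$q, 0)
  # zero within-strata variance: complete determination
  expect_equal(compute_q(c(5, 5, 9, 9), c("A", "A", "B", "B"))$q, 1)
})

test_that("degenerate and invalid inputs are handled", {
  qr <- compute_q(rep(3, 10), sample(c("A", "B"), 10, replace = TRUE))
  expect_true(qr$degenerate)
  expect_equal(qr$q, 0)
  expect_error(compute_q(c(1, Inf, 2, 3), c("A", "A", "B", "B")),
               "non-finite")
  expect_error(compute_q(numeric(0), character(0)), "at least 2")
  expect_error(compute_q(1:4, c("A", "B")), "different numbers")
})

test_that("compute_q agrees with an independent ANOVA decomposition", {
  set.seed(42)
  for (i in 1:200) {
    inst <- rand_instance()
    expect_lt(abs(compute_q(inst$y, inst$g)$q -
                    anova_q_oracle(inst$y, inst$g)), 1e-10)
  }
})

test_that("the q identity and bounds hold on random instances", {
  set.seed(7)
  for (i in 1:100) {
    inst <- rand_instance()
    qr <- compute_q(inst$y, inst$g)
    expect_gte(qr$q, 0)
    expect_lte(qr$q, 1)
    expect_lte(qr$ssw, qr$sst + 1e-12)
    expect_lt(abs(qr$q - (1 - qr$ssw / qr$sst)), 1e-12)
    expect_equal(sum(qr$per_stratum$n), qr$n_used)
    # population-variance form: SST = N sigma^2, SSW = sum N_h sigma_h^2
    expect_equal(qr$sst, qr$n_used * mean((inst$y - mean(inst$y))^2),
                 tolerance = 1e-10)
    expect_equal(qr$ssw, sum(qr$per_stratum$n * qr$per_stratum$var),
                 tolerance = 1e-10)
  }
})

test_that("q and F are scale invariant; Welch t is location-scale stable", {
  set.seed(11)
  y <- rnorm(60, 5)
  g1 <- sample(c("A", "B", "C"), 60, replace = TRUE)
  g2 <- sample(c("u", "v"), 60, replace = TRUE)
  expect_lt(abs(compute_q(3.7 * y, g1)$q - compute_q(y, g1)$q), 1e-12)
  f1 <- ecological_detector(y, g1, g2)
  f2 <- ecological_detector(3.7 * y, g1, g2)
  expect_equal(f2$f_statistic, f1$f_statistic, tolerance = 1e-12)
  t1 <- risk_detector(y, g1)$pairs$t_statistic
  t2 <- risk_detector(3.7 * y, g1)$pairs$t_statistic
  expect_equal(t2, t1, tolerance = 1e-12)
})

test_that("risk detector reproduces the Welch oracle", {
  y <- c(0, 1, 1, 3, 3, 4)
  g <- c("A", "A", "A", "B", "B", "B")
  rc <- risk_detector(y, g)
  oracle <- t.test(y[g == "A"], y[g == "B"], var.equal = FALSE)
  expect_equal(rc$pairs$t_statistic, unname(oracle$statistic),
               tolerance = 1e-12)
  expect_equal(rc$pairs$df, unname(oracle$parameter), tolerance = 1e-12)
  expect_equal(rc$pairs$p_value, oracle$p.value, tolerance = 1e-12)
  expect_true(rc$pairs$significant)

  set.seed(3)
  for (i in 1:25) {
    y <- rnorm(40)
    g <- sample(c("A", "B", "C"), 40, replace = TRUE)
    rc <- risk_detector(y, g)
    for (j in seq_len(nrow(rc$pairs))) {
      a <- rc$pairs$stratum_a[j]; b <- rc$pairs$stratum_b[j]
      o <- t.test(y[g == a], y[g == b], var.equal = FALSE)
      expect_equal(rc$pairs$t_statistic[j], unname(o$statistic),
                   tolerance = 1e-10)
      expect_equal(rc$pairs$df[j], unname(o$parameter), tolerance = 1e-10)
    }
  }
})

test_that("identical strata give t = 0 and tiny strata are excluded", {
  y <- c(1, 2, 3, 1, 2, 3)
  g <- c("A", "A", "A", "B", "B", "B")
  rc <- risk_detector(y, g)
  expect_equal(rc$pairs$t_statistic, 0)
  expect_false(rc$pairs$significant)

  # singleton stratum cannot enter comparisons
  rc2 <- risk_detector(c(y, 9), c(g, "C"))
  expect_false("C" %in% c(rc2$pairs$stratum_a, rc2$pairs$stratum_b))
  expect_warning(risk_detector(c(1, 2), c("A", "B")), "no comparisons")
})

test_that("risk detector recovers a planted ordering of stratum means", {
  set.seed(5)
  mu <- c(A = 0, B = 2, C = 4)
  g <- sample(names(mu), 600, replace = TRUE)
  y <- mu[g] + rnorm(600, 0, 0.5)
  rc <- risk_detector(y, g)
  for (j in seq_len(nrow(rc$pairs))) {
    expected_sign <- sign(mu[rc$pairs$stratum_a[j]] -
                            mu[rc$pairs$stratum_b[j]])
    expect_equal(sign(rc$pairs$t_statistic[j]), unname(expected_sign))
    expect_true(rc$pairs$significant[j])
  }
})

test_that("ecological detector follows the F-ratio arithmetic", {
  set.seed(9)
  y <- rnorm(100)
  g <- sample(c("A", "B"), 100, replace = TRUE)
  same <- ecological_detector(y, g, g)
  expect_equal(same$f_statistic, 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$dominant, "tie")

  # direct arithmetic: F = (N_a (N_b - 1) SSW_a) / (N_b (N_a - 1) SSW_b)
  g2 <- sample(c("u", "v", "w"), 100, replace = TRUE)
  er <- ecological_detector(y, g, g2)
  ssw_a <- compute_q(y, g)$ssw
  ssw_b <- compute_q(y, g2)$ssw
  expect_equal(er$f_statistic,
               (100 * 99 * ssw_a) / (100 * 99 * ssw_b), tolerance = 1e-12)
  # equal sample sizes: the N factors cancel, F = SSW_a / SSW_b
  expect_equal(er$f_statistic, ssw_a / ssw_b, tolerance = 1e-12)
})

test_that("ecological detector finds the planted dominant factor", {
  set.seed(13)
  n <- 2000
  strong <- sample(1:4, n, replace = TRUE)
  noisef <- sample(1:4, n, replace = TRUE)
  y <- c(-1.5, -0.5, 0.5, 1.5)[strong] + rnorm(n)
  er <- ecological_detector(y, paste0("s", strong), paste0("x", noisef))
  expect_lt(er$p_value, 0.05)
  expect_equal(er$dominant, "strata")   # both plain vectors share the name
  expect_lt(er$ssw_a, er$ssw_b)

  zero_ssw <- ecological_detector(c(1, 1, 2, 2), c("A", "A", "B", "B"),
                                  c("u", "u", "v", "v"))
  expect_true(zero_ssw$infinite)
  expect_equal(zero_ssw$f_statistic, Inf)
})

test_that("overlay forms the observed joint partition", {
  a <- c("a", "a", "b", "b")
  b <- c("x", "y", "x", "y")
  ov <- overlay(a, b)
  expect_equal(nrow(ov$strata), 4L)
  expect_equal(ov$strata$n, rep(1L, 4))

  # constant second factor: overlay is the first partition relabelled
  ov2 <- overlay(a, rep("k", 4))
  expect_equal(nrow(ov2$strata), 2L)
  expect_equal(as.integer(factor(ov2$assignment)),
               as.integer(factor(a)))

  # idempotence
  ov3 <- overlay(a, a)
  expect_equal(nrow(ov3$strata), 2L)
  expect_equal(as.integer(factor(ov3$assignment)), as.integer(factor(a)))

  expect_error(overlay(a, c("x", "y")), "different numbers")
})

test_that("interaction classification follows the discriminant table", {
  expect_equal(classify_interaction(0.094, 0.042, 0.178)$type,
               "Enhance, nonlinear")
  expect_equal(classify_interaction(0.3, 0.2, 0.1)$type,
               "Weaken, nonlinear")
  expect_equal(classify_interaction(0.1, 0.2, 0.25)$type, "Enhance, bi")
  expect_equal(classify_interaction(0.1, 0.2, 0.30)$type, "Independent")
  expect_equal(classify_interaction(0.1, 0.2, 0.35)$type,
               "Enhance, nonlinear")
  expect_equal(classify_interaction(0.1, 0.2, 0.15)$type, "Weaken, single")
  # boundary ties resolve toward the adjacent category nearer independence
  expect_equal(classify_interaction(0.1, 0.2, 0.2)$type, "Enhance, bi")
  expect_equal(classify_interaction(0.1, 0.2, 0.1)$type, "Weaken, single")
  expect_error(classify_interaction(-0.1, 0.2, 0.3), "\\[0, 1\\]")
  expect_error(classify_interaction(0.1, 1.2, 0.3), "\\[0, 1\\]")
})

test_that("interaction classification is total and deterministic", {
  set.seed(21)
  labels <- c("Weaken, nonlinear", "Weaken, single", "Enhance, bi",
              "Independent", "Enhance, nonlinear")
  for (i in 1:500) {
    q3 <- runif(3)
    t1 <- classify_interaction(q3[1], q3[2], q3[3])$type
    t2 <- classify_interaction(q3[1], q3[2], q3[3])$type
    expect_identical(t1, t2)
    expect_true(t1 %in% labels)
  }
})

test_that("overlay refinement makes q monotone, so overlays never weaken", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    y <- rnorm(n)
    a <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    b <- sample(LETTERS[1:sample(2:4, 1)], n, replace = TRUE)
    ir <- interaction_detector(y, a, b)
    expect_gte(ir$q_ab, max(ir$q_a, ir$q_b) - 1e-12)
    expect_false(ir$type %in% c("Weaken, nonlinear", "Weaken, single"))
  }
})

test_that("interaction detector identifies planted structure", {
  set.seed(17)
  n <- 3000
  a <- sample(1:3, n, replace = TRUE)
  b <- sample(1:3, n, replace = TRUE)

  # pure multiplicative cross term, no main effects: nonlinear enhancement
  y <- 1.2 * (a - 2) * (b - 2) + rnorm(n)
  ir <- interaction_detector(y, paste0("a", a), paste0("b", b))
  expect_equal(ir$type, "Enhance, nonlinear")
  expect_lt(max(ir$q_a, ir$q_b), 0.02)
  expect_gt(ir$q_ab, 0.2)

  # outcome depends only on factor a: the overlay adds nothing beyond a
  y2 <- (a - 2) + rnorm(n, 0, 0.5)
  ir2 <- interaction_detector(y2, paste0("a", a), paste0("b", b))
  expect_equal(ir2$q_ab, ir2$q_a, tolerance = 0.02)
  expect_true(ir2$type %in% c("Enhance, bi", "Independent"))
})

test_that("detectors respect record-wise exclusion of missing codes", {
  y <- c(1, 2, 3, 4, 100)
  g <- c("A", "A", "B", "B", NA)
  qr <- compute_q(y, g)
  expect_equal(qr$n_used, 4L)
  expect_equal(qr$q, 0.8)
})
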