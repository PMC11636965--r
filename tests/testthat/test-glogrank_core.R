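test_that("consistency, regime propensity, and IPW weight: hand values", {
  tc <- toy_crossed_data()
  dat <- tc$data
  m <- tc$model
  # regime assigning "0" then "1"; subject 1 received a1="0", a2="1" at t2=0.6
  r01 <- Filter(function(r) unname(r$rules[[1]][["all"]]) == "0" &&
                  unname(r$rules[[2]][["all"]]) == "1", tc$regimes)[[1]]
  r00 <- Filter(function(r) unname(r$rules[[1]][["all"]]) == "0" &&
                  unname(r$rules[[2]][["all"]]) == "0", tc$regimes)[[1]]

  # both decisions in force at u = 1: pi = 0.5 * 0.5, weight = 4
  expect_equal(consistency_indicator(dat, 1, r01, 1.0), 1)
  expect_equal(regime_propensity(dat, 1, r01, 1.0, m), 0.25)
  expect_equal(ipw_weight(dat, 1, r01, 1.0, m), 4)

  # only decision 1 in force at u = 0.5: pi = 0.5, weight = 2
  expect_equal(regime_propensity(dat, 1, r01, 0.5, m), 0.5)
  expect_equal(ipw_weight(dat, 1, r01, 0.5, m), 2)

  # a stage-2 mismatch breaks consistency only once decision 2 is in force
  expect_equal(consistency_indicator(dat, 1, r00, 0.5), 1)
  expect_equal(consistency_indicator(dat, 1, r00, 1.0), 0)
  expect_equal(ipw_weight(dat, 1, r00, 1.0, m), 0)

  # past the follow-up time the weight is zero regardless
  expect_equal(ipw_weight(dat, 1, r01, 2.5, m), 0)
})

test_that("pooled baseline hazard reduces to Nelson-Aalen", {
  # one arm, unit weights: increments are (# events)/(# at risk)
  des1 <- design_single("0", probs = 1)
  df <- data.frame(id = 1:3, kappa = 1L, t1 = 0, a1 = "0",
                   u = c(1, 2, 3), delta = c(1, 1, 0))
  dat <- smart_data(df, des1)
  reg <- enumerate_regimes(des1)
  bh <- baseline_hazard(dat, reg, propensity_known(des1))
  expect_equal(bh$grid, c(1, 2))
  expect_equal(bh$increments, c(1 / 3, 1 / 2))

  # two arms at p = 0.5: every subject contributes weight 2 to exactly one
  # regime, so the pooled estimator equals Nelson-Aalen on the pooled sample
  tw <- toy_two_arm()
  bh2 <- baseline_hazard(tw$data, tw$regimes, tw$model)
  u <- tw$data$U
  na_inc <- vapply(bh2$grid, function(t) {
    sum(u == t & tw$data$delta == 1) / sum(u >= t)
  }, numeric(1))
  expect_equal(bh2$increments, na_inc)
})

test_that("worked two-arm example gives score 4/3", {
  tw <- toy_two_arm()
  sv <- score_vector(tw$data, tw$regimes, tw$model)
  expect_equal(unname(sv), 4 / 3)
  # influence contributions reproduce the score exactly
  infl <- influence_matrix(tw$data, tw$regimes, tw$model)
  expect_equal(unname(colSums(infl)), 4 / 3)
})

test_that("single-stage case reduces to the standard logrank statistic", {
  set.seed(42)
  n <- 150
  des <- design_single(c("A", "B", "C"))
  df <- data.frame(id = 1:n, kappa = 1L, t1 = 0,
                   a1 = sample(c("A", "B", "C"), n, replace = TRUE),
                   u = round(rexp(n, 0.4), 3), delta = rbinom(n, 1, 0.7))
  dat <- smart_data(df, des)
  reg <- enumerate_regimes(des)
  sv <- score_vector(dat, reg, propensity_known(des))
  sd <- survival::survdiff(survival::Surv(u, delta) ~ a1, data = df)
  oe <- (sd$obs - sd$exp)[1:2]        # O - E for arms A and B
  expect_equal(unname(sv), unname(oe) / (1 / 3), tolerance = 1e-10)
})

test_that("influence column sums reproduce the score on simulated data", {
  sc <- builtin_scenario("null_eight_cov")
  dat <- simulate_smart(sc, 300, seed = 4)
  reg <- enumerate_regimes(sc$design)
  m <- propensity_stratified(dat)
  L <- choose_truncation(dat)$L
  sv <- score_vector(dat, reg, m, L)
  infl <- influence_matrix(dat, reg, m, L)
  expect_equal(unname(colSums(infl)), unname(sv),
               tolerance = 1e-8 * max(1, max(abs(sv))))
})

test_that("weighted risk shares are proper proportions", {
  sc <- builtin_scenario("null_eight_cov")
  dat <- simulate_smart(sc, 300, seed = 6)
  res <- glr_test(dat)
  risk <- res$diagnostics$weighted_at_risk
  expect_true(all(risk >= 0))
  den <- rowSums(risk)
  q <- risk[den > 0, , drop = FALSE] / den[den > 0]
  expect_true(all(q >= 0 & q <= 1))
  expect_equal(rowSums(q), rep(1, nrow(q)))
})

test_that("residual adjustment behaves as an orthogonal projection", {
  sc <- builtin_scenario("null_crossed_cov")
  dat <- simulate_smart(sc, 250, seed = 8)
  reg <- enumerate_regimes(sc$design)
  m <- propensity_stratified(dat)
  L <- choose_truncation(dat)$L
  infl <- influence_matrix(dat, reg, m, L)

  # constant regressors are dropped; nothing changes
  ra0 <- residual_adjust(infl, matrix(1, nrow(infl), 1))
  expect_identical(ra0$p, 0L)
  expect_equal(ra0$influence, infl)

  # ML score columns sum to zero, so the adjusted score equals the plain one
  S <- score_matrix(m, dat)
  ra <- residual_adjust(infl, S)
  expect_equal(ra$score, colSums(infl), tolerance = 1e-8)
  # ... while the residual sums of squares can only shrink
  expect_true(all(colSums(ra$influence^2) <= colSums(infl^2) + 1e-10))

  # centered covariates shift the score but keep shrinking the variance
  cx <- cbind(x = as.numeric(dat$df$x1_c) - mean(dat$df$x1_c))
  ra2 <- residual_adjust(infl, cbind(S, cx))
  expect_true(all(colSums(ra2$influence^2) <=
                    colSums(ra$influence^2) + 1e-10))

  # exact collinearity is an error naming the offending column
  expect_error(residual_adjust(infl, cbind(a = cx[, 1], b = 2 * cx[, 1])),
               "collinear regressor column")
})

test_that("covariance estimate, correction, and quadratic form are coherent", {
  set.seed(12)
  infl <- matrix(rnorm(250 * 3), 250, 3)
  cov <- covariance_estimate(infl)
  expect_s3_class(cov, "glr_cov")
  expect_identical(cov$rank, 3L)
  expect_equal(cov$matrix, crossprod(infl) / 250)

  covc <- bias_correct(cov, n = 250, p_eff = 10)
  expect_equal(covc$correction_factor, 250 / 240)
  expect_equal(covc$matrix, cov$matrix * 250 / 240)
  expect_error(bias_correct(cov, n = 5, p_eff = 10), "must exceed")

  sc <- colSums(infl)
  g <- gscore_test(sc, cov, 250)
  gc <- gscore_test(sc, covc, 250)
  expect_lt(gc$statistic, g$statistic)
  expect_gt(gc$p_value, g$p_value)
  # full-rank case agrees with the direct quadratic form
  direct <- drop(t(sc) %*% solve(cov$matrix, sc)) / 250
  expect_equal(g$statistic, direct, tolerance = 1e-10)
  expect_identical(g$df, 3L)

  # rank-deficient covariance: df equals the numerical rank
  infl2 <- cbind(infl[, 1], infl[, 1], infl[, 2])
  cov2 <- covariance_estimate(infl2)
  expect_identical(cov2$rank, 2L)
  expect_identical(gscore_test(colSums(infl2), cov2, 250)$df, 2L)
})

test_that("statistic is invariant to which regime is the reference", {
  sc <- builtin_scenario("null_eight_cov")
  dat <- simulate_smart(sc, 300, seed = 14)
  reg <- enumerate_regimes(sc$design)
  r1 <- glr_test(dat, reg, propensity = "known", correction = "none")
  r2 <- glr_test(dat, c(reg[c(3, 8, 1)], reg[-c(3, 8, 1)]),
                 propensity = "known", correction = "none")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
  expect_identical(r1$df, r2$df)
})

test_that("a perfectly symmetric dataset gives a zero score", {
  des <- design_single(c("A", "B"))
  df <- data.frame(id = 1:6, kappa = 1L, t1 = 0,
                   a1 = rep(c("A", "B"), 3),
                   u = rep(c(1, 2, 3), each = 2), delta = rep(c(1, 1, 0), each = 2))
  dat <- smart_data(df, des)
  sv <- score_vector(dat, enumerate_regimes(des), propensity_known(des))
  expect_equal(unname(sv), 0)
})

test_that("known covariance ranks: 5 of 7 for the 8-regime design, full for 4", {
  sc8 <- builtin_scenario("null_eight_cov")
  sc4 <- builtin_scenario("null_basic")
  for (s in c(31, 32, 33)) {
    r8 <- glr_test(simulate_smart(sc8, 500, seed = s))
    expect_identical(r8$covariance$rank, 5L)
    expect_identical(r8$df, 5L)
    r4 <- glr_test(simulate_smart(sc4, 500, seed = s))
    expect_identical(r4$covariance$rank, 3L)
  }
})

test_that("two-regime comparison yields a 1-df test", {
  sc <- builtin_scenario("null_basic")
  dat <- simulate_smart(sc, 300, seed = 17)
  reg <- enumerate_regimes(sc$design)
  res <- glr_test(dat, reg[c(1, 4)])
  expect_identical(res$df, 1L)
  expect_length(res$score, 1L)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("glr_test returns a complete, printable result object", {
  sc <- builtin_scenario("null_crossed_cov")
  dat <- simulate_smart(sc, 250, seed = 19)
  res <- glr_test(dat, adjust = TRUE)
  expect_s3_class(res, "glr_test")
  expect_identical(res$D, 4L)
  expect_length(res$score, 3L)
  expect_identical(res$options$correction, "dof")
  expect_true(all(c("x1_b", "x1_c", "x2_w") %in% res$options$adjust))
  expect_identical(res$options$p_eff,
                   3L + res$options$p_gamma + length(res$options$adjust))
  expect_equal(res$at_risk_fraction, mean(dat$U >= res$L))
  expect_output(print(res), "Generalized logrank-type test")
  expect_output(print(res), "p = ")
})

test_that("accounting for estimated propensities shrinks the covariance", {
  # glr_test with stratified propensities residual-adjusts on the ML score
  # columns; each diagonal entry of the covariance is a residual sum of
  # squares and can only shrink relative to the unadjusted influence
  sc <- builtin_scenario("null_basic")
  dat <- simulate_smart(sc, 400, seed = 23)
  reg <- enumerate_regimes(sc$design)
  m <- propensity_stratified(dat)
  L <- choose_truncation(dat)$L
  infl <- influence_matrix(dat, reg, m, L)
  cov_raw <- covariance_estimate(infl)
  rs <- glr_test(dat, propensity = m, correction = "none", L = L)
  expect_true(all(diag(rs$covariance$matrix) <=
                    diag(cov_raw$matrix) + 1e-10))
  expect_identical(rs$df, cov_raw$rank)
  # the adjusted score still equals the influence column sums
  expect_equal(unname(rs$score), unname(colSums(infl)), tolerance = 1e-8)
})
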