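test_that("the packaged toy CSV loads with correct fields", {
  des <- read_design(system.file("extdata", "design_crossed.yaml",
                                 package = "glogrank"))
  dat <- read_smart_data(system.file("extdata", "toy_crossed.csv",
                                     package = "glogrank"), des)
  expect_s3_class(dat, "smart_data")
  expect_identical(dat$n, 3L)
  expect_identical(dat$kappa, c(2L, 1L, 2L))
  expect_identical(dat$Amat[, 1], c("0", "1", "1"))
  expect_identical(dat$Amat[, 2], c("1", NA, "0"))
  expect_equal(dat$U, c(2.4, 0.4, 3.1))
  expect_length(validate_data(dat), 0L)
})

test_that("structural invariants are enforced", {
  des <- design_crossed()
  base <- data.frame(id = 1:2, kappa = c(2L, 1L), t1 = 0,
                     t2 = c(0.5, NA), a1 = c("0", "1"), a2 = c("1", NA),
                     u = c(2, 1), delta = c(1L, 0L))
  expect_s3_class(smart_data(base, des), "smart_data")

  bad <- base; bad$t2[1] <- -0.1
  expect_error(smart_data(bad, des), "decision times not increasing")

  bad <- base; bad$a2[2] <- "0"
  expect_error(smart_data(bad, des), "a2 populated but kappa < 2")

  bad <- base; bad$a2[1] <- NA
  expect_error(smart_data(bad, des), "a2 missing for a subject with kappa >= 2")

  bad <- base; bad$t2[1] <- 3
  expect_error(smart_data(bad, des), "t2 exceeds follow-up time")

  bad <- base; bad$t1[1] <- 0.2
  expect_error(smart_data(bad, des), "t1 must equal 0")

  bad <- base; bad$delta[1] <- 2
  expect_error(smart_data(bad, des), "delta must be 0 or 1")

  bad <- base; bad$kappa[1] <- 3L
  expect_error(smart_data(bad, des), "kappa must be an integer in 1..K")

  expect_error(smart_data(base[, setdiff(names(base), "u")], des),
               "missing mandatory column")
})

test_that("validate_data flags infeasible treatments and unmatched strata", {
  des <- design_basic()
  df <- data.frame(id = 1:3, kappa = c(2L, 2L, 1L), t1 = 0,
                   t2 = c(0.5, 0.6, NA), a1 = c("0", "1", "1"),
                   a2 = c("1", "1", NA), u = c(2, 2, 0.3),
                   delta = 1L, x2_resp = c(1L, 0L, NA))
  dat <- smart_data(df, des)
  v <- validate_data(dat)
  # subject 2 is a nonresponder treated with "1" (outside feasible {0})
  expect_length(v, 1L)
  expect_match(v, "subject 2: stage-2 treatment '1' outside feasible set \\{0\\}")

  df$x2_resp[2] <- NA   # history matches no stage-2 stratum
  dat2 <- smart_data(df, des)
  expect_match(validate_data(dat2), "matches no stage-2 stratum")
})

test_that("event_grid returns distinct event times up to L", {
  des <- design_single()
  mk <- function(u, delta) {
    smart_data(data.frame(id = seq_along(u), kappa = 1L, t1 = 0,
                          a1 = rep_len(c("0", "1"), length(u)),
                          u = u, delta = delta), des)
  }
  d <- mk(c(1, 2, 2, 3, 4), c(1, 1, 1, 1, 0))
  expect_equal(event_grid(d), c(1, 2, 3))
  expect_equal(event_grid(d, L = 2.5), c(1, 2))
  expect_error(event_grid(mk(c(1, 2), c(0, 0))), "no events")
})

test_that("choose_truncation picks the last event time meeting the target", {
  des <- design_single()
  d100 <- smart_data(data.frame(id = 1:100, kappa = 1L, t1 = 0,
                                a1 = rep_len(c("0", "1"), 100),
                                u = 1:100, delta = 1L), des)
  tr <- choose_truncation(d100, target_fraction = 0.02)
  expect_equal(tr$L, 99)
  expect_equal(tr$at_risk_fraction, 0.02)

  d4 <- smart_data(data.frame(id = 1:4, kappa = 1L, t1 = 0,
                              a1 = c("0", "1", "0", "1"),
                              u = 1:4, delta = 1L), des)
  tr2 <- choose_truncation(d4, target_fraction = 0.5)
  expect_equal(tr2$L, 3)
  expect_equal(tr2$at_risk_fraction, 0.5)
})

test_that("choose_truncation is monotone in the target fraction", {
  sc <- builtin_scenario("null_basic")
  dat <- simulate_smart(sc, 200, seed = 11)
  Ls <- vapply(c(0.01, 0.02, 0.05, 0.2),
               function(f) choose_truncation(dat, f)$L, numeric(1))
  expect_true(all(diff(Ls) <= 0))
  expect_true(all(vapply(c(0.01, 0.02, 0.05, 0.2), function(f) {
    choose_truncation(dat, f)$at_risk_fraction >= f
  }, logical(1))))
})

test_that("smart_data is invariant to row permutation up to reordering", {
  sc <- builtin_scenario("null_crossed_cov")
  dat <- simulate_smart(sc, 80, seed = 5)
  perm <- sample(80)
  dat_p <- smart_data(dat$df[perm, ], sc$design)
  expect_equal(dat_p$U, dat$U[perm])
  expect_identical(dat_p$strat, dat$strat[perm, ])
  expect_equal(choose_truncation(dat_p)$L, choose_truncation(dat)$L)
})

test_that("read_smart_data applies a column-name schema", {
  des <- design_single()
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write.csv(data.frame(subj = 1:4, stagecount = 1L, arm = c("0", "1", "0", "1"),
                       time = c(1, 2, 3, 4), event = c(1, 1, 0, 1)),
            tf, row.names = FALSE)
  dat <- read_smart_data(tf, des,
                         schema = c(id = "subj", kappa = "stagecount",
                                    a1 = "arm", u = "time", delta = "event"))
  expect_identical(dat$n, 4L)
  expect_equal(event_grid(dat), c(1, 2, 4))
  expect_error(read_smart_data(tf, des, schema = c(u = "notthere")),
               "schema column not in file")
})
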