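# Shared helpers for the glogrank test suite.

# A minimal single-stage two-arm data set used in several hand-worked checks:
# arm A has events at 1 and 3; arm B has an event at 2 and a censoring at 4.
toy_two_arm <- function() {
  des <- design_single(c("A", "B"))
  df <- data.frame(
    id = 1:4, kappa = 1L, t1 = 0,
    a1 = c("A", "A", "B", "B"),
    u = c(1, 3, 2, 4), delta = c(1, 1, 1, 0)
  )
  list(design = des, data = smart_data(df, des),
       regimes = enumerate_regimes(des),
       model = propensity_known(des))
}

# A small two-stage data set on the crossed design with every field populated
# by hand, for scalar consistency / propensity / weight checks.
toy_crossed_data <- function() {
  des <- design_crossed()
  df <- data.frame(
    id = 1:6, kappa = c(2L, 1L, 2L, 2L, 1L, 2L),
    t1 = 0, t2 = c(0.6, NA, 0.7, 0.5, NA, 0.8),
    a1 = c("0", "1", "1", "0", "0", "1"),
    a2 = c("1", NA, "0", "0", NA, "1"),
    u = c(2.4, 0.4, 3.1, 1.9, 0.3, 2.2),
    delta = c(1L, 1L, 0L, 1L, 1L, 1L),
    x1_b = c(1, 0, 1, 0, 1, 0),
    x1_c = c(0.31, -0.82, 1.05, -0.2, 0.6, 0.1)
  )
  list(design = des, data = smart_data(df, des),
       regimes = enumerate_regimes(des),
       model = propensity_known(des))
}

# Count embedded regimes by brute force: generate every function mapping each
# reachable stratum at each stage to one feasible option and count the
# distinct combinations.  Independent of enumerate_regimes() internals.
brute_force_regime_count <- function(design) {
  possible <- rep(list(NULL), length(design$stages))
  count_from <- function(k, possible) {
    if (k > length(design$stages)) return(1L)
    reach <- reachable_strata(design, k, possible)
    strata <- design$stages[[k]]$strata[reach]
    if (length(strata) == 0L) return(count_from(k + 1L, possible))
    choice_sets <- lapply(strata, function(s) s$feasible)
    total <- 0L
    idx <- rep(1L, length(choice_sets))
    repeat {
      opts <- unique(unlist(Map(function(s, i) s$feasible[i],
                                strata, as.list(idx))))
      possible[[k]] <- opts
      total <- total + count_from(k + 1L, possible)
      j <- length(idx)
      while (j >= 1L) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(choice_sets[[j]])) break
        idx[j] <- 1L
        j <- j - 1L
      }
      if (j < 1L) break
    }
    total
  }
  count_from(1L, possible)
}

mc_band <- function(p_hat, reps) max(3 * sqrt(p_hat * (1 - p_hat) / reps), 0.01)
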