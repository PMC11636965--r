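#' Scenario configuration for the SMART simulator
#'
#' A scenario couples a \code{\link{smart_design}} with a generative model
#' for two-stage SMART data with a time-to-event outcome:
#' \itemize{
#'  \item baseline covariates \code{x1_b} (Bernoulli(0.5)) and \code{x1_c}
#'    (standard normal), and an intermediate covariate \code{x2_w} drawn at
#'    the second decision as N(0.4 x1_c, 1);
#'  \item an exponential event hazard \code{h1 exp(theta_b x1_b + theta_c
#'    x1_c)} before the second decision and \code{h2 exp(theta_b x1_b +
#'    theta_c x1_c + theta_w x2_w)} after it;
#'  \item a subject-level second-decision time drawn uniformly on
#'    \code{t2_window};
#'  \item responder status Bernoulli(\code{resp_prob}) ascertained at the
#'    second decision (designs that stratify on response);
#'  \item independent censoring uniform on \code{cens_window};
#'  \item an alternative-hypothesis hazard multiplier \code{zeta} applied on
#'    the designated treatment path (\code{alt_path}); \code{zeta = 1} means
#'    the null holds.  Under \code{zeta = 1} the hazard does not depend on
#'    treatment at all, so the event-time law is identical across every
#'    embedded regime by construction.
#' }
#'
#' @param design A \code{\link{smart_design}} (two-stage, single baseline
#'   stratum).
#' @param name Scenario identifier.
#' @param h1,h2 Baseline hazard rates before/after the second decision.
#' @param theta Named numeric: log-linear hazard coefficients \code{b},
#'   \code{c} (baseline) and \code{w} (intermediate); zero means the
#'   covariate does not affect the outcome.
#' @param t2_window,cens_window Uniform ranges for the second-decision time
#'   and the independent censoring time.
#' @param resp_prob Responder probability, or \code{NULL} for designs
#'   without response stratification.
#' @param zeta Hazard multiplier on the designated path; 1 = null.
#' @param alt_path \code{list(stage =, options =)}: the treatment path whose
#'   hazard is multiplied by \code{zeta} (stage-1 options act from baseline,
#'   stage-2 options act after the second decision).
#' @param stage2_arms Stage-1 options whose subjects can reach a second
#'   decision (default: all; the control arm of the control design is
#'   excluded automatically by \code{\link{builtin_scenario}}).
#' @return An object of class \code{"glr_scenario"}.
#' @export
scenario_config <- function(design, name = "custom", h1 = 0.3, h2 = 0.45,
                            theta = c(b = 0, c = 0, w = 0),
                            t2_window = c(0.5, 1.0),
                            cens_window = c(1.0, 4.5),
                            resp_prob = 0.5, zeta = 1,
                            alt_path = NULL,
                            stage2_arms = NULL) {
  stop_if_invalid(design)
  th <- c(b = 0, c = 0, w = 0)
  th[names(theta)] <- theta
  if (is.null(stage2_arms) && design$K >= 2L) {
    stage2_arms <- design$stages[[1]]$options
  }
  stopifnot(zeta > 0, h1 > 0, h2 > 0,
            t2_window[1] > 0, diff(t2_window) >= 0, diff(cens_window) >= 0)
  structure(list(design = design, name = name, h1 = h1, h2 = h2,
                 theta = th, t2_window = t2_window,
                 cens_window = cens_window, resp_prob = resp_prob,
                 zeta = zeta, alt_path = alt_path,
                 stage2_arms = stage2_arms),
            class = "glr_scenario")
}

#' Built-in simulation scenarios
#'
#' \code{builtin_scenario} returns one named scenario;
#' \code{builtin_scenarios} lists them all.  The null scenarios (hazards
#' identical across regimes by construction) are:
#' \describe{
#'  \item{\code{null_basic}}{\code{\link{design_basic}}, no covariate-hazard
#'    associations.}
#'  \item{\code{null_basic_cov}}{same design, covariates associated with the
#'    outcome.}
#'  \item{\code{null_crossed_cov}}{\code{\link{design_crossed}}, covariates
#'    associated with the outcome.}
#'  \item{\code{null_control_cov}}{\code{\link{design_basic}(control =
#'    TRUE)} (5 embedded regimes), covariates associated with the outcome.}
#'  \item{\code{null_eight_cov}}{\code{\link{design_response8}} (8 embedded
#'    regimes), covariates associated with the outcome.}
#' }
#' Each has an \code{alt_*} counterpart taking a hazard multiplier
#' \code{zeta} (> 1) on a designated treatment path; \code{zeta = 1}
#' recovers the null twin.  Censoring windows are fixed so that the
#' censoring proportion falls in the 25\%--40\% range (30\%--45\% for the
#' crossed and control scenarios) at the scenarios' design sample sizes.
#'
#' @param name Scenario name.
#' @param zeta Hazard multiplier for \code{alt_*} scenarios (default 2).
#' @return \code{builtin_scenario}: a \code{"glr_scenario"};
#'   \code{builtin_scenarios}: a named list of them.
#' @export
builtin_scenario <- function(name, zeta = NULL) {
  base <- sub("^(null|alt)_", "", name)
  is_alt <- grepl("^alt_", name)
  z <- if (is_alt) zeta %||% 2 else 1
  th_cov <- c(b = 0.4, c = 0.3, w = 0.4)
  cfg <- switch(
    base,
    basic = scenario_config(design_basic(), name, h1 = 0.3, h2 = 0.45,
                            theta = c(b = 0, c = 0, w = 0),
                            cens_window = c(1.2, 4.8), zeta = z,
                            alt_path = list(stage = 2L, options = "1")),
    basic_cov = scenario_config(design_basic(), name, h1 = 0.3, h2 = 0.45,
                                theta = th_cov, cens_window = c(1.2, 4.8),
                                zeta = z,
                                alt_path = list(stage = 2L, options = "1")),
    crossed_cov = scenario_config(design_crossed(), name, h1 = 0.3,
                                  h2 = 0.45, theta = th_cov,
                                  cens_window = c(0.8, 4.0),
                                  resp_prob = NULL, zeta = z,
                                  alt_path = list(stage = 2L,
                                                  options = "1")),
    control_cov = scenario_config(design_basic(control = TRUE), name,
                                  h1 = 0.3, h2 = 0.45, theta = th_cov,
                                  cens_window = c(0.8, 4.0), zeta = z,
                                  alt_path = list(stage = 1L,
                                                  options = "ctrl"),
                                  stage2_arms = c("0", "1")),
    eight_cov = scenario_config(design_response8(), name, h1 = 0.3,
                                h2 = 0.45, theta = th_cov,
                                cens_window = c(1.0, 4.0), zeta = z,
                                alt_path = list(stage = 2L, options = "2")),
    stop("unknown scenario '", name, "'; available: ",
         paste(names(builtin_scenarios()), collapse = ", "), call. = FALSE)
  )
  if (!base %in% c("basic", "basic_cov", "crossed_cov", "control_cov",
                   "eight_cov") ||
      !grepl("^(null|alt)_", name)) {
    stop("unknown scenario '", name, "'", call. = FALSE)
  }
  cfg
}

#' @rdname builtin_scenario
#' @export
builtin_scenarios <- function() {
  nms <- c("null_basic", "null_basic_cov", "null_crossed_cov",
           "null_control_cov", "null_eight_cov",
           "alt_basic_cov", "alt_crossed_cov", "alt_control_cov",
           "alt_eight_cov")
  stats::setNames(lapply(nms, builtin_scenario), nms)
}

uses_resp <- function(config) !is.null(config$resp_prob)

# Draw the latent trajectory shared by observed-data and potential-outcome
# simulation.  Treatments enter only through the zeta multiplier.
draw_latents <- function(config, n) {
  th <- config$theta
  x1_b <- stats::rbinom(n, 1, 0.5)
  x1_c <- stats::rnorm(n)
  t2p <- stats::runif(n, config$t2_window[1], config$t2_window[2])
  x2_w <- stats::rnorm(n, 0.4 * x1_c, 1)
  resp <- if (uses_resp(config)) {
    stats::rbinom(n, 1, config$resp_prob)
  } else rep(NA_integer_, n)
  lp1 <- th[["b"]] * x1_b + th[["c"]] * x1_c
  list(x1_b = x1_b, x1_c = x1_c, t2p = t2p, x2_w = x2_w, resp = resp,
       lp1 = lp1, lp2 = lp1 + th[["w"]] * x2_w)
}

alt_mult <- function(config, stage, trt) {
  ap <- config$alt_path
  if (is.null(ap) || config$zeta == 1 || ap$stage != stage) {
    return(rep(1, length(trt)))
  }
  ifelse(!is.na(trt) & trt %in% as.character(ap$options), config$zeta, 1)
}

# Event time given stage-1/stage-2 treatments (possibly NA stage 2 when the
# subject has no second decision): exponential pieces on either side of the
# subject's second-decision time.
draw_event_time <- function(config, lat, a1, a2) {
  n <- length(a1)
  m1 <- alt_mult(config, 1L, a1)
  m2 <- m1 * alt_mult(config, 2L, a2)
  e1 <- stats::rexp(n, rate = config$h1 * exp(lat$lp1) * m1)
  e2 <- stats::rexp(n, rate = config$h2 * exp(lat$lp2) * m2)
  ifelse(e1 <= lat$t2p, e1, lat$t2p + e2)
}

stage2_assign <- function(config, rows, a1, resp, draw = TRUE,
                          rule_fn = NULL) {
  design <- config$design
  dfx <- data.frame(x2_resp = resp)
  Am <- cbind(a1, NA_character_)
  si <- match_stratum(design, 2L, dfx[rows, , drop = FALSE],
                      Am[rows, , drop = FALSE])
  if (anyNA(si)) stop("simulated history matches no stage-2 stratum",
                      call. = FALSE)
  a2 <- rep(NA_character_, length(rows))
  for (s in unique(si)) {
    st <- design$stages[[2]]$strata[[s]]
    idx <- which(si == s)
    a2[idx] <- if (!is.null(rule_fn)) {
      rule_fn(st$name)
    } else if (length(st$feasible) == 1L) {
      st$feasible
    } else {
      sample(st$feasible, length(idx), replace = TRUE, prob = st$probs)
    }
  }
  list(stratum = si, a2 = a2)
}

#' Simulate an observed SMART dataset from a scenario
#'
#' Draws covariates, randomizes stage-1 treatment per the design, draws the
#' latent event time from the path-specific hazard, ascertains response and
#' the second-decision time, re-randomizes subjects still event-free and
#' uncensored at the second decision within their feasibility stratum, and
#' applies independent censoring.  Observed data equal their potential
#' analogs under the treatments actually received (consistency), sequential
#' randomization holds by construction, and censoring is independent of
#' everything.
#'
#' @param config A \code{"glr_scenario"}.
#' @param n Number of subjects.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A \code{\link{smart_data}} object.
#' @export
simulate_smart <- function(config, n, seed) {
  stopifnot(inherits(config, "glr_scenario"), n >= 1)
  set.seed(seed)
  design <- config$design
  lat <- draw_latents(config, n)
  s1 <- design$stages[[1]]$strata[[1]]
  a1 <- sample(s1$feasible, n, replace = TRUE, prob = s1$probs)
  cens <- stats::runif(n, config$cens_window[1], config$cens_window[2])
  has2 <- design$K >= 2L & a1 %in% config$stage2_arms
  # pre-decision-2 event time under the subject's stage-1 path
  m1 <- alt_mult(config, 1L, a1)
  e1 <- stats::rexp(n, rate = config$h1 * exp(lat$lp1) * m1)
  reach2 <- has2 & (e1 > lat$t2p) & (cens > lat$t2p)
  a2 <- rep(NA_character_, n)
  if (any(reach2)) {
    rows <- which(reach2)
    a2[rows] <- stage2_assign(config, rows, a1, lat$resp)$a2
  }
  m2 <- m1 * alt_mult(config, 2L, a2)
  e2 <- stats::rexp(n, rate = config$h2 * exp(lat$lp2) * m2)
  tev <- ifelse(e1 <= lat$t2p, e1, lat$t2p + e2)
  U <- pmin(tev, cens)
  delta <- as.numeric(tev <= cens)
  kappa <- ifelse(reach2, 2L, 1L)
  df <- data.frame(id = seq_len(n), kappa = kappa, t1 = 0,
                   t2 = ifelse(reach2, lat$t2p, NA_real_),
                   a1 = a1, a2 = a2, u = U, delta = delta,
                   x1_b = lat$x1_b, x1_c = lat$x1_c,
                   x2_w = ifelse(reach2, lat$x2_w, NA_real_),
                   stringsAsFactors = FALSE)
  if (uses_resp(config)) {
    df$x2_resp <- ifelse(reach2, lat$resp, NA_integer_)
  }
  if (design$K == 1L) {
    df <- df[c("id", "kappa", "t1", "a1", "u", "delta",
               "x1_b", "x1_c")]
    df$kappa <- 1L
  }
  smart_data(df, design)
}

#' Sample potential event times under a regime
#'
#' Draws \eqn{T^{*}(d)} directly: the trajectory a subject would follow if
#' treated by the regime's rules, with no censoring.  Under a null scenario
#' the returned distribution is identical for every embedded regime, which
#' is the construction the type-I-error calibration relies on.
#'
#' @param config A \code{"glr_scenario"}.
#' @param reg A \code{\link{regime}} of the scenario's design.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of potential event times.
#' @export
simulate_potential <- function(config, reg, n, seed) {
  stopifnot(inherits(config, "glr_scenario"), inherits(reg, "smart_regime"))
  set.seed(seed)
  design <- config$design
  lat <- draw_latents(config, n)
  s1 <- design$stages[[1]]$strata[[1]]
  a1 <- rep(assigned_treatment(reg, 1L, s1$name), n)
  has2 <- design$K >= 2L & a1 %in% config$stage2_arms
  m1 <- alt_mult(config, 1L, a1)
  e1 <- stats::rexp(n, rate = config$h1 * exp(lat$lp1) * m1)
  reach2 <- has2 & (e1 > lat$t2p)
  a2 <- rep(NA_character_, n)
  if (any(reach2)) {
    rows <- which(reach2)
    sa <- stage2_assign(config, rows, a1, lat$resp,
                        rule_fn = function(nm) {
                          assigned_treatment(reg, 2L, nm)
                        })
    a2[rows] <- sa$a2
  }
  m2 <- m1 * alt_mult(config, 2L, a2)
  e2 <- stats::rexp(n, rate = config$h2 * exp(lat$lp2) * m2)
  ifelse(e1 <= lat$t2p, e1, lat$t2p + e2)
}

#' Monte-Carlo rejection rate of the test under a scenario
#'
#' Simulates independent datasets from the scenario and applies one or more
#' test variants to each, reporting the proportion of p-values at or below
#' the level, with its Monte-Carlo standard error
#' \eqn{\sqrt{\hat p (1 - \hat p) / \mathrm{replicates}}}.  Under a null
#' scenario this estimates the type-I error; under an alternative, the
#' power.  Per-replicate seeds are derived deterministically from the master
#' seed.
#'
#' @param config A \code{"glr_scenario"}.
#' @param n Subjects per replicate.
#' @param replicates Number of Monte-Carlo replicates (>= 100 recommended).
#' @param variants Named list of test variants as in
#'   \code{\link{glr_test_variants}}; default is the bias-corrected test
#'   with estimated (stratified ML) propensities and no covariate
#'   adjustment.
#' @param level Significance level.
#' @param seed Master seed.
#' @param regimes Regime set (default: all embedded regimes).
#' @param target_fraction Truncation target passed to the test.
#' @return Data frame of class \code{"glr_calibration"} with one row per
#'   variant: \code{variant}, \code{rejection_proportion}, \code{mc_se},
#'   \code{replicates}, \code{n}, \code{level}, \code{scenario}.  The full
#'   p-value matrix is attached as attribute \code{"p_values"}.
#' @export
rejection_rate <- function(config, n, replicates,
                           variants = list(
                             corrected = list(propensity = "stratified",
                                              adjust = FALSE,
                                              correction = "dof")),
                           level = 0.05, seed = 1, regimes = NULL,
                           target_fraction = 0.02) {
  stopifnot(inherits(config, "glr_scenario"), replicates >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, replicates)
  if (is.null(regimes)) regimes <- enumerate_regimes(config$design)
  pv <- matrix(NA_real_, replicates, length(variants),
               dimnames = list(NULL, names(variants)))
  for (r in seq_len(replicates)) {
    dat <- simulate_smart(config, n, seeds[r])
    res <- glr_test_variants(dat, regimes, variants,
                             target_fraction = target_fraction)
    pv[r, ] <- vapply(res, `[[`, numeric(1), "p_value")
  }
  prop <- colMeans(pv <= level)
  out <- data.frame(variant = names(variants),
                    rejection_proportion = as.numeric(prop),
                    mc_se = sqrt(prop * (1 - prop) / replicates),
                    replicates = replicates, n = n, level = level,
                    scenario = config$name, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "p_values") <- pv
  class(out) <- c("glr_calibration", "data.frame")
  out
}

#' @export
print.glr_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' on %s\n", x$name, x$design$label))
  cat(sprintf("  h1 = %.3g, h2 = %.3g, theta = (b %.2g, c %.2g, w %.2g), zeta = %.3g\n",
              x$h1, x$h2, x$theta[["b"]], x$theta[["c"]], x$theta[["w"]],
              x$zeta))
  cat(sprintf("  decision-2 window [%.2g, %.2g], censoring window [%.2g, %.2g]\n",
              x$t2_window[1], x$t2_window[2], x$cens_window[1],
              x$cens_window[2]))
  invisible(x)
}
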