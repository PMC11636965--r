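#' Generalized logrank-type test machinery
#'
#' @description
#' These functions implement the IPW logrank-type test of equality of the
#' hazard functions \eqn{\lambda(u, d^1) = \cdots = \lambda(u, d^D)} of the
#' event-time distributions that would be seen if the whole population
#' followed each regime \eqn{d^j} in a set \eqn{\mathcal{D}}.  For a subject
#' at time \eqn{u}, with decision times \eqn{\mathcal{T}_k}, treatments
#' \eqn{A_k}, follow-up \eqn{U}, and event indicator \eqn{\Delta}:
#' \itemize{
#'  \item the consistency indicator \eqn{C(u,d) = \prod_{k=1}^{\kappa}
#'    [I(\mathcal{T}_k > u) + I(\mathcal{T}_k \le u) I\{A_k =
#'    d_k(H_k)\}]} is 1 while every treatment received so far matches what
#'    the regime would have assigned;
#'  \item the regime propensity \eqn{\pi(u,d) = \prod_{k=1}^{\kappa}
#'    [I(\mathcal{T}_k > u) + I(\mathcal{T}_k \le u)\,\omega_k\{H_k,
#'    d_k(H_k)\}]} is the probability of that consistency;
#'  \item the weight \eqn{\Omega(u,d) = C(u,d)\, I(U \ge u) / \pi(u,d)}
#'    re-weights consistent at-risk subjects to represent the population
#'    following \eqn{d}.  Under censoring that is independent of the evolving
#'    history (possibly excepting stage-1 treatment), the censoring survival
#'    function cancels from the statistic and this weight is complete.
#' }
#' With \eqn{dN(u) = I(U = u, \Delta = 1)} and \eqn{Y(u) = I(U \ge u)}, the
#' pooled baseline hazard increment is
#' \eqn{d\hat\Lambda_0(u) = \sum_i\sum_j \Omega_i(u,d^j) dN_i(u) /
#' \sum_i\sum_j \Omega_i(u,d^j) Y_i(u)} and the score for regime \eqn{j}
#' (relative to the last regime, the reference) is
#' \eqn{\mathfrak{T}^j = \sum_i \int_0^L \Omega_i(u,d^j)\{dN_i(u) -
#' d\hat\Lambda_0(u) Y_i(u)\}}.  The scores are not sums of iid terms; the
#' per-subject influence approximation subtracts the risk-share
#' \eqn{\hat q(u,d^j)} weighted pooled residual, giving the sandwich
#' covariance \eqn{\hat\Sigma = n^{-1}\sum_i \hat{\mathfrak{T}}_i
#' \hat{\mathfrak{T}}_i^T} and the statistic \eqn{\mathbb{Z} = n^{-1}
#' \mathfrak{T}^T \hat\Sigma^{-} \mathfrak{T}}, referred to
#' \eqn{\chi^2_\nu} with \eqn{\nu = \mathrm{rank}(\hat\Sigma)}.
#'
#' @name glogrank_core
NULL

# Per-regime, per-stage assignment info: for each subject the option the
# regime assigns in the subject's stratum (NA when no rule applies -- which
# can only happen for subjects already inconsistent at an earlier stage),
# whether the received treatment matches, and the assignment probability.
regime_stage_info <- function(data, regimes, model) {
  n <- data$n; K <- data$K; D <- length(regimes)
  stratnames <- lapply(seq_len(K), function(k) {
    vapply(data$design$stages[[k]]$strata, `[[`, character(1), "name")
  })
  match_arr <- array(FALSE, c(n, K, D))
  omg_arr <- array(1, c(n, K, D))
  for (j in seq_len(D)) {
    for (k in seq_len(K)) {
      r <- regimes[[j]]$rules[[k]]
      lut <- rep(NA_character_, length(stratnames[[k]]))
      lut[match(names(r), stratnames[[k]])] <- unname(r)
      reached <- data$kappa >= k
      assign <- rep(NA_character_, n)
      si <- data$strat[, k]
      if (any(reached & is.na(si))) {
        stop("subject matches no stage-", k,
             " stratum; validate the data", call. = FALSE)
      }
      assign[reached] <- lut[si[reached]]
      ok <- reached & !is.na(assign)
      match_arr[ok, k, j] <- data$Amat[ok, k] == assign[ok]
      if (any(ok)) {
        om <- omega_stage(model, data, k, assign, which(ok))
        if (any(om[ok] <= 0, na.rm = TRUE)) {
          stop("positivity violation: assignment probability 0 for a reached stage",
               call. = FALSE)
        }
        omg_arr[ok, k, j] <- om[ok]
      }
    }
  }
  list(match = match_arr, omega = omg_arr)
}

# Evaluate Y, dN, and the weight matrices Omega_j over the event grid.
weights_eval <- function(data, regimes, model, grid) {
  n <- data$n; K <- data$K; D <- length(regimes); m <- length(grid)
  info <- regime_stage_info(data, regimes, model)
  Y <- outer(data$U, grid, ">=") * 1
  dN <- outer(data$U, grid, "==") * data$delta
  inforce <- lapply(seq_len(K), function(k) {
    tk <- data$Tmat[, k]
    tk[is.na(tk)] <- Inf           # unreached stage never in force
    outer(tk, grid, "<=")
  })
  Omega <- vector("list", D)
  for (j in seq_len(D)) {
    C <- matrix(TRUE, n, m)
    P <- matrix(1, n, m)
    for (k in seq_len(K)) {
      C <- C & (!inforce[[k]] | match_col(info$match[, k, j], m))
      P <- P * ifelse(inforce[[k]], info$omega[, k, j], 1)
    }
    O <- matrix(0, n, m)
    idx <- C & (Y > 0)
    O[idx] <- 1 / P[idx]
    Omega[[j]] <- O
  }
  list(Y = Y, dN = dN, Omega = Omega)
}

match_col <- function(v, m) matrix(v, nrow = length(v), ncol = m)

# Core computation shared by all user-facing entry points.
glr_fit_engine <- function(data, regimes, model, L) {
  D <- length(regimes)
  grid <- event_grid(data, L)
  w <- weights_eval(data, regimes, model, grid)
  n <- data$n; m <- length(grid)
  risk <- matrix(vapply(w$Omega, function(O) colSums(O * w$Y), numeric(m)),
                 nrow = m)
  evnt <- matrix(vapply(w$Omega, function(O) colSums(O * w$dN), numeric(m)),
                 nrow = m)
  den <- rowSums(risk)
  num <- rowSums(evnt)
  dLam <- ifelse(den > 0, num / den, 0)
  qmat <- sweep(risk, 1, ifelse(den > 0, den, 1), "/")  # m x D risk shares
  qmat[den <= 0, ] <- 0
  M <- w$dN - sweep(w$Y, 2, dLam, "*")
  resid <- lapply(w$Omega, function(O) O * M)   # per-regime residual mats
  svec <- vapply(resid[-D], sum, numeric(1))
  pooled <- Reduce(`+`, resid)
  own <- matrix(vapply(resid[-D], rowSums, numeric(n)), nrow = n)
  infl <- own - pooled %*% qmat[, -D, drop = FALSE]
  consistent_n <- vapply(w$Omega, function(O) sum(O[, 1] > 0), numeric(1))
  list(grid = grid, L = L, dLam = dLam, qmat = qmat, risk = risk,
       score = svec, influence = infl, consistent_n = consistent_n,
       n = n, D = D)
}

#' Consistency indicator \eqn{C(u, d)} for one subject
#'
#' @param data A \code{\link{smart_data}} object.
#' @param i Subject row index.
#' @param reg A \code{\link{regime}}.
#' @param u Time point (\code{u >= 0}).
#' @return 0 or 1.  Stages whose decision time exceeds \code{u}, or not
#'   reached by the subject, never break consistency.
#' @export
consistency_indicator <- function(data, i, reg, u) {
  stopifnot(inherits(data, "smart_data"), u >= 0)
  for (k in seq_len(data$kappa[i])) {
    if (is.na(data$Tmat[i, k]) || data$Tmat[i, k] > u) next
    si <- data$strat[i, k]
    if (is.na(si)) stop("subject matches no stage-", k, " stratum",
                        call. = FALSE)
    nm <- data$design$stages[[k]]$strata[[si]]$name
    if (!nm %in% names(reg$rules[[k]])) {
      stop(sprintf("regime '%s' has no stage-%d rule for stratum '%s'",
                   reg$label, k, nm), call. = FALSE)
    }
    if (data$Amat[i, k] != reg$rules[[k]][[nm]]) return(0)
  }
  1
}

#' Regime propensity \eqn{\pi(u, d)} for one subject
#'
#' The probability of receiving treatments consistent with the regime
#' through all decisions reached and in force by time \code{u}: the product
#' over such decisions of the assignment probability of the option the
#' regime assigns in the subject's stratum.
#'
#' @inheritParams consistency_indicator
#' @param model A \code{"glr_propensity"} model.
#' @return Probability in (0, 1].
#' @export
regime_propensity <- function(data, i, reg, u, model) {
  stopifnot(inherits(data, "smart_data"), u >= 0)
  p <- 1
  for (k in seq_len(data$kappa[i])) {
    if (is.na(data$Tmat[i, k]) || data$Tmat[i, k] > u) next
    si <- data$strat[i, k]
    nm <- data$design$stages[[k]]$strata[[si]]$name
    if (!nm %in% names(reg$rules[[k]])) {
      stop(sprintf("regime '%s' has no stage-%d rule for stratum '%s'",
                   reg$label, k, nm), call. = FALSE)
    }
    ok <- omega(model, data, i, k, reg$rules[[k]][[nm]])
    if (ok <= 0) stop("positivity violation: zero assignment probability",
                      call. = FALSE)
    p <- p * ok
  }
  p
}

#' IPW weight \eqn{\Omega(u, d)} for one subject
#'
#' \eqn{\Omega = C(u,d)\, I(U \ge u) / \pi(u,d)}: zero for subjects
#' inconsistent with the regime or no longer at risk; the propensity is not
#' evaluated (and cannot error) for such subjects.
#'
#' @inheritParams regime_propensity
#' @return Nonnegative weight.
#' @export
ipw_weight <- function(data, i, reg, u, model) {
  if (data$U[i] < u) return(0)
  if (consistency_indicator(data, i, reg, u) == 0) return(0)
  1 / regime_propensity(data, i, reg, u, model)
}

#' Pooled baseline cumulative-hazard increments
#'
#' At each event time \eqn{u \le L},
#' \eqn{d\hat\Lambda_0(u) = \sum_i\sum_j \Omega_i(u,d^j) dN_i(u) /
#' \sum_i\sum_j \Omega_i(u,d^j) Y_i(u)} with 0/0 defined as 0.  With a
#' single regime and unit weights this is the Nelson-Aalen estimator.
#'
#' @param data A \code{\link{smart_data}} object.
#' @param regimes List of \code{\link{regime}} objects (one or more).
#' @param model A \code{"glr_propensity"} model.
#' @param L Truncation time.
#' @return List with \code{grid} and \code{increments}.
#' @export
baseline_hazard <- function(data, regimes, model, L = Inf) {
  grid <- event_grid(data, L)
  w <- weights_eval(data, regimes, model, grid)
  num <- Reduce(`+`, lapply(w$Omega, function(O) colSums(O * w$dN)))
  den <- Reduce(`+`, lapply(w$Omega, function(O) colSums(O * w$Y)))
  list(grid = grid, increments = ifelse(den > 0, num / den, 0))
}

#' Score vector of the generalized logrank test
#'
#' \eqn{\mathfrak{T}^j = \sum_i \sum_{u \le L} \Omega_i(u,d^j)\{dN_i(u) -
#' d\hat\Lambda_0(u) Y_i(u)\}} for \eqn{j = 1, \ldots, D-1}; the last regime
#' in \code{regimes} is the reference.
#'
#' @inheritParams baseline_hazard
#' @return Named numeric vector of length \code{D - 1}.
#' @export
score_vector <- function(data, regimes, model, L = Inf) {
  stopifnot(length(regimes) >= 2L)
  eng <- glr_fit_engine(data, regimes, model, L)
  stats::setNames(eng$score,
                  vapply(regimes[-length(regimes)], `[[`, character(1),
                         "label"))
}

#' Per-subject influence contributions to the score vector
#'
#' The plug-in influence approximation
#' \eqn{\hat{\mathfrak{T}}^j_i = \sum_u \Omega_i(u,d^j)\{dN_i -
#' d\hat\Lambda_0 Y_i\} - \sum_{j'} \sum_u \Omega_i(u,d^{j'})\,
#' \hat q(u,d^j)\{dN_i - d\hat\Lambda_0 Y_i\}}, where \eqn{\hat q(u,d^j)}
#' is regime \eqn{j}'s share of the pooled weighted risk set.  Column sums
#' reproduce the score vector exactly.
#'
#' @inheritParams baseline_hazard
#' @return Numeric matrix, subjects by \code{D - 1}.
#' @export
influence_matrix <- function(data, regimes, model, L = Inf) {
  stopifnot(length(regimes) >= 2L)
  glr_fit_engine(data, regimes, model, L)$influence
}

#' Sandwich covariance estimate of the score vector
#'
#' \eqn{\hat\Sigma = n^{-1}\sum_i \hat{\mathfrak{T}}_i
#' \hat{\mathfrak{T}}_i^T}, with numerical rank determined by the eigenvalue
#' threshold \code{rank_tol} times the largest eigenvalue.  Some designs and
#' regime sets induce exact linear dependencies among the scores (regimes
#' sharing early-stage treatments), making \eqn{\hat\Sigma} singular; the
#' generalized-inverse quadratic form in \code{\link{gscore_test}} handles
#' this, with degrees of freedom equal to the rank.
#'
#' @param influence Influence matrix (subjects x D-1), possibly
#'   residual-adjusted.
#' @param rank_tol Relative eigenvalue threshold for the numerical rank.
#' @return Object of class \code{"glr_cov"}: \code{matrix}, \code{rank},
#'   \code{eigen}, \code{rank_tol}, and flags \code{corrected},
#'   \code{adjusted}.
#' @export
covariance_estimate <- function(influence, rank_tol = 1e-8) {
  influence <- as.matrix(influence)
  n <- nrow(influence)
  S <- crossprod(influence) / n
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lmax <- max(e$values, 0)
  rank <- if (lmax <= 0) 0L else sum(e$values > rank_tol * lmax)
  structure(list(matrix = S, rank = rank, eigen = e, rank_tol = rank_tol,
                 n = n, corrected = FALSE, adjusted = FALSE,
                 correction_factor = 1),
            class = "glr_cov")
}

#' Residual adjustment of the influence contributions
#'
#' Regresses each column of the influence matrix, without intercept, on the
#' supplied regressors (propensity-score contributions and/or mean-centered
#' functions of the history) and returns the residuals and their column
#' sums.  Because the ML score columns sum to zero, adjusting on them alone
#' leaves the score totals unchanged while shrinking the covariance -- this
#' is how estimation of the propensity parameters is taken into account, and
#' how outcome-associated covariates increase power.  Constant columns are
#' dropped before fitting; remaining rank deficiency is an error.
#'
#' @param influence Influence matrix (subjects x D-1).
#' @param regressors Numeric matrix of per-subject regressors.
#' @return List with \code{influence} (residuals), \code{score} (column sums
#'   of the residuals), \code{p} (number of regressor columns used), and
#'   \code{dropped} (names of dropped constant columns).
#' @export
residual_adjust <- function(influence, regressors) {
  influence <- as.matrix(influence)
  X <- as.matrix(regressors)
  if (is.null(colnames(X)) && ncol(X)) {
    colnames(X) <- paste0("r", seq_len(ncol(X)))
  }
  keep <- apply(X, 2, function(v) {
    max(v) - min(v) > 1e-12 * max(1, max(abs(v)))
  })
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) {
    return(list(influence = influence, score = colSums(influence), p = 0L,
                dropped = dropped))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear regressor column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res <- qr.resid(qx, influence)
  list(influence = res, score = colSums(res), p = ncol(X), dropped = dropped)
}

#' Small-sample covariance correction
#'
#' The sandwich covariance understates the variability of the score when
#' \code{n} is moderate, making the plain test anti-conservative.  The
#' implemented correction inflates the covariance by
#' \code{n / (n - p_eff)}, where \code{p_eff} counts the score dimension
#' \code{D - 1} plus the number of residual-regression columns; ranks are
#' unchanged and the corrected statistic is never larger than the
#' uncorrected one.
#'
#' @param cov A \code{"glr_cov"} object.
#' @param n Sample size.
#' @param p_eff Effective number of fitted quantities.
#' @return The corrected \code{"glr_cov"}.
#' @export
bias_correct <- function(cov, n, p_eff) {
  stopifnot(inherits(cov, "glr_cov"))
  if (n <= p_eff) stop("n must exceed p_eff for the correction",
                       call. = FALSE)
  f <- n / (n - p_eff)
  cov$matrix <- cov$matrix * f
  cov$eigen$values <- cov$eigen$values * f
  cov$corrected <- TRUE
  cov$correction_factor <- f
  cov
}

#' Generalized score test from a score vector and covariance
#'
#' \eqn{\mathbb{Z} = n^{-1} \mathfrak{T}^T \hat\Sigma^{-} \mathfrak{T}} with
#' the eigendecomposition pseudoinverse at the covariance's stored rank, and
#' p-value from the upper tail of \eqn{\chi^2_\nu}, \eqn{\nu =
#' \mathrm{rank}(\hat\Sigma)}.
#'
#' @param score Score vector (length D-1), plain or residual-adjusted.
#' @param cov A \code{"glr_cov"} object computed from the matching influence
#'   matrix.
#' @param n Sample size.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
gscore_test <- function(score, cov, n) {
  stopifnot(inherits(cov, "glr_cov"))
  score <- as.numeric(score)
  if (length(score) != nrow(cov$matrix)) {
    stop("score and covariance dimensions differ", call. = FALSE)
  }
  if (cov$rank == 0L) {
    warning("covariance has rank 0; statistic set to 0")
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  keep <- seq_len(cov$rank)
  proj <- drop(crossprod(cov$eigen$vectors[, keep, drop = FALSE], score))
  z <- sum(proj^2 / cov$eigen$values[keep]) / n
  z <- max(z, 0)
  list(statistic = z, df = cov$rank,
       p_value = stats::pchisq(z, df = cov$rank, lower.tail = FALSE))
}

# Build the default covariate-augmentation regressors: baseline covariates
# as-is, later-stage covariates multiplied by the indicator of reaching that
# stage with 0 imputed otherwise, all mean-centered.
augment_covariates <- function(data, cols = NULL) {
  if (is.null(cols) || isTRUE(cols)) cols <- data$covcols
  cols <- as.character(cols)
  if (!length(cols)) return(matrix(numeric(0), nrow = data$n, ncol = 0))
  out <- matrix(0, data$n, length(cols), dimnames = list(NULL, cols))
  for (ci in seq_along(cols)) {
    cl <- cols[ci]
    if (!cl %in% names(data$df)) stop("covariate column not found: ", cl,
                                      call. = FALSE)
    stg <- if (grepl("^x[0-9]+_", cl)) {
      as.integer(sub("^x([0-9]+)_.*$", "\\1", cl))
    } else 1L
    v <- as.numeric(data$df[[cl]])
    if (stg > 1L) {
      v[data$kappa < stg] <- 0
      v[is.na(v)] <- 0
    } else if (anyNA(v)) {
      stop("missing values in baseline covariate ", cl, call. = FALSE)
    }
    out[, ci] <- v - mean(v)
  }
  out
}

resolve_propensity <- function(propensity, data, covariate_spec) {
  if (inherits(propensity, "glr_propensity")) return(propensity)
  switch(match.arg(propensity, c("stratified", "known", "logistic")),
         known = propensity_known(data$design),
         stratified = propensity_stratified(data),
         logistic = propensity_logistic(data,
                                        covariate_spec = covariate_spec))
}

#' Generalized logrank-type test for a set of treatment regimes
#'
#' Runs the full test pipeline on observed SMART (or observational) data:
#' truncation-time selection, propensity fitting, IPW weights, pooled
#' baseline hazard, score vector, influence contributions, residual
#' adjustment (when propensities are estimated and/or covariates are
#' incorporated), small-sample covariance correction, and the
#' generalized-inverse chi-squared test.
#'
#' @param data A \code{\link{smart_data}} object.
#' @param regimes List of \code{\link{regime}} objects (\code{NULL} = all
#'   embedded regimes of the design).  The last regime is the reference;
#'   the statistic is invariant to which regime plays that role.
#' @param propensity \code{"stratified"} (default; estimated sample
#'   proportions, recommended for SMART data), \code{"known"} (design
#'   randomization probabilities), \code{"logistic"}, or a fitted
#'   \code{"glr_propensity"} object.
#' @param covariate_spec Passed to \code{\link{propensity_logistic}}.
#' @param adjust \code{FALSE} (default), \code{TRUE} (augment the residual
#'   regression with all covariate columns, centered, with later-stage
#'   covariates zero-imputed for subjects not reaching the stage), or a
#'   character vector of covariate columns.  Only covariates thought to be
#'   associated with the outcome should be included.
#' @param correction \code{"dof"} (default; inflate the covariance by
#'   \code{n / (n - p_eff)}) or \code{"none"}.
#' @param L Truncation time; \code{NULL} selects it via
#'   \code{\link{choose_truncation}}.
#' @param target_fraction Target at-risk fraction for automatic truncation.
#' @param rank_tol Relative eigenvalue threshold for the covariance rank.
#' @return Object of class \code{"glr_test"}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{score}, \code{covariance} (a \code{"glr_cov"}),
#'   \code{L}, \code{at_risk_fraction}, \code{n}, \code{regime_labels},
#'   \code{options}, and \code{diagnostics} (event grid, baseline-hazard
#'   increments, per-regime weighted at-risk curves and consistent-subject
#'   counts).
#' @examples
#' sc <- builtin_scenario("null_basic")
#' dat <- simulate_smart(sc, n = 300, seed = 1)
#' glr_test(dat)
#' @export
glr_test <- function(data, regimes = NULL, propensity = "stratified",
                     covariate_spec = NULL, adjust = FALSE,
                     correction = c("dof", "none"), L = NULL,
                     target_fraction = 0.02, rank_tol = 1e-8) {
  correction <- match.arg(correction)
  variant <- list(propensity = propensity, covariate_spec = covariate_spec,
                  adjust = adjust, correction = correction)
  glr_test_variants(data, regimes, list(test = variant), L = L,
                    target_fraction = target_fraction,
                    rank_tol = rank_tol)[[1]]
}

#' Run several test variants on one dataset
#'
#' Evaluates multiple configurations (propensity mode, covariate adjustment,
#' correction) on the same data, sharing the weight and influence
#' computations between variants with the same propensity mode.  Used by
#' \code{\link{rejection_rate}} to calibrate several statistics per
#' simulated replicate.
#'
#' @inheritParams glr_test
#' @param variants Named list; each element a list with entries
#'   \code{propensity}, \code{adjust}, \code{correction}, and optionally
#'   \code{covariate_spec} (see \code{\link{glr_test}} for defaults).
#' @return Named list of \code{"glr_test"} objects.
#' @export
glr_test_variants <- function(data, regimes = NULL, variants, L = NULL,
                              target_fraction = 0.02, rank_tol = 1e-8) {
  stopifnot(inherits(data, "smart_data"))
  if (is.null(regimes)) regimes <- enumerate_regimes(data$design)
  if (inherits(regimes, "smart_regime")) regimes <- list(regimes)
  if (length(regimes) < 2L) stop("need at least 2 regimes to compare",
                                 call. = FALSE)
  labels <- unique(vapply(regimes, `[[`, character(1), "label"))
  if (length(labels) != length(regimes)) {
    stop("regimes must be distinct", call. = FALSE)
  }
  at_risk <- NA_real_
  if (is.null(L)) {
    tr <- choose_truncation(data, target_fraction)
    L <- tr$L
    at_risk <- tr$at_risk_fraction
  } else {
    at_risk <- mean(data$U >= L)
  }
  D <- length(regimes)
  modekey <- vapply(variants, function(v) {
    pr <- v$propensity %||% "stratified"
    if (inherits(pr, "glr_propensity")) "object" else pr
  }, character(1))
  out <- vector("list", length(variants))
  names(out) <- names(variants)
  for (mk in unique(modekey)) {
    vidx <- which(modekey == mk)
    v1 <- variants[[vidx[1]]]
    model <- resolve_propensity(v1$propensity %||% "stratified", data,
                                v1$covariate_spec)
    eng <- glr_fit_engine(data, regimes, model, L)
    smat <- if (model$fitted) score_matrix(model, data) else
      matrix(numeric(0), nrow = data$n, ncol = 0)
    for (vi in vidx) {
      v <- variants[[vi]]
      adjust <- v$adjust %||% FALSE
      correction <- v$correction %||% "dof"
      regressors <- smat
      adjust_cols <- character(0)
      if (!isFALSE(adjust)) {
        cx <- augment_covariates(data, adjust)
        adjust_cols <- colnames(cx)
        regressors <- cbind(regressors, cx)
      }
      if (ncol(regressors) > 0L) {
        ra <- residual_adjust(eng$influence, regressors)
        score <- ra$score
        infl <- ra$influence
        p_reg <- ra$p
      } else {
        score <- eng$score
        infl <- eng$influence
        p_reg <- 0L
      }
      cov <- covariance_estimate(infl, rank_tol)
      cov$adjusted <- p_reg > 0L
      p_eff <- 0L
      if (correction == "dof") {
        p_eff <- (D - 1L) + p_reg
        cov <- bias_correct(cov, data$n, p_eff)
      }
      gt <- gscore_test(score, cov, data$n)
      out[[vi]] <- structure(list(
        statistic = gt$statistic, df = gt$df, p_value = gt$p_value,
        score = stats::setNames(score, vapply(regimes[-D], `[[`,
                                              character(1), "label")),
        covariance = cov, L = L, at_risk_fraction = at_risk, n = data$n,
        D = D,
        regime_labels = vapply(regimes, `[[`, character(1), "label"),
        reference = regimes[[D]]$label,
        options = list(propensity = model$mode, adjust = adjust_cols,
                       correction = correction, p_eff = p_eff,
                       p_gamma = model$param_count, rank_tol = rank_tol,
                       target_fraction = target_fraction),
        diagnostics = list(grid = eng$grid, dLambda0 = eng$dLam,
                           weighted_at_risk = eng$risk,
                           consistent_n = stats::setNames(
                             eng$consistent_n,
                             vapply(regimes, `[[`, character(1), "label")))),
        class = "glr_test")
    }
  }
  out
}

#' @export
print.glr_test <- function(x, digits = 4, ...) {
  cat("Generalized logrank-type test of equal hazards across regimes\n")
  cat(sprintf("  regimes: %d (reference: %s)\n", x$D, x$reference))
  cat(sprintf("  n = %d, truncation L = %s (%.1f%% at risk)\n", x$n,
              format(x$L, digits = digits), 100 * x$at_risk_fraction))
  cat(sprintf("  propensity = %s%s, correction = %s\n",
              x$options$propensity,
              if (length(x$options$adjust)) {
                paste0(", covariate-adjusted (",
                       paste(x$options$adjust, collapse = ", "), ")")
              } else "",
              x$options$correction))
  cat(sprintf("  Z = %s on %d df, p = %s\n",
              format(x$statistic, digits = digits), x$df,
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}
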