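#' Treatment-assignment probability models
#'
#' The IPW weights of the generalized logrank test require the
#' treatment-assignment probabilities \eqn{\omega_k(h_k, a_k)}: the
#' probability that a subject with history \eqn{h_k} who reached decision
#' \eqn{k} received option \eqn{a_k}.  Three modes are supported:
#' \describe{
#'   \item{known}{the randomization probabilities declared in the design,
#'     used verbatim (no parameters).}
#'   \item{stratified ML}{saturated maximum-likelihood estimates: within each
#'     feasibility stratum the estimated probability of an option is the
#'     sample proportion of subjects in that stratum assigned the option.
#'     Counterintuitively, using these estimates (with the estimation
#'     accounted for via residual adjustment) yields a more powerful test
#'     than using the known probabilities.}
#'   \item{logistic}{per-stratum logistic regression on history covariates,
#'     for observational data; restricted to binary feasible subsets.}
#' }
#'
#' @param design A \code{\link{smart_design}}.
#' @param data A \code{\link{smart_data}} object.
#' @param covariate_spec For \code{propensity_logistic}, a list of length
#'   \code{K}; element \code{k} is a character vector of covariate columns
#'   entering the stage-\code{k} linear predictor (\code{NULL} =
#'   intercept-only).
#' @return An object of class \code{"glr_propensity"}.
#' @name propensity
NULL

new_propensity <- function(mode, design, tables, fits = NULL,
                           param_count = 0L, param_names = character(0)) {
  structure(list(mode = mode, design = design, tables = tables, fits = fits,
                 param_count = param_count, param_names = param_names,
                 fitted = mode != "known"),
            class = "glr_propensity")
}

#' @rdname propensity
#' @export
propensity_known <- function(design) {
  stop_if_invalid(design)
  tables <- lapply(design$stages, function(st) lapply(st$strata, `[[`, "probs"))
  new_propensity("known", design, tables)
}

#' @rdname propensity
#' @export
propensity_stratified <- function(data, design = data$design) {
  stopifnot(inherits(data, "smart_data"))
  tables <- vector("list", design$K)
  pnames <- character(0)
  p <- 0L
  for (k in seq_len(design$K)) {
    strata <- design$stages[[k]]$strata
    tables[[k]] <- vector("list", length(strata))
    for (si in seq_along(strata)) {
      s <- strata[[si]]
      in_s <- which(data$kappa >= k & !is.na(data$strat[, k]) &
                    data$strat[, k] == si)
      if (!length(in_s)) {
        tables[[k]][[si]] <- NULL   # stratum never reached; never queried
        next
      }
      cnt <- vapply(s$feasible, function(a) sum(data$Amat[in_s, k] == a),
                    numeric(1))
      if (any(cnt == 0) && length(s$feasible) > 1L) {
        stop(sprintf(
          "stage %d stratum '%s': option '%s' assigned to no subject (degenerate ML fit)",
          k, s$name, s$feasible[which(cnt == 0)[1]]), call. = FALSE)
      }
      tables[[k]][[si]] <- cnt / sum(cnt)
      if (length(s$feasible) > 1L) {
        nonref <- s$feasible[-length(s$feasible)]
        p <- p + length(nonref)
        pnames <- c(pnames, sprintf("g%d.%s.%s", k, s$name, nonref))
      }
    }
  }
  new_propensity("stratified_ml", design, tables, param_count = p,
                 param_names = pnames)
}

#' @rdname propensity
#' @export
propensity_logistic <- function(data, design = data$design,
                                covariate_spec = NULL) {
  stopifnot(inherits(data, "smart_data"))
  if (is.null(covariate_spec)) covariate_spec <- vector("list", design$K)
  fits <- vector("list", design$K)
  pnames <- character(0)
  p <- 0L
  for (k in seq_len(design$K)) {
    strata <- design$stages[[k]]$strata
    fits[[k]] <- vector("list", length(strata))
    for (si in seq_along(strata)) {
      s <- strata[[si]]
      if (length(s$feasible) == 1L) next
      if (length(s$feasible) > 2L) {
        stop("logistic mode supports binary feasible subsets only",
             call. = FALSE)
      }
      in_s <- which(data$kappa >= k & !is.na(data$strat[, k]) &
                    data$strat[, k] == si)
      if (!length(in_s)) next
      cols <- covariate_spec[[k]]
      X <- cbind(`(Intercept)` = rep(1, length(in_s)))
      if (length(cols)) {
        for (cl in cols) {
          if (!cl %in% names(data$df)) stop("covariate column not found: ",
                                            cl, call. = FALSE)
          X <- cbind(X, as.numeric(data$df[[cl]][in_s]))
          colnames(X)[ncol(X)] <- cl
        }
      }
      y <- as.numeric(data$Amat[in_s, k] == s$feasible[1])
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial(),
                       control = list(epsilon = 1e-12, maxit = 100)))
      if (!fit$converged || any(abs(fit$coefficients) > 15)) {
        stop(sprintf(
          "stage %d stratum '%s': logistic fit did not converge (separation?)",
          k, s$name), call. = FALSE)
      }
      fits[[k]][[si]] <- list(coef = fit$coefficients, cols = cols,
                              target = s$feasible[1])
      p <- p + ncol(X)
      pnames <- c(pnames, sprintf("g%d.%s.%s", k, s$name, colnames(X)))
    }
  }
  new_propensity("logistic", data$design, tables = NULL, fits = fits,
                 param_count = p, param_names = pnames)
}

logistic_prob <- function(model, data, k, si, rows, option) {
  f <- model$fits[[k]][[si]]
  s <- model$design$stages[[k]]$strata[[si]]
  if (is.null(f)) {
    if (length(s$feasible) == 1L) {
      return(as.numeric(option == s$feasible))
    }
    stop(sprintf("stage %d stratum '%s': no logistic fit available", k,
                 s$name), call. = FALSE)
  }
  X <- cbind(1, if (length(f$cols)) {
    as.matrix(as.data.frame(lapply(f$cols, function(cl) {
      as.numeric(data$df[[cl]][rows])
    })))
  })
  pt <- stats::plogis(drop(X %*% f$coef))
  ifelse(option == f$target, pt,
         ifelse(option %in% s$feasible, 1 - pt, 0))
}

# Vectorized assignment probabilities at one stage: for each subject row in
# `rows` (all with kappa >= k and known stratum), the probability of the
# option in `options[rows]`.
omega_stage <- function(model, data, k, options, rows) {
  out <- rep(NA_real_, data$n)
  strata <- model$design$stages[[k]]$strata
  for (si in unique(data$strat[rows, k])) {
    rs <- rows[data$strat[rows, k] == si]
    s <- strata[[si]]
    if (model$mode == "logistic") {
      out[rs] <- logistic_prob(model, data, k, si, rs, options[rs])
    } else {
      tab <- model$tables[[k]][[si]]
      if (is.null(tab)) {
        stop(sprintf("stage %d stratum '%s': no fitted probabilities (stratum unseen at fit time)",
                     k, s$name), call. = FALSE)
      }
      pr <- tab[options[rs]]
      pr[is.na(pr)] <- 0
      out[rs] <- pr
    }
  }
  out
}

#' Assignment probability for one subject, stage, and option
#'
#' @param model A \code{\link{propensity_known}},
#'   \code{\link{propensity_stratified}}, or
#'   \code{\link{propensity_logistic}} model.
#' @param data A \code{\link{smart_data}} object.
#' @param i Subject row index.
#' @param k Stage index; the subject must have reached stage \code{k}.
#' @param option Treatment option label.  Querying an infeasible option
#'   returns 0 with a warning.
#' @return Probability in \code{[0, 1]}.
#' @export
omega <- function(model, data, i, k, option) {
  stopifnot(inherits(model, "glr_propensity"), inherits(data, "smart_data"))
  if (data$kappa[i] < k) stop("subject did not reach stage ", k,
                              call. = FALSE)
  si <- data$strat[i, k]
  if (is.na(si)) stop("subject matches no stage-", k, " stratum",
                      call. = FALSE)
  feas <- model$design$stages[[k]]$strata[[si]]$feasible
  option <- as.character(option)
  if (!option %in% feas) {
    warning(sprintf("option '%s' infeasible in stratum '%s'; probability 0",
                    option, model$design$stages[[k]]$strata[[si]]$name))
    return(0)
  }
  opts <- rep(option, data$n)
  omega_stage(model, data, k, opts, i)[i]
}

#' Per-subject maximum-likelihood score contributions
#'
#' Returns the matrix of per-subject contributions to the score (gradient of
#' the log-likelihood) of the fitted propensity parameters, one column per
#' parameter.  For the stratified ML model, the contribution of subject
#' \code{i} to the column for (stage k, stratum s, non-reference option a) is
#' \eqn{I(\text{subject in } s \text{ at } k)\{I(A_k = a) -
#' \hat\omega_k(s,a)\}}; for the logistic model it is the usual Bernoulli
#' score \eqn{x_i\{I(A_k = a) - p_i\}}.  Column sums vanish at the ML fit.
#' These contributions are the regressors of the residual-adjustment step
#' that accounts for propensity estimation.
#'
#' @param model A fitted \code{"glr_propensity"} (not \code{known} mode).
#' @param data A \code{\link{smart_data}} object (the fitting data).
#' @return Numeric matrix (subjects x parameters) with named columns.
#' @export
score_matrix <- function(model, data) {
  stopifnot(inherits(model, "glr_propensity"), inherits(data, "smart_data"))
  if (model$mode == "known") {
    stop("known-probability model has no parameters", call. = FALSE)
  }
  cols <- list()
  for (k in seq_len(model$design$K)) {
    strata <- model$design$stages[[k]]$strata
    for (si in seq_along(strata)) {
      s <- strata[[si]]
      if (length(s$feasible) == 1L) next
      in_s <- data$kappa >= k & !is.na(data$strat[, k]) & data$strat[, k] == si
      if (!any(in_s)) next
      if (model$mode == "stratified_ml") {
        tab <- model$tables[[k]][[si]]
        for (a in s$feasible[-length(s$feasible)]) {
          v <- numeric(data$n)
          v[in_s] <- (data$Amat[in_s, k] == a) - tab[[a]]
          cols[[sprintf("g%d.%s.%s", k, s$name, a)]] <- v
        }
      } else {
        f <- model$fits[[k]][[si]]
        rs <- which(in_s)
        pt <- logistic_prob(model, data, k, si, rs, rep(f$target, data$n)[rs])
        y <- as.numeric(data$Amat[rs, k] == f$target)
        X <- cbind(`(Intercept)` = 1, if (length(f$cols)) {
          as.matrix(as.data.frame(lapply(f$cols, function(cl) {
            as.numeric(data$df[[cl]][rs])
          })))
        })
        if (length(f$cols)) colnames(X) <- c("(Intercept)", f$cols)
        for (ci in seq_len(ncol(X))) {
          v <- numeric(data$n)
          v[rs] <- X[, ci] * (y - pt)
          cols[[sprintf("g%d.%s.%s", k, s$name, colnames(X)[ci])]] <- v
        }
      }
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = data$n, ncol = 0))
  }
  do.call(cbind, cols)
}

#' @export
print.glr_propensity <- function(x, ...) {
  cat(sprintf("propensity model: mode = %s, %d parameter(s)\n", x$mode,
              x$param_count))
  invisible(x)
}
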