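#' Assemble observed SMART data
#'
#' Builds the observed-data container for \code{n} subjects from a wide data
#' frame.  Per subject the observed data are: the number of decision points
#' reached \code{kappa}, decision times \code{t1..tK} (with \code{t1 = 0}),
#' treatments \code{a1..aK}, follow-up time \code{u} (event or censoring,
#' whichever first), event indicator \code{delta} (1 = event), and covariate
#' columns.  Covariate columns follow the convention \code{x<k>_<name>} for
#' information collected between decisions \code{k-1} and \code{k}; any other
#' column name is treated as baseline.  Stage-\code{k} fields are \code{NA}
#' for subjects with \code{kappa < k}.
#'
#' Structural invariants are enforced: \code{0 = t1 < t2 < ... < t_kappa <=
#' u}, \code{delta} in \{0, 1\}, treatments populated exactly for the stages
#' reached.  Each subject is matched to a feasibility stratum at every stage
#' reached by comparing the design's stratum key features with the subject's
#' prior treatments and covariates.
#'
#' @param df Data frame in the wide layout above.
#' @param design The \code{\link{smart_design}} the data come from.
#' @return An object of class \code{"smart_data"} with elements \code{df}
#'   (canonicalized), \code{design}, \code{n}, \code{K}, \code{U},
#'   \code{delta}, \code{kappa}, \code{Tmat}, \code{Amat} (n x K), and
#'   \code{strat} (n x K stratum indices, \code{NA} where unreached or
#'   unmatched).
#' @export
smart_data <- function(df, design) {
  stop_if_invalid(design)
  df <- as.data.frame(df)
  K <- design$K
  n <- nrow(df)
  if (n < 1L) stop("dataset is empty", call. = FALSE)
  need <- c("kappa", "u", "delta", paste0("a", seq_len(K)))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"t1" %in% names(df)) df$t1 <- 0
  for (k in seq_len(K)) {
    tk <- paste0("t", k)
    if (!tk %in% names(df)) df[[tk]] <- NA_real_
    if (!is.numeric(df[[tk]]) && !all(is.na(df[[tk]]))) {
      stop("non-numeric decision time column ", tk, call. = FALSE)
    }
    df[[tk]] <- as.numeric(df[[tk]])
  }
  if (!"id" %in% names(df)) df$id <- seq_len(n)
  kappa <- as.integer(df$kappa)
  U <- as.numeric(df$u)
  delta <- as.numeric(df$delta)
  if (any(is.na(kappa)) || any(kappa < 1L) || any(kappa > K)) {
    stop("kappa must be an integer in 1..K for every subject", call. = FALSE)
  }
  if (any(is.na(U)) || any(U < 0)) stop("non-numeric or negative follow-up",
                                        call. = FALSE)
  if (!all(delta %in% c(0, 1))) stop("delta must be 0 or 1", call. = FALSE)

  Tmat <- as.matrix(df[paste0("t", seq_len(K))])
  Amat <- matrix(NA_character_, n, K)
  for (k in seq_len(K)) Amat[, k] <- as.character(df[[paste0("a", k)]])
  Amat[Amat %in% c("", "NA")] <- NA_character_

  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("row %s: %s", paste(utils::head(i, 5), collapse = ","),
                   msg), call. = FALSE)
    }
  }
  bad_row(abs(Tmat[, 1]) > 0 | is.na(Tmat[, 1]), "t1 must equal 0")
  for (k in seq_len(K)) {
    reached <- kappa >= k
    bad_row(reached & is.na(Amat[, k]),
            sprintf("a%d missing for a subject with kappa >= %d", k, k))
    bad_row(!reached & !is.na(Amat[, k]),
            sprintf("a%d populated but kappa < %d", k, k))
    bad_row(!reached & !is.na(Tmat[, k]) & k > 1L,
            sprintf("t%d populated but kappa < %d", k, k))
    if (k > 1L) {
      bad_row(reached & (is.na(Tmat[, k]) | Tmat[, k] <= Tmat[, k - 1]),
              "decision times not increasing")
    }
    bad_row(reached & !is.na(Tmat[, k]) & Tmat[, k] > U,
            sprintf("t%d exceeds follow-up time", k))
  }

  covcols <- setdiff(names(df), c("id", "kappa", "u", "delta",
                                  paste0("t", seq_len(K)),
                                  paste0("a", seq_len(K))))
  strat <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    reached <- which(kappa >= k)
    strat[reached, k] <- match_stratum(design, k, df[reached, , drop = FALSE],
                                       Amat[reached, , drop = FALSE])
  }

  structure(list(df = df, design = design, n = n, K = K, U = U,
                 delta = delta, kappa = kappa, Tmat = Tmat, Amat = Amat,
                 strat = strat, covcols = covcols),
            class = "smart_data")
}

# Match each subject (rows of df/Amat) to the first declared stratum at
# stage k whose key features all hold.  Returns integer indices, NA if no
# stratum matches.
match_stratum <- function(design, k, df, Amat) {
  strata <- design$stages[[k]]$strata
  n <- nrow(df)
  out <- rep(NA_integer_, n)
  for (si in seq_along(strata)) {
    s <- strata[[si]]
    ok <- rep(TRUE, n)
    for (nm in names(s$key)) {
      vals <- s$key[[nm]]
      subj <- if (is_trt_feature(nm)) {
        j <- trt_feature_stage(nm)
        if (j > ncol(Amat)) stop("stratum key refers to stage ", j,
                                 " treatment beyond design", call. = FALSE)
        Amat[, j]
      } else {
        if (!nm %in% names(df)) {
          stop(sprintf("stage %d stratum '%s': key feature '%s' not a data column",
                       k, s$name, nm), call. = FALSE)
        }
        df[[nm]]
      }
      ok <- ok & !is.na(subj) & (as.character(subj) %in% as.character(vals))
    }
    out[is.na(out) & ok] <- si
  }
  out
}

#' Read observed SMART data from a wide CSV file
#'
#' @param path Path to a CSV file with columns \code{kappa, t1..tK, a1..aK,
#'   u, delta} and covariate columns; stage-\code{k} fields blank for
#'   subjects who did not reach decision \code{k}.
#' @param design The \code{\link{smart_design}}.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, for files using different headers.
#' @return A \code{\link{smart_data}} object.
#' @export
read_smart_data <- function(path, design, schema = NULL) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(df))
      if (is.na(idx)) stop("schema column not in file: ", schema[[canon]],
                           call. = FALSE)
      names(df)[idx] <- canon
    }
  }
  smart_data(df, design)
}

#' Validate observed SMART data against the design
#'
#' Checks feasibility of every received treatment given the subject's
#' feasibility stratum, flags subjects whose history matches no declared
#' stratum, and, if a regime set is supplied, warns about regimes with which
#' no subject's full treatment experience is consistent (a positivity
#' diagnostic).
#'
#' @param data A \code{\link{smart_data}} object.
#' @param regimes Optional list of \code{\link{regime}} objects.
#' @return Character vector of violation/warning messages; empty if clean.
#' @export
validate_data <- function(data, regimes = NULL) {
  stopifnot(inherits(data, "smart_data"))
  out <- character(0)
  design <- data$design
  for (k in seq_len(data$K)) {
    reached <- which(data$kappa >= k)
    for (i in reached) {
      si <- data$strat[i, k]
      if (is.na(si)) {
        out <- c(out, sprintf(
          "subject %s: history matches no stage-%d stratum",
          data$df$id[i], k))
        next
      }
      feas <- design$stages[[k]]$strata[[si]]$feasible
      if (!data$Amat[i, k] %in% feas) {
        out <- c(out, sprintf(
          "subject %s: stage-%d treatment '%s' outside feasible set {%s} of stratum '%s'",
          data$df$id[i], k, data$Amat[i, k], paste(feas, collapse = ","),
          design$stages[[k]]$strata[[si]]$name))
      }
    }
  }
  if (!is.null(regimes)) {
    for (j in seq_along(regimes)) {
      cons <- vapply(seq_len(data$n), function(i) {
        consistency_indicator(data, i, regimes[[j]], data$U[i])
      }, numeric(1))
      if (!any(cons > 0)) {
        out <- c(out, sprintf("regime '%s': no consistent subjects",
                              regimes[[j]]$label))
      }
    }
  }
  out
}

#' Distinct event times up to a truncation time
#'
#' @param data A \code{\link{smart_data}} object.
#' @param L Truncation time (default: no truncation).
#' @return Strictly increasing vector of the distinct observed event times
#'   \code{<= L}.
#' @export
event_grid <- function(data, L = Inf) {
  stopifnot(inherits(data, "smart_data"), L > 0)
  tt <- sort(unique(data$U[data$delta == 1 & data$U <= L]))
  if (!length(tt)) stop("no events before truncation time", call. = FALSE)
  tt
}

#' Choose the truncation time of the score integral
#'
#' Late event times, where few subjects remain at risk (and fewer still are
#' consistent with any particular regime), can exert undue influence on the
#' test statistic.  The integral is therefore truncated at the largest
#' observed event time \code{L} at which at least \code{target_fraction} of
#' subjects remain at risk; a target of 1\%-4\% is the recommended range,
#' with 2\% the default.
#'
#' @param data A \code{\link{smart_data}} object.
#' @param target_fraction Minimum fraction of subjects at risk at \code{L}.
#' @return A list with \code{L} and the achieved \code{at_risk_fraction}.
#' @export
choose_truncation <- function(data, target_fraction = 0.02) {
  stopifnot(inherits(data, "smart_data"),
            target_fraction > 0, target_fraction < 1)
  tt <- event_grid(data)
  frac <- vapply(tt, function(t) mean(data$U >= t), numeric(1))
  ok <- which(frac >= target_fraction)
  if (!length(ok)) {
    stop("no event time has the target at-risk fraction", call. = FALSE)
  }
  L <- tt[max(ok)]
  list(L = L, at_risk_fraction = mean(data$U >= L))
}

#' @export
print.smart_data <- function(x, ...) {
  cat(sprintf("smart_data: %d subjects, %d decision point(s), %d events (%.1f%% censored)\n",
              x$n, x$K, sum(x$delta == 1), 100 * mean(x$delta == 0)))
  cat(sprintf("  design: %s\n", x$design$label))
  cat(sprintf("  reached stage counts: %s\n",
              paste(sprintf("k>=%d: %d", seq_len(x$K),
                            vapply(seq_len(x$K),
                                   function(k) sum(x$kappa >= k), integer(1))),
                    collapse = ", ")))
  invisible(x)
}
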