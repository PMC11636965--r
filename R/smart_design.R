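#' Construct a feasibility stratum
#'
#' A feasibility stratum classifies the histories that can be present at a
#' decision point and declares which treatment options are feasible for
#' subjects in that class, together with the randomization probabilities over
#' the feasible subset.
#'
#' @param key Named list of history features identifying the stratum.  A
#'   feature named \code{a1}, \code{a2}, ... refers to the treatment received
#'   at that earlier decision; any other name refers to a covariate column of
#'   the data (for example a response indicator recorded between decisions).
#'   A feature value may be a vector, in which case membership is "value in
#'   set".  An empty key matches every history (a single stratum for the
#'   whole stage).
#' @param feasible Character (or coercible) vector of feasible option labels,
#'   a nonempty subset of the stage's option set.
#' @param probs Randomization probabilities over \code{feasible}; strictly
#'   positive and summing to 1.  Defaults to uniform.
#' @param name Display name; derived from \code{key} if omitted.
#'
#' @return An object of class \code{"glr_stratum"}.
#' @export
feasibility_stratum <- function(key = list(), feasible, probs = NULL,
                                name = NULL) {
  feasible <- as.character(feasible)
  if (is.null(probs)) probs <- rep(1 / length(feasible), length(feasible))
  key <- lapply(key, function(v) v)
  if (is.null(name)) {
    name <- if (length(key) == 0L) "all" else
      paste(vapply(seq_along(key), function(i) {
        paste0(names(key)[i], "=", paste(key[[i]], collapse = "|"))
      }, character(1)), collapse = ",")
  }
  structure(list(key = key, feasible = feasible,
                 probs = stats::setNames(as.numeric(probs), feasible),
                 name = name),
            class = "glr_stratum")
}

#' Construct a decision stage
#'
#' @param options Character (or coercible) vector of all treatment option
#'   labels available at this decision point.
#' @param strata List of \code{\link{feasibility_stratum}} objects declaring
#'   the feasibility strata at this stage, in a fixed order that also fixes
#'   the ordering of enumerated regimes.
#'
#' @return An object of class \code{"glr_stage"}.
#' @export
smart_stage <- function(options, strata) {
  if (inherits(strata, "glr_stratum")) strata <- list(strata)
  structure(list(options = as.character(options), strata = strata),
            class = "glr_stage")
}

#' Construct a SMART design
#'
#' Represents a sequential multiple assignment randomized trial design: the
#' number of decision points, the treatment option set at each, the
#' feasibility strata (classes of history for which different subsets of
#' options are feasible), and the randomization probabilities within each
#' stratum.
#'
#' @param stages List of \code{\link{smart_stage}} objects, one per decision
#'   point in order.
#' @param label Optional display name.
#'
#' @return An object of class \code{"smart_design"} with elements \code{K},
#'   \code{stages}, and \code{label}.
#' @seealso \code{\link{validate_design}}, \code{\link{enumerate_regimes}}
#' @export
smart_design <- function(stages, label = NULL) {
  if (inherits(stages, "glr_stage")) stages <- list(stages)
  stopifnot(length(stages) >= 1L)
  structure(list(K = length(stages), stages = stages,
                 label = label %||% "SMART design"),
            class = "smart_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a SMART design
#'
#' Checks the design invariants: distinct option labels within each stage,
#' every feasible subset nonempty and contained in the stage's option set,
#' and per-stratum randomization probabilities strictly positive and summing
#' to one (positivity).
#'
#' @param design A \code{\link{smart_design}}.
#' @return Character vector of violation messages; empty if the design is
#'   well formed.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "smart_design"))
  out <- character(0)
  for (k in seq_len(design$K)) {
    st <- design$stages[[k]]
    if (anyDuplicated(st$options)) {
      out <- c(out, sprintf("stage %d: duplicated option labels", k))
    }
    if (length(st$strata) == 0L) {
      out <- c(out, sprintf("stage %d: no feasibility strata declared", k))
    }
    for (s in st$strata) {
      tag <- sprintf("stage %d stratum '%s'", k, s$name)
      if (length(s$feasible) == 0L) {
        out <- c(out, paste0(tag, ": empty feasible subset"))
        next
      }
      if (!all(s$feasible %in% st$options)) {
        out <- c(out, sprintf(
          "%s: feasible options {%s} not all in stage option set", tag,
          paste(setdiff(s$feasible, st$options), collapse = ",")))
      }
      if (anyDuplicated(s$feasible)) {
        out <- c(out, paste0(tag, ": duplicated feasible options"))
      }
      if (length(s$probs) != length(s$feasible) || any(s$probs <= 0)) {
        out <- c(out, paste0(tag, ": probabilities must be strictly positive",
                             " over the feasible subset"))
      } else if (abs(sum(s$probs) - 1) > 1e-8) {
        out <- c(out, sprintf("%s: probabilities sum to %.6g != 1", tag,
                              sum(s$probs)))
      }
    }
  }
  out
}

stop_if_invalid <- function(design) {
  v <- validate_design(design)
  if (length(v)) {
    stop("invalid design:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(design)
}

# Treatment key features are names of the form "a<k>"; everything else is a
# covariate feature.
is_trt_feature <- function(nm) grepl("^a[0-9]+$", nm)
trt_feature_stage <- function(nm) as.integer(sub("^a", "", nm))

# Strata at stage k reachable under a partial regime, given the set of
# options the regime can assign at each earlier stage.  A stratum is
# reachable iff each of its treatment key features intersects the assignable
# set at that stage; covariate features never restrict reachability.
reachable_strata <- function(design, k, possible) {
  st <- design$stages[[k]]$strata
  keep <- vapply(st, function(s) {
    for (nm in names(s$key)) {
      if (is_trt_feature(nm)) {
        j <- trt_feature_stage(nm)
        if (j < k) {
          if (!length(intersect(as.character(s$key[[nm]]), possible[[j]]))) {
            return(FALSE)
          }
        }
      }
    }
    TRUE
  }, logical(1))
  which(keep)
}

#' Construct a treatment regime
#'
#' A regime is a rule table: for each stage, a named map from stratum name to
#' the feasible option the regime assigns there.  Only strata reachable under
#' the regime's earlier rules need rules.
#'
#' @param design The \code{\link{smart_design}} the regime belongs to.
#' @param rules List of length \code{design$K}; element \code{k} is a named
#'   character vector mapping stratum names (as in the design) to assigned
#'   option labels.
#' @param label Optional display label; derived from the rules if omitted.
#'
#' @return An object of class \code{"smart_regime"}.
#' @export
regime <- function(design, rules, label = NULL) {
  stop_if_invalid(design)
  stopifnot(length(rules) == design$K)
  rules <- lapply(seq_len(design$K), function(k) {
    r <- rules[[k]]
    if (length(r) == 0L) return(stats::setNames(character(0), character(0)))
    r <- stats::setNames(as.character(r), names(r))
    strata_names <- vapply(design$stages[[k]]$strata, `[[`, character(1),
                           "name")
    for (nm in names(r)) {
      idx <- match(nm, strata_names)
      if (is.na(idx)) {
        stop(sprintf("stage %d: unknown stratum '%s' in rule table", k, nm),
             call. = FALSE)
      }
      feas <- design$stages[[k]]$strata[[idx]]$feasible
      if (!r[[nm]] %in% feas) {
        stop(sprintf(
          "stage %d stratum '%s': rule output '%s' not in feasible set {%s}",
          k, nm, r[[nm]], paste(feas, collapse = ",")), call. = FALSE)
      }
    }
    r
  })
  if (is.null(label)) {
    label <- paste(vapply(seq_len(design$K), function(k) {
      r <- rules[[k]]
      if (!length(r)) return("-")
      paste(paste0(names(r), ":", unname(r)), collapse = ",")
    }, character(1)), collapse = " | ")
  }
  structure(list(rules = rules, K = design$K, design_label = design$label,
                 label = label),
            class = "smart_regime")
}

#' Enumerate the embedded regimes of a SMART design
#'
#' Produces the full set of regimes implied by the design: one feasible
#' choice per reachable, non-absorbed feasibility stratum per stage.  A
#' stage-\code{k} stratum multiplies the choices only for regimes whose
#' earlier rules can produce a history matching the stratum's treatment key
#' features; strata that are unreachable under a given set of earlier rules
#' contribute no rule (and no multiplicity) to that regime.  The ordering is
#' deterministic and lexicographic: stages outermost, then declared stratum
#' order, then declared option order, with earlier strata varying slowest.
#'
#' @param design A valid \code{\link{smart_design}}.
#' @return List of \code{\link{regime}} objects.
#' @export
enumerate_regimes <- function(design) {
  stop_if_invalid(design)
  K <- design$K
  expand_stage <- function(k, rules_so_far, possible) {
    if (k > K) {
      return(list(regime(design, rules_so_far)))
    }
    idx <- reachable_strata(design, k, possible)
    strata <- design$stages[[k]]$strata[idx]
    # all combinations of one feasible option per reachable stratum; first
    # stratum varies slowest
    combos <- list(stats::setNames(character(0), character(0)))
    for (s in strata) {
      combos <- unlist(lapply(combos, function(cmb) {
        lapply(s$feasible, function(opt) {
          c(cmb, stats::setNames(opt, s$name))
        })
      }), recursive = FALSE)
    }
    out <- list()
    for (cmb in combos) {
      out <- c(out, expand_stage(
        k + 1L, c(rules_so_far, list(cmb)),
        c(possible, list(unique(unname(cmb))))))
    }
    out
  }
  expand_stage(1L, list(), list())
}

#' Treatment assigned by a regime in a given stratum
#'
#' @param reg A \code{\link{regime}}.
#' @param k Stage (decision point) index.
#' @param stratum Stratum name, as declared in the design.
#' @param absorbed If \code{TRUE}, the history indicates the event has
#'   already occurred, the feasible set is empty, and no selection is made.
#' @return The assigned option label, or \code{NA_character_} for an
#'   absorbed stratum.
#' @export
assigned_treatment <- function(reg, k, stratum, absorbed = FALSE) {
  stopifnot(inherits(reg, "smart_regime"), k >= 1L, k <= reg$K)
  if (absorbed) return(NA_character_)
  r <- reg$rules[[k]]
  if (!stratum %in% names(r)) {
    stop(sprintf("stage %d: no rule for stratum '%s'", k, stratum),
         call. = FALSE)
  }
  unname(r[[stratum]])
}

#' @export
print.smart_design <- function(x, ...) {
  cat(sprintf("%s: %d decision point(s)\n", x$label, x$K))
  for (k in seq_len(x$K)) {
    st <- x$stages[[k]]
    cat(sprintf("  stage %d, options {%s}\n", k,
                paste(st$options, collapse = ",")))
    for (s in st$strata) {
      cat(sprintf("    %-24s feasible {%s}  probs (%s)\n", s$name,
                  paste(s$feasible, collapse = ","),
                  paste(format(s$probs, digits = 3), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
print.smart_regime <- function(x, ...) {
  cat("regime:", x$label, "\n")
  invisible(x)
}

#' @export
format.smart_regime <- function(x, ...) x$label

#' Read a SMART design from a YAML or JSON configuration file
#'
#' The configuration has a top-level \code{label} (optional) and a
#' \code{stages} list; each stage has \code{options} and \code{strata}, each
#' stratum having \code{key} (named map, possibly empty), \code{feasible},
#' and optional \code{probs} (default uniform).  See the packaged example
#' \code{system.file("extdata", "design_response8.yaml", package =
#' "glogrank")}.
#'
#' @param path Path to the configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return A \code{\link{smart_design}}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design config not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$stages)) stop("design config lacks 'stages'", call. = FALSE)
  stages <- lapply(cfg$stages, function(sg) {
    strata <- lapply(sg$strata, function(s) {
      feasibility_stratum(key = s$key %||% list(),
                          feasible = unlist(s$feasible),
                          probs = if (!is.null(s$probs)) unlist(s$probs),
                          name = s$name %||% NULL)
    })
    smart_stage(options = unlist(sg$options), strata = strata)
  })
  smart_design(stages, label = cfg$label %||% basename(path))
}
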