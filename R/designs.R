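#' Built-in SMART designs
#'
#' Ready-made two-stage designs covering the common SMART layouts for
#' time-to-event outcomes, with equal randomization within every feasibility
#' stratum.
#'
#' \describe{
#'   \item{\code{design_basic(control = FALSE)}}{Two initial treatments; at
#'     decision 2, subjects not yet experiencing the event are classified as
#'     responders (re-randomized to continue, \code{"0"}, or switch,
#'     \code{"1"}) or nonresponders (continue).  With \code{control = TRUE} a
#'     third up-front "standard of care" arm (\code{"ctrl"}) is added whose
#'     subjects are never re-randomized; the design then embeds 5 regimes,
#'     otherwise 4.}
#'   \item{\code{design_crossed()}}{Two initial (consolidation-type)
#'     treatments crossed with two second-stage (maintenance-type)
#'     treatments; any subject reaching decision 2 is re-randomized between
#'     the two maintenance options.  Embeds 4 regimes.}
#'   \item{\code{design_response8()}}{Two initial treatments; second-stage
#'     options \code{\{"2","3","4","5"\}} with feasibility depending on both
#'     the initial treatment and responder status, two feasible options per
#'     stratum.  Embeds 8 regimes.}
#'   \item{\code{design_single(options, probs)}}{A single-stage design
#'     (classical multi-arm trial), useful for checking the reduction of the
#'     generalized test to the standard logrank test.}
#' }
#'
#' Responder status is carried in the data as the stage-2 covariate column
#' \code{x2_resp} (1 = responder).
#'
#' @param control Add an up-front control arm (\code{design_basic} only).
#' @param options,probs Option labels and randomization probabilities
#'   (\code{design_single} only).
#' @return A \code{\link{smart_design}}.
#' @name builtin_designs
NULL

#' @rdname builtin_designs
#' @export
design_basic <- function(control = FALSE) {
  a1 <- if (control) c("0", "1", "ctrl") else c("0", "1")
  s2key <- if (control) list(a1 = c("0", "1")) else list()
  smart_design(
    list(
      smart_stage(a1, feasibility_stratum(list(), a1)),
      smart_stage(c("0", "1"), list(
        feasibility_stratum(c(s2key, list(x2_resp = 1)), c("0", "1")),
        feasibility_stratum(c(s2key, list(x2_resp = 0)), "0", probs = 1)
      ))
    ),
    label = if (control) "two-arm + responder re-randomization + control"
            else "two-arm + responder re-randomization"
  )
}

#' @rdname builtin_designs
#' @export
design_crossed <- function() {
  smart_design(
    list(
      smart_stage(c("0", "1"), feasibility_stratum(list(), c("0", "1"))),
      smart_stage(c("0", "1"), feasibility_stratum(list(), c("0", "1")))
    ),
    label = "consolidation x maintenance"
  )
}

#' @rdname builtin_designs
#' @export
design_response8 <- function() {
  smart_design(
    list(
      smart_stage(c("0", "1"), feasibility_stratum(list(), c("0", "1"))),
      smart_stage(c("2", "3", "4", "5"), list(
        feasibility_stratum(list(a1 = "1", x2_resp = 1), c("2", "5")),
        feasibility_stratum(list(a1 = "1", x2_resp = 0), c("3", "5")),
        feasibility_stratum(list(a1 = "0", x2_resp = 1), c("2", "4")),
        feasibility_stratum(list(a1 = "0", x2_resp = 0), c("3", "4"))
      ))
    ),
    label = "response-stratified, 8 embedded regimes"
  )
}

#' @rdname builtin_designs
#' @export
design_single <- function(options = c("0", "1"), probs = NULL) {
  smart_design(
    list(smart_stage(options,
                     feasibility_stratum(list(), options, probs = probs))),
    label = "single-stage"
  )
}
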