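#' Engine mechanics options
#'
#' The within-search bookkeeping of the encounter model admits two
#' depletion dialects, and rival searches can either be simulated seeker
#' by seeker or drawn from their exact per-foray probability:
#'
#' * `depletion = "per_territory_minus40"`: a successful visit removes the
#'   whole visited territory (`territory_tiles` tiles) from the field for
#'   the rest of the foray, so that female is unavailable thereafter.
#' * `depletion = "per_attempt_minus1"`: every attempt excludes exactly one
#'   visited tile, giving the attempt-probability sequence `TU/(T-1)`,
#'   `(TU-1)/(T-2)`, `(TU-2)/(T-3)`; territories are never removed.
#' * `rival_mode = "explicit"`: every rival performs its own simulated
#'   copulation search. `"closed_form"`: the foray cuckold event is drawn
#'   directly from its exact probability (only available without shared
#'   depletion, where rival searches are independent).
#' * `shared_depletion`: when `TRUE`, all EPC seekers of a foray (the focal
#'   male and every rival) search a common pool in uniformly random order,
#'   so one male's success removes that female for everyone; when `FALSE`
#'   each seeker searches the fresh field independently.
#'
#' The default (`per_territory_minus40` with shared depletion and explicit
#' rivals) is the calibrated combination: with a shared pool the model
#' reproduces the qualitative and most quantitative published behaviours of
#' the payoff curves, including that roving never beats mate guarding under
#' heavy wandering pressure with a male-biased sex ratio; without sharing,
#' extra-pair gains are overstated at high roving prevalence.  See the
#' package vignette for the calibration analysis.
#'
#' @param depletion one of `"per_territory_minus40"`, `"per_attempt_minus1"`.
#' @param rival_mode one of `"explicit"`, `"closed_form"`.
#' @param shared_depletion logical flag.
#' @return an object of class `mechanics_options`.
#' @examples
#' mechanics_options()
#' mechanics_options("per_attempt_minus1", "closed_form", shared_depletion = FALSE)
#' @export
mechanics_options <- function(depletion = c("per_territory_minus40",
                                            "per_attempt_minus1"),
                              rival_mode = c("explicit", "closed_form"),
                              shared_depletion = TRUE) {
  depletion <- match.arg(depletion)
  rival_mode <- match.arg(rival_mode)
  shared_depletion <- isTRUE(shared_depletion)
  if (shared_depletion && rival_mode == "closed_form")
    stop("closed-form rival mode requires shared_depletion = FALSE ",
         "(rival searches must be independent)")
  structure(list(depletion = depletion, rival_mode = rival_mode,
                 shared_depletion = shared_depletion),
            class = "mechanics_options")
}

#' @export
print.mechanics_options <- function(x, ...) {
  cat("<mechanics_options>", mechanics_fingerprint(x), "\n")
  invisible(x)
}

#' Short deterministic fingerprint of a mechanics choice
#'
#' Embedded in results tables so every output records the interpretation
#' it was produced under.
#'
#' @param mechanics a [mechanics_options()].
#' @return a single string such as
#'   `"per_territory_minus40/explicit/shared"`.
#' @export
mechanics_fingerprint <- function(mechanics) {
  stopifnot(inherits(mechanics, "mechanics_options"))
  paste(mechanics$depletion, mechanics$rival_mode,
        if (mechanics$shared_depletion) "shared" else "independent",
        sep = "/")
}

.depletion_code <- function(depletion) {
  switch(depletion, per_attempt_minus1 = 0L, per_territory_minus40 = 1L,
         stop("unknown depletion dialect: ", depletion))
}

#' Success probability of a single EPC attempt
#'
#' Under the tile-exclusion dialect (`per_attempt_minus1`) the probability
#' that attempt `k` of a copulation search succeeds is
#' `max(0, TU - (k - 1)) / (T - k)`: each previous attempt has excluded one
#' visited tile from both the unguarded pool and the total.  Under
#' `per_territory_minus40` the probability is state-dependent (it depends
#' on which territories earlier successes removed), so no closed form per
#' attempt index exists and this function refuses it.
#'
#' @param k attempt index within the search (1-based).
#' @param total_tiles total tiles `T` at the start of the search.
#' @param unguarded_tiles unguarded tiles `TU` at the start of the search;
#'   must not exceed `T - 1` (the focal male's current tile is never a
#'   target).
#' @param depletion depletion dialect (see [mechanics_options()]).
#' @return success probability of attempt `k`.
#' @examples
#' attempt_probability(1, 100000, 40000)   # 40000 / 99999
#' attempt_probability(3, 600, 160)        # 158 / 597
#' @export
attempt_probability <- function(k, total_tiles, unguarded_tiles,
                                depletion = "per_attempt_minus1") {
  stopifnot(length(k) >= 1, all(k >= 1), all(k == floor(k)))
  if (depletion != "per_attempt_minus1")
    stop("attempt probabilities have a closed form only under ",
         "per_attempt_minus1; use the search engine for ",
         "per_territory_minus40")
  if (total_tiles <= max(k))
    stop("total_tiles must exceed the attempt index")
  if (unguarded_tiles < 0 || unguarded_tiles > total_tiles - 1)
    stop("unguarded_tiles must lie in [0, total_tiles - 1]")
  pmax(0, unguarded_tiles - (k - 1)) / (total_tiles - k)
}
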