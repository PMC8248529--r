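.resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed), seed >= 0)
  as.double(seed)
}

.field_args <- function(view) {
  list(total_tiles = view$total_tiles,
       territory_tiles = view$focal_female_tiles,
       n_partner_terrs = view$n_rovers,
       n_unpaired_fem = view$n_unpaired_females,
       n_wanderers = view$n_wanderers)
}

#' Monte Carlo draws of one copulation search
#'
#' Simulates the focal male's three-attempt copulation search on a fresh
#' per-foray view of the field and returns the number of EPCs gained on
#' each of `n` independent searches.  No rivals act here; use
#' [cuckold_check()] for the rival side or [simulate_runs()] for full
#' replicates.
#'
#' @param field a [build_field()] result or [field_for_foray()] view.
#' @param n number of independent searches to draw.
#' @param mechanics a [mechanics_options()].
#' @param seed integer seed for the engine's own random stream; if `NULL`,
#'   one is drawn from R's session RNG.
#' @return integer vector of length `n` with values in
#'   `0..attempts_per_foray`.
#' @examples
#' f <- build_field(field_config(n_pairs = 6, roving_fraction = 1))
#' copulation_search(f, n = 10, seed = 1)
#' @export
copulation_search <- function(field, n = 1,
                              mechanics = mechanics_options(),
                              seed = NULL) {
  stopifnot(inherits(field, "mating_field"), n >= 1)
  fa <- .field_args(field)
  # no rival acts during a focal-only search: expose every unguarded
  # territory as an ownerless target so no rival seekers are spawned
  m <- .cpp_simulate(as.integer(n), 1L, field$config$attempts_per_foray,
                     fa$total_tiles, fa$territory_tiles, 0L,
                     fa$n_partner_terrs + fa$n_unpaired_fem, 0L,
                     focal_roving = FALSE, focal_searches = TRUE,
                     depletion = .depletion_code(mechanics$depletion),
                     shared = FALSE, rival_closed_form = FALSE,
                     seed = .resolve_seed(seed))
  m[, "E"]
}

#' Monte Carlo draws of the per-foray cuckold event
#'
#' Lets every rival EPC seeker (roving residents and wanderers) run a
#' copulation search against a fresh per-foray view of the field with the
#' focal male away, and reports whether at least one of them visited the
#' focal male's female.  At most one cuckolding visit per foray is counted.
#'
#' @inheritParams copulation_search
#' @param field a foray view in which the focal male is roving; calling
#'   this when he is mate guarding is a contract violation (a guarded
#'   female cannot be cuckolded).
#' @return integer vector of length `n` with values 0/1.
#' @export
cuckold_check <- function(field, n = 1, mechanics = mechanics_options(),
                          seed = NULL) {
  stopifnot(inherits(field, "mating_field"), n >= 1)
  if (inherits(field, "foray_view") && !isTRUE(field$focal_roving))
    stop("cuckold_check() requires a foray on which the focal male roves")
  fa <- .field_args(field)
  m <- .cpp_simulate(as.integer(n), 1L, field$config$attempts_per_foray,
                     fa$total_tiles, fa$territory_tiles, fa$n_partner_terrs,
                     fa$n_unpaired_fem, field$n_wanderers,
                     focal_roving = TRUE, focal_searches = FALSE,
                     depletion = .depletion_code(mechanics$depletion),
                     shared = mechanics$shared_depletion,
                     rival_closed_form = mechanics$rival_mode == "closed_form",
                     seed = .resolve_seed(seed))
  m[, "C"]
}

#' Simulate full replicates of the focal male's reproductive success
#'
#' Runs `n` independent replicates of the scenario described by `config`.
#' Each replicate consists of `forays` departures of the focal male; on
#' each foray he performs a copulation search (up to
#' `attempts_per_foray` EPCs) while the rival seekers search the same
#' fresh field view, cuckolding him at most once per foray.  Reproductive
#' success is scored as `R = E + I - C` with `I = forays`.
#'
#' @param config a [field_config()].
#' @param n number of replicates.
#' @param mechanics a [mechanics_options()].
#' @param seed integer seed for the engine's random stream; if `NULL`, one
#'   is drawn from R's session RNG.
#' @return a data.frame with one row per replicate and integer columns
#'   `E`, `I`, `C`, `R`.
#' @examples
#' simulate_runs(condition1(n_pairs = 100, roving_fraction = 0.5),
#'               n = 5, seed = 1)
#' @export
simulate_runs <- function(config, n = 1, mechanics = mechanics_options(),
                          seed = NULL) {
  stopifnot(inherits(config, "field_config"), n >= 1)
  field <- build_field(config)
  fa <- .field_args(field)
  m <- .cpp_simulate(as.integer(n), config$forays, config$attempts_per_foray,
                     fa$total_tiles, fa$territory_tiles, fa$n_partner_terrs,
                     fa$n_unpaired_fem, field$n_wanderers,
                     focal_roving = TRUE, focal_searches = TRUE,
                     depletion = .depletion_code(mechanics$depletion),
                     shared = mechanics$shared_depletion,
                     rival_closed_form = mechanics$rival_mode == "closed_form",
                     seed = .resolve_seed(seed))
  E <- m[, "E"]; C <- m[, "C"]
  data.frame(E = E, I = rep.int(config$forays, n), C = C,
             R = E + config$forays - C)
}

#' @rdname simulate_runs
#' @param field a `mating_field` (e.g. from [manual_field()]):
#'   `simulate_field_runs()` runs replicates directly on a realized field,
#'   which is how degenerate geometries (such as `TU = T - 1`, where every
#'   attempt must succeed) are exercised.
#' @export
simulate_field_runs <- function(field, n = 1,
                                mechanics = mechanics_options(),
                                seed = NULL) {
  stopifnot(inherits(field, "mating_field"), n >= 1)
  fa <- .field_args(field)
  forays <- field$config$forays
  m <- .cpp_simulate(as.integer(n), forays, field$config$attempts_per_foray,
                     fa$total_tiles, fa$territory_tiles, fa$n_partner_terrs,
                     fa$n_unpaired_fem, field$n_wanderers,
                     focal_roving = TRUE, focal_searches = TRUE,
                     depletion = .depletion_code(mechanics$depletion),
                     shared = mechanics$shared_depletion,
                     rival_closed_form = mechanics$rival_mode == "closed_form",
                     seed = .resolve_seed(seed))
  E <- m[, "E"]; C <- m[, "C"]
  data.frame(E = E, I = rep.int(forays, n), C = C, R = E + forays - C)
}

#' @rdname simulate_runs
#' @return `simulate_run()` returns a single-replicate list with elements
#'   `E`, `I`, `C`, `R`.
#' @export
simulate_run <- function(config, mechanics = mechanics_options(),
                         seed = NULL) {
  as.list(simulate_runs(config, n = 1, mechanics = mechanics, seed = seed))
}
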