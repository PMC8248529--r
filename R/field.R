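#' Half-up rounding
#'
#' Tactic counts are rounded half-up (0.5 always rounds away from zero for
#' positive input), unlike base R's round-half-even, so that e.g. 50%
#' roving among 999 non-focal males yields 500 rovers.
#'
#' @param x numeric vector, non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Describe a population scenario
#'
#' A `field_config` declares everything needed to lay out the mating field:
#' the number of bonded pairs, habitat density (tiles per pair), territory
#' size, the fraction of non-focal paired males that rove, the fraction of
#' unpaired wandering males added relative to the pair count, and whether
#' each wanderer is matched by an unpaired, always-unguarded female
#' (a balanced sex ratio).
#'
#' The focal male is always a rover: the question the model answers is how
#' his payoff compares to the fixed true-resident baseline of
#' `R = forays`, so the roving fraction applies to the other
#' `n_pairs - 1` paired males (count rounded half-up).  Wanderers hold no
#' territory of their own and act purely as cuckolding pressure; their
#' count is `round(wanderer_fraction * n_pairs)` (half-up).
#'
#' @param n_pairs number of male-female pairs (at least 2).
#' @param tiles_per_pair habitat tiles contributed by each pair (default
#'   100, i.e. 200 animals per 100 tiles of habitat).
#' @param territory_tiles tiles in one inhabited home range (default 40).
#' @param roving_fraction fraction of non-focal paired males that rove,
#'   in `[0, 1]`.
#' @param wanderer_fraction fraction of unpaired EPC-seeking males added,
#'   relative to `n_pairs`, in `[0, 1]`.
#' @param balanced_sex_ratio if `TRUE`, one unpaired and always-unguarded
#'   female territory is added per wanderer.
#' @param forays forays (departures from the territory) per replicate;
#'   one IPC is at risk on each (default 4).
#' @param attempts_per_foray EPC attempts per copulation search (default 3).
#' @param unpaired_female_tiles_added if `TRUE` (default) each unpaired
#'   female also adds `tiles_per_pair` tiles of habitat, holding population
#'   density constant; if `FALSE` her territory is carved out of the
#'   existing grid, raising density.
#' @return an object of class `field_config`.
#' @examples
#' field_config(n_pairs = 1000, roving_fraction = 1)
#' @export
field_config <- function(n_pairs = 1000,
                         tiles_per_pair = 100,
                         territory_tiles = 40,
                         roving_fraction = 0,
                         wanderer_fraction = 0,
                         balanced_sex_ratio = FALSE,
                         forays = 4,
                         attempts_per_foray = 3,
                         unpaired_female_tiles_added = TRUE) {
  stopifnot(length(n_pairs) == 1, length(roving_fraction) == 1,
            length(wanderer_fraction) == 1)
  if (!is.numeric(n_pairs) || n_pairs < 2 || n_pairs != floor(n_pairs))
    stop("n_pairs must be an integer >= 2 (a focal pair plus at least one other pair)")
  if (!is.numeric(roving_fraction) || is.na(roving_fraction) ||
      roving_fraction < 0 || roving_fraction > 1)
    stop("roving_fraction must lie in [0, 1]")
  if (!is.numeric(wanderer_fraction) || is.na(wanderer_fraction) ||
      wanderer_fraction < 0 || wanderer_fraction > 1)
    stop("wanderer_fraction must lie in [0, 1]")
  if (territory_tiles < 1 || tiles_per_pair < 1 ||
      territory_tiles > tiles_per_pair)
    stop("territory_tiles must lie in [1, tiles_per_pair]")
  if (forays < 1 || attempts_per_foray < 1)
    stop("forays and attempts_per_foray must be positive")
  structure(
    list(n_pairs = as.integer(n_pairs),
         tiles_per_pair = as.integer(tiles_per_pair),
         territory_tiles = as.integer(territory_tiles),
         roving_fraction = as.numeric(roving_fraction),
         wanderer_fraction = as.numeric(wanderer_fraction),
         balanced_sex_ratio = isTRUE(balanced_sex_ratio),
         forays = as.integer(forays),
         attempts_per_foray = as.integer(attempts_per_foray),
         unpaired_female_tiles_added = isTRUE(unpaired_female_tiles_added)),
    class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  cat("<field_config>\n")
  cat(sprintf("  pairs: %d (%d tiles/pair, %d-tile territories)\n",
              x$n_pairs, x$tiles_per_pair, x$territory_tiles))
  cat(sprintf("  roving fraction (non-focal paired males): %.2f\n",
              x$roving_fraction))
  cat(sprintf("  wanderer fraction: %.2f%s\n", x$wanderer_fraction,
              if (x$balanced_sex_ratio) " (+ matched unpaired females)" else ""))
  cat(sprintf("  forays: %d, attempts per foray: %d\n",
              x$forays, x$attempts_per_foray))
  invisible(x)
}

#' Realize the mating field for a scenario
#'
#' Turns a [field_config()] into the tile bookkeeping the engine operates
#' on: total tiles `T`, unguarded tiles `TU` targetable by the focal male
#' (a multiple of `territory_tiles`), the number of rival EPC seekers, and
#' the tactic assignment.  The focal male's own territory is never part of
#' `TU`: a rover cannot gain an EPC from his own partner.
#'
#' @param config a [field_config()].
#' @return an object of class `mating_field`: a list with elements
#'   `total_tiles`, `unguarded_tiles`, `n_rival_seekers`,
#'   `focal_female_tiles`, `n_true_residents`, `n_rovers` (non-focal),
#'   `n_wanderers`, `n_unpaired_females`, and the originating `config`.
#' @examples
#' build_field(field_config(n_pairs = 1000, roving_fraction = 1))
#' @export
build_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  n_rovers <- round_half_up(config$roving_fraction * (config$n_pairs - 1))
  n_true <- config$n_pairs - 1L - n_rovers
  n_wanderers <- round_half_up(config$wanderer_fraction * config$n_pairs)
  n_unpaired <- if (config$balanced_sex_ratio) n_wanderers else 0L
  total <- as.double(config$n_pairs) * config$tiles_per_pair
  if (n_unpaired > 0 && config$unpaired_female_tiles_added)
    total <- total + as.double(n_unpaired) * config$tiles_per_pair
  tu <- as.double(config$territory_tiles) * (n_rovers + n_unpaired)
  structure(
    list(total_tiles = total,
         unguarded_tiles = tu,
         n_rival_seekers = n_rovers + n_wanderers,
         focal_female_tiles = config$territory_tiles,
         n_true_residents = n_true,
         n_rovers = n_rovers,
         n_wanderers = n_wanderers,
         n_unpaired_females = n_unpaired,
         config = config),
    class = "mating_field")
}

#' @export
print.mating_field <- function(x, ...) {
  cat("<mating_field>\n")
  cat(sprintf("  T = %.0f tiles, TU = %.0f unguarded tiles (focal targets)\n",
              x$total_tiles, x$unguarded_tiles))
  cat(sprintf("  rival EPC seekers: %d (%d roving residents + %d wanderers)\n",
              x$n_rival_seekers, x$n_rovers, x$n_wanderers))
  cat(sprintf("  true residents: %d, unpaired females: %d\n",
              x$n_true_residents, x$n_unpaired_females))
  invisible(x)
}

#' Per-foray view of a mating field
#'
#' Returns a fresh view of the field for one foray: all within-search
#' depletion from previous forays is discarded (the encounter probability
#' resets at the start of every copulation search).  The focal female is
#' unguarded -- and therefore cuckoldable -- exactly when the focal male is
#' roving on this foray.
#'
#' @param field a [build_field()] result.
#' @param focal_roving is the focal male away on this foray? (default
#'   `TRUE`; the focal male roves on every foray in the standard model).
#' @return an object of class `foray_view` with the same tile counts as
#'   `field` plus `focal_roving`.
#' @export
field_for_foray <- function(field, focal_roving = TRUE) {
  stopifnot(inherits(field, "mating_field"))
  out <- unclass(field)
  out$focal_roving <- isTRUE(focal_roving)
  class(out) <- c("foray_view", "mating_field")
  out
}

#' Construct a mating field directly from tile counts
#'
#' Bypasses [field_config()] for unit-level work: build a field view with
#' an arbitrary total tile count and unguarded-territory count, e.g. the
#' degenerate `TU = T - 1` field on which every focal attempt must
#' succeed.  `n_rover_rivals` unguarded territories belong to roving rival
#' males (who also act as EPC seekers); `n_unpaired_females` are ownerless
#' targets; `n_wanderers` adds territory-less seekers.
#'
#' @param total_tiles total tiles `T`.
#' @param territory_tiles tiles per territory.
#' @param n_rover_rivals number of non-focal roving residents (each
#'   contributes one unguarded territory and one rival seeker).
#' @param n_unpaired_females number of unpaired, always-unguarded female
#'   territories.
#' @param n_wanderers number of wandering males (seekers without
#'   territories).
#' @param forays,attempts_per_foray search geometry (defaults 4 and 3).
#' @return a `mating_field`.
#' @examples
#' manual_field(121, 40, n_unpaired_females = 3)  # TU = T - 1
#' @export
manual_field <- function(total_tiles, territory_tiles = 40,
                         n_rover_rivals = 0, n_unpaired_females = 0,
                         n_wanderers = 0, forays = 4,
                         attempts_per_foray = 3) {
  tu <- territory_tiles * (n_rover_rivals + n_unpaired_females)
  stopifnot(total_tiles >= 2, territory_tiles >= 1,
            n_rover_rivals >= 0, n_unpaired_females >= 0, n_wanderers >= 0)
  if (tu > total_tiles - 1)
    stop("unguarded tiles may not exceed total_tiles - 1")
  structure(
    list(total_tiles = as.double(total_tiles),
         unguarded_tiles = as.double(tu),
         n_rival_seekers = as.integer(n_rover_rivals + n_wanderers),
         focal_female_tiles = as.integer(territory_tiles),
         n_true_residents = NA_integer_,
         n_rovers = as.integer(n_rover_rivals),
         n_wanderers = as.integer(n_wanderers),
         n_unpaired_females = as.integer(n_unpaired_females),
         config = list(forays = as.integer(forays),
                       attempts_per_foray = as.integer(attempts_per_foray))),
    class = "mating_field")
}

#' Scenario builders for the three study conditions
#'
#' Convenience constructors for the three social contexts the model
#' explores, identical to direct [field_config()] calls:
#' * `condition1()`: paired males only (true residents and rovers), no
#'   wanderers.
#' * `condition2()`: wandering males added (male-biased sex ratio).
#' * `condition3()`: wandering males plus one unpaired, always-unguarded
#'   female per wanderer (balanced sex ratio).
#'
#' @param n_pairs number of pairs.
#' @param roving_fraction fraction of non-focal paired males that rove.
#' @param wanderer_fraction fraction of wandering males added (relative to
#'   `n_pairs`); typical study values are 0.1 to 0.4.
#' @param ... passed on to [field_config()].
#' @return a [field_config()].
#' @examples
#' condition3(n_pairs = 1000, roving_fraction = 0.5, wanderer_fraction = 0.1)
#' @export
condition1 <- function(n_pairs = 1000, roving_fraction = 0, ...) {
  field_config(n_pairs = n_pairs, roving_fraction = roving_fraction,
               wanderer_fraction = 0, balanced_sex_ratio = FALSE, ...)
}

#' @rdname condition1
#' @export
condition2 <- function(n_pairs = 1000, roving_fraction = 0,
                       wanderer_fraction = 0.1, ...) {
  field_config(n_pairs = n_pairs, roving_fraction = roving_fraction,
               wanderer_fraction = wanderer_fraction,
               balanced_sex_ratio = FALSE, ...)
}

#' @rdname condition1
#' @export
condition3 <- function(n_pairs = 1000, roving_fraction = 0,
                       wanderer_fraction = 0.1, ...) {
  field_config(n_pairs = n_pairs, roving_fraction = roving_fraction,
               wanderer_fraction = wanderer_fraction,
               balanced_sex_ratio = TRUE, ...)
}

#' Which condition does a configuration describe?
#'
#' @param config a [field_config()].
#' @return 1, 2 or 3.
#' @keywords internal
condition_id <- function(config) {
  if (config$wanderer_fraction == 0) 1L
  else if (!config$balanced_sex_ratio) 2L
  else 3L
}
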