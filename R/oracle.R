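#' Closed-form expected EPCs of one copulation search
#'
#' Under the tile-exclusion dialect (`per_attempt_minus1`) the attempt
#' probabilities are fixed numbers, so by linearity of expectation the
#' expected number of EPCs in one search is simply their sum,
#' `sum_k max(0, TU - (k - 1)) / (T - k)`, independent of how successes
#' and failures interleave.  No closed form exists under
#' `per_territory_minus40` (the probabilities are state-dependent); use
#' [enumerate_run()] there.
#'
#' @param total_tiles total tiles `T`.
#' @param unguarded_tiles unguarded tiles `TU` targetable by the searcher.
#' @param attempts attempts per search (default 3).
#' @param depletion depletion dialect; only `"per_attempt_minus1"` is
#'   accepted.
#' @return the exact expectation of EPCs per search.
#' @examples
#' expected_epc_per_foray(600, 160)  # 160/599 + 159/598 + 158/597
#' @export
expected_epc_per_foray <- function(total_tiles, unguarded_tiles,
                                   attempts = 3,
                                   depletion = "per_attempt_minus1") {
  if (depletion != "per_attempt_minus1")
    stop("no closed form under ", depletion, "; use enumerate_run()")
  sum(attempt_probability(seq_len(attempts), total_tiles, unguarded_tiles))
}

# all permutations of 1..n as a list (n small; guarded by caller)
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .all_perms(n - 1)) {
      q <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, q[p])
    }
  }
  out
}

# Exact joint pmf of (focal EPCs e, cuckold indicator c) for one foray with
# a shared depletion pool: exhaustive branching over every draw of every
# seeker, averaged over all seeker orders.
#
# Dialect semantics mirror the engine exactly: under per_attempt_minus1 a
# seeker's eligible-territory count is frozen at the start of his search
# (the focal female slot persists within the search even after a hit, a
# repeat visit being idempotent), while under per_territory_minus40 each
# success removes the visited territory immediately.
.enum_foray_shared <- function(field, mechanics, focal_searches = TRUE,
                               focal_roving = TRUE, max_paths = 1e7) {
  attempts <- field$config$attempts_per_foray
  terr <- field$focal_female_tiles
  T0 <- field$total_tiles
  nr <- field$n_rovers
  nu <- field$n_unpaired_females
  nw <- field$n_wanderers
  dep <- mechanics$depletion

  seekers <- list()
  if (focal_searches) seekers[[1]] <- list(own = 0L, focal = TRUE)
  for (i in seq_len(nr))
    seekers[[length(seekers) + 1]] <- list(own = i, focal = FALSE)
  for (i in seq_len(nw))
    seekers[[length(seekers) + 1]] <- list(own = 0L, focal = FALSE)
  ns <- length(seekers)
  n_terr <- nr + nu  # ids 1..nr rover partners, nr+1..nr+nu unpaired

  P <- matrix(0, nrow = attempts + 1, ncol = 2)
  if (ns == 0) { P[1, 1] <- 1; return(P) }

  n_orders <- if (ns > 1) factorial(ns) else 1
  if (n_orders > max_paths)
    stop("enumeration state space exceeds max_paths; use a smaller miniature")
  nodes <- 0

  walk_order <- function(order) {
    rec_seeker <- function(si, avail, fem_avail, T_now, sh, pr, e, cuck) {
      if (si > ns) {
        P[e + 1, cuck + 1] <<- P[e + 1, cuck + 1] + pr
        return(invisible())
      }
      s <- seekers[[order[si]]]
      own_in <- s$own > 0 && avail[s$own]
      sfem <- !s$focal && focal_roving && fem_avail  # frozen for minus1
      elig0 <- sum(avail) - own_in + sfem

      rec_attempt <- function(k, avail, fem_avail, T_now, e_s, hit, pr) {
        nodes <<- nodes + 1
        if (nodes > max_paths)
          stop("enumeration state space exceeds max_paths; use a smaller miniature")
        if (k > attempts) {
          sh2 <- if (dep == "per_attempt_minus1") sh + attempts else sh
          rec_seeker(si + 1, avail, fem_avail, T_now, sh2, pr,
                     e + if (s$focal) e_s else 0L,
                     max(cuck, if (!s$focal && hit) 1L else 0L))
          return(invisible())
        }
        others <- which(avail)
        others <- others[others != s$own]
        if (dep == "per_attempt_minus1") {
          fem_branch <- sfem
          elig <- elig0
          num <- terr * elig0 - (k - 1) - sh
          den <- T0 - k - sh
        } else {
          fem_branch <- !s$focal && focal_roving && fem_avail
          elig <- length(others) + fem_branch
          num <- terr * elig
          den <- T_now - 1
        }
        p <- if (den <= 0 || num <= 0) 0 else min(1, num / den)
        if (p < 1)
          rec_attempt(k + 1, avail, fem_avail, T_now, e_s, hit, pr * (1 - p))
        if (p > 0 && elig > 0) {
          p_each <- p / elig
          for (j in others) {
            a2 <- avail; T2 <- T_now
            if (dep == "per_territory_minus40") {
              a2[j] <- FALSE; T2 <- T_now - terr
            }
            rec_attempt(k + 1, a2, fem_avail, T2, e_s + 1L, hit, pr * p_each)
          }
          if (fem_branch) {
            T2 <- if (dep == "per_territory_minus40") T_now - terr else T_now
            rec_attempt(k + 1, avail, FALSE, T2, e_s + 1L, TRUE, pr * p_each)
          }
        }
        invisible()
      }
      rec_attempt(1L, avail, fem_avail, T_now, 0L, FALSE, pr)
      invisible()
    }
    rec_seeker(1L, rep(TRUE, n_terr), TRUE, T0, 0L, 1, 0L, 0L)
  }

  orders <- if (ns > 1) .all_perms(ns) else list(1L)
  for (o in orders) walk_order(o)
  P / length(orders)
}

# Independent-seeker (non-shared) foray pmf: the focal search and every
# rival search run on the fresh field, so the joint factorizes into the
# focal e-pmf times a Bernoulli cuckold event with exact probability.
.enum_foray_indep <- function(field, mechanics, focal_searches = TRUE,
                              focal_roving = TRUE) {
  attempts <- field$config$attempts_per_foray
  terr <- field$focal_female_tiles
  T0 <- field$total_tiles
  nr <- field$n_rovers
  nu <- field$n_unpaired_females
  nw <- field$n_wanderers
  dep <- mechanics$depletion

  # single fresh-field search; returns joint pmf over (e, fem ever hit)
  single <- function(n_other0, fem0) {
    res <- matrix(0, attempts + 1, 2)
    elig0 <- n_other0 + fem0
    rec <- function(k, n_other, fem_in, T_now, e, hit, pr) {
      if (k > attempts) {
        res[e + 1, hit + 1] <<- res[e + 1, hit + 1] + pr
        return(invisible())
      }
      if (dep == "per_attempt_minus1") {
        fem_branch <- fem0     # slot persists at tile level
        elig <- elig0
        num <- terr * elig0 - (k - 1)
        den <- T0 - k
        n_branch <- n_other0
      } else {
        fem_branch <- fem_in
        elig <- n_other + fem_in
        num <- terr * elig
        den <- T_now - 1
        n_branch <- n_other
      }
      p <- if (den <= 0 || num <= 0) 0 else min(1, num / den)
      if (p < 1) rec(k + 1, n_other, fem_in, T_now, e, hit, pr * (1 - p))
      if (p > 0 && elig > 0) {
        if (n_branch > 0) {
          n2 <- if (dep == "per_territory_minus40") n_other - 1 else n_other
          T2 <- if (dep == "per_territory_minus40") T_now - terr else T_now
          rec(k + 1, n2, fem_in, T2, e + 1L, hit, pr * p * n_branch / elig)
        }
        if (fem_branch) {
          T2 <- if (dep == "per_territory_minus40") T_now - terr else T_now
          rec(k + 1, n_other, FALSE, T2, e + 1L, TRUE, pr * p / elig)
        }
      }
      invisible()
    }
    rec(1L, n_other0, fem0, T0, 0L, FALSE, 1)
    res
  }

  e_pmf <- if (focal_searches) rowSums(single(nr + nu, FALSE))
           else c(1, rep(0, attempts))
  p_no <- 1
  if (focal_roving) {
    if (nr > 0) p_no <- p_no * sum(single(nr - 1 + nu, TRUE)[, 1])^nr
    if (nw > 0) p_no <- p_no * sum(single(nr + nu, TRUE)[, 1])^nw
  }
  cbind(e_pmf * p_no, e_pmf * (1 - p_no))
}

#' Exact joint distribution of a foray's outcome
#'
#' Exhaustively enumerates every branch of every draw of one foray and
#' returns the exact joint probability mass of (EPCs gained by the focal
#' male, cuckold indicator).  Intended for miniature populations (a few
#' seekers, a few territories); the state space is guarded.
#'
#' @param field a `mating_field` (e.g. from [build_field()] or
#'   [manual_field()]).
#' @param mechanics a [mechanics_options()] (either rival mode; rival
#'   draws are integrated out exactly).
#' @param focal_searches,focal_roving foray structure flags.
#' @param max_paths guard on enumerated branches (default 1e7).
#' @return an `(attempts + 1) x 2` matrix `P` with `P[e + 1, c + 1]` the
#'   probability of gaining `e` EPCs and suffering `c` cuckoldings.
#' @export
enumerate_foray <- function(field, mechanics = mechanics_options(),
                            focal_searches = TRUE, focal_roving = TRUE,
                            max_paths = 1e7) {
  stopifnot(inherits(field, "mating_field"))
  if (mechanics$shared_depletion)
    .enum_foray_shared(field, mechanics, focal_searches, focal_roving,
                       max_paths)
  else
    .enum_foray_indep(field, mechanics, focal_searches, focal_roving)
}

#' Exact run-level expectations by exhaustive enumeration
#'
#' Convolves the exact per-foray joint distribution from
#' [enumerate_foray()] over the forays of a run (forays are independent:
#' the field view resets at the start of each search) to obtain the exact
#' distribution and expectations of E, C and R = E + I - C.  This is the
#' reference oracle used to validate the Monte Carlo engine on miniature
#' populations.
#'
#' @param config a [field_config()] or a `mating_field`.
#' @param mechanics a [mechanics_options()].
#' @param max_paths guard on enumerated branches.
#' @return a list with `E`, `C`, `R` (exact expectations), `var_R`,
#'   `pmf_R` (named vector over attainable R values), `per_foray_e` and
#'   `per_foray_c` (per-foray expectations), and `mass` (total enumerated
#'   probability, equal to 1 up to floating error).
#' @examples
#' mini <- field_config(n_pairs = 2, tiles_per_pair = 10,
#'                      territory_tiles = 4, roving_fraction = 1)
#' enumerate_run(mini, mechanics_options("per_attempt_minus1",
#'                                       shared_depletion = FALSE))
#' @export
enumerate_run <- function(config, mechanics = mechanics_options(),
                          max_paths = 1e7) {
  field <- if (inherits(config, "mating_field")) config
           else build_field(config)
  forays <- field$config$forays
  attempts <- field$config$attempts_per_foray
  Pf <- enumerate_foray(field, mechanics, max_paths = max_paths)

  # convolve the (e, c) pmf across independent forays
  PE <- matrix(0, nrow = forays * attempts + 1, ncol = forays + 1)
  PE[1, 1] <- 1
  for (f in seq_len(forays)) {
    nxt <- matrix(0, nrow = nrow(PE), ncol = ncol(PE))
    nz <- which(PE > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      Ei <- nz[r, 1]; Ci <- nz[r, 2]; pr0 <- PE[Ei, Ci]
      for (e in 0:attempts) for (cc in 0:1) {
        p <- Pf[e + 1, cc + 1]
        if (p > 0) nxt[Ei + e, Ci + cc] <- nxt[Ei + e, Ci + cc] + pr0 * p
      }
    }
    PE <- nxt
  }

  Evals <- 0:(forays * attempts)
  Cvals <- 0:forays
  EE <- sum(Evals * rowSums(PE))
  EC <- sum(Cvals * colSums(PE))
  Rmat <- outer(Evals, Cvals, function(e, cc) e + forays - cc)
  ER <- sum(Rmat * PE)
  varR <- sum(Rmat^2 * PE) - ER^2
  rv <- sort(unique(as.vector(Rmat)))
  pmf_R <- vapply(rv, function(r) sum(PE[Rmat == r]), numeric(1))
  names(pmf_R) <- rv
  e_f <- sum(0:attempts * rowSums(Pf))
  c_f <- sum(0:1 * colSums(Pf))
  list(E = EE, C = EC, R = ER, var_R = varR, pmf_R = pmf_R,
       per_foray_e = e_f, per_foray_c = c_f, mass = sum(PE))
}
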