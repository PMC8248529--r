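#' One-sample t-test against the true-resident baseline
#'
#' Classic two-tailed one-sample t-test of the replicate reproductive
#' successes against the payoff a pure mate-guarding male is guaranteed
#' (R = 4 under the default four-foray design).  A zero-variance sample --
#' which arises by construction at 0% roving, where every replicate scores
#' exactly the baseline -- is not an error: the test is reported as
#' undefined with a flag.
#'
#' @param values numeric vector of replicate R values (length >= 2).
#' @param baseline baseline payoff to test against (default 4).
#' @return a list of class `baseline_test` with elements `t`, `df`, `p`
#'   (two-tailed), `mean`, `undefined` (flag for zero-variance samples,
#'   where `t` and `p` are `NA`).
#' @examples
#' ttest_vs_baseline(c(5, 6, 7))          # t = 3.464..., df = 2
#' ttest_vs_baseline(rep(4, 100))         # undefined: no variance
#' @export
ttest_vs_baseline <- function(values, baseline = 4) {
  if (length(values) < 2)
    stop("at least two replicate values are required for a t-test")
  n <- length(values)
  s <- stats::sd(values)
  if (s == 0) {
    out <- list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean = mean(values), undefined = TRUE)
  } else {
    ht <- stats::t.test(values, mu = baseline, alternative = "two.sided")
    out <- list(t = unname(ht$statistic),
                df = as.integer(unname(ht$parameter)),
                p = ht$p.value, mean = mean(values), undefined = FALSE)
  }
  class(out) <- "baseline_test"
  out
}

#' @export
print.baseline_test <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("one-sample t vs baseline: undefined (zero variance), mean = %g, df = %d\n",
                x$mean, x$df))
  } else {
    cat(sprintf("one-sample t vs baseline: t(%d) = %.4f, p = %.4g, mean = %g\n",
                x$df, x$t, x$p, x$mean))
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of the raw p-values of one sweep (the family is
#' the set of roving-percentage cells within one condition, wanderer level
#' and population size).  Wraps the standard step-up procedure; adjusted
#' values are returned in the original order and never fall below the raw
#' p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric and lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Histogram summary of replicate outcomes
#'
#' Descriptive histogram of the replicate R values of one sweep cell, with
#' sample skewness and excess kurtosis, used to confirm that replicate
#' outcomes are approximately normally distributed at each roving level.
#'
#' @param values numeric vector (length >= 1).
#' @param n_bins suggested number of bins (passed to [graphics::hist()]
#'   breaks; the realized number may differ).  Constant input collapses to
#'   a single occupied bin.
#' @return a list with `breaks`, `counts`, `mids`, `n`, `skewness` and
#'   `kurtosis` (excess; both `NA` for constant input).
#' @export
histogram_summary <- function(values, n_bins = 30) {
  stopifnot(length(values) >= 1, is.numeric(values))
  if (diff(range(values)) == 0) {
    v <- values[1]
    return(list(breaks = c(v - 0.5, v + 0.5), counts = length(values),
                mids = v, n = length(values),
                skewness = NA_real_, kurtosis = NA_real_))
  }
  h <- graphics::hist(values, breaks = n_bins, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       n = length(values),
       skewness = e1071::skewness(values),
       kurtosis = e1071::kurtosis(values))
}

#' Roving level at which extra-pair success overtakes intra-pair success
#'
#' Locates the crossover between the EPC component of mean reproductive
#' success (mean E) and the IPC component (baseline minus mean C) along
#' the roving grid, by linear interpolation of their difference between
#' adjacent grid points.  Absence of a sign change is a valid result
#' (`NA`): under heavy wandering pressure with a male-biased sex ratio the
#' EPC component may never overtake the IPC component.
#'
#' @param cells a sweep result (one condition) as returned by
#'   [run_sweep()], or any data.frame with columns `roving_pct`,
#'   `epc_component` and `ipc_component`.
#' @return the interpolated roving percentage of the first crossover, or
#'   `NA_real_` if none occurs.
#' @examples
#' cells <- data.frame(roving_pct = c(50, 60),
#'                     epc_component = c(1.5, 2.5),
#'                     ipc_component = c(2.0, 2.0))
#' find_crossover(cells)  # 55
#' @export
find_crossover <- function(cells) {
  stopifnot(all(c("roving_pct", "epc_component", "ipc_component")
                %in% names(cells)))
  cells <- cells[order(cells$roving_pct), , drop = FALSE]
  d <- cells$epc_component - cells$ipc_component
  x <- cells$roving_pct
  for (i in seq_len(length(d) - 1)) {
    if (is.na(d[i]) || is.na(d[i + 1])) next
    if (d[i] == 0) return(x[i])
    if (d[i] < 0 && d[i + 1] >= 0) {
      if (d[i + 1] == 0) return(x[i + 1])
      return(x[i] + (x[i + 1] - x[i]) * (-d[i]) / (d[i + 1] - d[i]))
    }
  }
  NA_real_
}
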