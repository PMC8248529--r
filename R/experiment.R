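#' Derive a reproducible stream seed
#'
#' Maps `(master_seed, condition_id, roving_pct, replicate_index)` to a
#' deterministic engine seed.  The mapping is injective for
#' `condition_id < 21`, integer `roving_pct` in `0..100` and
#' `replicate_index < 1e6` (the offsets then fit below `2^31 - 1` without
#' wrapping), which covers any realistic sweep, so distinct cells and
#' replicates never share a stream.
#'
#' @param master_seed non-negative integer master seed.
#' @param condition_id small integer labelling the scenario (1-3 for the
#'   standard conditions).
#' @param roving_pct roving percentage of the cell (0-100).
#' @param replicate_index replicate number within the cell (0-based).
#' @return a single integer seed in `[1, 2^31 - 1]`.
#' @examples
#' derive_seed(42, 1, 60, 0)
#' @export
derive_seed <- function(master_seed, condition_id, roving_pct,
                        replicate_index = 0) {
  stopifnot(master_seed >= 0, condition_id >= 0, condition_id < 21,
            roving_pct >= 0, roving_pct <= 100,
            replicate_index >= 0, replicate_index < 1e6)
  m <- 2^31 - 1
  offset <- (condition_id * 101 + round(roving_pct)) * 1e6 + replicate_index
  ((master_seed %% m) + offset) %% m + 1
}

#' Specify a sweep over roving prevalence
#'
#' A sweep runs `replicates` independent [simulate_runs()] replicates at
#' each value of the roving grid, holding everything else in `config`
#' fixed, and aggregates each grid point into one cell of summary
#' statistics.  Defaults follow the study design: 5000 replicates per cell
#' on a 0-100% grid in 10-point steps.
#'
#' @param config a [field_config()]; its `roving_fraction` is ignored in
#'   favour of the grid.
#' @param roving_grid vector of roving fractions in `[0, 1]`.
#' @param replicates replicates per grid point (>= 1; a warning is issued
#'   below 1000, where cell statistics are unstable).
#' @param seed master seed; per-cell engine seeds are derived from it with
#'   [derive_seed()].
#' @param mechanics a [mechanics_options()].
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(config, roving_grid = seq(0, 1, by = 0.1),
                       replicates = 5000, seed = 1,
                       mechanics = mechanics_options()) {
  stopifnot(inherits(config, "field_config"),
            all(roving_grid >= 0 & roving_grid <= 1),
            length(roving_grid) >= 1, replicates >= 1)
  if (replicates < 1000)
    warning("fewer than 1000 replicates per cell: cell statistics will be unstable")
  structure(list(config = config,
                 roving_grid = as.numeric(roving_grid),
                 replicates = as.integer(replicates),
                 seed = as.numeric(seed),
                 mechanics = mechanics),
            class = "sweep_spec")
}

.aggregate_cell <- function(config, R_values, E_values, C_values,
                            roving_pct) {
  n <- length(R_values)
  tt <- ttest_vs_baseline(R_values, baseline = config$forays)
  data.frame(
    condition = condition_id(config),
    n_pairs = config$n_pairs,
    wanderer_pct = 100 * config$wanderer_fraction,
    balanced_sex_ratio = config$balanced_sex_ratio,
    roving_pct = roving_pct,
    reps = n,
    mean_R = mean(R_values),
    se_R = stats::sd(R_values) / sqrt(n),
    sd_R = stats::sd(R_values),
    mean_E = mean(E_values),
    mean_C = mean(C_values),
    delta_R = mean(E_values) - mean(C_values),
    ipc_component = config$forays - mean(C_values),
    epc_component = mean(E_values),
    t = tt$t,
    df = tt$df,
    p_raw = tt$p,
    undefined_test = tt$undefined)
}

#' Run a sweep over roving prevalence
#'
#' Executes the sweep cell by cell (deterministically given the master
#' seed: identical spec and seed give identical output) and post-processes
#' each cell with a one-sample t-test of mean R against the true-resident
#' baseline, plus Benjamini-Hochberg FDR correction across the cells of
#' the sweep.
#'
#' @param spec a [sweep_spec()].
#' @return a data.frame with one row per grid point; columns include the
#'   scenario descriptors, `mean_R`, `se_R`, `sd_R`, `mean_E`, `mean_C`,
#'   `delta_R`, `ipc_component`, `epc_component`, the test columns `t`,
#'   `df`, `p_raw`, `p_fdr`, `significant`, `undefined_test`, and the
#'   provenance columns `master_seed` and `mechanics`.
#' @examples
#' spec <- sweep_spec(condition1(n_pairs = 100),
#'                    roving_grid = c(0, 0.5, 1),
#'                    replicates = 200, seed = 1)
#' run_sweep(spec)
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  cfg <- spec$config
  cid <- condition_id(cfg)
  cells <- lapply(spec$roving_grid, function(rho) {
    cell_cfg <- cfg
    cell_cfg$roving_fraction <- rho
    pct <- round(100 * rho)
    cell_seed <- derive_seed(spec$seed, cid, pct, 0)
    runs <- simulate_runs(cell_cfg, n = spec$replicates,
                          mechanics = spec$mechanics, seed = cell_seed)
    .aggregate_cell(cell_cfg, runs$R, runs$E, runs$C, pct)
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$roving_pct), , drop = FALSE]
  out$p_fdr <- NA_real_
  ok <- !out$undefined_test
  if (any(ok)) out$p_fdr[ok] <- fdr_adjust(out$p_raw[ok])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < 0.05
  out$master_seed <- spec$seed
  out$mechanics <- mechanics_fingerprint(spec$mechanics)
  rownames(out) <- NULL
  out
}
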