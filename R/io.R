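.config_keys <- c("n_pairs", "tiles_per_pair", "territory_tiles",
                  "roving_fraction", "wanderer_fraction",
                  "balanced_sex_ratio", "forays", "attempts_per_foray",
                  "unpaired_female_tiles_added")
.spec_keys <- c("roving_grid", "replicates", "seed", "depletion",
                "rival_mode", "shared_depletion")

#' Load a sweep specification from a JSON or YAML file
#'
#' The file may contain any subset of the [field_config()] fields plus
#' `roving_grid`, `replicates`, `seed`, `depletion`, `rival_mode` and
#' `shared_depletion`; missing fields take the package defaults (an empty
#' file yields the standard design: condition 1, 1000 pairs, a 0-100%
#' roving grid in 10-point steps, 5000 replicates).  Unknown keys are
#' rejected with an error naming them.  The format is chosen by file
#' extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path path to the configuration file.
#' @return a [sweep_spec()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    if (file.size(path) == 0) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("unsupported configuration format '.", ext,
              "' (use .json, .yml or .yaml)")
  if (!is.list(raw)) stop("configuration must be a mapping of option names to values")
  unknown <- setdiff(names(raw), c(.config_keys, .spec_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(field_config, raw[intersect(names(raw), .config_keys)])
  mech <- mechanics_options(
    depletion = if (is.null(raw$depletion))
      "per_territory_minus40" else raw$depletion,
    rival_mode = if (is.null(raw$rival_mode)) "explicit" else raw$rival_mode,
    shared_depletion = if (is.null(raw$shared_depletion))
      TRUE else raw$shared_depletion)
  sweep_spec(cfg,
             roving_grid = if (is.null(raw$roving_grid))
               seq(0, 1, by = 0.1) else raw$roving_grid,
             replicates = if (is.null(raw$replicates)) 5000 else raw$replicates,
             seed = if (is.null(raw$seed)) 1 else raw$seed,
             mechanics = mech)
}

#' Write / read a results table
#'
#' `write_results()` serializes a [run_sweep()] table as an RFC-4180 CSV
#' (UTF-8, '.' decimal separator, header row) with rows ordered by
#' condition, population size, wanderer percentage and roving percentage.
#' Numeric fields are printed with 17 significant digits so the table
#' round-trips losslessly through `read_results()`.  An optional leading
#' comment line records the mechanics fingerprint and master seed; output
#' bytes are deterministic for a fixed seed and settings.
#'
#' @param table a results data.frame from [run_sweep()].
#' @param path output (input) file path.
#' @param provenance write the leading `#` fingerprint line (default
#'   `TRUE`).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the table.
#' @export
write_results <- function(table, path, provenance = TRUE) {
  stopifnot(is.data.frame(table))
  ord <- order(table$condition, table$n_pairs, table$wanderer_pct,
               table$roving_pct)
  table <- table[ord, , drop = FALSE]
  fmt <- function(col) {
    if (is.double(col)) ifelse(is.na(col), "NA", sprintf("%.17g", col))
    else as.character(col)
  }
  cells <- vapply(table, fmt, character(nrow(table)))
  if (nrow(table) == 1) cells <- matrix(cells, nrow = 1,
                                        dimnames = list(NULL, names(table)))
  lines <- c(paste(names(table), collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  if (provenance && all(c("mechanics", "master_seed") %in% names(table)))
    lines <- c(sprintf("# rovesim results; mechanics=%s; master_seed=%s",
                       table$mechanics[1], fmt(table["master_seed"][[1]])[1]),
               lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  read.csv(path, comment.char = "#", header = TRUE,
           stringsAsFactors = FALSE)
}
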