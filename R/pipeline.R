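# Orchestration: the full in-silico sweep over population sizes (constant
# lactose plus the two fluctuating regimes), a run manifest tying every
# number to its configuration and seeds, and a human-readable report.

#' Substitution-frequency sweep across population sizes and selection regimes
#'
#' For each population size, runs `reps` replicates under constant lactose
#' (full horizon) and `reps` replicates over a single 2,000-generation
#' lactose epoch, then reports the constant-regime `f_s`, the fluctuating
#' extrapolation (applied identically for both fluctuating regimes, each of
#' which contains two lactose epochs) and the combined value across the three
#' regimes.
#'
#' @param config A [sim_config()] template (its `horizon` is used for the
#'   constant-lactose arm).
#' @param sizes Population sizes to sweep.
#' @param reps Replicates per size per arm; default 100.
#' @param seed Integer master seed.
#' @param n_boot Bootstrap resamples for each summary; default 1000.
#' @param epoch Generations per fluctuating-regime lactose epoch; default 2000.
#' @return A list of class `fig_sweep`: `summary` (data frame with one row
#'   per size: `n_pop`, `f_s_lac`, `ci_low_lac`, `ci_high_lac`, `f_2k`,
#'   `f_s_fluct`, `f_s_combined`, `n_reps`) and `manifest` (see
#'   [run_manifest()]).
#' @export
reproduce_substitution_sweep <- function(config, sizes, reps = 100, seed = 1,
                                         n_boot = 1000, epoch = 2000) {
  if (!inherits(config, "sim_config")) abort_arg("config", "must be a sim_config")
  reps <- check_count(reps, "reps", lower = 1L)
  epoch <- check_count(epoch, "epoch", lower = 1L)
  seeds <- derive_seeds(seed, 2L)

  lac <- sweep_population_sizes(config, sizes, reps, seeds[1], n_boot = n_boot)
  cfg_epoch <- config
  cfg_epoch$horizon <- epoch
  fluct <- sweep_population_sizes(cfg_epoch, sizes, reps, seeds[2],
                                  n_boot = n_boot)

  summary <- data.frame(
    n_pop = lac$n_pop,
    f_s_lac = lac$f_s, ci_low_lac = lac$ci_low, ci_high_lac = lac$ci_high,
    f_2k = fluct$f_s,
    f_s_fluct = vapply(fluct$f_s, extrapolate_fluctuating, numeric(1)),
    f_s_combined = mapply(combined_fs, lac$f_s, fluct$f_s),
    n_reps = lac$n_reps
  )
  structure(list(summary = summary,
                 manifest = run_manifest(config, seed,
                                         sizes = sizes, reps = reps,
                                         epoch = epoch, n_boot = n_boot)),
            class = "fig_sweep")
}

#' Run manifest
#'
#' Records the configuration digest, master seed and settings of a run so
#' every reported number is traceable.
#'
#' @param config The [sim_config()] (or any configuration object) used.
#' @param seed Master seed.
#' @param ... Further named settings to record.
#' @return A list of class `run_manifest` with fields `config_digest`,
#'   `seed`, `package_version`, `created`, `settings`.
#' @export
run_manifest <- function(config, seed, ...) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  structure(list(
    config_digest = unname(tools::md5sum(f)),
    seed = seed,
    package_version = as.character(utils::packageVersion("epistasim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = list(...)
  ), class = "run_manifest")
}

validate_manifest <- function(manifest) {
  need <- c("config_digest", "seed", "package_version", "settings")
  for (field in need) {
    if (is.null(manifest[[field]])) {
      stop("invalid manifest: missing field `", field, "`", call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Write sweep results as CSV plus a JSON manifest
#'
#' @param sweep A `fig_sweep` from [reproduce_substitution_sweep()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  if (!inherits(sweep, "fig_sweep")) abort_arg("sweep", "must be a fig_sweep")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "substitution_sweep.csv")
  json <- file.path(dir, "manifest.json")
  utils::write.csv(sweep$summary, csv, row.names = FALSE)
  m <- unclass(sweep$manifest)
  m$created <- NULL # keep reruns byte-identical
  jsonlite::write_json(m, json, auto_unbox = TRUE, digits = NA)
  invisible(c(summary = csv, manifest = json))
}

#' Human-readable report of a set of computed results
#'
#' @param manifest A [run_manifest()].
#' @param results Named list of computed statistics (numbers or data frames);
#'   may be empty.
#' @return Character scalar of Markdown text; sections listed once per
#'   result, with config provenance up front. Missing (NULL) entries are
#'   listed as missing rather than failing.
#' @export
report <- function(manifest, results = list()) {
  if (!inherits(manifest, "run_manifest")) {
    abort_arg("manifest", "must be a run_manifest")
  }
  validate_manifest(manifest)
  lines <- c(
    "# Run report",
    "",
    sprintf("- config digest: `%s`", manifest$config_digest),
    sprintf("- master seed: %s", manifest$seed),
    sprintf("- package version: %s", manifest$package_version),
    ""
  )
  if (length(results) == 0L) {
    lines <- c(lines, "(no result sections)")
  } else {
    for (nm in names(results)) {
      lines <- c(lines, sprintf("## %s", nm), "")
      val <- results[[nm]]
      if (is.null(val)) {
        lines <- c(lines, "MISSING", "")
      } else if (is.data.frame(val)) {
        lines <- c(lines,
                   paste(utils::capture.output(print(val, row.names = FALSE)),
                         collapse = "\n"), "")
      } else {
        lines <- c(lines, paste(format(val), collapse = ", "), "")
      }
    }
  }
  paste(lines, collapse = "\n")
}
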