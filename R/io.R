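series_header <- function(config, seed = NULL) {
  h <- c(
    paste0("# pennaXY ", as.character(packageVersion("pennaXY"))),
    paste0("# mating: ", config$mating),
    paste0("# xy_regime: ", config$xy_regime),
    paste0("# config_hash: ", config_hash(config))
  )
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  h
}

config_hash <- function(config) {
  cfg <- config
  cfg$snapshot <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small stable polynomial hash; enough to flag config mismatches
  h <- 17
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 1000000007
  sprintf("%09d", h)
}

#' Write a time series as tab-separated text
#'
#' The header carries the package version, scenario, a config hash and the
#' seed as `#`-prefixed comment lines, followed by a tab-separated table.
#'
#' @param series a series data frame.
#' @param path output path.
#' @param config the run's [scenario_config()].
#' @param seed the replicate seed, if any.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, config, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(series_header(config, seed), con)
  write.table(series, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time series written by [write_series()]
#' @param path file path.
#' @return a data frame.
#' @export
read_series <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  # columns that were all-missing when written come back as logical
  df[] <- lapply(df, function(x)
    if (is.logical(x) && all(is.na(x))) as.numeric(x) else x)
  df
}

#' Write locus profiles as tab-separated text
#'
#' One row per locus and chromosome: columns `locus_rank` (1-based
#' activation rank), `chromosome`, `fraction`.
#'
#' @param profiles named list of numeric vectors (e.g. a run's
#'   `$profiles`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(names(profiles), function(nm)
    data.frame(locus_rank = seq_along(profiles[[nm]]), chromosome = nm,
               fraction = profiles[[nm]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$table <- lapply(as.data.frame(cfg$table), function(x)
    if (is.factor(x)) as.character(x) else x)
  cfg
}

list_to_config <- function(lst) {
  tab <- do.call(chromosome_table,
                 c(lst$table, list(basic_length = lst$basic_length)))
  lst$table <- tab
  do.call(scenario_config, lst)
}

#' Parse a scenario configuration
#'
#' Accepts either a preset name (`RU`, `RF`, `NU`, `NF`, `EU`, `EF`,
#' optionally `DESK-` prefixed) or the path to a YAML file with
#' [scenario_config()] fields (a `preset` key, if present, is expanded
#' first and the remaining keys override it; a `table` key may be a mapping
#' of table columns or a path to a tab-separated table).
#'
#' @param source preset name or file path.
#' @param ... overrides applied last.
#' @return a validated [scenario_config()].
#' @export
parse_config <- function(source, ...) {
  overrides <- list(...)
  if (file.exists(source)) {
    lst <- yaml::read_yaml(source)
    preset <- lst$preset
    lst$preset <- NULL
    if (!is.null(lst$table) && is.character(lst$table))
      lst$table <- read_chromosome_table(
        lst$table,
        basic_length = if (is.null(lst$basic_length)) 128L
                       else lst$basic_length)
    if (!is.null(lst$table) && is.list(lst$table) &&
        !inherits(lst$table, "chromosome_table"))
      lst$table <- do.call(chromosome_table, c(
        lst$table,
        list(basic_length = if (is.null(lst$basic_length)) 128L
                            else lst$basic_length)))
    args <- lst
    for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
    if (!is.null(preset)) return(do.call(scenario_preset,
                                         c(list(preset), args)))
    return(do.call(scenario_config, args))
  }
  do.call(scenario_preset, c(list(source), overrides))
}

#' Run a replicated experiment and write all outputs
#'
#' Executes `config$replicates` replicates (replicate `r` with seed
#' `config$seed + r - 1`), writing per-replicate series, the
#' replicate-averaged aggregate series, final locus profiles, and a YAML
#' manifest that echoes the full configuration and seed list so every
#' output can be reproduced byte for byte.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print per-replicate progress.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.yaml`).
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  validate_scenario_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + seq_len(config$replicates) - 1L
  runs <- vector("list", length(seeds))
  paths <- character(length(seeds))
  for (i in seq_along(seeds)) {
    runs[[i]] <- run_simulation(config, seed = seeds[i])
    paths[i] <- file.path(out_dir, sprintf("series_rep%02d.tsv", i))
    write_series(runs[[i]]$series, paths[i], config, seed = seeds[i])
    write_profiles(runs[[i]]$profiles,
                   file.path(out_dir, sprintf("profiles_rep%02d.tsv", i)))
    if (verbose)
      message("replicate ", i, "/", length(seeds), ": ",
              runs[[i]]$final_step, " steps",
              if (runs[[i]]$extinct) " (extinct)" else "")
  }
  agg_path <- file.path(out_dir, "series_aggregate.tsv")
  write_series(aggregate_series(runs), agg_path, config)
  manifest <- list(
    package = "pennaXY",
    version = as.character(packageVersion("pennaXY")),
    config = config_to_list(config),
    config_hash = config_hash(config),
    seeds = as.integer(seeds),
    series = basename(paths),
    aggregate = basename(agg_path),
    completed = vapply(runs, function(r) !r$extinct, logical(1)),
    extinct = vapply(runs, `[[`, logical(1), "extinct"),
    final_steps = vapply(runs, `[[`, numeric(1), "final_step")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Rebuild the configuration echoed in a manifest
#'
#' @param path path to a `manifest.yaml` written by [run_experiment()].
#' @return a [scenario_config()] identical to the one that produced the
#'   manifest.
#' @export
read_manifest_config <- function(path) {
  m <- yaml::read_yaml(path)
  list_to_config(m$config)
}
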