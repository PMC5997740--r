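cfg_to_cpp <- function(cfg) {
  tab <- cfg$table
  list(
    lattice_side = cfg$lattice_side,
    steps = cfg$steps,
    basic_length = cfg$basic_length,
    birth_check = cfg$birth_check,
    repro_age = cfg$repro_age,
    death_threshold = cfg$death_threshold,
    attempts_mean = cfg$attempts_mean,
    partner_range = cfg$partner_range,
    child_range = cfg$child_range,
    mating_code = if (cfg$mating == "faithful") 1L else 0L,
    regime_code = c(off = 0L, on = 1L, evolving = 2L)[[cfg$xy_regime]],
    modifier_step = cfg$modifier_step,
    mutation_dialect_code = mutation_dialect_code(cfg$mutation_dialect),
    crossover_dialect_code = crossover_dialect_code(cfg$crossover_dialect),
    panmictic = cfg$panmictic,
    ceiling = cfg$ceiling,
    record_every = cfg$record_every,
    comparator_index = match(cfg$comparator, tab$name) - 1L,
    sexpair_index = which(tab$is_sex_pair) - 1L,
    snapshot = cfg$snapshot,
    lengths = tab$length_genes,
    mutation_means = tab$mutation_mean,
    recomb_means = tab$recomb_mean
  )
}

safe_ratio <- function(num, den) ifelse(!is.na(den) & den > 0, num / den,
                                        NA_real_)

add_ratio_columns <- function(series) {
  for (coh in c("newborns", "youths", "adults")) {
    series[[paste0("ratio_X_over_10_", coh)]] <-
      safe_ratio(series[[paste0("frac_X_", coh)]],
                 series[[paste0("frac_comparator_", coh)]])
    series[[paste0("ratio_Y_over_X_", coh)]] <-
      safe_ratio(series[[paste0("frac_Y_", coh)]],
                 series[[paste0("frac_X_", coh)]])
    series[[paste0("ratio_M_over_F_", coh)]] <-
      safe_ratio(series[[paste0("n_males_", coh)]],
                 series[[paste0("n_females_", coh)]])
  }
  series
}

#' Run one simulation replicate
#'
#' Initializes a full lattice of mutation-free individuals of random sex and
#' age, then iterates Monte Carlo steps: ageing with disclosure of newly
#' activated homozygous defects and deaths (threshold `T` or maximum age
#' `L`), reproduction (females in random order, Poisson(`B`) conception
#' attempts, first success ends a female's attempts), and statistics
#' recording. The run is deterministic for a given `(config, seed)`.
#' Population extinction truncates the series and sets the `extinct` flag;
#' it is a reportable outcome, not an error.
#'
#' @param config a [scenario_config()].
#' @param seed seed for this replicate; defaults to `config$seed`.
#' @return list of class `"penna_run"`: `series` (data frame with cohort
#'   defect fractions, derived X/10, Y/X and M/F ratios, population counts
#'   and the mean normalized X-Y recombination), `profiles` (per-locus
#'   defective-allele fractions for X, Y and the comparator autosome at the
#'   final step), `extinct`, `final_step`, `final_pop`, `initial_xy_rate`,
#'   `seed`, `config`, and `snapshot` if requested.
#' @export
run_simulation <- function(config, seed = config$seed) {
  validate_scenario_config(config)
  set.seed(as.integer(seed))
  out <- cpp_run_simulation(cfg_to_cpp(config))
  series <- add_ratio_columns(as.data.frame(out$series))
  res <- list(series = series, profiles = out$profiles,
              extinct = out$extinct, final_step = out$final_step,
              final_pop = out$final_pop,
              initial_xy_rate = out$initial_xy_rate,
              seed = as.integer(seed), config = config)
  if (config$snapshot) res$snapshot <- lapply(out$snapshot, normalize_ind,
                                              table = config$table)
  class(res) <- "penna_run"
  res
}

normalize_ind <- function(ind, table) {
  pairs <- ind$genome
  names(pairs) <- table$name
  list(sex = if (ind$sex == 1L) "male" else "female",
       age = ind$age, cum_defects = ind$cum_defects,
       xy_modifier = ind$xy_modifier,
       position = c(ind$row + 1L, ind$col + 1L),
       genome = structure(list(pairs = pairs), table = table,
                          class = "penna_genome"))
}

#' Run replicates and average their time series
#'
#' Replicate `r` uses seed `config$seed + r - 1`, each with its own
#' generator state, so results do not depend on execution order.
#'
#' @param config a [scenario_config()].
#' @param replicates number of replicates (default from config).
#' @return list of class `"penna_replicates"`: `runs` (list of
#'   [run_simulation()] results), `aggregate` (per-step arithmetic mean of
#'   every recorded column across replicates), `seeds`, `config`.
#' @export
run_replicates <- function(config, replicates = config$replicates) {
  seeds <- config$seed + seq_len(replicates) - 1L
  runs <- lapply(seeds, function(s) run_simulation(config, seed = s))
  structure(list(runs = runs, aggregate = aggregate_series(runs),
                 seeds = seeds, config = config),
            class = "penna_replicates")
}

#' Average time series across replicates
#'
#' Arithmetic mean per recorded step of every numeric column; steps missing
#' from a truncated (extinct) replicate simply contribute fewer values.
#'
#' @param runs a `"penna_replicates"` object, or a list of `"penna_run"`
#'   objects or of their `series` data frames.
#' @return a data frame in the same layout as a single series.
#' @export
aggregate_series <- function(runs) {
  if (inherits(runs, "penna_replicates")) runs <- runs$runs
  series <- lapply(runs, function(r) if (inherits(r, "penna_run")) r$series
                   else r)
  all <- do.call(rbind, series)
  cols <- setdiff(names(all), "step")
  agg <- aggregate(all[cols], by = list(step = all$step),
                   FUN = function(x) mean(x, na.rm = TRUE))
  agg[order(agg$step), , drop = FALSE]
}

#' @export
print.penna_run <- function(x, ...) {
  cat("<penna_run> ", x$config$mating, " mating, X-Y regime '",
      x$config$xy_regime, "'\n", sep = "")
  cat("  steps run: ", x$final_step, if (x$extinct) "  (EXTINCT)", "\n",
      sep = "")
  cat("  final population: ", x$final_pop, "\n", sep = "")
  invisible(x)
}

#' @export
print.penna_replicates <- function(x, ...) {
  cat("<penna_replicates> ", length(x$runs), " replicates, seeds ",
      x$seeds[1], "..", x$seeds[length(x$seeds)], "\n", sep = "")
  ext <- sum(vapply(x$runs, `[[`, logical(1), "extinct"))
  if (ext > 0) cat("  extinct replicates: ", ext, "\n", sep = "")
  invisible(x)
}
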