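#' Scenario configuration
#'
#' Collects every free parameter of a run. Defaults follow the study
#' conditions: basic chromosome length (= maximum lifespan) `L = 128`, loci
#' checked before birth `b = 75`, reproductive age `R = 105`, genetic-death
#' threshold `T = 3` (unfaithful) or `T = 20` (faithful), mean conception
#' attempts per female per step `B = 8`, partner and child search ranges
#' `D_p = D_c = 6` on a 128 x 128 torus, 1,000,000 steps, 50 replicates.
#'
#' @param mating `"unfaithful"` (a new partner may be drawn at every
#'   conception attempt) or `"faithful"` (lifelong pair bond, dissolved only
#'   by death; widowed individuals may re-pair).
#' @param xy_regime X-Y recombination in males: `"on"` (the sex pair's table
#'   rate, as between X chromosomes), `"off"` (0), or `"evolving"` (each
#'   male carries a heritable modifier passed father to son, mutated by
#'   `+/- modifier_step` per transmission and absorbed at 0; initial value =
#'   the X-X rate).
#' @param basic_length,birth_check,repro_age,death_threshold,attempts_mean
#'   the parameters `L`, `b`, `R`, `T`, `B` described above.
#' @param partner_range,child_range toroidal Chebyshev search half-widths
#'   `D_p`, `D_c`.
#' @param lattice_side side of the torus; its square caps the population.
#' @param steps Monte Carlo steps (one step = one year of ageing).
#' @param replicates number of independent runs averaged by
#'   [run_replicates()].
#' @param seed base seed; replicate `r` uses `seed + r - 1`.
#' @param modifier_step mutation step of the X-Y recombination modifier.
#' @param table a [chromosome_table()].
#' @param comparator name of the autosome used as the X's comparator
#'   (default `"chr10"` if present, else the first autosome).
#' @param mutation_dialect,crossover_dialect see
#'   [replicate_with_mutation()] and [crossover()].
#' @param panmictic drop the lattice: partners are drawn from all eligible
#'   males and births are capped by `ceiling`.
#' @param ceiling population cap in panmictic mode (default
#'   `lattice_side^2`).
#' @param record_every record a time-series row every this many steps
#'   (default: every step up to 100,000 steps, every 100th beyond).
#' @param snapshot return the final population (sexes, ages, modifiers and
#'   full genomes) with the run.
#' @return a validated list of class `"scenario_config"`.
#' @seealso [scenario_preset()] for the named scenario grid.
#' @export
scenario_config <- function(mating = c("unfaithful", "faithful"),
                            xy_regime = c("on", "off", "evolving"),
                            basic_length = 128L,
                            birth_check = 75L,
                            repro_age = 105L,
                            death_threshold = NULL,
                            attempts_mean = 8,
                            partner_range = 6L,
                            child_range = 6L,
                            lattice_side = 128L,
                            steps = 1000000L,
                            replicates = 50L,
                            seed = 1L,
                            modifier_step = 0.05,
                            table = human_chromosome_table(basic_length),
                            comparator = NULL,
                            mutation_dialect = c("bernoulli", "poisson"),
                            crossover_dialect = c("poisson", "bernoulli"),
                            panmictic = FALSE,
                            ceiling = NULL,
                            record_every = NULL,
                            snapshot = FALSE) {
  mating <- match.arg(mating)
  xy_regime <- match.arg(xy_regime)
  mutation_dialect <- match.arg(mutation_dialect)
  crossover_dialect <- match.arg(crossover_dialect)
  if (is.null(death_threshold))
    death_threshold <- if (mating == "faithful") 20L else 3L
  if (is.null(ceiling)) ceiling <- as.integer(lattice_side)^2
  if (is.null(record_every))
    record_every <- if (steps <= 100000L) 1L else 100L
  validate_chromosome_table(table)
  if (is.null(comparator)) {
    autos <- table$name[!table$is_sex_pair]
    comparator <- if ("chr10" %in% autos) "chr10" else autos[1]
  }
  cfg <- list(
    mating = mating, xy_regime = xy_regime,
    basic_length = as.integer(basic_length),
    birth_check = as.integer(birth_check),
    repro_age = as.integer(repro_age),
    death_threshold = as.integer(death_threshold),
    attempts_mean = as.numeric(attempts_mean),
    partner_range = as.integer(partner_range),
    child_range = as.integer(child_range),
    lattice_side = as.integer(lattice_side),
    steps = as.integer(steps),
    replicates = as.integer(replicates),
    seed = as.integer(seed),
    modifier_step = as.numeric(modifier_step),
    table = table, comparator = comparator,
    mutation_dialect = mutation_dialect,
    crossover_dialect = crossover_dialect,
    panmictic = isTRUE(panmictic),
    ceiling = as.integer(ceiling),
    record_every = as.integer(record_every),
    snapshot = isTRUE(snapshot)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#' @param cfg a [scenario_config()].
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (!(0L < birth_check && birth_check < repro_age &&
          repro_age <= basic_length))
      stop("need 0 < birth_check (b) < repro_age (R) <= basic_length (L); ",
           "got b=", birth_check, ", R=", repro_age, ", L=", basic_length)
    if (death_threshold < 1L) stop("death_threshold (T) must be >= 1")
    if (attempts_mean < 0) stop("attempts_mean (B) must be >= 0")
    if (steps < 0L) stop("steps must be >= 0")
    if (replicates < 1L) stop("replicates must be >= 1")
    if (record_every < 1L) stop("record_every must be >= 1")
    if (modifier_step < 0) stop("modifier_step must be >= 0")
    if (!panmictic) {
      if (lattice_side < 2L) stop("lattice_side must be >= 2")
      if (partner_range < 1L || partner_range >= lattice_side)
        stop("partner_range (D_p) must be in 1..lattice_side-1")
      if (child_range < 1L || child_range >= lattice_side)
        stop("child_range (D_c) must be in 1..lattice_side-1")
    } else if (ceiling < 1L) {
      stop("ceiling must be >= 1 in panmictic mode")
    }
    if (attr(table, "basic_length") != basic_length)
      stop("chromosome table basic_length does not match config")
    if (mutation_dialect == "bernoulli" && any(table$mutation_mean > 1))
      stop("mutation_mean must be <= 1 under the bernoulli dialect")
    if (!comparator %in% table$name[!table$is_sex_pair])
      stop("comparator must name an autosome in the table")
  })
  invisible(cfg)
}

preset_grid <- list(
  RU = list(xy_regime = "on",       mating = "unfaithful", death_threshold = 3L),
  RF = list(xy_regime = "on",       mating = "faithful",   death_threshold = 20L),
  NU = list(xy_regime = "off",      mating = "unfaithful", death_threshold = 3L),
  NF = list(xy_regime = "off",      mating = "faithful",   death_threshold = 20L),
  EU = list(xy_regime = "evolving", mating = "unfaithful", death_threshold = 3L),
  EF = list(xy_regime = "evolving", mating = "faithful",   death_threshold = 20L)
)

#' Named scenario presets
#'
#' The six-scenario grid crossing the mating system with the X-Y
#' recombination regime: `RU` (recombination on, unfaithful, T = 3), `RF`
#' (on, faithful, T = 20), `NU` (off, unfaithful, T = 3), `NF` (off,
#' faithful, T = 20), `EU` (evolving, unfaithful, T = 3), `EF` (evolving,
#' faithful, T = 20). Full-scale presets use the 23-pair table on a
#' 128 x 128 lattice for 1,000,000 steps and 50 replicates. Prefixing
#' `DESK-` (e.g. `"DESK-NU"`) selects the desk-scale profile: 32 x 32
#' lattice, three-pair toy table, 20,000 steps, 5 replicates. Every field
#' can be overridden through `...`.
#'
#' @param name preset name, case-insensitive.
#' @param ... overrides passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name, ...) {
  name <- toupper(name)
  desk <- startsWith(name, "DESK-")
  key <- sub("^DESK-", "", name)
  if (!key %in% names(preset_grid))
    stop("unknown preset '", name, "'; available: ",
         paste(c(names(preset_grid), paste0("DESK-", names(preset_grid))),
               collapse = ", "))
  args <- preset_grid[[key]]
  if (desk) {
    args$lattice_side <- 32L
    args$steps <- 20000L
    args$replicates <- 5L
    args$table <- toy_chromosome_table()
  }
  overrides <- list(...)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(scenario_config, args)
}
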