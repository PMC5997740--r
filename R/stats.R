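#' Age cohort of an individual
#'
#' Newborns are individuals at the birth time (age 0, i.e. born this step),
#' youths lie strictly between birth and the reproductive age, adults are at
#' or beyond the reproductive age.
#'
#' @param age integer age(s).
#' @param repro_age the reproductive age `R`.
#' @return character vector: `"newborns"`, `"youths"` or `"adults"`.
#' @export
cohort_of <- function(age, repro_age) {
  ifelse(age == 0L, "newborns",
         ifelse(age < repro_age, "youths", "adults"))
}

pool_fraction <- function(pop, table, chrom = c("X", "Y", "comparator"),
                          comparator = NULL, per_locus = FALSE) {
  chrom <- match.arg(chrom)
  sex_name <- table$name[table$is_sex_pair]
  len <- if (chrom == "comparator") {
    table$length_genes[match(comparator, table$name)]
  } else {
    table$length_genes[table$is_sex_pair]
  }
  counts <- if (per_locus) numeric(len) else 0
  ncopies <- 0L
  for (ind in pop) {
    copies <- list()
    if (chrom == "X") {
      p <- ind$genome$pairs[[sex_name]]
      copies <- if (ind$sex == "female") list(p$a, p$b) else list(p$a)
    } else if (chrom == "Y") {
      if (ind$sex == "male") copies <- list(ind$genome$pairs[[sex_name]]$b)
    } else {
      p <- ind$genome$pairs[[comparator]]
      copies <- list(p$a, p$b)
    }
    for (cp in copies) {
      counts <- counts + if (per_locus) cp else sum(cp)
      ncopies <- ncopies + 1L
    }
  }
  if (ncopies == 0L) return(if (per_locus) rep(NA_real_, len) else NA_real_)
  if (per_locus) counts / ncopies else counts / (ncopies * len)
}

#' Cohort mutation-load ratios
#'
#' Mean per-copy defective-allele fractions are computed for three pools: X
#' copies (both copies in females, the single X in males), Y copies (males
#' only) and the comparator autosome (both copies, everyone); the X/10 and
#' Y/X readouts are ratios of these means. Using per-copy fractions rather
#' than raw counts keeps chromosomes of unequal configured length
#' comparable; for length-matched X and comparator the two coincide. A ratio
#' whose denominator pool is empty or defect-free is reported as `NA`
#' (undefined), never as 0.
#'
#' @param pop list of individuals (e.g. a run snapshot), each with `$sex`
#'   (`"male"`/`"female"`) and `$genome`.
#' @param table the [chromosome_table()] of the population.
#' @param comparator autosome name for the X/10 denominator.
#' @return list with `ratio_X_over_10`, `ratio_Y_over_X` and the three pool
#'   means `frac_X`, `frac_Y`, `frac_comparator`.
#' @export
mutation_ratios <- function(pop, table, comparator) {
  if (length(pop) == 0L)
    return(list(ratio_X_over_10 = NA_real_, ratio_Y_over_X = NA_real_,
                frac_X = NA_real_, frac_Y = NA_real_,
                frac_comparator = NA_real_))
  fx <- pool_fraction(pop, table, "X")
  fy <- pool_fraction(pop, table, "Y")
  fc <- pool_fraction(pop, table, "comparator", comparator = comparator)
  list(
    ratio_X_over_10 = if (!is.na(fc) && fc > 0) fx / fc else NA_real_,
    ratio_Y_over_X = if (!is.na(fx) && fx > 0 && !is.na(fy)) fy / fx
                     else NA_real_,
    frac_X = fx, frac_Y = fy, frac_comparator = fc
  )
}

#' Males-per-female ratio of a cohort
#'
#' @param pop list of individuals with `$sex`.
#' @return `count(males) / count(females)`; `NA` when there are no females.
#' @export
sex_ratio <- function(pop) {
  sexes <- vapply(pop, `[[`, character(1), "sex")
  nf <- sum(sexes == "female")
  if (nf == 0L) return(NA_real_)
  sum(sexes == "male") / nf
}

#' Per-locus defective-allele profile
#'
#' For each locus (ranked by activation time, i.e. in bit order) the
#' fraction of defective alleles across all pooled copies of the named
#' chromosome type: `"X"` pools both female copies and the male X, `"Y"`
#' pools male Y copies only, an autosome name pools both copies of
#' everyone.
#'
#' @param pop list of individuals with `$sex` and `$genome`.
#' @param table the population's [chromosome_table()].
#' @param chrom `"X"`, `"Y"` or an autosome name.
#' @return numeric vector of length `length_genes`, values in `[0, 1]`
#'   (`NA` if the pool is empty).
#' @export
locus_profile <- function(pop, table, chrom) {
  if (chrom %in% c("X", "Y")) {
    pool_fraction(pop, table, chrom, per_locus = TRUE)
  } else {
    if (!chrom %in% table$name[!table$is_sex_pair])
      stop("unknown chromosome: ", chrom)
    pool_fraction(pop, table, "comparator", comparator = chrom,
                  per_locus = TRUE)
  }
}

#' OLS slope of the Y/X ratio against time
#'
#' Ordinary least-squares fit of a cohort's Y/X mutation ratio against the
#' simulation step, with the slope rescaled to per-100,000-step units (the
#' scale on which the degeneration rate is usually quoted). `NA` ratio
#' values (undefined early steps) are dropped.
#'
#' @param series a run or aggregate series data frame.
#' @param cohort `"newborns"`, `"youths"` or `"adults"`.
#' @return list with `slope` (per 100,000 steps), `intercept` and
#'   `r_squared`.
#' @export
yx_slope <- function(series, cohort = c("newborns", "youths", "adults")) {
  cohort <- match.arg(cohort)
  y <- series[[paste0("ratio_Y_over_X_", cohort)]]
  keep <- !is.na(y)
  if (sum(keep) < 2L) stop("need at least two defined Y/X values")
  x <- series$step[keep] / 1e5
  fit <- lm(y[keep] ~ x)
  sstot <- sum((y[keep] - mean(y[keep]))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(fit$residuals^2) / sstot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' First step at which X-Y recombination is fully suppressed
#'
#' The first recorded step whose mean normalized X-Y recombination equals
#' 0. Because the modifier walk is absorbing at 0, a later non-zero value
#' indicates the series was not produced by the evolving regime's absorbing
#' dynamics; the first zero is still returned, with a warning.
#'
#' @param series a run or aggregate series data frame with a
#'   `mean_norm_xy_recomb` column.
#' @return the step (numeric), or `NA` if the rate never reaches 0.
#' @export
suppression_step <- function(series) {
  r <- series$mean_norm_xy_recomb
  hit <- which(!is.na(r) & r == 0)
  if (length(hit) == 0L) return(NA_real_)
  first <- hit[1]
  later <- r[seq_along(r) > first]
  if (any(!is.na(later) & later > 0))
    warning("recombination rose above 0 after its first zero ",
            "(non-absorbing series)")
  series$step[first]
}

#' Jukes-Cantor correction for multiple substitutions
#'
#' Converts an observed substitution fraction `p` into an estimated
#' divergence `K = -(3/4) * log(1 - (4/3) p)`, the one-parameter correction
#' for unobserved multiple hits at the same site. Defined for
#' `0 <= p < 0.75`; `K >= p`, with equality only at 0.
#'
#' @param p substitution fraction(s) in `[0, 0.75)`.
#' @return corrected divergence(s).
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p) | p < 0 | p >= 0.75))
    stop("jukes_cantor is defined for 0 <= p < 0.75")
  -0.75 * log(1 - 4 * p / 3)
}
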