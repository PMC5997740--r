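stats_table <- function() {
  chromosome_table(c("chr10", "XY"), c(8L, 8L), c(0, 0), c(0, 0),
                   c(FALSE, TRUE), basic_length = 8L)
}

test_that("age cohorts split at birth and reproductive age", {
  expect_identical(cohort_of(0L, 105L), "newborns")
  expect_identical(cohort_of(1L, 105L), "youths")
  expect_identical(cohort_of(104L, 105L), "youths")
  expect_identical(cohort_of(105L, 105L), "adults")
  expect_identical(cohort_of(c(0L, 50L, 120L), 105L),
                   c("newborns", "youths", "adults"))
})

test_that("mutation ratios reproduce a hand-computed example", {
  tab <- stats_table()
  # one female: X copies with fractions 0.5 and 0.25, chr10 both 0.25
  f <- make_ind("female", tab, list(
    list(a = c(1L, 1L, rep(0L, 6)), b = c(1L, 1L, rep(0L, 6))),
    list(a = c(1L, 1L, 1L, 1L, rep(0L, 4)), b = c(1L, 1L, rep(0L, 6)))))
  out <- mutation_ratios(list(f), tab, "chr10")
  expect_equal(out$frac_X, 0.375)
  expect_equal(out$frac_comparator, 0.25)
  expect_equal(out$ratio_X_over_10, 1.5)
  expect_true(is.na(out$ratio_Y_over_X))  # no males, empty Y pool
})

test_that("defect-free and empty cohorts give undefined ratios, not zero", {
  tab <- stats_table()
  zero <- make_ind("male", tab, list(
    list(a = integer(8), b = integer(8)),
    list(a = integer(8), b = integer(8))))
  out <- mutation_ratios(list(zero), tab, "chr10")
  expect_true(is.na(out$ratio_X_over_10))
  expect_true(is.na(out$ratio_Y_over_X))
  empty <- mutation_ratios(list(), tab, "chr10")
  expect_true(is.na(empty$frac_X))
  expect_true(is.na(empty$ratio_X_over_10))
})

test_that("mutation ratios equal a naive per-individual loop", {
  set.seed(40)
  tab <- stats_table()
  for (i in 1:50) {
    pop <- lapply(seq_len(sample(2:12, 1)), function(j)
      make_ind(sample(c("male", "female"), 1), tab, list(
        list(a = as.integer(runif(8) < 0.4), b = as.integer(runif(8) < 0.4)),
        list(a = as.integer(runif(8) < 0.4),
             b = as.integer(runif(8) < 0.4)))))
    out <- mutation_ratios(pop, tab, "chr10")
    fx <- naive_pool_fraction(collect_copies(pop, tab, "X"))
    fy <- naive_pool_fraction(collect_copies(pop, tab, "Y"))
    fc <- naive_pool_fraction(collect_copies(pop, tab, "chr10"))
    expect_equal(out$frac_X, fx)
    expect_equal(out$frac_Y, fy)
    expect_equal(out$frac_comparator, fc)
    if (!is.na(fc) && fc > 0) expect_equal(out$ratio_X_over_10, fx / fc)
  }
})

test_that("sex ratio counts males per female", {
  mk <- function(s) list(sex = s)
  expect_equal(sex_ratio(lapply(c("male", "male", "female", "female"), mk)),
               1.0)
  expect_equal(sex_ratio(lapply(rep("female", 5), mk)), 0.0)
  expect_true(is.na(sex_ratio(lapply(rep("male", 3), mk))))
})

test_that("locus profiles match hand-set bits and a naive loop", {
  tab <- stats_table()
  m <- make_ind("male", tab, list(
    list(a = integer(8), b = integer(8)),
    list(a = c(1L, rep(0L, 7)), b = rep(1L, 8))))       # X then Y
  f <- make_ind("female", tab, list(
    list(a = integer(8), b = integer(8)),
    list(a = c(1L, 1L, rep(0L, 6)), b = integer(8))))   # two X copies
  pop <- list(m, f)
  # X pool: male a + female a,b -> 3 copies; locus 1 defective in 2 of 3
  px <- locus_profile(pop, tab, "X")
  expect_equal(px[1], 2 / 3)
  expect_equal(px[2], 1 / 3)
  expect_equal(px[3:8], rep(0, 6))
  py <- locus_profile(pop, tab, "Y")
  expect_equal(py, rep(1, 8))
  pa <- locus_profile(pop, tab, "chr10")
  expect_equal(pa, rep(0, 8))
  expect_error(locus_profile(pop, tab, "chrZ"), "unknown chromosome")

  set.seed(41)
  for (i in 1:20) {
    pop <- lapply(1:6, function(j)
      make_ind(sample(c("male", "female"), 1), tab, list(
        list(a = as.integer(runif(8) < 0.5), b = as.integer(runif(8) < 0.5)),
        list(a = as.integer(runif(8) < 0.5),
             b = as.integer(runif(8) < 0.5)))))
    for (chrom in c("X", "Y", "chr10")) {
      copies <- collect_copies(pop, tab, chrom)
      naive <- if (length(copies) == 0) rep(NA_real_, 8)
               else colMeans(do.call(rbind, copies))
      expect_equal(locus_profile(pop, tab, chrom), naive)
    }
  }
})

test_that("locus profiles from a run lie in [0, 1] and cover the genome", {
  r <- run_simulation(scenario_preset("DESK-RU", lattice_side = 16L,
                                      steps = 500L, replicates = 1L),
                      seed = 13)
  for (p in r$profiles) {
    expect_length(p, 128L)
    expect_true(all(is.na(p) | (p >= 0 & p <= 1)))
  }
})

test_that("Y/X slope recovers a synthetic line exactly", {
  steps <- seq(0, 100000, by = 500)
  series <- data.frame(step = steps,
                       ratio_Y_over_X_youths = 1 + 16.69 * steps / 1e5)
  fit <- yx_slope(series, "youths")
  expect_equal(fit$slope, 16.69)
  expect_equal(fit$r_squared, 1)
  flat <- data.frame(step = steps, ratio_Y_over_X_adults = 2)
  expect_equal(yx_slope(flat, "adults")$slope, 0)
})

test_that("Y/X slope equals closed-form least squares on noisy series", {
  set.seed(42)
  for (i in 1:20) {
    x <- 0:200 * 100
    y <- 0.5 + 0.02 * x / 1e5 + rnorm(length(x), sd = 0.3)
    y[sample(length(y), 5)] <- NA  # undefined early ratios are dropped
    series <- data.frame(step = x, ratio_Y_over_X_newborns = y)
    fit <- yx_slope(series, "newborns")
    keep <- !is.na(y)
    xs <- x[keep] / 1e5
    ys <- y[keep]
    slope <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sum((xs - mean(xs))^2)
    expect_equal(fit$slope, slope)
  }
})

test_that("suppression step is the first zero of the normalized rate", {
  never <- data.frame(step = 0:10 * 1000,
                      mean_norm_xy_recomb = seq(1, 0.5, length.out = 11))
  expect_true(is.na(suppression_step(never)))
  hit <- data.frame(step = 0:20 * 1000,
                    mean_norm_xy_recomb = c(seq(1, 0.05, length.out = 17),
                                            rep(0, 4)))
  expect_equal(suppression_step(hit), 17000)
  bounce <- data.frame(step = 0:4, mean_norm_xy_recomb = c(1, 0, 0.3, 0, 0))
  expect_warning(s <- suppression_step(bounce), "non-absorbing")
  expect_equal(s, 1)
})

test_that("Jukes-Cantor correction matches its closed form", {
  expect_equal(jukes_cantor(0), 0)
  # small-p limit: K/p -> 1
  expect_equal(jukes_cantor(1e-8) / 1e-8, 1, tolerance = 1e-6)
  expect_equal(jukes_cantor(0.3), 0.38312, tolerance = 5e-6)
  expect_error(jukes_cantor(0.75), "0 <= p < 0.75")
  expect_error(jukes_cantor(-0.1), "0 <= p < 0.75")
  # strictly increasing and at least the identity on (0, 0.75)
  p <- seq(0.001, 0.74, length.out = 200)
  k <- jukes_cantor(p)
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= p))
})
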