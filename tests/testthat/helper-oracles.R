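# Naive reference implementations and tiny fixtures used as independent
# oracles against the bit-packed C++ paths.

# report every failure instead of aborting the run after the default 10
options(testthat.progress.max_fails = 1000)

naive_popcount <- function(bits) sum(bits)

naive_homo_count <- function(a, b, lo, hi) {
  if (lo >= hi) return(0L)
  idx <- (lo + 1L):hi  # [lo, hi) in 0-based coordinates
  sum(a[idx] == 1L & b[idx] == 1L)
}

naive_torus_distance <- function(a, b, side) {
  d <- abs(a - b)
  max(pmin(d, side - d))
}

# all cells of a side x side grid within toroidal Chebyshev distance range_d
# of `cell`, by exhaustive scan
naive_cells_within <- function(cell, range_d, side) {
  out <- NULL
  for (r in 1:side) for (c in 1:side) {
    if (r == cell[1] && c == cell[2]) next
    if (naive_torus_distance(c(r, c), cell, side) <= range_d)
      out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

tiny_table <- function(len = 16L, mu = 0.1, rec = 0.5) {
  chromosome_table(c("a1", "a2", "xy"), rep(len, 3L), rep(mu, 3L),
                   rep(rec, 3L), c(FALSE, FALSE, TRUE), basic_length = len)
}

random_genome <- function(table, p = 0.3) {
  pairs <- lapply(table$length_genes, function(n)
    list(a = as.integer(runif(n) < p), b = as.integer(runif(n) < p)))
  names(pairs) <- table$name
  new_genome(table, pairs)
}

# hand-built population member for the stats module
make_ind <- function(sex, table, bits_by_chrom, age = 1L) {
  pairs <- lapply(seq_len(nrow(table)), function(i) bits_by_chrom[[i]])
  names(pairs) <- table$name
  list(sex = sex, age = age, cum_defects = 0L, xy_modifier = 0,
       genome = new_genome(table, pairs))
}

# mean per-copy defective fraction of a pooled set of copies (list of bit
# vectors), the quantity the ratio readouts are built from
naive_pool_fraction <- function(copies) {
  if (length(copies) == 0L) return(NA_real_)
  mean(vapply(copies, function(cp) mean(cp), numeric(1)))
}

# collect the pooled copies of one chromosome type from a population
collect_copies <- function(pop, table, chrom) {
  sex_name <- table$name[table$is_sex_pair]
  out <- list()
  for (ind in pop) {
    if (chrom == "X") {
      p <- ind$genome$pairs[[sex_name]]
      out <- c(out, if (ind$sex == "female") list(p$a, p$b) else list(p$a))
    } else if (chrom == "Y") {
      if (ind$sex == "male")
        out <- c(out, list(ind$genome$pairs[[sex_name]]$b))
    } else {
      p <- ind$genome$pairs[[chrom]]
      out <- c(out, list(p$a, p$b))
    }
  }
  out
}

desk_scenarios <- new.env(parent = emptyenv())

# desk-scale replicate sets used by several behavioural tests; computed once
desk_runs <- function(preset, seed = 1L) {
  key <- paste0(preset, "_", seed)
  if (is.null(desk_scenarios[[key]])) {
    cfg <- scenario_preset(preset, seed = seed)
    desk_scenarios[[key]] <- run_replicates(cfg)
  }
  desk_scenarios[[key]]
}
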