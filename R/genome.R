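dialect_codes <- list(
  mutation = c(bernoulli = 0L, poisson = 1L),
  crossover = c(poisson = 0L, bernoulli = 1L)
)

mutation_dialect_code <- function(dialect) {
  dialect <- match.arg(dialect, c("bernoulli", "poisson"))
  dialect_codes$mutation[[dialect]]
}

crossover_dialect_code <- function(dialect) {
  dialect <- match.arg(dialect, c("poisson", "bernoulli"))
  dialect_codes$crossover[[dialect]]
}

check_bits <- function(x, arg = "chromosome") {
  if (length(x) < 1L || !all(x %in% c(0L, 1L)))
    stop(arg, " must be a non-empty vector of 0/1 alleles")
  as.integer(x)
}

#' Replicate a chromosome with mutation
#'
#' Copies a bit-string chromosome, introducing new defective (1) alleles at
#' uniformly chosen loci. Mutation is one-way: a locus already defective
#' stays defective when hit (the event is consumed, there are no reversions),
#' so the defect count never decreases.
#'
#' Under the default `"bernoulli"` dialect, with probability `mutation_mean`
#' exactly one uniformly chosen locus is hit (requires
#' `mutation_mean <= 1`); under `"poisson"` the number of hits is drawn from
#' a Poisson with that mean.
#'
#' @param chrom integer vector of 0/1 alleles.
#' @param mutation_mean expected new mutations per replication.
#' @param dialect `"bernoulli"` (default) or `"poisson"`.
#' @return the mutated copy, an integer vector of the same length.
#' @export
replicate_with_mutation <- function(chrom, mutation_mean,
                                    dialect = c("bernoulli", "poisson")) {
  chrom <- check_bits(chrom)
  dialect <- match.arg(dialect)
  if (!is.finite(mutation_mean) || mutation_mean < 0)
    stop("mutation_mean must be a non-negative number")
  if (dialect == "bernoulli" && mutation_mean > 1)
    stop("mutation_mean must be <= 1 under the bernoulli dialect")
  cpp_mutate_chrom(chrom, mutation_mean, mutation_dialect_code(dialect))
}

#' Reciprocal crossover between two homologous chromosomes
#'
#' Draws a number of crossover events (Poisson with mean `recomb_mean` by
#' default, or a single Bernoulli event) at distinct intergenic boundaries
#' `1..length-1` and returns the two reciprocal exchange products. The
#' multiset of alleles at every position is conserved: what leaves one
#' product enters the other.
#'
#' @param a,b integer 0/1 vectors of equal length.
#' @param recomb_mean expected crossover events per meiosis.
#' @param dialect `"poisson"` (default) or `"bernoulli"` (at most one event).
#' @param points optional integer vector of forced boundaries (positions
#'   after which the exchange starts, in `1..length-1`); when given,
#'   `recomb_mean` and `dialect` are ignored.
#' @return list with elements `a` and `b`, the two products, and `points`,
#'   the boundaries used.
#' @export
crossover <- function(a, b, recomb_mean = 0,
                      dialect = c("poisson", "bernoulli"), points = NULL) {
  a <- check_bits(a, "a")
  b <- check_bits(b, "b")
  if (length(a) != length(b))
    stop("crossover requires chromosomes of equal length")
  if (!is.null(points)) {
    points <- as.integer(points)
    if (any(points < 1L | points > length(a) - 1L))
      stop("crossover points must lie in 1..length-1")
    out <- cpp_crossover_at(a, b, points)
    out$points <- sort(points)
    return(out)
  }
  dialect <- match.arg(dialect)
  if (!is.finite(recomb_mean) || recomb_mean < 0)
    stop("recomb_mean must be a non-negative number")
  cpp_crossover_chrom(a, b, recomb_mean, crossover_dialect_code(dialect))
}

#' Construct a diploid genome
#'
#' @param table a [chromosome_table()].
#' @param pairs optional named list (one entry per chromosome, in table
#'   order) of `list(a = bits, b = bits)`; defaults to all-zero
#'   (mutation-free) copies. For the sex pair of a male, copy `a` is the X
#'   and copy `b` the Y.
#' @return a list of class `"penna_genome"` with elements `pairs` and
#'   attribute `table`.
#' @export
new_genome <- function(table, pairs = NULL) {
  validate_chromosome_table(table)
  if (is.null(pairs)) {
    pairs <- lapply(table$length_genes, function(n)
      list(a = integer(n), b = integer(n)))
    names(pairs) <- table$name
  }
  if (length(pairs) != nrow(table))
    stop("genome must have one pair per chromosome spec")
  for (i in seq_len(nrow(table))) {
    p <- pairs[[i]]
    p$a <- check_bits(p$a)
    p$b <- check_bits(p$b)
    if (length(p$a) != table$length_genes[i] ||
        length(p$b) != table$length_genes[i])
      stop("copy lengths of '", table$name[i], "' do not match its spec")
    pairs[[i]] <- p
  }
  names(pairs) <- table$name
  structure(list(pairs = pairs), table = table, class = "penna_genome")
}

#' Form a haploid gamete from a diploid genome
#'
#' Mimics meiosis pair by pair: both copies are replicated with mutation,
#' the replicates recombine, and one of the two products is chosen uniformly.
#' Autosomes and the female sex pair recombine at the table's per-pair rate;
#' the male sex pair recombines at `xy_recomb` (0 = suppressed). For a male,
#' the product of the sex pair that keeps the chromosome head (index-0 side)
#' of the parental Y is the Y: `sex_carried` records which product was
#' drawn.
#'
#' @param genome a [new_genome()].
#' @param sex `"male"` or `"female"`.
#' @param xy_recomb expected X-Y crossovers for a male's sex pair; ignored
#'   for females (their sex pair is X-X and uses the table rate).
#' @param mutation_dialect,crossover_dialect see
#'   [replicate_with_mutation()] and [crossover()].
#' @return list of class `"penna_gamete"`: `chromosomes` (named list of bit
#'   vectors) and `sex_carried` (`"X"` or `"Y"`).
#' @export
make_gamete <- function(genome, sex = c("female", "male"), xy_recomb = NULL,
                        mutation_dialect = c("bernoulli", "poisson"),
                        crossover_dialect = c("poisson", "bernoulli")) {
  sex <- match.arg(sex)
  table <- attr(genome, "table")
  mdial <- mutation_dialect_code(match.arg(mutation_dialect))
  cdial <- crossover_dialect_code(match.arg(crossover_dialect))
  if (sex == "male") {
    if (is.null(xy_recomb) || !is.finite(xy_recomb) || xy_recomb < 0)
      stop("a male gamete requires a non-negative xy_recomb")
  }
  chroms <- vector("list", nrow(table))
  names(chroms) <- table$name
  sex_carried <- "X"
  for (i in seq_len(nrow(table))) {
    rate <- table$recomb_mean[i]
    if (table$is_sex_pair[i] && sex == "male") rate <- xy_recomb
    g <- cpp_make_gamete_chrom(genome$pairs[[i]]$a, genome$pairs[[i]]$b,
                               table$mutation_mean[i], mdial, rate, cdial)
    chroms[[i]] <- g$bits
    if (table$is_sex_pair[i] && sex == "male" && g$pick == 1L)
      sex_carried <- "Y"
  }
  structure(list(chromosomes = chroms, sex_carried = sex_carried),
            class = "penna_gamete")
}

#' Count homozygous defects over an activation window
#'
#' Counts loci where both copies carry the defective allele, within the
#' half-open window `[lo, hi)` of 0-based gene indices on every chromosome
#' pair, and sums over pairs. The sex pair's X and Y copies are compared
#' positionally like any homologous pair. `lo`/`hi` are recycled across
#' chromosomes, so per-chromosome windows (e.g. one activation year of
#' `length/L` loci each) can be given as vectors.
#'
#' @param genome a [new_genome()].
#' @param lo,hi window bounds, scalars or one value per chromosome.
#' @return integer count.
#' @export
count_homozygous_defects <- function(genome, lo, hi) {
  table <- attr(genome, "table")
  n <- nrow(table)
  lo <- rep_len(as.integer(lo), n)
  hi <- rep_len(as.integer(hi), n)
  total <- 0L
  for (i in seq_len(n)) {
    if (lo[i] < 0L || hi[i] > table$length_genes[i] || lo[i] > hi[i])
      stop("window [", lo[i], ",", hi[i], ") out of range for '",
           table$name[i], "'")
    total <- total + cpp_count_homo_window(genome$pairs[[i]]$a,
                                           genome$pairs[[i]]$b, lo[i], hi[i])
  }
  total
}

#' Count defective alleles per copy of one chromosome
#'
#' Reports the popcount of each copy separately so that callers can pool X
#' copies (both sexes) and Y copies (males only) independently.
#'
#' @param genome a [new_genome()].
#' @param spec_name chromosome name in the genome's table.
#' @return integer vector of length 2: defects on copy `a` and copy `b`.
#' @export
count_defective_alleles <- function(genome, spec_name) {
  table <- attr(genome, "table")
  i <- match(spec_name, table$name)
  if (is.na(i)) stop("unknown chromosome name: ", spec_name)
  c(cpp_popcount_chrom(genome$pairs[[i]]$a),
    cpp_popcount_chrom(genome$pairs[[i]]$b))
}
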