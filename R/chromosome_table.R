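#' Build a chromosome table
#'
#' A chromosome table holds the static per-pair parameters of the simulated
#' genome: length in genes (a multiple of the basic length `L`, which is also
#' the maximum lifespan), the expected number of new defective mutations per
#' chromosome copy per replication, the expected number of crossover events
#' per meiosis, and a flag marking the single pair treated as X/Y.
#'
#' @param name character vector of chromosome labels.
#' @param length_genes integer vector of locus counts; each must be a positive
#'   multiple of `basic_length`.
#' @param mutation_mean expected new mutations per copy per replication.
#' @param recomb_mean expected crossovers per meiosis for the pair.
#' @param is_sex_pair logical; exactly one entry must be `TRUE`.
#' @param basic_length the basic chromosome length `L` (loci activated over a
#'   lifetime of `L` years at `length_genes / L` per year). Default 128.
#' @return A `data.frame` of class `"chromosome_table"` with attribute
#'   `basic_length`.
#' @seealso [toy_chromosome_table()], [human_chromosome_table()],
#'   [read_chromosome_table()]
#' @export
chromosome_table <- function(name, length_genes, mutation_mean, recomb_mean,
                             is_sex_pair, basic_length = 128L) {
  tab <- data.frame(
    name = as.character(name),
    length_genes = as.integer(length_genes),
    mutation_mean = as.numeric(mutation_mean),
    recomb_mean = as.numeric(recomb_mean),
    is_sex_pair = as.logical(is_sex_pair),
    stringsAsFactors = FALSE
  )
  attr(tab, "basic_length") <- as.integer(basic_length)
  class(tab) <- c("chromosome_table", "data.frame")
  validate_chromosome_table(tab)
  tab
}

#' Validate a chromosome table
#'
#' Checks the structural invariants: positive lengths that are multiples of
#' the basic length, non-negative rates, and exactly one sex pair.
#'
#' @param tab a [chromosome_table()].
#' @return `tab`, invisibly; errors on violation.
#' @export
validate_chromosome_table <- function(tab) {
  L <- attr(tab, "basic_length")
  required <- c("name", "length_genes", "mutation_mean", "recomb_mean",
                "is_sex_pair")
  if (!all(required %in% names(tab)))
    stop("chromosome table must have columns: ",
         paste(required, collapse = ", "))
  if (is.null(L) || length(L) != 1L || is.na(L) || L < 1L)
    stop("chromosome table needs a positive 'basic_length' attribute")
  if (nrow(tab) < 1L) stop("chromosome table is empty")
  if (anyDuplicated(tab$name)) stop("duplicated chromosome names")
  if (any(tab$length_genes <= 0L))
    stop("length_genes must be positive")
  if (any(tab$length_genes %% L != 0L))
    stop("length_genes must be multiples of basic_length (", L, ")")
  if (any(tab$mutation_mean < 0)) stop("mutation_mean must be >= 0")
  if (any(tab$recomb_mean < 0)) stop("recomb_mean must be >= 0")
  if (sum(tab$is_sex_pair) != 1L)
    stop("exactly one chromosome pair must have is_sex_pair = TRUE")
  invisible(tab)
}

#' Genome-wide mutation input of a chromosome table
#'
#' Twice the sum of per-copy mutation means: the expected number of new
#' defective mutations entering a zygote per generation (both copies of every
#' chromosome are replicated once during gamete formation). The shipped
#' tables are calibrated so this equals 1, the rate commonly estimated for
#' deleterious mutations in humans.
#'
#' @param tab a [chromosome_table()].
#' @return a single number.
#' @export
genome_mutation_rate <- function(tab) 2 * sum(tab$mutation_mean)

#' Three-pair toy chromosome table
#'
#' A deliberately small genome for fast, desk-scale runs: two autosomes (one
#' of them the comparator standing in for the 10th autosome) and one sex
#' pair, each of one basic length (128 loci, one activated per year).
#'
#' The values calibrate a 20,000-step desk run (about 180 generations at
#' reproductive age 105) to traverse the same qualitative regimes a
#' full-genome run traverses over a million steps. Per-copy mutation means
#' of 0.35 give a genome-wide input of 2.1 new mutations per zygote per
#' generation, inside the empirical human range, and make Y-linked defect
#' accumulation visible within the run. Per-meiosis crossover means of 0.35
#' are an ordinary single-crossover probability for small bit-string model
#' chromosomes and, as the sex pair's rate, start the evolvable X-Y
#' modifier seven +/- 0.05 walk steps from its absorbing zero, so that
#' suppression can complete within a desk run's generations. See the
#' methods vignette for the full calibration argument.
#'
#' @param basic_length basic chromosome length, default 128.
#' @return a [chromosome_table()].
#' @export
toy_chromosome_table <- function(basic_length = 128L) {
  chromosome_table(
    name = c("A1", "A2", "XY"),
    length_genes = rep(basic_length, 3L),
    mutation_mean = rep(0.35, 3L),
    recomb_mean = rep(0.35, 3L),
    is_sex_pair = c(FALSE, FALSE, TRUE),
    basic_length = basic_length
  )
}

# Approximate human gene counts (Ensembl-era protein-coding, rounded to
# multiples of 128) and sex-averaged genetic map lengths in Morgans. This is
# a synthetic, documented approximation -- a config artifact users can
# replace, not reference data.
human_table_data <- function() {
  list(
    name = c(paste0("chr", 1:22), "chrX"),
    units = c(16L, 10L, 9L, 6L, 7L, 8L, 7L, 6L, 6L, 6L, 10L, 8L, 3L, 5L,
              5L, 7L, 9L, 2L, 11L, 4L, 2L, 3L, 6L),
    morgans = c(2.86, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.68, 1.66, 1.81,
                1.58, 1.75, 1.26, 1.20, 1.42, 1.35, 1.29, 1.17, 1.08, 1.08,
                0.62, 0.74, 1.80)
  )
}

#' Synthetic 23-pair human-like chromosome table
#'
#' A full-genome table with 23 chromosome pairs whose lengths follow human
#' per-chromosome gene counts rounded to multiples of the basic length,
#' per-copy mutation means proportional to length and summing so that the
#' genome-wide input is one new mutation per zygote per generation, and
#' per-meiosis crossover counts taken from sex-averaged genetic map lengths
#' in Morgans. The X pair matches the 10th autosome in both length (768
#' loci) and recombination, which is why chromosome 10 serves as the default
#' comparator. The values are a documented synthetic approximation of the
#' real human genome and are fully overridable via [chromosome_table()] or
#' [read_chromosome_table()].
#'
#' @param basic_length basic chromosome length, default 128.
#' @param genome_target expected new mutations per zygote per generation
#'   (default 1).
#' @return a [chromosome_table()].
#' @export
human_chromosome_table <- function(basic_length = 128L, genome_target = 1) {
  d <- human_table_data()
  len <- d$units * basic_length
  mu <- (genome_target / 2) * len / sum(len)
  chromosome_table(
    name = d$name,
    length_genes = len,
    mutation_mean = mu,
    recomb_mean = d$morgans,
    is_sex_pair = d$name == "chrX",
    basic_length = basic_length
  )
}

#' Read a chromosome table from tab-separated text
#'
#' The file must have a header row with exactly the columns `name`,
#' `length_genes`, `mutation_mean`, `recomb_mean`, `is_sex_pair`; unknown
#' columns are rejected. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param basic_length basic chromosome length used to validate lengths.
#' @return a [chromosome_table()].
#' @export
read_chromosome_table <- function(path, basic_length = 128L) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("name", "length_genes", "mutation_mean", "recomb_mean",
                "is_sex_pair")
  extra <- setdiff(names(df), required)
  if (length(extra) > 0)
    stop("unknown column(s) in chromosome table: ",
         paste(extra, collapse = ", "))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing column(s) in chromosome table: ",
         paste(missing, collapse = ", "))
  chromosome_table(df$name, df$length_genes, df$mutation_mean,
                   df$recomb_mean, as.logical(df$is_sex_pair),
                   basic_length = basic_length)
}

#' Write a chromosome table as tab-separated text
#'
#' @param tab a [chromosome_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chromosome_table <- function(tab, path) {
  validate_chromosome_table(tab)
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
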