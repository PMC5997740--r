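#' Create an empty toroidal lattice
#'
#' A square grid with opposite edges identified; each cell holds at most one
#' individual. Distance is toroidal Chebyshev (square neighbourhoods of
#' half-width `d`), matching the square search ranges used for partner
#' seeking and child placement.
#'
#' @param side grid side length.
#' @return an environment of class `"penna_lattice"` with fields `side`,
#'   `occ` (side x side character matrix of occupant ids, `NA` = empty) and
#'   `inds` (id -> individual).
#' @export
new_lattice <- function(side) {
  side <- as.integer(side)
  if (side < 1L) stop("lattice side must be positive")
  lat <- new.env(parent = emptyenv())
  lat$side <- side
  lat$occ <- matrix(NA_character_, side, side)
  lat$inds <- new.env(parent = emptyenv())
  class(lat) <- "penna_lattice"
  lat
}

check_cell <- function(lat, cell) {
  cell <- as.integer(cell)
  if (length(cell) != 2L || any(cell < 1L) || any(cell > lat$side))
    stop("cell must be (row, col) within 1..side")
  cell
}

#' Place an individual on the lattice
#'
#' @param lat a [new_lattice()].
#' @param ind a list with at least an `$id` element (unique token).
#' @param cell `(row, col)`, 1-based.
#' @return the individual, with `$position` set, invisibly.
#' @export
lattice_place <- function(lat, ind, cell) {
  cell <- check_cell(lat, cell)
  if (is.null(ind$id)) stop("individual must carry an id")
  id <- as.character(ind$id)
  if (!is.na(lat$occ[cell[1], cell[2]]))
    stop("cell (", cell[1], ",", cell[2], ") is already occupied")
  if (!is.null(lat$inds[[id]]))
    stop("individual '", id, "' is already on the lattice")
  ind$position <- cell
  lat$occ[cell[1], cell[2]] <- id
  lat$inds[[id]] <- ind
  invisible(ind)
}

#' Remove an individual from the lattice
#'
#' @param lat a [new_lattice()].
#' @param id the individual's id (or a list with `$id`).
#' @return the removed individual, invisibly.
#' @export
lattice_remove <- function(lat, id) {
  if (is.list(id)) id <- id$id
  id <- as.character(id)
  ind <- lat$inds[[id]]
  if (is.null(ind)) stop("individual '", id, "' is not on the lattice")
  lat$occ[ind$position[1], ind$position[2]] <- NA_character_
  rm(list = id, envir = lat$inds)
  invisible(ind)
}

#' Number of occupied cells
#' @param lat a [new_lattice()].
#' @return integer.
#' @export
lattice_occupancy <- function(lat) sum(!is.na(lat$occ))

# 1-based cells at toroidal Chebyshev distance <= range_d from cell,
# excluding cell itself, deduplicated under wraparound
cells_within <- function(lat, cell, range_d) {
  off <- cpp_torus_offsets(lat$side, as.integer(range_d))
  if (nrow(off) == 0L) return(matrix(integer(0), 0, 2))
  cbind((cell[1] - 1L + off[, 1]) %% lat$side + 1L,
        (cell[2] - 1L + off[, 2]) %% lat$side + 1L)
}

#' Individuals within a toroidal Chebyshev distance
#'
#' All occupants of cells at distance `1..range_d` from `cell` (the anchor
#' cell itself is excluded) that satisfy `predicate`. Order is unspecified;
#' choosing among them is the caller's job.
#'
#' @param lat a [new_lattice()].
#' @param cell `(row, col)` anchor.
#' @param range_d positive search half-width, `< side`.
#' @param predicate optional function(individual) -> logical.
#' @return list of individuals.
#' @export
neighbors_within <- function(lat, cell, range_d, predicate = NULL) {
  cell <- check_cell(lat, cell)
  if (range_d < 1L || range_d >= lat$side)
    stop("range_d must be in 1..side-1")
  cells <- cells_within(lat, cell, range_d)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    id <- lat$occ[cells[i, 1], cells[i, 2]]
    if (is.na(id)) next
    ind <- lat$inds[[id]]
    if (is.null(predicate) || isTRUE(predicate(ind)))
      out[[length(out) + 1L]] <- ind
  }
  out
}

#' Free cells within a toroidal Chebyshev distance
#'
#' @inheritParams neighbors_within
#' @return integer matrix with columns row, col (possibly 0 rows).
#' @export
free_cells_within <- function(lat, cell, range_d) {
  cell <- check_cell(lat, cell)
  if (range_d < 1L || range_d >= lat$side)
    stop("range_d must be in 1..side-1")
  cells <- cells_within(lat, cell, range_d)
  keep <- vapply(seq_len(nrow(cells)),
                 function(i) is.na(lat$occ[cells[i, 1], cells[i, 2]]),
                 logical(1))
  cells[keep, , drop = FALSE]
}

#' Toroidal Chebyshev distance between two cells
#'
#' @param a,b cells `(row, col)`.
#' @param side lattice side.
#' @return integer distance.
#' @export
torus_distance <- function(a, b, side) {
  d <- abs(a - b)
  d <- pmin(d, side - d)
  max(d)
}
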