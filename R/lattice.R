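#' Define a cohort lattice
#'
#' A lattice is the multidimensional grid of discrete cohorts over which
#' regionally-varying regression parameters live. Each dimension is a
#' discrete attribute (e.g. a bucketized history group, a comorbidity flag)
#' with a finite number of levels; a cohort is one cell of the grid,
#' addressed by a zero-based multi-index.
#'
#' @param ... Named dimension cardinalities, e.g. `history = 32, cc = 2`, or
#'   a single named integer vector.
#' @return An object of class `quilt_lattice`.
#' @examples
#' lat <- quilt_lattice(history = 4, cc = 2)
#' n_cells(lat)
#' @export
quilt_lattice <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dims <- dots[[1]]
  } else {
    dims <- unlist(dots)
  }
  if (length(dims) < 1L) stop_input("a lattice needs at least one dimension")
  if (is.null(names(dims)) || any(names(dims) == "")) {
    names(dims) <- paste0("dim", seq_along(dims))
  }
  dims <- vapply(dims, as.integer, integer(1))
  if (any(dims < 1L)) stop_input("dimension cardinalities must be >= 1")
  structure(list(dims = dims), class = "quilt_lattice")
}

#' @export
print.quilt_lattice <- function(x, ...) {
  cat("<quilt_lattice> ", paste(sprintf("%s[%d]", names(x$dims), x$dims),
    collapse = " x "
  ), " (", n_cells(x), " cells)\n", sep = "")
  invisible(x)
}

#' Number of cells in a lattice
#' @param lattice A `quilt_lattice`.
#' @return Integer cell count (product of dimension cardinalities).
#' @export
n_cells <- function(lattice) prod(lattice$dims)

#' Convert zero-based multi-indices to linear cell ids
#'
#' Dimension 1 varies fastest. Linear ids are 1-based (R convention);
#' multi-indices are 0-based, matching the history-group numbering where
#' bucket bit 0 is the least significant.
#'
#' @param lattice A `quilt_lattice`.
#' @param kappa Integer vector (one multi-index) or matrix with one row per
#'   multi-index and one column per lattice dimension.
#' @return Integer vector of 1-based linear cell ids.
#' @export
cell_id <- function(lattice, kappa) {
  if (is.null(dim(kappa))) kappa <- matrix(kappa, nrow = 1L)
  D <- length(lattice$dims)
  if (ncol(kappa) != D) {
    stop_input("multi-index has %d entries; lattice has %d dimensions", ncol(kappa), D)
  }
  for (d in seq_len(D)) {
    bad <- kappa[, d] < 0L | kappa[, d] >= lattice$dims[d]
    if (any(bad)) {
      stop_input(
        "multi-index out of bounds in dimension '%s' (cardinality %d)",
        names(lattice$dims)[d], lattice$dims[d]
      )
    }
  }
  strides <- cumprod(c(1L, lattice$dims[-D]))
  as.integer(kappa %*% strides + 1L)
}

#' Convert linear cell ids back to zero-based multi-indices
#' @param lattice A `quilt_lattice`.
#' @param cells Integer vector of 1-based linear cell ids.
#' @return Integer matrix, one row per cell, one column per dimension.
#' @export
cell_multi_index <- function(lattice, cells) {
  D <- length(lattice$dims)
  out <- matrix(0L, length(cells), D, dimnames = list(NULL, names(lattice$dims)))
  rem <- as.integer(cells) - 1L
  for (d in seq_len(D)) {
    out[, d] <- rem %% lattice$dims[d]
    rem <- rem %/% lattice$dims[d]
  }
  out
}

#' Enumerate interaction terms of an additive lattice decomposition
#'
#' Lists every subset of lattice dimensions of size at most `max_order`,
#' in canonical order: by subset size, then lexicographically. The empty
#' subset is the zero-order (global) term.
#'
#' @param lattice A `quilt_lattice`.
#' @param max_order Maximum interaction order (0 = global term only).
#' @return List of integer vectors of dimension indices (possibly empty).
#' @export
enumerate_terms <- function(lattice, max_order) {
  D <- length(lattice$dims)
  max_order <- as.integer(max_order)
  if (max_order < 0L || max_order > D) {
    stop_input("max_order must be between 0 and %d (got %d)", D, max_order)
  }
  terms <- list(integer(0))
  for (k in seq_len(max_order)) {
    subs <- utils::combn(D, k, simplify = FALSE)
    # combn emits lexicographic order already
    terms <- c(terms, subs)
  }
  terms
}
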