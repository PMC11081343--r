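#' Additive multi-order decomposition of a lattice-varying parameter
#'
#' Represents a parameter theta(kappa) defined on every cell of a cohort
#' lattice as the sum of interaction terms: a global (zero-order) value,
#' per-dimension main effects, pairwise interaction tensors, and so on up
#' to a truncation order. Writing cohort-specific parameters this way lets
#' hierarchical priors partially pool sparse high-order cells toward the
#' lower-order structure they refine.
#'
#' For vector-valued parameters (one coefficient per time interval, per
#' feature, ...) every term carries a trailing coefficient axis of length
#' `n_coef`; materialization returns a `n_cells x n_coef` matrix.
#'
#' @param lattice A [quilt_lattice()].
#' @param max_order Truncation order of the decomposition (default 2).
#' @param n_coef Length of the trailing coefficient axis (default 1).
#' @param order_scales Per-order prior scale multipliers, length
#'   `max_order + 1`. Default `2^-(0:max_order)`: each additional
#'   interaction order halves the prior scale, encoding shrinkage of
#'   higher-order terms.
#' @param base_scale Base prior scale multiplied into `order_scales`.
#' @return An object of class `quilt_dp` with all coefficients zero.
#' @examples
#' dp <- decomposed_parameter(quilt_lattice(a = 2, b = 2), max_order = 2)
#' dp_length(dp) # 1 + 2 + 2 + 4 packed coefficients
#' @export
decomposed_parameter <- function(lattice, max_order = 2L, n_coef = 1L,
                                 order_scales = NULL, base_scale = 1) {
  stopifnot(inherits(lattice, "quilt_lattice"))
  subsets <- enumerate_terms(lattice, max_order)
  if (is.null(order_scales)) order_scales <- 2^-(0:max_order)
  if (length(order_scales) != max_order + 1L) {
    stop_input("order_scales must have length max_order + 1")
  }
  if (any(order_scales <= 0) || base_scale <= 0) {
    stop_input("prior scales must be positive")
  }
  offset <- 0L
  terms <- vector("list", length(subsets))
  for (t in seq_along(subsets)) {
    S <- subsets[[t]]
    size <- if (length(S)) prod(lattice$dims[S]) else 1L
    terms[[t]] <- list(
      dims = S, order = length(S), size = as.integer(size),
      offset = offset
    )
    offset <- offset + as.integer(size)
  }
  dp <- structure(
    list(
      lattice = lattice, max_order = as.integer(max_order),
      n_coef = as.integer(n_coef), terms = terms, n_rows = offset,
      order_scales = order_scales, base_scale = base_scale,
      values = matrix(0, nrow = offset, ncol = n_coef)
    ),
    class = "quilt_dp"
  )
  dp$design <- dp_design_matrix(dp)
  dp
}

#' @export
print.quilt_dp <- function(x, ...) {
  cat(sprintf(
    "<quilt_dp> %d-dim lattice (%d cells), max order %d, %d terms, %d x %d coefficients\n",
    length(x$lattice$dims), n_cells(x$lattice), x$max_order,
    length(x$terms), x$n_rows, x$n_coef
  ))
  invisible(x)
}

# Sparse map M (n_cells x n_rows) with materialized = M %*% values.
# Row order within a term: linear index over the term's dimensions with the
# first listed dimension varying fastest (mirrors cell_id).
dp_design_matrix <- function(dp) {
  lat <- dp$lattice
  nc <- n_cells(lat)
  km <- cell_multi_index(lat, seq_len(nc))
  i_idx <- integer(0)
  j_idx <- integer(0)
  for (term in dp$terms) {
    S <- term$dims
    if (length(S) == 0L) {
      rows <- rep.int(1L, nc)
    } else {
      card <- lat$dims[S]
      strides <- cumprod(c(1L, card[-length(card)]))
      rows <- as.integer(km[, S, drop = FALSE] %*% strides) + 1L
    }
    i_idx <- c(i_idx, seq_len(nc))
    j_idx <- c(j_idx, term$offset + rows)
  }
  Matrix::sparseMatrix(
    i = i_idx, j = j_idx, x = 1,
    dims = c(nc, dp$n_rows)
  )
}

#' Number of packed coefficients of a decomposed parameter
#' @param dp A `quilt_dp`.
#' @return Integer: rows times the coefficient axis length.
#' @export
dp_length <- function(dp) dp$n_rows * dp$n_coef

#' Materialize a decomposed parameter at one cohort cell
#'
#' Sums every interaction term's tensor, indexed at the cell's multi-index
#' restricted to the term's dimensions.
#'
#' @param dp A `quilt_dp`.
#' @param kappa Zero-based multi-index of the cell.
#' @return Numeric vector of length `n_coef`.
#' @export
materialize <- function(dp, kappa) {
  cell <- cell_id(dp$lattice, kappa)
  drop(as.matrix(dp$design[cell, , drop = FALSE] %*% dp$values))
}

#' Materialize a decomposed parameter over every lattice cell
#' @param dp A `quilt_dp`.
#' @return Dense `n_cells x n_coef` matrix; row i is cell id i.
#' @export
materialize_all <- function(dp) {
  as.matrix(dp$design %*% dp$values)
}

#' Pack a decomposed parameter's coefficients into a flat vector
#'
#' Column-major over the (term-blocked rows) x (coefficient axis) matrix;
#' the order is canonical and stable, so `unpack(dp, pack(dp))` round-trips
#' exactly and serialized vectors are comparable across runs.
#'
#' @param dp A `quilt_dp`.
#' @return Numeric vector of length `dp_length(dp)`.
#' @export
pack <- function(dp) as.vector(dp$values)

#' @rdname pack
#' @param values Numeric vector of length `dp_length(dp)`.
#' @export
unpack <- function(dp, values) {
  if (length(values) != dp_length(dp)) {
    stop_input(
      "expected %d packed coefficients, got %d",
      dp_length(dp), length(values)
    )
  }
  dp$values <- matrix(values, nrow = dp$n_rows, ncol = dp$n_coef)
  dp
}

# Per-packed-row prior scale (base * order multiplier), recycled over the
# coefficient axis by callers.
dp_row_scales <- function(dp) {
  s <- numeric(dp$n_rows)
  for (term in dp$terms) {
    s[term$offset + seq_len(term$size)] <-
      dp$base_scale * dp$order_scales[term$order + 1L]
  }
  s
}

# Per-packed-row interaction order.
dp_row_orders <- function(dp) {
  o <- integer(dp$n_rows)
  for (term in dp$terms) {
    o[term$offset + seq_len(term$size)] <- term$order
  }
  o
}

#' Log prior density of a decomposition under zero-mean normal terms
#'
#' Every term tensor gets an independent zero-mean normal prior whose scale
#' is `base_scale * order_scales[order + 1]` — the order-graded shrinkage
#' that pools high-order interactions toward lower-order structure.
#' (Slope decompositions inside a fitted model additionally carry horseshoe
#' local-global scales; see the model builder.)
#'
#' @param dp A `quilt_dp` holding the values to evaluate.
#' @return Scalar log density.
#' @export
dp_log_prior_normal <- function(dp) {
  s <- dp_row_scales(dp)
  sum(stats::dnorm(dp$values, mean = 0, sd = s, log = TRUE))
}

#' Serialize / restore a decomposed parameter as JSON text
#'
#' Full-precision structured text: lattice, truncation, prior scales, and
#' the packed coefficient payload. `dp_from_json(dp_to_json(dp))`
#' round-trips exactly.
#'
#' @param dp A `quilt_dp`.
#' @return `dp_to_json`: a JSON string. `dp_from_json`: a `quilt_dp`.
#' @export
dp_to_json <- function(dp) {
  jsonlite::toJSON(
    list(
      dims = as.list(dp$lattice$dims), max_order = dp$max_order,
      n_coef = dp$n_coef, order_scales = dp$order_scales,
      base_scale = dp$base_scale, values = pack(dp)
    ),
    auto_unbox = TRUE, digits = I(17)
  )
}

#' @rdname dp_to_json
#' @param json JSON string produced by `dp_to_json`.
#' @export
dp_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  lat <- quilt_lattice(unlist(obj$dims))
  dp <- decomposed_parameter(
    lat,
    max_order = obj$max_order, n_coef = obj$n_coef,
    order_scales = obj$order_scales, base_scale = obj$base_scale
  )
  unpack(dp, obj$values)
}
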