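#' Ordinal (proportional-odds) discharge-placement probabilities
#'
#' Discharge placement takes one of `K + 1` acuity-ordered categories
#' (default 6: home = 0 up to other less-acute inpatient = 5). The model is
#' cumulative-logistic: `Pr(I >= k) = logistic(eta - c_k)` for ordered
#' cutpoints `c_1 < ... < c_K`, with `eta = xi' x` the linear predictor.
#' Category probabilities telescope:
#' `p_k = Pr(I >= k) - Pr(I >= k + 1)`, with `Pr(I >= 0) = 1` and
#' `Pr(I >= K + 1) = 0`.
#'
#' @param eta Linear predictor(s), numeric vector.
#' @param cutpoints Strictly increasing cutpoint vector (length K), or an
#'   `n x K` matrix of per-episode cutpoints.
#' @return A list with `exceedance` (`n x K`, `Pr(I >= k)`) and
#'   `probs` (`n x (K + 1)`, category probabilities).
#' @examples
#' ordinal_probs(0, c(-1, 0, 1, 2, 3))
#' @export
ordinal_probs <- function(eta, cutpoints) {
  if (is.null(dim(cutpoints))) {
    cutpoints <- matrix(cutpoints, length(eta), length(cutpoints), byrow = TRUE)
  }
  if (any(matrixStats_rowDiffs(cutpoints) <= 0)) {
    stop_input("cutpoints must be strictly increasing")
  }
  K <- ncol(cutpoints)
  exceed <- stats::plogis(eta - cutpoints)
  probs <- cbind(1, exceed) - cbind(exceed, 0)
  list(exceedance = exceed, probs = probs)
}

# rowDiffs without a matrixStats dependency.
matrixStats_rowDiffs <- function(m) {
  if (ncol(m) < 2L) {
    return(matrix(numeric(0), nrow(m), 0))
  }
  m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
}

#' Ordinal placement log likelihood
#'
#' @param eta Linear predictor(s).
#' @param cutpoints As in [ordinal_probs()].
#' @param observed Integer placement category in `0..K`.
#' @return Per-episode log likelihood `log p_I`.
#' @export
ordinal_log_likelihood <- function(eta, cutpoints, observed) {
  op <- ordinal_probs(eta, cutpoints)
  K <- ncol(op$exceedance)
  if (any(observed < 0 | observed > K | observed != round(observed))) {
    stop_input("observed placement must be an integer in 0..%d", K)
  }
  log(op$probs[cbind(seq_along(eta), observed + 1L)])
}

#' Build the 10-entry treatment covariate vector
#'
#' Concatenates the five exceedance probabilities `Pr(I >= k)` with the
#' five observed-placement indicators `1{I >= k}`. Feeding the model's own
#' assignment probabilities into the hazard adjusts the placement-effect
#' estimates for confounding by the selection process, while the
#' indicator block carries the actual treatment received.
#'
#' @param exceedance `n x 5` matrix (or length-5 vector) of nonincreasing
#'   exceedance probabilities.
#' @param observed Integer placements in 0..5.
#' @return `n x 10` treatment covariate matrix.
#' @export
build_treatment_covariates <- function(exceedance, observed) {
  if (is.null(dim(exceedance))) exceedance <- matrix(exceedance, nrow = 1L)
  assert_prob_vector(exceedance, "exceedance probabilities")
  if (any(matrixStats_rowDiffs(exceedance) > 1e-12)) {
    stop_input("exceedance probabilities must be nonincreasing in k")
  }
  K <- ncol(exceedance)
  ind <- outer(observed, seq_len(K), ">=") * 1
  cbind(exceedance, ind)
}

#' Non-positivity constraint for placement-effect coefficients
#'
#' Discharge placements are acuity-ordered; domain knowledge says more
#' intensive placement cannot increase the hazard through the monotone
#' indicator block, so its coefficients are mapped to `(-Inf, 0]` by a
#' smooth strictly increasing transform, `-softplus(raw)`.
#'
#' @param raw Unconstrained real coefficients.
#' @return Constrained coefficients, always `<= 0`.
#' @export
constrain_treatment_effects <- function(raw) {
  -softplus(raw)
}

#' Per-cohort ordered cutpoints from unconstrained coefficients
#'
#' Row layout: column 1 is `c_1` (free), columns `2..K` are raw increments
#' mapped through softplus and cumulated, so rows are strictly increasing
#' for any real input — the unconstrained space the variational
#' approximation lives in.
#'
#' @param raw `n x K` matrix of unconstrained values.
#' @return `n x K` matrix of strictly increasing cutpoints.
#' @export
cutpoints_from_raw <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  K <- ncol(raw)
  out <- matrix(0, nrow(raw), K)
  out[, 1L] <- raw[, 1L]
  if (K > 1L) {
    acc <- raw[, 1L]
    for (k in 2:K) {
      acc <- acc + softplus(raw[, k])
      out[, k] <- acc
    }
  }
  out
}
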