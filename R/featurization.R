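#' Quantile cutoffs for binarizing count features
#'
#' Claims-derived count features are sparse and heavy tailed; coding each
#' one as a battery of threshold indicators puts every model coefficient on
#' the same log-hazard-ratio scale. Cutoffs are empirical quantiles (lower /
#' type-1: exactly reproducible from the sorted sample, no interpolation)
#' evaluated on a probability grid, deduplicated, and sorted. A cutoff at or
#' below the feature minimum would code a constant all-ones column and is
#' removed; features with no surviving cutoff (e.g. constants) are flagged
#' dropped and excluded from the design.
#'
#' @param x Numeric matrix or data frame, episodes x features.
#' @param probs Strictly increasing quantile grid in (0, 1). The default
#'   covers deciles plus the 95th and 99th percentiles to resolve the heavy
#'   right tail.
#' @return An object of class `quilt_cutoffs`: per-feature cutoff lists,
#'   the grid, and dropped-feature flags.
#' @examples
#' ct <- compute_cutoffs(cbind(f = c(0, 0, 0, 0, 1, 2, 3, 4, 5, 100)), probs = c(.5, .9))
#' ct$cutoffs$f # 1 and 5
#' @export
compute_cutoffs <- function(x, probs = c(seq(0.1, 0.9, by = 0.1), 0.95, 0.99)) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop_input("feature matrix must be non-empty")
  if (any(probs <= 0) || any(probs >= 1) || any(diff(probs) <= 0)) {
    stop_input("quantile grid must be strictly increasing within (0, 1)")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  cutoffs <- vector("list", ncol(x))
  names(cutoffs) <- colnames(x)
  dropped <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (any(!is.finite(v))) {
      stop_input("feature '%s' contains non-finite values", colnames(x)[j])
    }
    q <- unname(stats::quantile(v, probs = probs, type = 1))
    q <- sort(unique(q))
    q <- q[q > min(v)]
    cutoffs[[j]] <- q
    dropped[j] <- length(q) == 0L
  }
  names(dropped) <- colnames(x)
  structure(
    list(cutoffs = cutoffs, probs = probs, dropped = dropped),
    class = "quilt_cutoffs"
  )
}

#' @export
print.quilt_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<quilt_cutoffs> %d features (%d dropped), %d design columns\n",
    length(x$cutoffs), sum(x$dropped), sum(lengths(x$cutoffs))
  ))
  invisible(x)
}

#' Binarize features against a cutoff table
#'
#' One design column per (feature, cutoff) pair coding `1{x >= cutoff}`;
#' the coding is monotone in the underlying value. Column names record the
#' threshold (`feature>=cutoff`) so coefficients read as named inequalities.
#'
#' @param x Numeric matrix or data frame whose columns cover every
#'   non-dropped feature of `cutoffs`.
#' @param cutoffs A [compute_cutoffs()] table.
#' @return Binary design matrix with named columns.
#' @export
binarize <- function(x, cutoffs) {
  x <- as.matrix(x)
  feats <- names(cutoffs$cutoffs)[!cutoffs$dropped]
  missing <- setdiff(feats, colnames(x))
  if (length(missing)) {
    stop_input("features absent from input: %s", paste(missing, collapse = ", "))
  }
  cols <- list()
  for (f in feats) {
    for (cut in cutoffs$cutoffs[[f]]) {
      cols[[sprintf("%s>=%g", f, cut)]] <- as.numeric(x[, f] >= cut)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Sparse linear embedding of utilization history
#'
#' Projects the lagged-history count block to a few latent dimensions with
#' a sparse linear factorization: rank-`latent_dim` SVD initialization
#' refined by alternating least squares with L1 soft-thresholding on the
#' loadings. Each latent dimension then gets a single bucketization cutoff
#' at the median of the training scores, so held-out episodes map to one of
#' `2^latent_dim` history groups by thresholding.
#'
#' @param h Nonnegative count matrix, episodes x history features.
#' @param latent_dim Number of latent dimensions (default 5, giving 32
#'   history groups).
#' @param sparsity_weight L1 penalty on loadings (default 0.1).
#' @param n_iter Alternating refinement sweeps.
#' @param seed Integer seed (the procedure is deterministic; the seed is
#'   recorded so serialized embeddings state their provenance).
#' @return An object of class `quilt_embedding`: `loadings`
#'   (features x latent_dim, unit columns), `cutoffs` (per-dimension
#'   medians), `latent_dim`, `seed`.
#' @export
embed_history <- function(h, latent_dim = 5L, sparsity_weight = 0.1,
                          n_iter = 10L, seed = 1L) {
  h <- as.matrix(h)
  if (any(h < 0)) stop_input("history counts must be nonnegative")
  if (latent_dim < 1L) stop_input("latent_dim must be >= 1")
  if (latent_dim >= ncol(h)) {
    stop_input(
      "latent_dim (%d) must be smaller than the history feature count (%d)",
      latent_dim, ncol(h)
    )
  }
  set.seed(as.integer(seed))
  if (all(h == 0)) {
    W <- matrix(0, ncol(h), latent_dim)
  } else {
    sv <- svd(h, nu = latent_dim, nv = latent_dim)
    W <- sv$v
    S <- h %*% W
    for (iter in seq_len(n_iter)) {
      # loadings update: ridge-free LS then soft-threshold toward sparsity
      StS <- crossprod(S)
      W_new <- t(solve(StS + diag(1e-8, latent_dim), crossprod(S, h)))
      W_new <- sign(W_new) * pmax(abs(W_new) - sparsity_weight / nrow(h), 0)
      nrm <- sqrt(colSums(W_new^2))
      live <- nrm > 1e-12
      W_new[, live] <- sweep(W_new[, live, drop = FALSE], 2, nrm[live], "/")
      W <- W_new
      S <- h %*% W
    }
  }
  scores <- h %*% W
  cutoffs <- apply(scores, 2, stats::median)
  structure(
    list(
      loadings = W, cutoffs = cutoffs,
      latent_dim = as.integer(latent_dim), seed = as.integer(seed)
    ),
    class = "quilt_embedding"
  )
}

#' Project history counts onto a fitted embedding
#' @param h Count matrix with the training history feature columns.
#' @param embedding A [embed_history()] fit.
#' @return Score matrix, episodes x latent_dim.
#' @export
embedding_scores <- function(h, embedding) {
  as.matrix(h) %*% embedding$loadings
}

#' Assign episodes to cohort lattice cells
#'
#' The history group is formed by thresholding each latent score at its
#' bucketization cutoff: bit d is `1{score_d >= cutoff_d}` and dimension 1
#' contributes the least significant bit, so `latent_dim = 5` yields groups
#' 0..31. The full cohort multi-index is the history group followed by any
#' discrete attributes (each in `0..cardinality-1`).
#'
#' @param scores Score matrix (episodes x latent_dim) from
#'   [embedding_scores()].
#' @param embedding The [embed_history()] fit holding the cutoffs.
#' @param attrs Optional integer matrix / data frame of discrete attributes
#'   (0-based levels), one column per extra lattice dimension.
#' @param attr_cards Integer vector of attribute cardinalities.
#' @return A list: `kappa` (integer matrix of 0-based multi-indices),
#'   `lattice` (the implied [quilt_lattice()]), `cell` (1-based linear ids).
#' @export
assign_cohort <- function(scores, embedding, attrs = NULL, attr_cards = integer(0)) {
  scores <- as.matrix(scores)
  if (ncol(scores) != embedding$latent_dim) {
    stop_input(
      "scores have %d columns; embedding has latent_dim %d",
      ncol(scores), embedding$latent_dim
    )
  }
  bits <- sweep(scores, 2, embedding$cutoffs, ">=")
  group <- as.integer(bits %*% 2^(seq_len(ncol(scores)) - 1L))
  kappa <- cbind(history = group)
  cards <- c(history = 2L^embedding$latent_dim)
  if (!is.null(attrs)) {
    attrs <- as.matrix(attrs)
    if (length(attr_cards) != ncol(attrs)) {
      stop_input("attr_cards must give one cardinality per attribute column")
    }
    for (j in seq_len(ncol(attrs))) {
      if (any(attrs[, j] < 0 | attrs[, j] >= attr_cards[j])) {
        stop_input("attribute %d outside 0..%d", j, attr_cards[j] - 1L)
      }
    }
    nm <- colnames(attrs) %||% paste0("attr", seq_len(ncol(attrs)))
    colnames(attrs) <- nm
    kappa <- cbind(kappa, attrs)
    cards <- c(cards, stats::setNames(as.integer(attr_cards), nm))
  }
  lattice <- quilt_lattice(cards)
  list(kappa = kappa, lattice = lattice, cell = cell_id(lattice, kappa))
}

#' Serialize / restore cutoff tables and embeddings as JSON text
#' @param x A `quilt_cutoffs` or `quilt_embedding`.
#' @return A JSON string (full numeric precision).
#' @export
featurization_to_json <- function(x) {
  if (inherits(x, "quilt_cutoffs")) {
    jsonlite::toJSON(
      list(
        kind = "cutoffs", probs = x$probs,
        cutoffs = x$cutoffs, dropped = x$dropped
      ),
      auto_unbox = TRUE, digits = I(17)
    )
  } else if (inherits(x, "quilt_embedding")) {
    jsonlite::toJSON(
      list(
        kind = "embedding", latent_dim = x$latent_dim, seed = x$seed,
        cutoffs = x$cutoffs, loadings = x$loadings
      ),
      auto_unbox = TRUE, digits = I(17)
    )
  } else {
    stop_input("unsupported object")
  }
}

#' @rdname featurization_to_json
#' @param json JSON produced by `featurization_to_json`.
#' @export
featurization_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (identical(obj$kind, "cutoffs")) {
    structure(
      list(
        cutoffs = lapply(obj$cutoffs, as.numeric),
        probs = obj$probs,
        dropped = stats::setNames(as.logical(obj$dropped), names(obj$cutoffs))
      ),
      class = "quilt_cutoffs"
    )
  } else if (identical(obj$kind, "embedding")) {
    structure(
      list(
        loadings = as.matrix(obj$loadings), cutoffs = as.numeric(obj$cutoffs),
        latent_dim = as.integer(obj$latent_dim), seed = as.integer(obj$seed)
      ),
      class = "quilt_embedding"
    )
  } else {
    stop_input("unrecognized serialized featurization object")
  }
}
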