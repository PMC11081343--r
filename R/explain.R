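#' Exact ground-truth attribution of a linear prediction
#'
#' For an additive model the attribution question has a closed answer: the
#' contribution of feature j to the prediction is its coefficient times its
#' value, and the base value is the episode's cohort/interval intercept.
#' `base + sum(contributions)` reproduces the prediction to machine
#' precision — the property that separates reading a quilt model off from
#' approximating a blackbox.
#'
#' @param coefficients Named numeric coefficient vector.
#' @param x Feature vector aligned with `coefficients`.
#' @param base Intercept / base value.
#' @return A `quilt_attribution`: list with `base`, `contributions` (named),
#'   and `prediction`.
#' @export
ground_truth_attribution <- function(coefficients, x, base = 0) {
  if (length(coefficients) != length(x)) {
    stop_input(
      "coefficients (%d) and features (%d) differ in length",
      length(coefficients), length(x)
    )
  }
  contr <- as.numeric(coefficients) * as.numeric(x)
  names(contr) <- names(coefficients) %||% paste0("x", seq_along(contr))
  structure(
    list(base = base, contributions = contr, prediction = base + sum(contr)),
    class = "quilt_attribution"
  )
}

#' @export
print.quilt_attribution <- function(x, ...) {
  cat(sprintf(
    "<quilt_attribution> base %.4f + sum %.4f = %.4f over %d features\n",
    x$base, sum(x$contributions), x$prediction, length(x$contributions)
  ))
  invisible(x)
}

#' @method as_tibble quilt_attribution
#' @export
as_tibble.quilt_attribution <- function(x, ...) {
  tibble::tibble(feature = names(x$contributions), contribution = x$contributions)
}

#' Regression-based KernelSHAP attributions
#'
#' Approximates Shapley values of `predict_fn` at one instance by weighted
#' least squares over feature coalitions: each sampled coalition keeps the
#' instance's values on its member features and fills the rest from
#' background rows (marginal/interventional sampling), predictions are
#' averaged over the background, and the Shapley kernel weights the
#' regression. The efficiency constraint — attributions sum to
#' `predict_fn(instance) - mean background prediction` — is imposed by
#' eliminating the last feature. All `2^p - 2` non-trivial coalitions are
#' enumerated when the budget allows; otherwise coalitions are sampled by
#' kernel-weighted size with the seed controlling everything.
#'
#' @param predict_fn Function mapping a numeric matrix of rows to scores.
#' @param instance Numeric feature vector to explain.
#' @param background Matrix/data frame of background rows (same columns).
#' @param n_coalitions Coalition budget (at least `length(instance) + 2`).
#' @param conditioning How off-coalition features are filled: `"marginal"`
#'   (interventional; every background row, correlations broken) or
#'   `"conditional"` (faithful to the data: only background rows matching
#'   the instance on the coalition features are averaged, so perfectly
#'   correlated features share credit). Conditional falls back to the
#'   marginal fill for coalitions with no matching row.
#' @param seed Integer seed.
#' @return A `quilt_attribution` with the KernelSHAP estimates; `base` is
#'   the mean background prediction.
#' @export
kernel_shap <- function(predict_fn, instance, background,
                        n_coalitions = 2048L,
                        conditioning = c("marginal", "conditional"),
                        seed = 1L) {
  conditioning <- match.arg(conditioning)
  x <- as.numeric(instance)
  p <- length(x)
  bg <- as.matrix(background)
  if (nrow(bg) < 1L) stop_input("background set must be nonempty")
  if (ncol(bg) != p) stop_input("background has %d columns; instance has %d", ncol(bg), p)
  if (n_coalitions < p + 2L) stop_input("n_coalitions must be at least p + 2")
  set.seed(as.integer(seed))

  fx <- as.numeric(predict_fn(matrix(x, 1L)))
  f0 <- mean(predict_fn(bg))

  # coalition matrix Z (rows: coalitions; 1 = feature from the instance)
  if (p <= 1L) stop_input("need at least 2 features")
  total <- 2^p - 2
  if (total <= n_coalitions) {
    Z <- as.matrix(expand.grid(rep(list(0:1), p)))[-c(1, 2^p), , drop = FALSE]
    sizes <- rowSums(Z)
    w <- (p - 1) / (choose(p, sizes) * sizes * (p - sizes))
  } else {
    sz_support <- 1:(p - 1)
    sz_weight <- (p - 1) / (sz_support * (p - sz_support))
    sizes <- sample(sz_support, n_coalitions,
      replace = TRUE,
      prob = sz_weight / sum(sz_weight)
    )
    Z <- t(vapply(
      sizes,
      function(s) {
        z <- numeric(p)
        z[sample.int(p, s)] <- 1
        z
      }, numeric(p)
    ))
    w <- rep(1, n_coalitions) # size already sampled by kernel mass
  }
  storage.mode(Z) <- "double"

  # value of each coalition: mean prediction with off-coalition entries
  # drawn from the background (full marginal average)
  vals <- apply(Z, 1L, function(z) {
    on <- z == 1
    if (conditioning == "conditional") {
      match_rows <- rowSums(abs(bg[, on, drop = FALSE] -
        matrix(x[on], nrow(bg), sum(on), byrow = TRUE))) == 0
      if (any(match_rows)) {
        return(mean(predict_fn(bg[match_rows, , drop = FALSE])))
      }
    }
    synth <- bg
    synth[, on] <- matrix(x[on], nrow(bg), sum(on), byrow = TRUE)
    mean(predict_fn(synth))
  })

  # WLS with efficiency: phi_p eliminated via sum(phi) = fx - f0
  y <- vals - f0 - Z[, p] * (fx - f0)
  A <- Z[, -p, drop = FALSE] - Z[, p]
  WA <- A * w
  XtX <- crossprod(WA, A)
  phi_head <- tryCatch(
    solve(XtX, crossprod(WA, y)),
    error = function(e) {
      stop_input("singular KernelSHAP system; increase n_coalitions")
    }
  )
  phi <- c(as.numeric(phi_head), (fx - f0) - sum(phi_head))
  names(phi) <- colnames(bg) %||% paste0("x", seq_len(p))
  structure(
    list(base = f0, contributions = phi, prediction = f0 + sum(phi)),
    class = "quilt_attribution"
  )
}

#' Disagreement between two attribution vectors
#'
#' Spearman rank correlation of the absolute attributions, and the
#' fraction of the top-k features (by absolute attribution) the two
#' rankings share — the quantities that show a posthoc explainer drifting
#' from the model's exact internal account.
#'
#' @param a,b `quilt_attribution` objects (or named numeric vectors) over
#'   the same features.
#' @param top_k Size of the head compared (default 5, capped at p).
#' @return A tibble: `rank_correlation`, `top_k`, `top_k_overlap`.
#' @export
disagreement_metrics <- function(a, b, top_k = 5L) {
  va <- if (inherits(a, "quilt_attribution")) a$contributions else a
  vb <- if (inherits(b, "quilt_attribution")) b$contributions else b
  if (length(va) != length(vb)) stop_input("attribution vectors differ in length")
  if (length(va) < 2L) stop_input("need at least 2 features")
  top_k <- min(as.integer(top_k), length(va))
  rc <- suppressWarnings(stats::cor(abs(va), abs(vb), method = "spearman"))
  ta <- order(abs(va), decreasing = TRUE)[seq_len(top_k)]
  tb <- order(abs(vb), decreasing = TRUE)[seq_len(top_k)]
  tibble::tibble(
    rank_correlation = rc, top_k = top_k,
    top_k_overlap = length(intersect(ta, tb)) / top_k
  )
}
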