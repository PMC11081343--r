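# Internal numerical helpers shared across modules.

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Derivative of softplus is the logistic function; kept named for clarity
# at call sites that chain gradients through the transform.
softplus_grad <- function(x) stats::plogis(x)

# Inverse of softplus for y > 0: log(exp(y) - 1), stable for large y.
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  y + log(-expm1(-y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_prob_vector <- function(p, what = "probabilities") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_input("%s must lie in [0, 1] and be finite", what)
  }
  invisible(p)
}

# Draw a 32-bit-safe child seed from a parent seed and a stream label.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 7919L) %% 2147483L
}
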