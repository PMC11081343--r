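#' Assemble a quilt survival model from episode data
#'
#' Binds together the three likelihood components — the piecewise
#' exponential wait-time model with lattice-varying intercepts `alpha`,
#' slopes `beta`, and treatment coefficients `gamma`; the ordinal
#' discharge-placement model with lattice-varying cutpoints and slopes
#' `xi`; and the order-graded shrinkage priors — into one differentiable
#' joint density over unconstrained latents, ready for variational fitting.
#'
#' Treatment covariates are the five placement exceedance probabilities
#' (recomputed from the current ordinal parameters inside every density
#' evaluation, so the confounding adjustment is jointly inferred, not a
#' frozen two-stage plug-in) plus the five observed-placement indicators,
#' whose hazard coefficients are constrained non-positive.
#'
#' @param data Data frame of episodes.
#' @param features Character vector: names of binary (0/1) design columns.
#' @param time,event,placement Column names for the wait time (days > 0),
#'   event indicator (0/1), and placement category (integer 0..5).
#' @param cohorts Character vector of cohort columns (0-based integer
#'   levels), one per lattice dimension; or NULL for a single global cohort.
#' @param lattice Optional [quilt_lattice()]; inferred from the cohort
#'   columns (max level + 1) when NULL.
#' @param breakpoints PEM breakpoints in days (see [pem_config()]).
#' @param max_order Decomposition truncation order applied to every
#'   parameter block (capped at the lattice dimension count). Individual
#'   blocks can be overridden via `orders`.
#' @param orders Optional named list overriding `max_order` per block:
#'   `alpha`, `beta`, `gamma`, `cut`, `xi`.
#' @param priors Named list of prior scales: `alpha_scale` (normal
#'   intercepts), `gamma_ind_scale` (normal, raw non-positive placement
#'   block), `cut_scale` (normal cutpoints), `hs_global_scale` (half-Cauchy
#'   scale of the horseshoe global for slope blocks).
#' @return An object of class `quilt_model` (data bound, parameters unset).
#' @export
quilt_model <- function(data, features, time = "time", event = "event",
                        placement = "placement", cohorts = NULL,
                        lattice = NULL, breakpoints = c(7, 28, 63),
                        max_order = 2L, orders = list(),
                        priors = list()) {
  data <- as.data.frame(data)
  need <- c(features, time, event, placement, cohorts)
  missing <- setdiff(need, names(data))
  if (length(missing)) stop_input("columns absent from data: %s", paste(missing, collapse = ", "))

  X <- as.matrix(data[features])
  if (!all(X %in% c(0, 1))) stop_input("feature columns must be binary 0/1 (binarize first)")
  tvec <- as.numeric(data[[time]])
  tvec[tvec <= 0] <- 0.5 # same-day events floored to half a day
  evec <- as.numeric(data[[event]])
  if (!all(evec %in% c(0, 1))) stop_input("event column must be 0/1")
  ivec <- as.integer(data[[placement]])
  if (any(ivec < 0L | ivec > 5L)) stop_input("placement must be an integer in 0..5")

  if (is.null(cohorts)) {
    lattice <- lattice %||% quilt_lattice(global = 1L)
    kappa <- matrix(0L, nrow(data), length(lattice$dims))
  } else {
    kappa <- as.matrix(data[cohorts])
    storage.mode(kappa) <- "integer"
    if (is.null(lattice)) {
      cards <- apply(kappa, 2, max) + 1L
      lattice <- quilt_lattice(stats::setNames(as.integer(cards), cohorts))
    }
  }
  cell <- cell_id(lattice, kappa)

  pem <- pem_config(breakpoints)
  nI <- pem$n_intervals
  p <- ncol(X)
  D <- length(lattice$dims)
  ord <- function(name) min(as.integer(orders[[name]] %||% max_order), D)
  pri <- utils::modifyList(
    list(
      alpha_scale = 3, gamma_ind_scale = 1, cut_scale = 3,
      hs_global_scale = 1
    ),
    priors
  )

  dps <- list(
    alpha = decomposed_parameter(lattice, ord("alpha"),
      n_coef = nI,
      base_scale = pri$alpha_scale
    ),
    beta = decomposed_parameter(lattice, ord("beta"), n_coef = p * nI),
    gp = decomposed_parameter(lattice, ord("gamma"), n_coef = 5L * nI),
    gi = decomposed_parameter(lattice, ord("gamma"),
      n_coef = 5L * nI,
      base_scale = pri$gamma_ind_scale
    ),
    cut = decomposed_parameter(lattice, ord("cut"),
      n_coef = 5L,
      base_scale = pri$cut_scale
    ),
    xi = decomposed_parameter(lattice, ord("xi"), n_coef = p)
  )

  # Flat unconstrained latent layout. Slope blocks (beta, gp, xi) are
  # horseshoe: raw normal z, per-coefficient log local scale u, one log
  # global scale v per block.
  layout <- list()
  off <- 0L
  add <- function(name, len) {
    layout[[name]] <<- list(offset = off, length = as.integer(len))
    off <<- off + as.integer(len)
  }
  add("alpha", dp_length(dps$alpha))
  add("beta_z", dp_length(dps$beta))
  add("beta_u", dp_length(dps$beta))
  add("beta_v", 1L)
  add("gp_z", dp_length(dps$gp))
  add("gp_u", dp_length(dps$gp))
  add("gp_v", 1L)
  add("gi", dp_length(dps$gi))
  add("cut", dp_length(dps$cut))
  add("xi_z", dp_length(dps$xi))
  add("xi_u", dp_length(dps$xi))
  add("xi_v", 1L)

  structure(
    list(
      X = X, time = tvec, event = evec, placement = ivec,
      ind_block = outer(ivec, 1:5, ">=") * 1,
      cell = cell, kappa = kappa, lattice = lattice, pem = pem,
      exposure = pem_exposure(tvec, pem),
      event_interval = pem_interval_index(tvec, pem),
      features = features, cohorts = cohorts,
      time_col = time, event_col = event, placement_col = placement,
      n = nrow(data), p = p, n_intervals = nI,
      dps = dps, layout = layout, n_latent = off, priors = pri,
      init_alpha = crude_interval_log_rates(
        evec, pem_interval_index(tvec, pem), pem_exposure(tvec, pem)
      )
    ),
    class = "quilt_model"
  )
}

#' @export
print.quilt_model <- function(x, ...) {
  cat(sprintf(
    "<quilt_model> %d episodes, %d binary features, %s lattice, %d intervals, %d latents\n",
    x$n, x$p, paste(x$lattice$dims, collapse = "x"), x$n_intervals, x$n_latent
  ))
  invisible(x)
}

# Crude constant log hazard per interval (events / person-days): the
# initialization of the zero-order baseline term. Starting the intercepts
# near the marginal rates keeps the bounded exceedance-probability
# covariates from absorbing the baseline early in training.
crude_interval_log_rates <- function(event, event_interval, exposure) {
  nI <- ncol(exposure)
  vapply(seq_len(nI), function(i) {
    ev <- sum(event[event_interval == i])
    ex <- sum(exposure[, i])
    log(max(ev, 0.5) / max(ex, 1))
  }, numeric(1))
}

qm_slice <- function(z, model, name) {
  b <- model$layout[[name]]
  z[(b$offset + 1L):(b$offset + b$length)]
}

# Horseshoe row-scale matrix for a slope dp: order multipliers expanded to
# (rows x coef) shape.
qm_row_scale_mat <- function(dp) {
  matrix(dp_row_scales(dp), nrow = dp$n_rows, ncol = dp$n_coef)
}

# Constrained cell-level parameter arrays from an unconstrained latent
# vector. Returns materialized matrices per block plus intermediates the
# gradient needs.
qm_constrain <- function(model, z) {
  dps <- model$dps
  nI <- model$n_intervals
  grab <- function(name, dp) matrix(qm_slice(z, model, name), dp$n_rows, dp$n_coef)

  Ca <- grab("alpha", dps$alpha)

  hs_block <- function(zname, uname, vname, dp) {
    zz <- grab(zname, dp)
    uu <- grab(uname, dp)
    vv <- qm_slice(z, model, vname)
    rs <- qm_row_scale_mat(dp)
    C <- zz * exp(uu) * exp(vv) * rs
    list(z = zz, u = uu, v = vv, rs = rs, C = C)
  }
  hb <- hs_block("beta_z", "beta_u", "beta_v", dps$beta)
  hg <- hs_block("gp_z", "gp_u", "gp_v", dps$gp)
  hx <- hs_block("xi_z", "xi_u", "xi_v", dps$xi)

  Cgi <- grab("gi", dps$gi)
  Ccut <- grab("cut", dps$cut)

  A_cells <- as.matrix(dps$alpha$design %*% Ca)
  B_cells <- as.matrix(dps$beta$design %*% hb$C)
  GP_cells <- as.matrix(dps$gp$design %*% hg$C)
  GIraw_cells <- as.matrix(dps$gi$design %*% Cgi)
  GI_cells <- -softplus(GIraw_cells)
  CUTraw_cells <- as.matrix(dps$cut$design %*% Ccut)
  CUT_cells <- cutpoints_from_raw(CUTraw_cells)
  XI_cells <- as.matrix(dps$xi$design %*% hx$C)

  list(
    Ca = Ca, hb = hb, hg = hg, hx = hx, Cgi = Cgi, Ccut = Ccut,
    A = A_cells, B = B_cells, GP = GP_cells,
    GIraw = GIraw_cells, GI = GI_cells,
    CUTraw = CUTraw_cells, CUT = CUT_cells, XI = XI_cells
  )
}

# Log prior over all latent blocks in unconstrained space (half-Cauchy
# terms include the exp-transform log-Jacobians), plus its gradient.
qm_log_prior_grad <- function(model, z, cp) {
  grad <- numeric(model$n_latent)
  lp <- 0
  put <- function(name, g) {
    b <- model$layout[[name]]
    grad[(b$offset + 1L):(b$offset + b$length)] <<- as.vector(g)
  }
  # normal blocks (order-graded scales)
  for (blk in list(
    list("alpha", model$dps$alpha, cp$Ca),
    list("gi", model$dps$gi, cp$Cgi),
    list("cut", model$dps$cut, cp$Ccut)
  )) {
    s <- qm_row_scale_mat(blk[[2]])
    lp <- lp + sum(stats::dnorm(blk[[3]], 0, s, log = TRUE))
    put(blk[[1]], -blk[[3]] / s^2)
  }
  # horseshoe blocks: z ~ N(0,1); local ~ C+(0,1); global ~ C+(0, tau0)
  tau0 <- model$priors$hs_global_scale
  for (blk in list(
    list("beta", cp$hb), list("gp", cp$hg), list("xi", cp$hx)
  )) {
    h <- blk[[2]]
    lp <- lp + sum(stats::dnorm(h$z, 0, 1, log = TRUE))
    lp <- lp + sum(log(2 / pi) + h$u - softplus(2 * h$u))
    lp <- lp + log(2 / (pi * tau0)) + h$v - softplus(2 * h$v - 2 * log(tau0))
    put(paste0(blk[[1]], "_z"), -h$z)
    put(paste0(blk[[1]], "_u"), 1 - 2 * stats::plogis(2 * h$u))
    put(paste0(blk[[1]], "_v"), 1 - 2 * stats::plogis(2 * h$v - 2 * log(tau0)))
  }
  list(lp = lp, grad = grad)
}

#' Joint log density of the quilt model at given latents
#'
#' The minibatch-scaled joint density: `(n / batch) * sum over the batch of
#' [PEM log likelihood + ordinal placement log likelihood] + log prior`,
#' with all constraint transforms and their log-Jacobians applied. Used as
#' the stochastic ELBO integrand.
#'
#' @param model A [quilt_model()].
#' @param z Unconstrained latent vector of length `model$n_latent`.
#' @param batch Integer indices of the episodes in the batch (default: all).
#' @return Scalar log density.
#' @export
quilt_joint_log_density <- function(model, z, batch = seq_len(model$n)) {
  qm_density_grad(model, z, batch, want_grad = FALSE)$value
}

# Core density + analytic gradient. scale = n / |batch| multiplies the
# likelihood; the prior enters once.
qm_density_grad <- function(model, z, batch, want_grad = TRUE) {
  if (length(z) != model$n_latent) {
    stop_input("latent vector has length %d; expected %d", length(z), model$n_latent)
  }
  cp <- qm_constrain(model, z)
  if (length(batch) == 0L) {
    # priors-only evaluation (empty batch)
    prior <- qm_log_prior_grad(model, z, cp)
    return(list(value = prior$lp, grad = prior$grad, log_lik = 0))
  }
  nI <- model$n_intervals
  p <- model$p
  ncell <- n_cells(model$lattice)
  scale <- model$n / length(batch)

  Xb <- model$X[batch, , drop = FALSE]
  cells_b <- model$cell[batch]
  Db <- model$ind_block[batch, , drop = FALSE]
  Eb <- model$exposure[batch, , drop = FALSE]
  evb <- model$event[batch]
  idxb <- model$event_interval[batch]
  Ib <- model$placement[batch]
  B <- length(batch)

  # ordinal part
  eta <- rowSums(Xb * cp$XI[cells_b, , drop = FALSE])
  cutb <- cp$CUT[cells_b, , drop = FALSE]
  P <- stats::plogis(eta - cutb) # B x 5 exceedance
  Pd <- P * (1 - P)
  Pfull <- cbind(1, P, 0)
  pcat <- Pfull[cbind(seq_len(B), Ib + 1L)] - Pfull[cbind(seq_len(B), Ib + 2L)]
  pcat <- pmax(pcat, 1e-300)
  ll_ord <- sum(log(pcat))

  # survival part
  W <- cbind(P, Db)
  LH <- matrix(0, B, nI)
  for (i in seq_len(nI)) {
    bi <- cp$B[cells_b, ((i - 1L) * p + 1L):(i * p), drop = FALSE]
    gpi <- cp$GP[cells_b, ((i - 1L) * 5L + 1L):(i * 5L), drop = FALSE]
    gii <- cp$GI[cells_b, ((i - 1L) * 5L + 1L):(i * 5L), drop = FALSE]
    LH[, i] <- cp$A[cells_b, i] + rowSums(Xb * bi) +
      rowSums(P * gpi) + rowSums(Db * gii)
  }
  lam <- exp(LH)
  cumhaz <- rowSums(lam * Eb)
  ll_surv <- sum(evb * LH[cbind(seq_len(B), idxb)]) - sum(cumhaz)

  prior <- qm_log_prior_grad(model, z, cp)
  value <- scale * (ll_surv + ll_ord) + prior$lp
  if (!is.finite(value)) {
    stop("non-finite joint density (check hazards/cutpoints for divergence)",
      call. = FALSE
    )
  }
  if (!want_grad) {
    return(list(value = value))
  }

  # --- gradients ---
  # d log-lik / d log-hazard
  Dn <- -lam * Eb
  Dn[cbind(seq_len(B), idxb)] <- Dn[cbind(seq_len(B), idxb)] + evb

  # d ll_surv / d P (through the gamma prob-block covariates)
  eP <- matrix(0, B, 5L)
  for (i in seq_len(nI)) {
    gpi <- cp$GP[cells_b, ((i - 1L) * 5L + 1L):(i * 5L), drop = FALSE]
    eP <- eP + Dn[, i] * gpi
  }
  # d ll_ord / d P
  og <- matrix(0, B, 5L)
  sel1 <- Ib >= 1L
  og[cbind(which(sel1), Ib[sel1])] <- 1 / pcat[sel1]
  sel2 <- Ib <= 4L
  og[cbind(which(sel2), Ib[sel2] + 1L)] <- og[cbind(which(sel2), Ib[sel2] + 1L)] - 1 / pcat[sel2]
  fP <- eP + og

  grad_eta <- rowSums(fP * Pd)

  # per-cell accumulations
  G_A <- matrix(0, ncell, nI)
  G_B <- matrix(0, ncell, p * nI)
  G_GP <- matrix(0, ncell, 5L * nI)
  G_GIm <- matrix(0, ncell, 5L * nI) # d ll / d GI (constrained scale)
  G_CUT <- matrix(0, ncell, 5L)
  G_XI <- matrix(0, ncell, p)
  for (c_id in unique(cells_b)) {
    sel <- cells_b == c_id
    Dc <- Dn[sel, , drop = FALSE]
    Xc <- Xb[sel, , drop = FALSE]
    G_A[c_id, ] <- colSums(Dc)
    G_B[c_id, ] <- as.vector(crossprod(Xc, Dc)) # p x nI, interval-major
    G_GP[c_id, ] <- as.vector(crossprod(P[sel, , drop = FALSE], Dc))
    G_GIm[c_id, ] <- as.vector(crossprod(Db[sel, , drop = FALSE], Dc))
    G_CUT[c_id, ] <- -colSums((fP * Pd)[sel, , drop = FALSE])
    G_XI[c_id, ] <- crossprod(Xc, grad_eta[sel])
  }

  # chain GI through -softplus
  G_GIraw <- -G_GIm * stats::plogis(cp$GIraw)
  # chain CUT through c_1 + cumsum(softplus(raw_2..5))
  G_CUTraw <- matrix(0, ncell, 5L)
  rev_cum <- t(apply(G_CUT, 1L, function(r) rev(cumsum(rev(r)))))
  if (ncell == 1L) rev_cum <- matrix(rev_cum, 1L, 5L)
  G_CUTraw[, 1L] <- rev_cum[, 1L]
  G_CUTraw[, 2:5] <- stats::plogis(cp$CUTraw[, 2:5, drop = FALSE]) * rev_cum[, 2:5, drop = FALSE]

  grad <- prior$grad
  bump <- function(name, g) {
    b <- model$layout[[name]]
    i <- (b$offset + 1L):(b$offset + b$length)
    grad[i] <<- grad[i] + scale * as.vector(as.matrix(g))
  }
  dps <- model$dps
  bump("alpha", Matrix::crossprod(dps$alpha$design, G_A))
  gB <- as.matrix(Matrix::crossprod(dps$beta$design, G_B))
  gGP <- as.matrix(Matrix::crossprod(dps$gp$design, G_GP))
  gXI <- as.matrix(Matrix::crossprod(dps$xi$design, G_XI))
  bump("gi", Matrix::crossprod(dps$gi$design, G_GIraw))
  bump("cut", Matrix::crossprod(dps$cut$design, G_CUTraw))
  # horseshoe chain: C = z * exp(u) * exp(v) * rs
  hs_bump <- function(prefix, h, gC) {
    bump(paste0(prefix, "_z"), gC * exp(h$u) * exp(h$v[1]) * h$rs)
    bump(paste0(prefix, "_u"), gC * h$C)
    bump(paste0(prefix, "_v"), sum(gC * h$C))
  }
  hs_bump("beta", cp$hb, gB)
  hs_bump("gp", cp$hg, gGP)
  hs_bump("xi", cp$hx, gXI)

  list(value = value, grad = grad, log_lik = scale * (ll_surv + ll_ord))
}
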