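# Full forward pass and analytic reverse-mode gradients for the composite
# objective. Training is full-batch, so all intermediates are kept and the
# backward pass mirrors the forward pass exactly; correctness is guarded by a
# finite-difference test. Everything here is internal; the exported encoder
# functions in model.R call the same primitives.

# Precompute the per-fold constants: features, aggregation operator, GCN
# propagation, and pair node indices.
make_model_data <- function(g, pairs, labels) {
  adj <- graph_adjacency(g)
  stopifnot(nrow(pairs) == length(labels), all(labels %in% c(0, 1)))
  list(
    X = g$features,
    agg = mean_aggregator(adj),
    P = gcn_propagation(adj),
    mi = as.integer(pairs[, 1]),
    di = as.integer(g$m + pairs[, 2]),
    y = as.numeric(labels),
    m = g$m, n = g$n, N = g$n_nodes
  )
}

draw_eps <- function(cfg, N) {
  D <- cfg$latent_dim
  list(
    vae = if (cfg$use_vae) matrix(stats::rnorm(N * D), N, D),
    gvae = if (cfg$use_gvae) matrix(stats::rnorm(N * D), N, D)
  )
}

# Returns the loss breakdown, pair scores and (optionally) gradients with the
# same nesting as `state`. `eps` must be supplied in train mode when latent
# sampling is on, so finite differences evaluate the identical function.
model_loss_grad <- function(state, data, cfg, train_cfg, eps = NULL,
                            train = TRUE, want_grad = TRUE) {
  sample_latent <- train && cfg$sample_latent
  sgn <- if (train_cfg$kl_sign == "penalize") 1 else -1
  N <- data$N
  grads <- list()

  # ---- forward: SAGE ----
  if (cfg$use_sage) {
    sf <- sage_forward(data$X, data$agg, state$sage, cfg)
    Xt <- sf$H
  } else {
    Xt <- data$X
  }

  # ---- forward: VAE on raw features ----
  kl_vae <- 0
  if (cfg$use_vae) {
    pv <- state$vae
    MU <- row_add(data$X %*% pv$W_mu, pv$b_mu)
    ln_v <- layer_norm_forward(row_add(data$X %*% pv$W_lv, pv$b_lv),
                               pv$gamma, pv$beta)
    V <- ln_v$out
    SIG2 <- exp(V)
    Z <- if (sample_latent) MU + sqrt(SIG2) * eps$vae else MU
    kl_vae <- 0.5 * sum(SIG2 + MU^2 - V - 1) / N
  }

  # ---- forward: GVAE on the encoded graph ----
  kl_gvae <- 0
  if (cfg$use_gvae) {
    pg <- state$gvae
    Q <- data$P %*% Xt
    MUt <- row_add(Q %*% pg$W_mu, pg$b_mu)
    ln_g <- layer_norm_forward(row_add(Q %*% pg$W_lv, pg$b_lv),
                               pg$gamma, pg$beta)
    Vt <- ln_g$out
    SIG2t <- exp(Vt)
    Zt <- if (sample_latent) MUt + sqrt(SIG2t) * eps$gvae else MUt
    kl_gvae <- 0.5 * sum(SIG2t + MUt^2 - Vt - 1) / N
  }

  # ---- forward: fusion and predictor ----
  blocks <- list(
    if (cfg$use_vae) Z,
    if (cfg$use_gvae) Zt,
    if (cfg$use_sage) Xt
  )
  fused <- do.call(cbind, Filter(Negate(is.null), blocks))
  pp <- state$pred
  ZH <- fused[data$mi, , drop = FALSE] * fused[data$di, , drop = FALSE]
  H1pre <- row_add(ZH %*% pp$W1, pp$b1)
  H1 <- relu(H1pre)
  logit <- drop(H1 %*% pp$w2) + pp$b2
  np <- length(data$y)
  pred_loss <- mean(softplus(logit) - data$y * logit)
  total <- pred_loss + sgn * (train_cfg$beta_vae * kl_vae +
                              train_cfg$beta_gvae * kl_gvae)
  scores <- stats::plogis(logit)

  out <- list(
    breakdown = loss_breakdown(pred_loss, kl_vae, kl_gvae,
                               train_cfg$beta_vae, train_cfg$beta_gvae,
                               train_cfg$kl_sign),
    scores = scores
  )
  if (!want_grad) return(out)

  # ---- backward: predictor ----
  dlogit <- (scores - data$y) / np
  grads$pred <- list(
    W1 = NULL, b1 = NULL,
    w2 = crossprod(H1, dlogit), b2 = sum(dlogit)
  )
  dH1 <- tcrossprod(dlogit, drop(pp$w2))
  dH1pre <- dH1 * (H1pre > 0)
  grads$pred$W1 <- crossprod(ZH, dH1pre)
  grads$pred$b1 <- colSums(dH1pre)
  dZH <- tcrossprod(dH1pre, pp$W1)

  dF <- matrix(0, N, ncol(fused))
  dF <- accumulate_rows(dF, data$mi, dZH * fused[data$di, , drop = FALSE])
  dF <- accumulate_rows(dF, data$di, dZH * fused[data$mi, , drop = FALSE])

  # split fused gradient back into blocks (order Z, Zt, Xt)
  off <- 0L
  take <- function(w) {
    blk <- dF[, (off + 1L):(off + w), drop = FALSE]
    off <<- off + w
    blk
  }
  dZ <- if (cfg$use_vae) take(cfg$latent_dim)
  dZt <- if (cfg$use_gvae) take(cfg$latent_dim)
  dXt <- if (cfg$use_sage) take(ncol(Xt)) else NULL

  # ---- backward: VAE ----
  if (cfg$use_vae) {
    cf <- sgn * train_cfg$beta_vae / N
    dMU <- cf * MU + dZ
    dV <- cf * 0.5 * (SIG2 - 1)
    if (sample_latent) dV <- dV + dZ * eps$vae * 0.5 * sqrt(SIG2)
    lb <- layer_norm_backward(dV, ln_v)
    grads$vae <- list(
      W_mu = crossprod(data$X, dMU), b_mu = colSums(dMU),
      W_lv = crossprod(data$X, lb$dU), b_lv = colSums(lb$dU),
      gamma = lb$dgamma, beta = lb$dbeta
    )
  }

  # ---- backward: GVAE ----
  if (cfg$use_gvae) {
    cg <- sgn * train_cfg$beta_gvae / N
    dMUt <- cg * MUt + dZt
    dVt <- cg * 0.5 * (SIG2t - 1)
    if (sample_latent) dVt <- dVt + dZt * eps$gvae * 0.5 * sqrt(SIG2t)
    lbg <- layer_norm_backward(dVt, ln_g)
    pg <- state$gvae
    grads$gvae <- list(
      W_mu = crossprod(Q, dMUt), b_mu = colSums(dMUt),
      W_lv = crossprod(Q, lbg$dU), b_lv = colSums(lbg$dU),
      gamma = lbg$dgamma, beta = lbg$dbeta
    )
    dQ <- tcrossprod(dMUt, pg$W_mu) + tcrossprod(lbg$dU, pg$W_lv)
    if (cfg$use_sage) {
      dXt_g <- crossprod(data$P, dQ)
      dXt <- if (is.null(dXt)) dXt_g else dXt + dXt_g
    }
  }

  # ---- backward: SAGE ----
  if (cfg$use_sage) {
    L <- length(state$sage)
    dH <- dXt
    sage_grads <- vector("list", L)
    for (l in rev(seq_len(L))) {
      lay <- state$sage[[l]]
      dPre <- if (l < L) dH * (sf$pre[[l]] > 0) else dH
      gl <- list(
        W_self = crossprod(sf$inputs[[l]], dPre),
        b = colSums(dPre)
      )
      if (cfg$tie_sage_weights) {
        gl$W_self <- gl$W_self + crossprod(sf$aggs[[l]], dPre)
        W_agg <- lay$W_self
      } else {
        gl$W_agg <- crossprod(sf$aggs[[l]], dPre)
        W_agg <- lay$W_agg
      }
      # keep field order identical to the state for flatten/unflatten
      sage_grads[[l]] <- gl[names(lay)]
      if (l > 1L) {
        dH <- crossprod(data$agg, tcrossprod(dPre, W_agg)) +
          tcrossprod(dPre, lay$W_self)
      }
    }
    grads$sage <- sage_grads
  }

  out$grads <- grads[names(state)]
  out
}
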