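#' Model architecture configuration
#'
#' Defaults: two GraphSAGE layers of width 64 (ReLU on the hidden layer,
#' identity on the last), latent width 64 for both variational encoders, and
#' a one-hidden-layer (width 64) predictor. The three `use_*` switches are
#' the component-ablation toggles; see [ablation_config()] for the presets.
#'
#' @param sage_layers Number of GraphSAGE layers.
#' @param sage_dim Width of every GraphSAGE layer.
#' @param latent_dim Latent width of the VAE and the graph VAE.
#' @param predictor_hidden Hidden width of the pair-scoring MLP.
#' @param use_sage,use_vae,use_gvae Component toggles. With `use_sage = FALSE`
#'   the raw node features stand in for the SAGE output, so the graph VAE
#'   (if enabled) convolves the raw features and the SAGE block is dropped
#'   from the fusion.
#' @param tie_sage_weights If `TRUE` the self and aggregate paths of each
#'   SAGE layer share one weight matrix.
#' @param sk_kernel Sigmoid-kernel variant used when features are built from
#'   an association matrix, see [sigmoid_kernel()].
#' @param sample_latent If `TRUE`, training draws latent codes by
#'   reparameterization; the default `FALSE` trains on the posterior means
#'   (the KL terms still regularize both posteriors). At the default KL
#'   weights the stochastic pass injects noise without a compensating
#'   objective, so deterministic training is the default; evaluation always
#'   uses posterior means either way.
#' @return A `model_config` list.
#' @export
model_config <- function(sage_layers = 2L, sage_dim = 64L, latent_dim = 64L,
                         predictor_hidden = 64L,
                         use_sage = TRUE, use_vae = TRUE, use_gvae = TRUE,
                         tie_sage_weights = FALSE,
                         sk_kernel = "logistic", sample_latent = FALSE) {
  stopifnot(sage_layers >= 1L, sage_dim >= 1L, latent_dim >= 1L,
            predictor_hidden >= 1L)
  if (!use_sage && !use_vae && !use_gvae) {
    stop("configuration error: at least one encoder component must be enabled",
         call. = FALSE)
  }
  structure(
    list(sage_layers = as.integer(sage_layers), sage_dim = as.integer(sage_dim),
         latent_dim = as.integer(latent_dim),
         predictor_hidden = as.integer(predictor_hidden),
         use_sage = use_sage, use_vae = use_vae, use_gvae = use_gvae,
         tie_sage_weights = tie_sage_weights, sk_kernel = sk_kernel,
         sample_latent = sample_latent),
    class = "model_config"
  )
}

#' Component-ablation presets
#'
#' `"full"` runs SAGE + VAE + graph VAE; `"sage_only"` scores the SAGE
#' embedding directly; `"dva_only"` scores the feature-space VAE code alone;
#' `"gva_only"` scores the graph-VAE code computed on the raw features.
#'
#' @param preset One of `"full"`, `"sage_only"`, `"dva_only"`, `"gva_only"`.
#' @param ... Passed on to [model_config()].
#' @return A `model_config`.
#' @export
ablation_config <- function(preset = c("full", "sage_only", "dva_only",
                                       "gva_only"), ...) {
  preset <- match.arg(preset)
  switch(preset,
    full      = model_config(...),
    sage_only = model_config(use_vae = FALSE, use_gvae = FALSE, ...),
    dva_only  = model_config(use_sage = FALSE, use_gvae = FALSE, ...),
    gva_only  = model_config(use_sage = FALSE, use_vae = FALSE, ...)
  )
}

# width of the fused representation under a config
fused_width <- function(cfg, input_dim) {
  sage_out <- if (cfg$use_sage) cfg$sage_dim else input_dim
  w <- 0L
  if (cfg$use_vae) w <- w + cfg$latent_dim
  if (cfg$use_gvae) w <- w + cfg$latent_dim
  if (cfg$use_sage) w <- w + cfg$sage_dim
  w
}

#' Initialize trainable model state
#'
#' Glorot-uniform weight matrices, zero biases, unit scale / zero shift for
#' the normalization layers of the two variance paths.
#'
#' @param cfg A [model_config()].
#' @param input_dim Width of the node feature matrix.
#' @param seed Integer seed for the weight draw.
#' @return A `model_state`: nested list of parameter matrices/vectors.
#' @export
init_model_state <- function(cfg, input_dim, seed = 1L) {
  set.seed(seed)
  D <- cfg$latent_dim
  sage_out <- if (cfg$use_sage) cfg$sage_dim else input_dim
  state <- list()
  if (cfg$use_sage) {
    widths <- c(input_dim, rep(cfg$sage_dim, cfg$sage_layers))
    state$sage <- lapply(seq_len(cfg$sage_layers), function(l) {
      lay <- list(W_self = glorot(widths[l], widths[l + 1]),
                  b = numeric(widths[l + 1]))
      if (!cfg$tie_sage_weights) {
        lay$W_agg <- glorot(widths[l], widths[l + 1])
      }
      lay
    })
  }
  if (cfg$use_vae) {
    state$vae <- list(
      W_mu = glorot(input_dim, D), b_mu = numeric(D),
      W_lv = glorot(input_dim, D), b_lv = numeric(D),
      gamma = rep(1, D), beta = numeric(D)
    )
  }
  if (cfg$use_gvae) {
    state$gvae <- list(
      W_mu = glorot(sage_out, D), b_mu = numeric(D),
      W_lv = glorot(sage_out, D), b_lv = numeric(D),
      gamma = rep(1, D), beta = numeric(D)
    )
  }
  wf <- fused_width(cfg, input_dim)
  state$pred <- list(
    W1 = glorot(wf, cfg$predictor_hidden), b1 = numeric(cfg$predictor_hidden),
    w2 = glorot(cfg$predictor_hidden, 1L), b2 = 0
  )
  structure(state, class = "model_state")
}

# feature-wise standardization over nodes with learned affine; eps keeps the
# inverse standard deviation finite for constant columns
layer_norm_forward <- function(U, gamma, beta, eps = 1e-5) {
  n <- nrow(U)
  mu <- colMeans(U)
  Uc <- row_add(U, -mu)
  v <- colMeans(Uc^2)
  istd <- 1 / sqrt(v + eps)
  Un <- row_broadcast(Uc, istd)
  list(out = row_add(row_broadcast(Un, gamma), beta),
       Un = Un, istd = istd, gamma = gamma)
}

layer_norm_backward <- function(dV, cache) {
  n <- nrow(dV)
  dUn <- row_broadcast(dV, cache$gamma)
  s1 <- colSums(dUn)
  s2 <- colSums(dUn * cache$Un)
  dU <- row_broadcast(n * dUn - rep(s1, each = n) - cache$Un * rep(s2, each = n),
                      cache$istd / n)
  list(dU = dU, dgamma = colSums(dV * cache$Un), dbeta = colSums(dV))
}

#' GraphSAGE mean-aggregation encoder
#'
#' At each layer every node combines the mean of its neighbors' features with
#' its own: `h_v = act(W_agg . mean_{u in N(v)} h_u + W_self . h_v + b)`.
#' Nodes with no neighbors contribute a zero aggregate. Hidden layers use
#' ReLU; the final layer is linear.
#'
#' @param g An `mda_graph` (its `features` are the layer-0 input).
#' @param state A `model_state` with a `sage` component.
#' @param cfg The matching [model_config()].
#' @return The mid-level embedding matrix, `(m + n) x sage_dim`.
#' @export
sage_encode <- function(g, state, cfg = model_config()) {
  agg <- mean_aggregator(graph_adjacency(g))
  sage_forward(g$features, agg, state$sage, cfg)$H
}

sage_forward <- function(X, agg, sage, cfg) {
  L <- length(sage)
  H <- X
  pre <- vector("list", L)
  inputs <- vector("list", L)
  aggs <- vector("list", L)
  for (l in seq_len(L)) {
    lay <- sage[[l]]
    W_agg <- lay$W_agg %||% lay$W_self
    if (ncol(H) != nrow(lay$W_self)) {
      stop("dimension error: SAGE layer ", l, " expects input width ",
           nrow(lay$W_self), ", got ", ncol(H), call. = FALSE)
    }
    inputs[[l]] <- H
    S <- agg %*% H
    aggs[[l]] <- S
    P <- row_add(S %*% W_agg + H %*% lay$W_self, lay$b)
    pre[[l]] <- P
    H <- if (l < L) relu(P) else P
  }
  list(H = H, pre = pre, inputs = inputs, aggs = aggs)
}

#' Variational encoder on raw node features
#'
#' The posterior mean is a single affine map of the features; the variance
#' path is an affine map followed by feature-wise standardization over nodes
#' (with learned scale/shift) and exponentiation, so variances are strictly
#' positive.
#'
#' @param X Node feature matrix.
#' @param state A `model_state` with a `vae` component.
#' @return A `latent_gaussian`: list with `mean`, `var` and `logvar`
#'   matrices of shape `(m + n) x latent_dim`.
#' @export
vae_encode <- function(X, state) {
  p <- state$vae
  if (ncol(X) != nrow(p$W_mu)) {
    stop("dimension error: encoder expects input width ", nrow(p$W_mu),
         ", got ", ncol(X), call. = FALSE)
  }
  mean <- row_add(X %*% p$W_mu, p$b_mu)
  ln <- layer_norm_forward(row_add(X %*% p$W_lv, p$b_lv), p$gamma, p$beta)
  new_latent_gaussian(mean, ln$out)
}

#' Graph variational encoder on the encoded graph
#'
#' Both posterior paths are single graph-convolution layers using the
#' symmetric self-loop normalization `D^{-1/2}(A + I)D^{-1/2}` (see
#' [gcn_propagation()]); the variance path adds the same normalization layer
#' as [vae_encode()] before exponentiation.
#'
#' @param g An `mda_graph` supplying the adjacency.
#' @param X_mid Node embedding matrix to convolve (typically the
#'   [sage_encode()] output).
#' @param state A `model_state` with a `gvae` component.
#' @return A `latent_gaussian`.
#' @export
gvae_encode <- function(g, X_mid, state) {
  p <- state$gvae
  if (ncol(X_mid) != nrow(p$W_mu)) {
    stop("dimension error: graph encoder expects input width ", nrow(p$W_mu),
         ", got ", ncol(X_mid), call. = FALSE)
  }
  Q <- gcn_propagation(graph_adjacency(g)) %*% X_mid
  mean <- row_add(Q %*% p$W_mu, p$b_mu)
  ln <- layer_norm_forward(row_add(Q %*% p$W_lv, p$b_lv), p$gamma, p$beta)
  new_latent_gaussian(mean, ln$out)
}

new_latent_gaussian <- function(mean, logvar) {
  stopifnot(all(dim(mean) == dim(logvar)), all(is.finite(mean)))
  structure(list(mean = mean, var = exp(logvar), logvar = logvar),
            class = "latent_gaussian")
}

#' @export
print.latent_gaussian <- function(x, ...) {
  cat("<latent_gaussian> ", nrow(x$mean), " nodes x ", ncol(x$mean),
      " latent dims\n", sep = "")
  invisible(x)
}

#' Draw latent codes from a Gaussian posterior
#'
#' Training mode uses the reparameterization `Z = mean + sqrt(var) * eps`
#' with standard normal `eps`; evaluation mode returns the posterior mean
#' exactly, which makes scoring deterministic.
#'
#' @param q A `latent_gaussian`.
#' @param mode `"eval"` (default) or `"train"`.
#' @param eps Optional pre-drawn standard-normal matrix (same shape as the
#'   mean); drawn from the current RNG when omitted in train mode.
#' @return Latent code matrix `Z`.
#' @export
reparameterize <- function(q, mode = c("eval", "train"), eps = NULL) {
  mode <- match.arg(mode)
  if (mode == "eval") return(q$mean)
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(q$mean)), nrow(q$mean), ncol(q$mean))
  }
  q$mean + sqrt(q$var) * eps
}

#' Fuse encoder outputs by column-wise concatenation
#'
#' Blocks are concatenated in the order VAE code, graph-VAE code, SAGE
#' embedding; `NULL` blocks (ablated components) are skipped.
#'
#' @param Z,Z_tilde,X_tilde Matrices with equal row counts, or `NULL`.
#' @return The fused feature matrix.
#' @export
fuse_features <- function(Z = NULL, Z_tilde = NULL, X_tilde = NULL) {
  blocks <- Filter(Negate(is.null), list(Z, Z_tilde, X_tilde))
  if (length(blocks) == 0L) stop("nothing to fuse", call. = FALSE)
  rows <- vapply(blocks, nrow, 1L)
  if (length(unique(rows)) != 1L) {
    stop("dimension error: fused blocks have differing row counts",
         call. = FALSE)
  }
  do.call(cbind, blocks)
}

#' Score microbe-disease pairs
#'
#' Combines the fused embeddings of a microbe node and a disease node by
#' Hadamard (elementwise) product and maps the result through a small MLP
#' (affine, ReLU, affine) and a logistic output, giving a score in (0, 1).
#'
#' @param fused Fused node feature matrix (`m + n` rows).
#' @param microbe Integer vector of microbe node indices (`1..m`).
#' @param disease Integer vector of disease node indices (`m+1..m+n`).
#' @param state A `model_state` with a `pred` component.
#' @param m Number of microbes (partition boundary).
#' @return Numeric vector of association scores.
#' @export
score_pairs <- function(fused, microbe, disease, state, m) {
  if (any(microbe < 1L | microbe > m) ||
      any(disease <= m | disease > nrow(fused))) {
    stop("index error: pair indices outside the microbe/disease partition",
         call. = FALSE)
  }
  p <- state$pred
  zh <- fused[microbe, , drop = FALSE] * fused[disease, , drop = FALSE]
  h1 <- relu(row_add(zh %*% p$W1, p$b1))
  stats::plogis(drop(h1 %*% p$w2) + p$b2)
}
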