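#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' `0.5 * sum_i (var_i + mean_i^2 - log var_i - 1)` summed over latent
#' dimensions and averaged over nodes, so the penalty weight is independent
#' of dataset size.
#'
#' @param q A `latent_gaussian`.
#' @return Nonnegative scalar.
#' @export
kl_gaussian <- function(q) {
  if (any(q$var <= 0)) {
    stop("domain error: nonpositive posterior variance", call. = FALSE)
  }
  0.5 * sum(q$var + q$mean^2 - log(q$var) - 1) / nrow(q$mean)
}

#' Binary cross-entropy of association scores
#'
#' Mean over pairs of `-[y log s + (1 - y) log(1 - s)]`. Scores touching the
#' boundary are clamped to 1e-12 away from it (reported via a message when
#' `quiet = FALSE`).
#'
#' @param scores Predicted scores in (0, 1).
#' @param labels 0/1 labels, same length.
#' @param quiet Suppress the clamping message.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(scores, labels, quiet = TRUE) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  eps <- 1e-12
  if (any(scores <= 0 | scores >= 1)) {
    if (!quiet) message("bce_loss: scores clamped to [", eps, ", 1 - ", eps, "]")
  }
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log1p(-s))
}

#' Combine the predictor and KL losses into the training objective
#'
#' Default (`kl_sign = "penalize"`) adds the beta-weighted KL terms, the
#' standard variational regularizer; `"subtract"` flips their sign.
#'
#' @param pred_loss,kl_vae,kl_gvae Scalar loss components.
#' @param beta_vae,beta_gvae Nonnegative KL weights.
#' @param kl_sign `"penalize"` or `"subtract"`.
#' @return A `loss_breakdown` list with the components and the total.
#' @export
total_loss <- function(pred_loss, kl_vae, kl_gvae,
                       beta_vae = 1e-3, beta_gvae = 1e-3,
                       kl_sign = c("penalize", "subtract")) {
  loss_breakdown(pred_loss, kl_vae, kl_gvae, beta_vae, beta_gvae,
                 match.arg(kl_sign))
}

loss_breakdown <- function(pred_loss, kl_vae, kl_gvae, beta_vae, beta_gvae,
                           kl_sign) {
  sgn <- if (kl_sign == "penalize") 1 else -1
  structure(
    list(pred_loss = pred_loss, kl_vae = kl_vae, kl_gvae = kl_gvae,
         beta_vae = beta_vae, beta_gvae = beta_gvae, kl_sign = kl_sign,
         total = pred_loss + sgn * (beta_vae * kl_vae + beta_gvae * kl_gvae)),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.5f = pred %.5f %s %g*kl_vae %.5f %s %g*kl_gvae %.5f\n",
              x$total, x$pred_loss,
              if (x$kl_sign == "penalize") "+" else "-", x$beta_vae, x$kl_vae,
              if (x$kl_sign == "penalize") "+" else "-", x$beta_gvae, x$kl_gvae))
  invisible(x)
}

#' Training hyperparameters
#'
#' Defaults: Adam with learning rate 1e-3, 200 full-batch epochs, KL weights
#' 1e-3, no early stopping.
#'
#' @param epochs Number of full-batch epochs (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is implemented.
#' @param beta_vae,beta_gvae KL penalty weights.
#' @param kl_sign See [total_loss()].
#' @param patience Early-stop patience in epochs on the total loss
#'   (`Inf` disables).
#' @param seed Integer seed fixing weight initialization, latent draws and
#'   any sampling downstream.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-3,
                         optimizer = "adam", beta_vae = 1e-3, beta_gvae = 1e-3,
                         kl_sign = c("penalize", "subtract"),
                         patience = Inf, seed = 1L) {
  stopifnot(epochs >= 1L, learning_rate > 0, optimizer == "adam",
            beta_vae >= 0, beta_gvae >= 0)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         optimizer = optimizer, beta_vae = beta_vae, beta_gvae = beta_gvae,
         kl_sign = match.arg(kl_sign), patience = patience,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the association predictor
#'
#' Full-batch gradient optimization of all parameters (SAGE, both
#' variational encoders, predictor) under the composite objective
#' (cross-entropy plus beta-weighted KL terms). All randomness — weight
#' initialization and per-epoch latent draws — is fixed by
#' `train_cfg$seed`, so identical calls produce identical fits.
#'
#' @param g Training `mda_graph` (must not contain held-out test edges).
#' @param pairs Data frame or matrix of labeled training pairs with columns
#'   (microbe index, disease index) in association-matrix coordinates.
#' @param labels 0/1 vector, or a `label`/`y` column in `pairs`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A `dvamda_fit` with the trained `state`, the per-epoch loss
#'   `history` tibble, and the configs; see [predict.dvamda_fit()],
#'   [tidy.dvamda_fit()], [autoplot.dvamda_fit()].
#' @export
train_dvamda <- function(g, pairs, labels = NULL,
                         model_cfg = model_config(),
                         train_cfg = train_config()) {
  if (is.null(labels)) {
    lab_col <- intersect(c("label", "y"), colnames(pairs))[1]
    if (is.na(lab_col)) stop("labels missing", call. = FALSE)
    labels <- pairs[[lab_col]]
  }
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  data <- make_model_data(g, pairs, labels)

  set.seed(train_cfg$seed)
  state <- init_model_state(model_cfg, ncol(data$X),
                            seed = sample.int(.Machine$integer.max, 1))
  theta <- flatten_params(state)
  opt <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
  history <- vector("list", train_cfg$epochs)
  best <- Inf
  stall <- 0L

  for (epoch in seq_len(train_cfg$epochs)) {
    eps <- if (model_cfg$sample_latent) draw_eps(model_cfg, data$N)
    res <- model_loss_grad(state, data, model_cfg, train_cfg, eps = eps,
                           train = TRUE, want_grad = TRUE)
    bd <- res$breakdown
    if (!is.finite(bd$total)) {
      stop("non-finite loss at epoch ", epoch, " (pred ", bd$pred_loss,
           ", kl_vae ", bd$kl_vae, ", kl_gvae ", bd$kl_gvae, ")",
           call. = FALSE)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, pred_loss = bd$pred_loss, kl_vae = bd$kl_vae,
      kl_gvae = bd$kl_gvae, total = bd$total
    )
    grad <- flatten_params(res$grads)
    step <- adam_step(opt, grad, train_cfg$learning_rate)
    opt <- step$opt
    theta <- theta - step$delta
    state <- unflatten_params(theta, state)

    if (bd$total < best - 1e-9) {
      best <- bd$total
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= train_cfg$patience) {
        history <- history[seq_len(epoch)]
        break
      }
    }
  }

  structure(
    list(state = state, model_cfg = model_cfg, train_cfg = train_cfg,
         graph = g, history = dplyr::bind_rows(history),
         input_dim = ncol(data$X)),
    class = "dvamda_fit"
  )
}

adam_step <- function(opt, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, delta = lr * mhat / (sqrt(vhat) + eps))
}

#' @export
print.dvamda_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<dvamda_fit> ", nrow(x$history), " epochs; final total loss ",
      signif(last$total, 5), " (pred ", signif(last$pred_loss, 5), ")\n",
      sep = "")
  invisible(x)
}

#' Score microbe-disease pairs with a trained model
#'
#' Runs the deterministic evaluation-mode forward pass (posterior means, no
#' latent sampling) and returns one score per requested pair.
#'
#' @param object A `dvamda_fit`.
#' @param pairs Data frame or matrix of (microbe index, disease index)
#'   pairs in association-matrix coordinates.
#' @param graph Graph to score on; defaults to the training graph.
#' @param ... Unused.
#' @return A tibble with columns `microbe`, `disease`, `score`.
#' @export
predict.dvamda_fit <- function(object, pairs, graph = object$graph, ...) {
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  data <- make_model_data(graph, pairs, numeric(nrow(pairs)))
  res <- model_loss_grad(object$state, data, object$model_cfg,
                         object$train_cfg, train = FALSE, want_grad = FALSE)
  tibble::tibble(microbe = pairs[, 1], disease = pairs[, 2],
                 score = res$scores)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch loss history of a fit
#'
#' @param x A `dvamda_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `pred_loss`, `kl_vae`, `kl_gvae`, `total`.
#' @export
tidy.dvamda_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `dvamda_fit`.
#' @param ... Unused.
#' @return Tibble with epoch count, final losses and parameter count.
#' @export
glance.dvamda_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    pred_loss = last$pred_loss, kl_vae = last$kl_vae,
    kl_gvae = last$kl_gvae, total = last$total,
    n_parameters = length(flatten_params(x$state))
  )
}
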