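# Forward-model operations, checked against hand-constructed weights and
# brute-force oracles on small graphs.

# a model state with hand-set SAGE weights on a given graph width
manual_sage_state <- function(width, W_self, W_agg, b = numeric(ncol(W_self))) {
  list(sage = list(list(W_self = W_self, b = b, W_agg = W_agg)))
}

test_that("SAGE with identity self-weights passes isolated nodes through", {
  A <- toy_assoc(rbind(c(1, 0), c(0, 0)))  # microbe 2 is isolated
  X <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  g <- build_graph(A, X)
  st <- manual_sage_state(2, diag(2), matrix(0, 2, 2))
  cfg <- model_config(sage_layers = 1L, sage_dim = 2L)
  H <- sage_encode(g, st, cfg)
  expect_equal(H[2, ], c(3, 4))  # isolated: zero aggregate, identity self
})

test_that("SAGE mean aggregation matches a brute-force neighbor loop", {
  # star center: disease 1 linked to microbes with features (2,0) and (0,2)
  A <- toy_assoc(rbind(c(1), c(1)))
  X <- rbind(c(2, 0), c(0, 2), c(0, 0))
  g <- build_graph(A, X)
  st <- manual_sage_state(2, matrix(0, 2, 2), diag(2))
  H <- sage_encode(g, st, model_config(sage_layers = 1L, sage_dim = 2L))
  expect_equal(H[3, ], c(1, 1))  # mean of the two neighbor features

  # random small graphs vs an explicit double loop
  for (seed in 1:100) {
    set.seed(seed)
    m <- sample(2:5, 1); n <- sample(1:3, 1)
    A <- random_assoc(m, n, density = 0.5, seed = seed)
    N <- m + n
    d <- 3
    X <- matrix(rnorm(N * d), N, d)
    g <- build_graph(A, X)
    W_self <- matrix(rnorm(d * 2), d, 2)
    W_agg <- matrix(rnorm(d * 2), d, 2)
    b <- rnorm(2)
    st <- manual_sage_state(d, W_self, W_agg, b)
    H <- sage_encode(g, st, model_config(sage_layers = 1L, sage_dim = 2L))

    adj <- graph_adjacency(g)
    for (v in 1:N) {
      nb <- which(adj[v, ] == 1)
      aggv <- if (length(nb) == 0) numeric(d) else colMeans(X[nb, , drop = FALSE])
      expect_equal(H[v, ], drop(aggv %*% W_agg + X[v, ] %*% W_self) + b,
                   tolerance = 1e-10)
    }
  }
})

test_that("SAGE output is equivariant under node relabeling", {
  for (seed in 1:5) {
    A <- random_assoc(4, 3, density = 0.5, seed = seed)
    set.seed(seed + 50)
    X <- matrix(rnorm(7 * 7), 7, 7)
    g <- build_graph(A, X)
    cfg <- model_config(sage_layers = 2L, sage_dim = 4L)
    st <- init_model_state(cfg, 7, seed = seed)
    H <- sage_encode(g, st, cfg)

    # permute microbes and diseases (within their partitions)
    pm <- sample(4); pd <- sample(3)
    Ap <- toy_assoc(A$values[pm, pd])
    Xp <- X[c(pm, 4 + pd), ]
    Hp <- sage_encode(build_graph(Ap, Xp), st, cfg)
    expect_equal(Hp, H[c(pm, 4 + pd), ], tolerance = 1e-10)
  }
})

test_that("VAE encoder produces an affine mean and positive variances", {
  A <- random_assoc(5, 3, seed = 9)
  X <- mda_node_features(A)
  cfg <- small_model_cfg()
  st <- init_model_state(cfg, ncol(X), seed = 2)
  q <- vae_encode(X, st)
  expect_equal(dim(q$mean), c(8L, cfg$latent_dim))
  expect_equal(dim(q$var), dim(q$mean))
  expect_true(all(q$var > 0))
  # identity mean path reproduces the input
  st_id <- list(vae = list(W_mu = diag(ncol(X)), b_mu = numeric(ncol(X)),
                           W_lv = diag(ncol(X)), b_lv = numeric(ncol(X)),
                           gamma = rep(1, ncol(X)), beta = numeric(ncol(X))))
  expect_equal(vae_encode(X, st_id)$mean, X)
  expect_error(vae_encode(X[, 1:3], st), "dimension error")
})

test_that("graph VAE convolves with the symmetric self-loop normalization", {
  # no edges: propagation is diagonal with unit scale, so the mean is affine
  A0 <- toy_assoc(matrix(0, 3, 2))
  X0 <- matrix(rnorm(10), 5, 2)
  st <- list(gvae = list(W_mu = diag(2), b_mu = c(0, 0),
                         W_lv = diag(2), b_lv = c(0, 0),
                         gamma = c(1, 1), beta = c(0, 0)))
  g0 <- build_graph(A0, X0)
  expect_equal(gvae_encode(g0, X0, st)$mean, X0, tolerance = 1e-12)

  # two connected nodes with equal features get equal posterior means
  A1 <- toy_assoc(matrix(1, 1, 1))
  X1 <- rbind(c(1, 2), c(1, 2))
  g1 <- build_graph(A1, X1)
  q1 <- gvae_encode(g1, X1, st)
  expect_equal(q1$mean[1, ], q1$mean[2, ])
})

test_that("reparameterization is exact in eval mode and unbiased in train mode", {
  mean <- matrix(c(0.5, -1, 2, 0), 2, 2)
  q <- dvamda:::new_latent_gaussian(mean, matrix(log(0.25), 2, 2))
  expect_identical(reparameterize(q, "eval"), q$mean)

  # zero variance collapses the sample onto the mean
  q0 <- list(mean = mean, var = matrix(0, 2, 2))
  expect_equal(reparameterize(structure(q0, class = "latent_gaussian"),
                              "train", eps = matrix(rnorm(4), 2, 2)),
               mean)

  # Monte-Carlo: sample mean within 4 standard errors of the posterior mean
  set.seed(1)
  draws <- replicate(10000, reparameterize(q, "train")[1, 1])
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(draws) - q$mean[1, 1]), 4 * se)
})

test_that("fusion concatenates blocks in order and tolerates ablated blocks", {
  Z <- matrix(1, 4, 3); Zt <- matrix(2, 4, 2); Xt <- matrix(3, 4, 5)
  fused <- fuse_features(Z, Zt, Xt)
  expect_equal(dim(fused), c(4L, 10L))
  expect_equal(fused[, 1:3], Z)
  expect_equal(fused[, 4:5], Zt)
  expect_equal(fuse_features(Z, NULL, Xt), cbind(Z, Xt))
  expect_error(fuse_features(Z, matrix(0, 3, 2), Xt), "dimension error")
})

test_that("pair scores come from the Hadamard product through the MLP", {
  set.seed(4)
  fused <- matrix(rnorm(6 * 4), 6, 4)
  st <- list(pred = list(W1 = matrix(rnorm(4 * 3), 4, 3), b1 = rnorm(3),
                         w2 = matrix(rnorm(3), 3, 1), b2 = 0.2))
  m <- 3
  s <- score_pairs(fused, c(1, 2), c(4, 5), st, m)
  expect_true(all(s > 0 & s < 1))

  # all-ones disease embedding makes the Hadamard product the microbe row
  fused1 <- fused; fused1[4, ] <- 1
  zh <- fused1[1, ]
  manual <- plogis(drop(pmax(zh %*% st$pred$W1 + st$pred$b1, 0) %*%
                          st$pred$w2) + st$pred$b2)
  expect_equal(score_pairs(fused1, 1, 4, st, m), manual, tolerance = 1e-12)

  # zero microbe embedding: score is the bias path, identical for all pairs
  fused0 <- fused; fused0[2, ] <- 0
  s0 <- score_pairs(fused0, c(2, 2), c(4, 6), st, m)
  expect_equal(s0[1], s0[2])

  # Hadamard symmetry: swapping the two embedding roles leaves scores fixed
  swapped <- fused
  swapped[c(1, 4), ] <- fused[c(4, 1), ]
  expect_equal(score_pairs(swapped, 1, 4, st, m),
               score_pairs(fused, 1, 4, st, m))

  expect_error(score_pairs(fused, 4, 5, st, m), "index error")
  expect_error(score_pairs(fused, 1, 2, st, m), "index error")
})

test_that("ablation presets assemble the advertised architectures", {
  expect_equal(ablation_config("full")[c("use_sage", "use_vae", "use_gvae")],
               list(use_sage = TRUE, use_vae = TRUE, use_gvae = TRUE))
  expect_equal(ablation_config("sage_only")[c("use_sage", "use_vae", "use_gvae")],
               list(use_sage = TRUE, use_vae = FALSE, use_gvae = FALSE))
  expect_equal(ablation_config("dva_only")[c("use_sage", "use_vae", "use_gvae")],
               list(use_sage = FALSE, use_vae = TRUE, use_gvae = FALSE))
  expect_equal(ablation_config("gva_only")[c("use_sage", "use_vae", "use_gvae")],
               list(use_sage = FALSE, use_vae = FALSE, use_gvae = TRUE))
  expect_error(model_config(use_sage = FALSE, use_vae = FALSE,
                            use_gvae = FALSE), "configuration error")
})

test_that("the eval-mode forward pass is deterministic", {
  A <- random_assoc(6, 4, seed = 12)
  prob <- toy_problem(A, seed = 12)
  cfg <- small_model_cfg()
  tc <- train_config(epochs = 5L, seed = 3)
  fit <- train_dvamda(prob$graph, prob$pairs, prob$labels, cfg, tc)
  s1 <- predict(fit, prob$pairs)
  s2 <- predict(fit, prob$pairs)
  expect_identical(s1, s2)
})
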