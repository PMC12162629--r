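# Small fixtures built in code; no files on disk.

# association matrix from an explicit binary matrix
toy_assoc <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  mn <- sprintf("m%02d", seq_len(nrow(values)))
  dn <- sprintf("d%02d", seq_len(ncol(values)))
  dimnames(values) <- list(mn, dn)
  dvamda:::new_association_matrix(values, mn, dn)
}

# random binary association matrix with at least one link
random_assoc <- function(m, n, density = 0.3, seed = 1) {
  set.seed(seed)
  values <- matrix(rbinom(m * n, 1, density), m, n)
  if (sum(values) == 0) values[sample(m, 1), sample(n, 1)] <- 1
  mn <- sprintf("m%02d", seq_len(m))
  dn <- sprintf("d%02d", seq_len(n))
  dimnames(values) <- list(mn, dn)
  dvamda:::new_association_matrix(matrix(as.integer(values), m, n,
                                         dimnames = list(mn, dn)), mn, dn)
}

# graph plus balanced labeled pairs from an association matrix
toy_problem <- function(A, n_neg = sum(A$values), seed = 1) {
  X <- mda_node_features(A)
  g <- build_graph(A, X)
  pos <- which(A$values == 1L, arr.ind = TRUE)
  set.seed(seed)
  neg <- sample_negatives(A, min(n_neg, sum(A$values == 0)))
  pairs <- rbind(unname(pos), as.matrix(neg))
  list(graph = g, pairs = pairs,
       labels = c(rep(1, nrow(pos)), rep(0, nrow(neg))))
}

small_model_cfg <- function(...) {
  model_config(sage_dim = 8L, latent_dim = 6L, predictor_hidden = 8L, ...)
}
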