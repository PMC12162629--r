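# Kernel similarities over interaction profiles. Microbe profiles are the
# rows of the association matrix, disease profiles its columns.

#' Gaussian interaction profile (GIP) kernel
#'
#' `GK(i, j) = exp(-gamma * ||x_i - x_j||^2)` with the data-driven bandwidth
#' `gamma = 1 / mean_k(||x_k||^2)`. If every profile is all-zero the bandwidth
#' is undefined and is set to 1. The diagonal is exactly 1.
#'
#' @param profiles Numeric matrix, one interaction profile per row.
#' @return Symmetric similarity matrix with entries in (0, 1].
#' @export
gip_kernel <- function(profiles) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 1L)
  sq <- rowSums(profiles^2)
  gamma <- if (all(sq == 0)) 1 else 1 / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  k
}

#' Cosine similarity of interaction profiles
#'
#' `CS(i, j) = x_i . x_j / (||x_i|| ||x_j||)`, with 0 whenever either profile
#' has zero norm (including the diagonal entry of an all-zero profile).
#'
#' @inheritParams gip_kernel
#' @return Symmetric similarity matrix; entries in \[0, 1\] for nonnegative
#'   profiles.
#' @export
cosine_kernel <- function(profiles) {
  profiles <- as.matrix(profiles)
  nrm <- sqrt(rowSums(profiles^2))
  ip <- tcrossprod(profiles)
  denom <- outer(nrm, nrm)
  k <- ifelse(denom > 0, ip / denom, 0)
  k <- pmin(pmax((k + t(k)) / 2, -1), 1)
  diag(k) <- as.numeric(nrm > 0)
  k
}

#' Sigmoid kernel of interaction profiles
#'
#' The default maps the profile inner product through the logistic function,
#' `SK(i, j) = 1 / (1 + exp(-x_i . x_j))`; `kind = "tanh"` uses
#' `tanh(x_i . x_j)` instead. The kernel function is injectable because more
#' than one "sigmoid functional kernel" circulates in the association-
#' prediction literature.
#'
#' @inheritParams gip_kernel
#' @param kind `"logistic"` (default) or `"tanh"`.
#' @return Symmetric similarity matrix.
#' @export
sigmoid_kernel <- function(profiles, kind = c("logistic", "tanh")) {
  kind <- match.arg(kind)
  profiles <- as.matrix(profiles)
  ip <- tcrossprod(profiles)
  k <- switch(kind, logistic = stats::plogis(ip), tanh = tanh(ip))
  (k + t(k)) / 2
}

#' Average-fuse three similarity matrices
#'
#' Elementwise mean `(GK + CS + SK) / 3`; the result stays in \[0, 1\] when
#' the inputs do.
#'
#' @param gk,cs,sk Square similarity matrices of identical shape.
#' @return The fused similarity matrix.
#' @export
fuse_similarities <- function(gk, cs, sk) {
  if (!all(dim(gk) == dim(cs)) || !all(dim(gk) == dim(sk))) {
    stop("dimension error: similarity matrices differ in shape", call. = FALSE)
  }
  (gk + cs + sk) / 3
}

#' Assemble the node feature matrix from fused similarities
#'
#' Zero-pads the smaller of the two blocks on the right to width
#' `d = max(m, n)` and stacks microbes above diseases:
#' `X = [M; D+]`, shape `(m + n) x d`.
#'
#' @param M Fused microbe similarity matrix (m x m).
#' @param D Fused disease similarity matrix (n x n).
#' @return Numeric matrix of node features.
#' @export
build_node_features <- function(M, D) {
  stopifnot(nrow(M) == ncol(M), nrow(D) == ncol(D))
  d <- max(ncol(M), ncol(D))
  pad <- function(B) {
    if (ncol(B) < d) cbind(B, matrix(0, nrow(B), d - ncol(B))) else B
  }
  unname(rbind(pad(M), pad(D)))
}

#' Compute the full node feature matrix of an association matrix
#'
#' Convenience wrapper: computes GIP, cosine and sigmoid kernels for microbe
#' profiles (rows of A) and disease profiles (columns of A), average-fuses
#' each triple, and stacks the padded blocks with [build_node_features()].
#'
#' @param A An `association_matrix`.
#' @param sk_kernel Sigmoid-kernel variant, see [sigmoid_kernel()].
#' @param microbe_sim,disease_sim Optional precomputed square similarity
#'   matrices that replace the kernel fusion for that entity type (for
#'   example, ontology-derived similarities loaded from file).
#' @return Feature matrix of shape `(m + n) x max(m, n)`.
#' @export
mda_node_features <- function(A, sk_kernel = "logistic",
                              microbe_sim = NULL, disease_sim = NULL) {
  stopifnot(inherits(A, "association_matrix"))
  V <- A$values
  M <- microbe_sim %||%
    fuse_similarities(gip_kernel(V), cosine_kernel(V),
                      sigmoid_kernel(V, sk_kernel))
  D <- disease_sim %||%
    fuse_similarities(gip_kernel(t(V)), cosine_kernel(t(V)),
                      sigmoid_kernel(t(V), sk_kernel))
  stopifnot(nrow(M) == nrow(V), nrow(D) == ncol(V))
  build_node_features(M, D)
}

#' Read/write a square similarity matrix as TSV
#'
#' The file carries a header row and a leading name column; row and column
#' names must agree.
#'
#' @param path File path.
#' @return For the reader, a named square numeric matrix.
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  x <- as.matrix(df)
  stopifnot(nrow(x) == ncol(x), identical(rownames(x), colnames(x)))
  x
}

#' @rdname read_similarity_tsv
#' @param x Named square numeric matrix.
#' @export
write_similarity_tsv <- function(x, path) {
  stopifnot(nrow(x) == ncol(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
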