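# Internal numeric helpers shared by the encoders and the training loop.

# broadcast a length-ncol(M) vector across the rows of M
row_broadcast <- function(M, v) M * rep(v, each = nrow(M))
row_add <- function(M, v) M + rep(v, each = nrow(M))

relu <- function(x) pmax(x, 0)

# log(1 + exp(x)) without overflow
softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# flatten a nested list of numeric leaves into one vector, and back
flatten_params <- function(x) {
  if (is.list(x)) {
    return(unlist(lapply(x, flatten_params), use.names = FALSE))
  }
  as.numeric(x)
}

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(sk) {
    if (is.list(sk)) {
      return(lapply(sk, rebuild))
    }
    n <- length(sk)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(sk)) dim(out) <- dim(sk)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(pos == length(vec))
  out
}

# add rows of `contrib` into rows `idx` of `acc` (idx may repeat)
accumulate_rows <- function(acc, idx, contrib) {
  rs <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(rs))
  acc[rows, ] <- acc[rows, , drop = FALSE] + rs
  acc
}
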