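#' Read a microbe-disease pair list
#'
#' Parses a two-column text file of observed microbe-disease associations.
#' Fields may be tab- or comma-separated; lines starting with `#` and blank
#' lines are ignored. A first line whose fields look like column labels
#' (containing "microbe" or "disease", case-insensitively) is treated as a
#' header and skipped.
#'
#' @param path Path to the pair list.
#' @return A tibble with character columns `microbe` and `disease`, one row
#'   per line kept (duplicates are preserved here; they collapse when the
#'   association matrix is built).
#' @seealso [association_matrix()], [read_association_table()]
#' @export
read_association_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("input-format error: no data lines in '", path, "'", call. = FALSE)
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("input-format error: fewer than 2 columns at line ",
         line_no[bad[1]], " of '", path, "'", call. = FALSE)
  }
  microbe <- trimws(vapply(fields, `[[`, "", 1L))
  disease <- trimws(vapply(fields, `[[`, "", 2L))
  if (grepl("microbe|disease", paste(microbe[1], disease[1]), ignore.case = TRUE)) {
    microbe <- microbe[-1]
    disease <- disease[-1]
  }
  if (length(microbe) == 0L || all(microbe == "" | disease == "")) {
    stop("input-format error: zero usable pairs in '", path, "'", call. = FALSE)
  }
  tibble::tibble(microbe = microbe, disease = disease)
}

#' Build a binary association matrix from a pair table
#'
#' Each distinct (microbe, disease) pair becomes a 1; duplicate rows collapse.
#' Row/column order is first-appearance order of the names in the table.
#'
#' @param pairs A data frame with columns `microbe` and `disease` (names,
#'   whitespace-trimmed, matched exactly).
#' @return An `association_matrix`: a list with `values` (binary m x n matrix,
#'   microbes as rows), `microbe_names` and `disease_names`.
#' @export
association_matrix <- function(pairs) {
  stopifnot(all(c("microbe", "disease") %in% names(pairs)))
  microbe <- trimws(as.character(pairs$microbe))
  disease <- trimws(as.character(pairs$disease))
  if (length(microbe) == 0L) {
    stop("input-format error: zero distinct pairs", call. = FALSE)
  }
  mn <- unique(microbe)
  dn <- unique(disease)
  values <- matrix(0L, length(mn), length(dn), dimnames = list(mn, dn))
  values[cbind(match(microbe, mn), match(disease, dn))] <- 1L
  new_association_matrix(values, mn, dn)
}

new_association_matrix <- function(values, microbe_names, disease_names) {
  stopifnot(
    nrow(values) == length(microbe_names),
    ncol(values) == length(disease_names),
    all(values %in% c(0L, 1L)),
    !anyDuplicated(microbe_names),
    !anyDuplicated(disease_names)
  )
  structure(
    list(values = values, microbe_names = microbe_names,
         disease_names = disease_names),
    class = "association_matrix"
  )
}

#' Read a pair list and build the association matrix in one step
#'
#' @inheritParams read_association_pairs
#' @return An `association_matrix`.
#' @export
read_association_table <- function(path) {
  association_matrix(read_association_pairs(path))
}

#' Write an association matrix back out as a pair list
#'
#' One line per known association, tab-separated, with a header. Reading the
#' file back with [read_association_table()] reproduces the matrix exactly.
#'
#' @param A An `association_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_pairs <- function(A, path) {
  stopifnot(inherits(A, "association_matrix"))
  idx <- which(A$values == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  readr::write_tsv(
    tibble::tibble(
      microbe = A$microbe_names[idx[, 1]],
      disease = A$disease_names[idx[, 2]]
    ),
    path
  )
  invisible(path)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("<association_matrix> ", nrow(x$values), " microbes x ",
      ncol(x$values), " diseases, ", sum(x$values), " associations (density ",
      signif(mean(x$values), 3), ")\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.association_matrix <- function(x, ...) {
  idx <- which(x$values == 1L, arr.ind = TRUE)
  tibble::tibble(
    microbe = x$microbe_names[idx[, 1]],
    disease = x$disease_names[idx[, 2]]
  )
}

#' Build the bipartite microbe-disease graph
#'
#' Nodes are microbes (indices `1..m`) followed by diseases (`m+1..m+n`),
#' matching the row order of the node feature matrix. Each known association
#' A(i, j) = 1 contributes one undirected edge between node `i` and node
#' `m + j`; the graph is simple, with no self-loops and no within-partition
#' edges.
#'
#' @param A An `association_matrix`.
#' @param X Node feature matrix with `m + n` rows (microbes first).
#' @return An `mda_graph`: list with `m`, `n`, `n_nodes`, `edges` (two-column
#'   integer matrix of (microbe index, disease column index) pairs) and
#'   `features`.
#' @export
build_graph <- function(A, X) {
  stopifnot(inherits(A, "association_matrix"), is.matrix(X))
  m <- nrow(A$values)
  n <- ncol(A$values)
  if (nrow(X) != m + n) {
    stop("dimension error: X has ", nrow(X), " rows but graph has ",
         m + n, " nodes", call. = FALSE)
  }
  edges <- which(A$values == 1L, arr.ind = TRUE)
  dimnames(edges) <- list(NULL, c("microbe", "disease"))
  structure(
    list(m = m, n = n, n_nodes = m + n,
         edges = matrix(as.integer(edges), ncol = 2,
                        dimnames = list(NULL, c("microbe", "disease"))),
         features = X,
         microbe_names = A$microbe_names, disease_names = A$disease_names),
    class = "mda_graph"
  )
}

#' @export
print.mda_graph <- function(x, ...) {
  cat("<mda_graph> ", x$m, " microbe + ", x$n, " disease nodes, ",
      nrow(x$edges), " edges, feature width ", ncol(x$features), "\n", sep = "")
  invisible(x)
}

#' Remove held-out associations from a graph
#'
#' Used to keep test-fold positives invisible to message passing during
#' training. Features are unchanged; the input graph is not modified.
#'
#' @param g An `mda_graph`.
#' @param held_out Two-column matrix or data frame of (microbe index, disease
#'   index) pairs, in association-matrix coordinates. Every pair must be an
#'   edge of `g`.
#' @return A new `mda_graph` without the held-out edges.
#' @export
mask_edges <- function(g, held_out) {
  stopifnot(inherits(g, "mda_graph"))
  held_out <- as.matrix(held_out)[, 1:2, drop = FALSE]
  if (nrow(held_out) == 0L) return(g)
  key <- function(e) e[, 1] + (e[, 2] - 1) * g$m
  miss <- !(key(held_out) %in% key(g$edges))
  if (any(miss)) {
    stop("consistency error: held-out pair (", held_out[which(miss)[1], 1],
         ", ", held_out[which(miss)[1], 2], ") is not an edge of the graph",
         call. = FALSE)
  }
  g$edges <- g$edges[!(key(g$edges) %in% key(held_out)), , drop = FALSE]
  g
}

#' Dense adjacency matrix of an `mda_graph`
#'
#' @param g An `mda_graph`.
#' @return Symmetric 0/1 matrix of size `(m+n) x (m+n)`.
#' @export
graph_adjacency <- function(g) {
  N <- g$n_nodes
  adj <- matrix(0, N, N)
  if (nrow(g$edges) > 0L) {
    mi <- g$edges[, 1]
    di <- g$m + g$edges[, 2]
    adj[cbind(mi, di)] <- 1
    adj[cbind(di, mi)] <- 1
  }
  adj
}

# row-normalized neighbor-mean operator; isolated nodes get a zero row so the
# empty-neighborhood aggregate is the zero vector
mean_aggregator <- function(adj) {
  deg <- rowSums(adj)
  adj / pmax(deg, 1)
}

#' Symmetrically normalized GCN propagation matrix
#'
#' Adds self-loops and normalizes: `D^{-1/2} (A + I) D^{-1/2}` where `D` is
#' the degree matrix of `A + I`. This is the single-layer graph-convolution
#' operator used by the graph variational encoder.
#'
#' @param adj Symmetric 0/1 adjacency matrix (no self-loops).
#' @return The propagation matrix, same shape as `adj`.
#' @export
gcn_propagation <- function(adj) {
  at <- adj + diag(nrow(adj))
  dinv <- 1 / sqrt(rowSums(at))
  at * outer(dinv, dinv)
}
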