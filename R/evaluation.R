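#' Partition positive pairs into cross-validation folds
#'
#' Shuffles the pairs and deals them round-robin into `k` folds, so fold
#' sizes differ by at most one and the folds partition the input.
#'
#' @param pairs Data frame or matrix of pairs (one row each).
#' @param k Number of folds.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The input as a tibble with an integer `fold` column.
#' @export
make_folds <- function(pairs, k = 5L, seed = NULL) {
  pairs <- tibble::as_tibble(as.data.frame(pairs))
  if (k > nrow(pairs)) {
    stop("configuration error: k = ", k, " exceeds the ", nrow(pairs),
         " available pairs", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(nrow(pairs))
  fold <- integer(nrow(pairs))
  fold[ord] <- rep(seq_len(k), length.out = nrow(pairs))
  dplyr::mutate(pairs, fold = fold)
}

#' Sample negative (unknown) pairs uniformly
#'
#' Draws `count` distinct cells with A = 0, uniformly without replacement,
#' excluding any cells listed in `exclude`.
#'
#' @param A An `association_matrix`.
#' @param count Number of negatives to draw.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param exclude Optional data frame/matrix of (microbe, disease) index
#'   pairs to exclude from the candidate pool.
#' @return Tibble with integer columns `microbe` and `disease`.
#' @export
sample_negatives <- function(A, count, seed = NULL, exclude = NULL) {
  stopifnot(inherits(A, "association_matrix"))
  m <- nrow(A$values)
  zero_cells <- which(A$values == 0L)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ex <- as.matrix(as.data.frame(exclude)[, 1:2])
    zero_cells <- setdiff(zero_cells, ex[, 1] + (ex[, 2] - 1) * m)
  }
  if (count > length(zero_cells)) {
    stop("sampling error: requested ", count, " negatives but only ",
         length(zero_cells), " unknown cells are available", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cells <- sample(zero_cells, count)
  tibble::tibble(
    microbe = as.integer((cells - 1L) %% m + 1L),
    disease = as.integer((cells - 1L) %/% m + 1L)
  )
}

# rank-based AUC: P(random positive outscores random negative), ties 1/2;
# identical to the trapezoidal ROC area
auc_rank <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# average precision: mean of precision-at-rank over the positives, scores
# sorted descending (ties broken by position for determinism)
average_precision <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) return(NA_real_)
  ord <- order(-scores)
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  sum(prec_at * y) / npos
}

#' Classification metrics for scored pairs
#'
#' AUC is the probability that a random positive outscores a random negative
#' (ties count one half), i.e. the trapezoidal ROC area; AUPR is average
#' precision. Accuracy, precision and F1 are computed at the given score
#' threshold; precision and F1 are 0 by convention when no pair is predicted
#' positive. With single-class labels AUC and AUPR are reported as `NA`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold for ACC/PRE/F1.
#' @return One-row tibble `auc`, `aupr`, `acc`, `pre`, `f1`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  tibble::tibble(
    auc = auc_rank(scores, labels),
    aupr = average_precision(scores, labels),
    acc = mean(pred == labels),
    pre = pre, f1 = f1, threshold = threshold
  )
}

#' Five-fold cross-validation of the association predictor
#'
#' Implements the evaluation protocol: known associations are partitioned
#' into `k` folds; an equal number of unknown pairs is sampled once and
#' partitioned alongside them, so train and test negatives never overlap.
#' For each fold the test positives are removed from message passing (the
#' training graph carries no test edge) before the model is trained on the
#' train pairs and scored on the held-out pairs. Similarity-kernel node
#' features are computed once from the full known matrix, the convention of
#' the association-prediction literature; set `mask_features = TRUE` to also
#' recompute them per fold from the masked matrix (strictly leak-free but a
#' harder task).
#'
#' @param A An `association_matrix`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Integer seed driving fold assignment, negative sampling and
#'   per-fold training seeds.
#' @param mask_test_edges If `FALSE`, the training graph keeps the test
#'   edges (the naive, leakage-prone protocol) for comparison.
#' @param mask_features If `TRUE`, node features are recomputed per fold
#'   from the masked training matrix.
#' @param baseline If `TRUE` (default) also scores each fold with the
#'   degree-product baseline `deg(m) * deg(d)` from the training matrix.
#' @return A `dvamda_cv`: `fold_metrics` (per-fold tibble, incl.
#'   `baseline_auc` if requested), `average` (one-row tibble of fold means),
#'   and `predictions` (per-pair fold, label and score). See
#'   [tidy.dvamda_cv()], [glance.dvamda_cv()], [autoplot.dvamda_cv()].
#' @export
cross_validate <- function(A, model_cfg = model_config(),
                           train_cfg = train_config(), k = 5L, seed = 1L,
                           mask_test_edges = TRUE, mask_features = FALSE,
                           baseline = TRUE) {
  stopifnot(inherits(A, "association_matrix"))
  pos_idx <- which(A$values == 1L, arr.ind = TRUE)
  positives <- tibble::tibble(microbe = as.integer(pos_idx[, 1]),
                              disease = as.integer(pos_idx[, 2]))
  set.seed(seed)
  pos_folds <- make_folds(positives, k)
  negatives <- sample_negatives(A, nrow(positives), exclude = positives)
  neg_folds <- make_folds(negatives, k)
  fold_seeds <- sample.int(2^30, k)
  X_full <- if (!mask_features) {
    mda_node_features(A, sk_kernel = model_cfg$sk_kernel)
  }

  fold_out <- lapply(seq_len(k), function(f) {
    test_pos <- dplyr::filter(pos_folds, .data$fold == f)
    train_pos <- dplyr::filter(pos_folds, .data$fold != f)
    test_neg <- dplyr::filter(neg_folds, .data$fold == f)
    train_neg <- dplyr::filter(neg_folds, .data$fold != f)

    A_train <- A
    if (mask_test_edges) {
      A_train$values[cbind(test_pos$microbe, test_pos$disease)] <- 0L
    }
    X <- X_full %||% mda_node_features(A_train, sk_kernel = model_cfg$sk_kernel)
    g <- build_graph(A_train, X)
    # leak check: no test positive may survive as a training edge
    if (mask_test_edges && nrow(g$edges) > 0L) {
      ek <- g$edges[, 1] + (g$edges[, 2] - 1) * g$m
      tk <- test_pos$microbe + (test_pos$disease - 1) * g$m
      stopifnot(length(intersect(ek, tk)) == 0L)
    }

    train_pairs <- dplyr::bind_rows(
      dplyr::mutate(train_pos[, 1:2], label = 1),
      dplyr::mutate(train_neg[, 1:2], label = 0)
    )
    tc <- train_cfg
    tc$seed <- fold_seeds[f]
    fit <- train_dvamda(g, train_pairs[, 1:2], train_pairs$label,
                        model_cfg = model_cfg, train_cfg = tc)

    test_pairs <- dplyr::bind_rows(
      dplyr::mutate(test_pos[, 1:2], label = 1),
      dplyr::mutate(test_neg[, 1:2], label = 0)
    )
    sc <- predict(fit, test_pairs[, 1:2])
    metrics <- compute_metrics(sc$score, test_pairs$label)
    if (baseline) {
      deg_m <- rowSums(A_train$values)
      deg_d <- colSums(A_train$values)
      base <- deg_m[test_pairs$microbe] * deg_d[test_pairs$disease]
      metrics$baseline_auc <- auc_rank(base, test_pairs$label)
    }
    list(
      metrics = dplyr::mutate(metrics, fold = f, .before = 1),
      predictions = tibble::tibble(
        fold = f, microbe = test_pairs$microbe, disease = test_pairs$disease,
        label = test_pairs$label, score = sc$score
      )
    )
  })

  fold_metrics <- dplyr::bind_rows(lapply(fold_out, `[[`, "metrics"))
  average <- dplyr::summarise(
    fold_metrics,
    dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("^fold$"), mean)
  )
  structure(
    list(fold_metrics = fold_metrics, average = average,
         predictions = dplyr::bind_rows(lapply(fold_out, `[[`, "predictions")),
         k = k, seed = seed, model_cfg = model_cfg, train_cfg = train_cfg,
         mask_test_edges = mask_test_edges, mask_features = mask_features),
    class = "dvamda_cv"
  )
}

#' @export
print.dvamda_cv <- function(x, ...) {
  cat("<dvamda_cv> ", x$k, "-fold cross-validation (seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  average: AUC %.4f  AUPR %.4f  ACC %.4f  PRE %.4f  F1 %.4f\n",
              x$average$auc, x$average$aupr, x$average$acc, x$average$pre,
              x$average$f1))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `dvamda_cv`.
#' @param ... Unused.
#' @return Tibble of per-fold metrics.
#' @export
tidy.dvamda_cv <- function(x, ...) x$fold_metrics

#' Fold-averaged cross-validation metrics
#' @param x A `dvamda_cv`.
#' @param ... Unused.
#' @return One-row tibble of fold means.
#' @export
glance.dvamda_cv <- function(x, ...) x$average

#' Recompute the fold-averaged AUC after shuffling test labels
#'
#' Permutes the labels within each fold's test set and recomputes AUC — the
#' permutation-null control; an intact pipeline gives values near 0.5.
#'
#' @param cv A `dvamda_cv`.
#' @param seed Integer seed for the permutation.
#' @return Average AUC over folds under shuffled labels.
#' @export
shuffled_label_auc <- function(cv, seed = 1L) {
  set.seed(seed)
  per_fold <- dplyr::group_by(cv$predictions, .data$fold)
  per_fold <- dplyr::summarise(
    per_fold, auc = auc_rank(.data$score, sample(.data$label))
  )
  mean(per_fold$auc)
}

#' Leave-one-disease-out case-study ranking
#'
#' Removes every known association of one disease from the training
#' supervision and from the graph (its node is isolated during message
#' passing), trains on the remaining associations with balanced negatives,
#' then scores all microbes against the held-out disease and returns the top
#' of the ranking. Ties are broken by microbe index. By default the
#' similarity-kernel features are computed from the full catalogue (the
#' discovery-protocol convention); `mask_features = TRUE` also removes the
#' disease's links from the feature computation, which leaves the held-out
#' disease with an uninformative profile and is useful only as a negative
#' control.
#'
#' @param A An `association_matrix`.
#' @param disease Disease name (exact match) or column index.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param top_k Number of microbes to return.
#' @param seed Integer seed for negative sampling (training seed comes from
#'   `train_cfg`).
#' @param mask_features If `TRUE`, features are computed from the masked
#'   matrix as well.
#' @return Tibble `rank`, `microbe`, `microbe_index`, `score`, sorted by
#'   descending score.
#' @export
case_study_rank <- function(A, disease, model_cfg = model_config(),
                            train_cfg = train_config(), top_k = 10L,
                            seed = 1L, mask_features = FALSE) {
  stopifnot(inherits(A, "association_matrix"))
  d_idx <- if (is.character(disease)) {
    match(trimws(disease), A$disease_names)
  } else {
    as.integer(disease)
  }
  if (is.na(d_idx) || d_idx < 1L || d_idx > ncol(A$values)) {
    stop("lookup error: unknown disease '", disease, "'", call. = FALSE)
  }
  A_train <- A
  A_train$values[, d_idx] <- 0L
  X <- mda_node_features(if (mask_features) A_train else A,
                         sk_kernel = model_cfg$sk_kernel)
  g <- build_graph(A_train, X)

  pos_idx <- which(A_train$values == 1L, arr.ind = TRUE)
  positives <- tibble::tibble(microbe = as.integer(pos_idx[, 1]),
                              disease = as.integer(pos_idx[, 2]))
  # the held-out disease's cells get no supervision at all, so exclude its
  # whole column from the negative pool as well
  held_col <- tibble::tibble(microbe = seq_len(nrow(A$values)),
                             disease = d_idx)
  set.seed(seed)
  negatives <- sample_negatives(A_train, nrow(positives),
                                exclude = dplyr::bind_rows(positives, held_col))
  train_pairs <- dplyr::bind_rows(
    dplyr::mutate(positives, label = 1),
    dplyr::mutate(negatives, label = 0)
  )
  fit <- train_dvamda(g, train_pairs[, 1:2], train_pairs$label,
                      model_cfg = model_cfg, train_cfg = train_cfg)
  cand <- tibble::tibble(microbe = seq_len(nrow(A$values)), disease = d_idx)
  sc <- predict(fit, cand)
  ord <- order(-sc$score, sc$microbe)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  tibble::tibble(
    rank = seq_along(keep),
    microbe = A$microbe_names[keep],
    microbe_index = keep,
    score = sc$score[keep]
  )
}
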