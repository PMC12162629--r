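test_that("fold assignment partitions pairs into near-equal folds", {
  pos <- tibble::tibble(microbe = rep(1:90, each = 5),
                        disease = rep(1:5, times = 90))
  folds <- make_folds(pos, k = 5, seed = 7)
  expect_equal(tabulate(folds$fold, 5), rep(90L, 5))  # 450 positives
  expect_equal(nrow(folds), 450L)
  expect_identical(make_folds(pos, k = 5, seed = 7), folds)  # seeded

  # partition / disjointness / balance on many random sizes
  set.seed(1)
  for (rep in 1:200) {
    np <- sample(5:60, 1)
    k <- sample(2:5, 1)
    p <- tibble::tibble(microbe = seq_len(np), disease = 1L)
    f <- make_folds(p, k = k)
    sizes <- tabulate(f$fold, k)
    expect_equal(sum(sizes), np)
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_error(make_folds(pos[1:3, ], k = 5), "configuration error")
})

test_that("negative sampling draws only unknown cells, without duplicates", {
  A <- toy_assoc(rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)))
  neg <- sample_negatives(A, 5, seed = 3)
  expect_equal(nrow(neg), 5L)
  expect_true(all(A$values[as.matrix(neg)] == 0L))
  expect_equal(anyDuplicated(neg), 0L)

  pos <- tibble::as_tibble(which(A$values == 1L, arr.ind = TRUE))
  names(pos) <- c("microbe", "disease")
  expect_error(sample_negatives(A, 9, exclude = pos), "sampling error")

  # uniformity over the zero cells (chi-squared on 1000 seeded draws)
  draws <- do.call(rbind, lapply(1:1000, function(s) {
    sample_negatives(A, 1, seed = s)
  }))
  counts <- table(paste(draws$microbe, draws$disease))
  expect_equal(length(counts), sum(A$values == 0))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("metrics match brute-force oracles", {
  # perfectly separated scores
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$acc, 1)

  # worked example: 3 of 4 positive-negative pairs concordant
  m2 <- compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(m2$auc, 0.75)

  # exhaustive concordant-pair oracle on all label patterns up to length 8
  auc_oracle <- function(s, y) {
    pos <- which(y == 1); neg <- which(y == 0)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(5)
  for (n in 2:8) {
    for (labs in 0:(2^n - 1)) {
      y <- as.integer(intToBits(labs))[1:n]
      if (sum(y) == 0 || sum(y) == n) next
      s <- sample(round(runif(n), 1))  # rounded scores induce ties
      expect_equal(compute_metrics(s, y)$auc, auc_oracle(s, y),
                   tolerance = 1e-12)
    }
  }

  # average precision against a per-rank loop
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    ord <- order(-s)
    yo <- y[ord]
    ap <- mean(sapply(which(yo == 1), function(r) sum(yo[1:r]) / r))
    expect_equal(compute_metrics(s, y)$aupr, ap, tolerance = 1e-12)
  }

  # threshold metrics
  m3 <- compute_metrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0), threshold = 0.5)
  expect_equal(m3$acc, 0.5)
  expect_equal(m3$pre, 0.5)
  expect_equal(m3$f1, 0.5)

  # single-class labels: ranking metrics undefined, not zero
  m4 <- compute_metrics(c(0.2, 0.6), c(1, 1))
  expect_true(is.na(m4$auc) && is.na(m4$aupr))
})

test_that("label-shuffled scores give chance-level AUC", {
  set.seed(11)
  inside <- 0
  for (rep in 1:50) {
    s <- runif(500)
    y <- sample(rep(c(0, 1), each = 250))
    a <- dvamda:::auc_rank(s, y)
    inside <- inside + (a >= 0.40 && a <= 0.60)
  }
  expect_gte(inside / 50, 0.98)
})

test_that("cross-validation is balanced, leak-free and averages its folds", {
  A <- random_assoc(25, 8, density = 0.25, seed = 41)
  cv <- cross_validate(A, small_model_cfg(),
                       train_config(epochs = 15L), k = 4, seed = 2)
  expect_equal(nrow(cv$fold_metrics), 4L)
  expect_equal(cv$average$auc, mean(cv$fold_metrics$auc), tolerance = 1e-12)
  expect_equal(cv$average$f1, mean(cv$fold_metrics$f1), tolerance = 1e-12)

  preds <- cv$predictions
  # each fold's test set is balanced and scores lie in (0, 1)
  bal <- dplyr::count(preds, .data$fold, .data$label)
  expect_true(all(tapply(bal$n, bal$fold, function(x) x[1] == x[2])))
  expect_true(all(preds$score > 0 & preds$score < 1))
  # negatives are genuinely unknown pairs; positives genuinely known
  expect_true(all(A$values[as.matrix(preds[preds$label == 0,
                                           c("microbe", "disease")])] == 0L))
  expect_true(all(A$values[as.matrix(preds[preds$label == 1,
                                           c("microbe", "disease")])] == 1L))
  # the positive folds partition all known associations
  expect_equal(sum(preds$label), sum(A$values))
  # no pair is tested twice
  expect_equal(anyDuplicated(preds[, c("microbe", "disease", "label")]), 0L)

  expect_identical(
    glance(cross_validate(A, small_model_cfg(),
                          train_config(epochs = 15L), k = 4, seed = 2)),
    glance(cv)
  )  # protocol is seed-deterministic
})

test_that("case-study ranking isolates the held-out disease and ranks all microbes", {
  set.seed(1)
  truth <- generate_mda(synthetic_config(m = 40, n = 8, r = 2, p_in = 0.5,
                                         p_out = 0.02, seed = 5))
  A <- truth$association
  d <- which.max(colSums(A$values))
  rk <- case_study_rank(A, A$disease_names[d], small_model_cfg(),
                        train_config(epochs = 60L), top_k = 10, seed = 3)
  expect_equal(nrow(rk), 10L)
  expect_true(all(diff(rk$score) <= 0))
  expect_equal(rk$rank, 1:10)
  expect_true(all(rk$microbe %in% A$microbe_names))

  # unknown disease errors out
  expect_error(case_study_rank(A, "no-such-disease"), "lookup error")

  # requesting more than m microbes truncates to m
  rk_all <- case_study_rank(A, d, small_model_cfg(),
                            train_config(epochs = 5L), top_k = 100, seed = 3)
  expect_equal(nrow(rk_all), 40L)
})

test_that("case-study ranking recovers planted block members", {
  truth <- generate_mda(synthetic_config(m = 60, n = 10, r = 2, p_in = 0.45,
                                         p_out = 0.02, seed = 8))
  A <- truth$association
  d <- 1
  block <- which(truth$microbe_group == truth$disease_group[d])
  rk <- case_study_rank(A, d, small_model_cfg(),
                        train_config(epochs = 120L), top_k = length(block),
                        seed = 4)
  recovered <- mean(block %in% rk$microbe_index)
  expect_gte(recovered, 0.6)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    s <- round(runif(n), 2)  # ties included
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    ours <- compute_metrics(s, y)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("result objects draw their standard plots", {
  A <- random_assoc(10, 5, density = 0.3, seed = 61)
  prob <- toy_problem(A, seed = 61)
  fit <- train_dvamda(prob$graph, prob$pairs, prob$labels,
                      small_model_cfg(), train_config(epochs = 6L, seed = 1))
  p1 <- autoplot(fit)
  expect_s3_class(p1, "ggplot")
  cv <- cross_validate(A, small_model_cfg(), train_config(epochs = 6L),
                       k = 3, seed = 1)
  p2 <- autoplot(cv)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_association(A)
  expect_s3_class(p3, "ggplot")
  # curves reach the (1, 1) corner for every fold
  built <- ggplot2::ggplot_build(p2)
  expect_true(all(is.finite(built$data[[1]]$x)))
})
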