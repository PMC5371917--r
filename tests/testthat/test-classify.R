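# Bagged trees, cross-validation bookkeeping, ROC/AUC, comparison harness.

make_clusters <- function(n_per_class = 12, sep = 8, seed = 1, p = 4) {
  set.seed(seed)
  classes <- behavior_classes()
  X <- do.call(rbind, lapply(seq_along(classes), function(k)
    matrix(rnorm(n_per_class * p, mean = sep * k), n_per_class, p)))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(classes, each = n_per_class))
}

test_that("bagged trees fit separable clusters perfectly and deterministically", {
  d <- make_clusters()
  m <- train_bagged_trees(d$X, d$y, n_trees = 5, seed = 3)
  expect_length(m$trees, 5)
  pr <- predict(m, d$X)
  expect_equal(as.character(pr$labels), d$y)
  expect_true(all(abs(rowSums(pr$vote_fractions) - 1) < 1e-12))

  set.seed(99)
  probe <- matrix(rnorm(40, mean = 12), 10, 4)
  m2 <- train_bagged_trees(d$X, d$y, n_trees = 5, seed = 3)
  expect_identical(predict(m, probe)$vote_fractions,
                   predict(m2, probe)$vote_fractions)
})

test_that("with bootstrap disabled a 1-tree ensemble equals a single tree", {
  d <- make_clusters(n_per_class = 10, sep = 3, seed = 5)
  m <- train_bagged_trees(d$X, d$y, n_trees = 1, seed = 1, bootstrap = FALSE)
  single <- wearsense:::fit_cart(wearsense:::as_feature_df(d$X),
                                 factor(d$y, levels = behavior_classes()))
  probe <- d$X + matrix(rnorm(length(d$X), sd = 0.5), nrow(d$X))
  df <- as.data.frame(probe)
  expect_equal(as.character(predict(m, probe)$labels),
               as.character(predict(single, df, type = "class")))
})

test_that("vote fractions match hand-counted per-tree predictions", {
  d <- make_clusters(n_per_class = 8, sep = 4, seed = 7)
  m <- train_bagged_trees(d$X, d$y, n_trees = 7, seed = 2)
  set.seed(1)
  probe <- d$X[c(1, 10, 20), ] + rnorm(12, sd = 2)
  df <- as.data.frame(probe)
  counts <- matrix(0, 3, 3, dimnames = list(NULL, m$class_order))
  for (tree in m$trees) {
    p <- as.character(predict(tree, df, type = "class"))
    for (i in 1:3) counts[i, p[i]] <- counts[i, p[i]] + 1
  }
  expect_equal(predict(m, probe)$vote_fractions, counts / 7,
               ignore_attr = TRUE)
})

test_that("prediction ties break toward the first class in class_order", {
  # two unsplit majority-vote trees that always disagree
  lvl <- c("flapping", "painting")
  df1 <- data.frame(f1 = c(0, 1, 2),
                    .y = factor(c("flapping", "flapping", "painting"), lvl))
  df2 <- data.frame(f1 = c(0, 1, 2),
                    .y = factor(c("painting", "painting", "flapping"), lvl))
  t1 <- rpart::rpart(.y ~ f1, df1, method = "class",
                     control = rpart::rpart.control(minsplit = 99))
  t2 <- rpart::rpart(.y ~ f1, df2, method = "class",
                     control = rpart::rpart.control(minsplit = 99))
  m <- structure(list(n_trees = 2L, trees = list(t1, t2), bootstrap_seed = 0,
                      class_order = lvl, n_features = 1L,
                      feature_names = "f1",
                      registry_version = feature_registry_version()),
                 class = "bagged_trees")
  pr <- predict(m, matrix(0.5, 1, 1))
  expect_equal(unname(pr$vote_fractions[1, ]), c(0.5, 0.5))
  expect_equal(as.character(pr$labels), "flapping")
})

test_that("training rejects degenerate input", {
  d <- make_clusters()
  expect_error(train_bagged_trees(d$X[1:12, ], d$y[1:12]),
               class = "ws_input_error")              # single class
  m <- train_bagged_trees(d$X, d$y, n_trees = 3, seed = 1)
  expect_error(predict(m, d$X[, 1:2]), class = "ws_input_error")
})

test_that("stratified folds are approximately equal and class-balanced", {
  y <- rep(behavior_classes(), each = 55)
  fold <- wearsense:::with_seed(4, wearsense:::stratified_folds(y, 10))
  sizes <- as.vector(table(fold))
  expect_true(all(sizes %in% c(16L, 17L)))
  expect_equal(sum(sizes), 165)
  # leave-one-out: 12 folds of size 1
  y2 <- rep(c("flapping", "painting"), 6)
  f2 <- wearsense:::with_seed(1, wearsense:::stratified_folds(y2, 12))
  expect_equal(sort(as.vector(table(f2))), rep(1L, 12))
  expect_error(wearsense:::stratified_folds(y2, 7), class = "ws_config_error")
  expect_error(wearsense:::stratified_folds(y2, 7), "K <= 6")
})

test_that("CV on separable data is perfect with exact bookkeeping", {
  d <- make_clusters(n_per_class = 12, sep = 10, seed = 11)
  rep_n <- 2
  cv <- repeated_kfold_cv(d$X, d$y, K = 3, n_repeats = rep_n, n_trees = 5,
                          seed = 8)
  expect_equal(cv$overall_accuracy, 1.0)
  expect_true(all(cv$confusion[upper.tri(cv$confusion)] == 0))
  expect_true(all(cv$confusion[lower.tri(cv$confusion)] == 0))
  # conservation: entries sum to n * repeats; rows to class counts * repeats
  expect_equal(sum(cv$confusion), 36 * rep_n)
  expect_equal(unname(rowSums(cv$confusion)), rep(12 * rep_n, 3))
  expect_equal(cv$overall_accuracy,
               sum(diag(cv$confusion)) / sum(cv$confusion), tolerance = 1e-15)
  expect_equal(cv$overall_accuracy, mean(cv$per_repeat_accuracy),
               tolerance = 1e-15)
  expect_length(cv$per_fold_indices, rep_n)
  expect_error(repeated_kfold_cv(d$X, d$y, K = 20), class = "ws_config_error")
})

test_that("one-vs-rest AUC behaves at the extremes and matches the rank oracle", {
  y <- c("flapping", "flapping", "painting", "painting", "sibbing", "sibbing")
  perfect <- diag(3)[match(y, behavior_classes()), ]
  colnames(perfect) <- behavior_classes()
  expect_equal(roc_auc_ovr(y, perfect)$macro_auc, 1.0)

  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, behavior_classes()))
  expect_equal(unname(roc_auc_ovr(y, flat)$per_class_auc), rep(0.5, 3))

  set.seed(6)
  y10 <- sample(behavior_classes(), 10, replace = TRUE, prob = c(.4, .4, .2))
  sc <- matrix(runif(30), 10, 3, dimnames = list(NULL, behavior_classes()))
  res <- roc_auc_ovr(y10, sc)
  for (cl in behavior_classes()) {
    if (!cl %in% y10) next
    expect_equal(res$per_class_auc[[cl]],
                 oracle_auc_pairwise(y10, sc[, cl], cl))
  }

  w <- capture_warnings(
    res1 <- roc_auc_ovr(rep("flapping", 4),
                        matrix(runif(8), 4, 2,
                               dimnames = list(NULL, c("flapping", "painting")))))
  expect_true(any(grepl("absent", w)))
  expect_true(is.na(res1$per_class_auc[["painting"]]))
})

test_that("the comparison harness evaluates six models on shared folds", {
  d <- make_clusters(n_per_class = 15, sep = 6, seed = 13)
  tab <- compare_classifiers(d$X, d$y, K = 3, seed = 4, n_repeats = 2)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$model, c("complex_tree", "simple_tree", "linear_svm",
                               "gaussian_svm", "boosted_trees", "bagged_trees"))
  expect_equal(dim(attr(tab, "fold")), c(45L, 2L))
  expect_true(all(tab$accuracy[tab$model != "linear_svm"] > 0.5,
                  na.rm = TRUE))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1, na.rm = TRUE))
})

test_that("accuracy does not improve as sensor noise grows", {
  run_at <- function(noise, seed) {
    recs <- generate_dataset(n_per_class = 16, duration = 2, seed = seed,
                             noise_sd = noise)
    wins <- unlist(lapply(recs, segment_windows), recursive = FALSE)
    fm <- feature_matrix(wins)
    repeated_kfold_cv(fm$X, fm$labels, K = 4, n_repeats = 1, n_trees = 10,
                      seed = seed)$overall_accuracy
  }
  accs <- vapply(c(0.3, 1.2, 3.0), function(ns)
    mean(vapply(1:3, function(s) run_at(ns, s), 0)), 0)
  expect_gte(accs[1], accs[3])
})

test_that("model persistence embeds and enforces the registry version", {
  d <- make_clusters(n_per_class = 8, seed = 15)
  m <- train_bagged_trees(d$X, d$y, n_trees = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, d$X)$labels, predict(m, d$X)$labels)
  m$registry_version <- "0.0"
  save_model(m, path)
  expect_error(load_model(path), class = "ws_config_error")
})
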