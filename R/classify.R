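# Bagged decision-tree ensemble, repeated stratified K-fold cross-validation,
# one-vs-rest ROC/AUC, and the six-classifier comparison harness.

# Fixed class ordering: the three behavior classes in canonical order when
# the labels are drawn from them, alphabetical otherwise. The ordering breaks
# prediction ties (first class wins).
class_levels <- function(y) {
  u <- unique(as.character(y))
  canon <- behavior_classes()
  if (all(u %in% canon)) canon[canon %in% u] else sort(u)
}

as_feature_df <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  as.data.frame(X)
}

# One CART classification tree (Gini splits). Grown unpruned (cp = 0) and,
# when max_splits is given, pruned back to the cost-complexity step with at
# most that many splits -- mirroring "complex" / "simple" preset trees.
fit_cart <- function(df, y, max_splits = NULL, weights = NULL,
                     max_depth = 30L) {
  df$.y <- y
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2L, minbucket = 1L,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L, maxdepth = max_depth)
  f <- stats::as.formula(".y ~ .")
  environment(f) <- environment()
  fit <- rpart::rpart(f, data = df, method = "class", control = ctrl,
                      weights = weights,
                      parms = list(split = "gini"))
  if (!is.null(max_splits) && !is.null(fit$cptable)) {
    tab <- fit$cptable
    ok <- tab[tab[, "nsplit"] <= max_splits, , drop = FALSE]
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"])
  }
  fit
}

#' Train a bagged ensemble of decision trees
#'
#' Bootstrap aggregating: each of `n_trees` unpruned CART trees (Gini split
#' criterion) is fit on a with-replacement resample of the training set of
#' the same size ("bag"); prediction is by majority vote. Deterministic given
#' `seed`.
#'
#' @param X Feature matrix (rows = samples), no missing values.
#' @param y Class labels; at least two classes must be present.
#' @param n_trees Ensemble size (default 40).
#' @param seed RNG seed for the bootstrap resamples.
#' @param bootstrap Set `FALSE` to train every tree on the full training set
#'   (test hook; with `n_trees = 1` the ensemble then equals a single tree).
#' @return An object of class `bagged_trees`.
#' @export
train_bagged_trees <- function(X, y, n_trees = 40, seed = 1, bootstrap = TRUE) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = class_levels(y))
  if (nlevels(y) < 2) abort_input("training requires at least two classes")
  if (any(!is.finite(X))) abort_input("feature matrix contains missing values")
  if (nrow(X) != length(y)) abort_input("X and y disagree on sample count")
  df <- as_feature_df(X)
  n <- nrow(df)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    fit_cart(df[idx, , drop = FALSE], y[idx])
  }))
  structure(
    list(n_trees = as.integer(n_trees), trees = trees, bootstrap_seed = seed,
         class_order = levels(y), n_features = ncol(X),
         feature_names = colnames(df),
         registry_version = feature_registry_version()),
    class = "bagged_trees"
  )
}

#' Predict from a bagged ensemble
#'
#' @param object A `bagged_trees` model.
#' @param X Feature matrix with the training column count.
#' @param ... Unused.
#' @return List with `labels` (factor in the model's class order; the vote
#'   argmax, ties going to the first class in `class_order`) and
#'   `vote_fractions` (rows summing to 1).
#' @export
predict.bagged_trees <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features)
    abort_input(sprintf("feature count mismatch: model expects %d, got %d",
                        object$n_features, ncol(X)))
  df <- as.data.frame(X)
  names(df) <- setdiff(object$feature_names, ".y")
  k <- length(object$class_order)
  votes <- matrix(0, nrow(df), k, dimnames = list(NULL, object$class_order))
  for (tree in object$trees) {
    p <- as.character(predict(tree, df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(p, object$class_order))] <-
      votes[cbind(seq_len(nrow(df)), match(p, object$class_order))] + 1
  }
  frac <- votes / object$n_trees
  labels <- factor(object$class_order[apply(frac, 1, which.max)],
                   levels = object$class_order)
  list(labels = labels, vote_fractions = frac)
}

# Stratified fold assignment: within each class the samples are spread over
# folds as evenly as possible, and the leftover (+1) samples go to the
# currently least-loaded folds, so global fold sizes differ by at most one.
# K = n is leave-one-out (stratification is vacuous there). Consumes the
# active RNG stream.
stratified_folds <- function(y, K) {
  y <- factor(as.character(y), levels = class_levels(y))
  if (K == length(y)) return(sample(seq_len(K)))   # leave-one-out
  fold <- integer(length(y))
  load <- numeric(K)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    nc <- length(idx)
    if (nc < K)
      abort_config(sprintf(
        "class '%s' has only %d samples; use K <= %d", cl, nc, nc))
    base <- nc %/% K
    extra <- nc %% K
    counts <- rep(base, K)
    if (extra > 0) {
      ord <- order(load + stats::runif(K, 0, 1e-9))  # random tie-break
      counts[ord[seq_len(extra)]] <- base + 1L
    }
    fold[idx] <- sample(rep.int(seq_len(K), counts))
    load <- load + counts
  }
  fold
}

#' Repeated stratified K-fold cross-validation of the bagged ensemble
#'
#' Each repeat draws fresh stratified folds of approximately equal size; every
#' sample is tested exactly once per repeat. The confusion matrix is pooled
#' over folds and repeats (entries therefore sum to `n_samples * n_repeats`),
#' and the reported overall accuracy -- the mean of the per-repeat accuracies
#' -- equals `trace(confusion) / sum(confusion)` identically. AUC is the
#' macro one-vs-rest AUC over the pooled vote fractions.
#'
#' @param X Feature matrix.
#' @param y Class labels; every class needs at least `K` members.
#' @param K Number of folds (default 10).
#' @param n_repeats Number of CV repeats averaged over (default 10).
#' @param n_trees Ensemble size per fold model (default 40).
#' @param seed RNG seed controlling folds and bootstraps.
#' @return An object of class `cv_report`.
#' @export
repeated_kfold_cv <- function(X, y, K = 10, n_repeats = 10, n_trees = 40,
                              seed = 1) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = class_levels(y))
  n <- length(y)
  k <- nlevels(y)
  conf <- matrix(0, k, k, dimnames = list(true = levels(y),
                                          predicted = levels(y)))
  per_fold_indices <- vector("list", n_repeats)
  acc_rep <- numeric(n_repeats)
  all_scores <- vector("list", n_repeats)
  all_truth <- vector("list", n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(y, K)
      per_fold_indices[[r]] <- fold
      preds <- factor(rep(NA_character_, n), levels = levels(y))
      scores <- matrix(NA_real_, n, k, dimnames = list(NULL, levels(y)))
      for (f in seq_len(K)) {
        te <- fold == f
        sub_seed <- sample.int(2147483646L, 1)
        model <- train_bagged_trees(X[!te, , drop = FALSE], y[!te],
                                    n_trees = n_trees, seed = sub_seed)
        pr <- predict(model, X[te, , drop = FALSE])
        preds[te] <- pr$labels
        scores[te, ] <- pr$vote_fractions
      }
      conf <- conf + unclass(table(y, preds))
      acc_rep[r] <- mean(preds == y)
      all_scores[[r]] <- scores
      all_truth[[r]] <- y
    }
  })
  roc <- roc_auc_ovr(unlist(lapply(all_truth, as.character)),
                     do.call(rbind, all_scores))
  structure(
    list(confusion = conf,
         per_class_accuracy = diag(conf) / rowSums(conf),
         overall_accuracy = sum(diag(conf)) / sum(conf),
         per_repeat_accuracy = acc_rep,
         auc = roc$macro_auc, roc = roc,
         per_fold_indices = per_fold_indices,
         n_repeats = n_repeats, K = K, n_samples = n,
         class_order = levels(y)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV x %d repeats on %d samples\n",
              x$K, x$n_repeats, x$n_samples))
  cat(sprintf("  overall accuracy: %.1f%%  macro AUC: %.3f\n",
              100 * x$overall_accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}

#' One-vs-rest ROC curves and macro AUC
#'
#' Per class, that class is treated as positive and all others as negative;
#' the AUC is the Mann-Whitney rank statistic of the class's score column
#' (midranks for ties). Classes absent from `y_true` get `NA` with a warning
#' and are excluded from the macro average.
#'
#' @param y_true True labels.
#' @param scores Matrix of per-class scores (columns named by class, rows
#'   summing to ~1, e.g. vote fractions).
#' @return List with `macro_auc`, `per_class_auc`, and `curves` (a data frame
#'   of fpr/tpr points per class for plotting or export).
#' @export
roc_auc_ovr <- function(y_true, scores) {
  y <- as.character(y_true)
  scores <- as.matrix(scores)
  classes <- colnames(scores) %||% class_levels(y)
  colnames(scores) <- classes
  aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  curves <- list()
  for (cl in classes) {
    pos <- y == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warning(sprintf("class '%s' absent from y_true (or its complement); AUC undefined", cl))
      next
    }
    sc <- scores[, cl]
    r <- rank(sc)
    aucs[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(sc, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    keep <- c(diff(sc[ord]) != 0, TRUE)   # collapse score ties
    curves[[cl]] <- data.frame(class = cl,
                               fpr = c(0, fp[keep] / n0),
                               tpr = c(0, tp[keep] / n1),
                               stringsAsFactors = FALSE)
  }
  list(macro_auc = mean(aucs, na.rm = TRUE), per_class_auc = aucs,
       curves = do.call(rbind, curves))
}

# SAMME multiclass AdaBoost over shallow CART trees. Weak learners are
# reweighted by exp(alpha * 1{wrong}) with alpha = log((1-err)/err) + log(k-1).
adaboost_trees <- function(X, y, n_learners = 30, max_depth = 3L) {
  df <- as_feature_df(X)
  y <- factor(as.character(y), levels = class_levels(y))
  k <- nlevels(y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  for (m in seq_len(n_learners)) {
    fit <- fit_cart(df, y, weights = w * n, max_depth = max_depth)
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y])
    if (err >= 1 - 1 / k) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  structure(list(learners = learners, alphas = alphas,
                 class_order = levels(y),
                 feature_names = names(df)),
            class = "adaboost_trees")
}

predict_adaboost_scores <- function(object, X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- object$feature_names
  k <- length(object$class_order)
  score <- matrix(0, nrow(df), k,
                  dimnames = list(NULL, object$class_order))
  for (i in seq_along(object$learners)) {
    p <- as.character(predict(object$learners[[i]], df, type = "class"))
    score[cbind(seq_len(nrow(df)), match(p, object$class_order))] <-
      score[cbind(seq_len(nrow(df)), match(p, object$class_order))] +
      object$alphas[i]
  }
  sweep(score, 1, pmax(rowSums(score), .Machine$double.eps), "/")
}

svm_scorer <- function(kernel) {
  function(Xtr, ytr, seed) {
    fit <- suppressWarnings(
      with_seed(seed, e1071::svm(x = Xtr, y = ytr, kernel = kernel,
                                 probability = TRUE)))
    list(score = function(Xte) {
      pr <- attr(predict(fit, Xte, probability = TRUE), "probabilities")
      pr[, levels(ytr), drop = FALSE]
    })
  }
}

#' Compare six classifiers on identical cross-validation folds
#'
#' Runs the comparison battery -- complex tree (at most 100 splits), simple
#' tree (at most 4 splits), linear SVM, Gaussian-kernel SVM, boosted trees
#' (SAMME adaptive boosting, 30 learners) and bagged trees (40 learners) --
#' under shared stratified K-fold assignments, reporting accuracy, macro
#' one-vs-rest AUC and wall-clock training time per model. As with the main
#' cross-validation, results are averaged over `n_repeats` independent fold
#' draws (every model sees the identical draws), so near-ties between models
#' are not decided by a single fold assignment. Training time is
#' hardware-dependent and reported for orientation only. A model that errors
#' yields an NA row rather than aborting the table.
#'
#' @param X Feature matrix.
#' @param y Class labels.
#' @param K Folds (default 10).
#' @param seed RNG seed (folds and any model randomness).
#' @param n_repeats Independent fold draws averaged over (default 10).
#' @param config Split budgets and learner counts; override to taste.
#' @return Data frame with 6 rows (model, accuracy, auc, train_time_s) and
#'   attribute `fold` holding the shared fold assignments (one column per
#'   repeat).
#' @export
compare_classifiers <- function(X, y, K = 10, seed = 1, n_repeats = 10,
                                config = list(complex_splits = 100,
                                              simple_splits = 4,
                                              boost_learners = 30,
                                              bagged_trees = 40)) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  y <- factor(as.character(y), levels = class_levels(y))
  k <- nlevels(y)
  folds <- with_seed(seed,
                     vapply(seq_len(n_repeats),
                            function(r) stratified_folds(y, K),
                            integer(length(y))))
  model_seeds <- with_seed(seed + 1, sample.int(2147483646L, 6))

  tree_fitter <- function(max_splits) function(Xtr, ytr, seed) {
    fit <- fit_cart(as_feature_df(Xtr), ytr, max_splits = max_splits)
    list(score = function(Xte) {
      pr <- predict(fit, as.data.frame(Xte), type = "prob")
      pr[, levels(ytr), drop = FALSE]
    })
  }
  fitters <- list(
    complex_tree = tree_fitter(config$complex_splits),
    simple_tree = tree_fitter(config$simple_splits),
    linear_svm = svm_scorer("linear"),
    gaussian_svm = svm_scorer("radial"),
    boosted_trees = function(Xtr, ytr, seed) {
      fit <- with_seed(seed, adaboost_trees(Xtr, ytr,
                                            n_learners = config$boost_learners))
      list(score = function(Xte) predict_adaboost_scores(fit, Xte))
    },
    bagged_trees = function(Xtr, ytr, seed) {
      fit <- train_bagged_trees(Xtr, ytr, n_trees = config$bagged_trees,
                                seed = seed)
      list(score = function(Xte) predict(fit, Xte)$vote_fractions)
    }
  )

  rows <- lapply(seq_along(fitters), function(mi) {
    name <- names(fitters)[mi]
    tryCatch({
      correct <- 0
      t_train <- 0
      pooled_scores <- vector("list", n_repeats)
      for (r in seq_len(n_repeats)) {
        fold <- folds[, r]
        scores <- matrix(NA_real_, length(y), k,
                         dimnames = list(NULL, levels(y)))
        for (f in seq_len(K)) {
          te <- fold == f
          t0 <- proc.time()[["elapsed"]]
          m <- fitters[[mi]](X[!te, , drop = FALSE], y[!te],
                             model_seeds[mi] + r)
          t_train <- t_train + (proc.time()[["elapsed"]] - t0)
          scores[te, ] <- m$score(X[te, , drop = FALSE])
        }
        pred <- factor(levels(y)[apply(scores, 1, which.max)],
                       levels = levels(y))
        correct <- correct + sum(pred == y)
        pooled_scores[[r]] <- scores
      }
      data.frame(model = name,
                 accuracy = correct / (length(y) * n_repeats),
                 auc = roc_auc_ovr(rep(as.character(y), n_repeats),
                                   do.call(rbind, pooled_scores))$macro_auc,
                 train_time_s = t_train, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("model '%s' failed: %s", name, conditionMessage(e)))
      data.frame(model = name, accuracy = NA_real_, auc = NA_real_,
                 train_time_s = NA_real_, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "fold") <- folds
  out
}

#' Export a CV report as CSV tables
#'
#' Writes a confusion-matrix table (per-class counts with percentages and
#' per-class accuracy, plus an overall row) and the pooled one-vs-rest ROC
#' points.
#'
#' @param report A [repeated_kfold_cv()] result.
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
export_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- report$confusion
  pct <- sweep(conf, 1, pmax(rowSums(conf), 1), "/") * 100
  tab <- data.frame(Classes = rownames(conf), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(conf)))
    tab[[colnames(conf)[j]]] <- sprintf("%d (%.0f%%)", conf[, j], pct[, j])
  tab$Accuracy <- sprintf("%.1f%%", 100 * report$per_class_accuracy)
  tab <- rbind(tab, c("Overall", rep("", ncol(conf)),
                      sprintf("%.1f%%", 100 * report$overall_accuracy)))
  p1 <- file.path(dir, "confusion.csv")
  utils::write.csv(tab, p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, "roc_points.csv")
  utils::write.csv(report$roc$curves, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Persist / restore a fitted ensemble
#'
#' The artifact embeds the feature-registry version; [load_model()] refuses a
#' model built against a different registry.
#'
#' @param model A `bagged_trees` model.
#' @param path Artifact path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bagged_trees"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!identical(model$registry_version, feature_registry_version()))
    abort_config(sprintf(
      "model was built with feature registry %s; this package uses %s",
      model$registry_version, feature_registry_version()))
  model
}
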