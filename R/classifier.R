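#' Train a bagged decision-tree ensemble
#'
#' Bootstrap aggregation over full-depth classification trees: each tree is
#' grown by recursive partitioning (Gini criterion, all features considered
#' at every split, as is standard when trees are produced by bagging) on a
#' with-replacement resample of the training set of the same size; the
#' ensemble predicts by simple majority vote. Training is deterministic
#' given \code{seed}.
#'
#' @param x data frame of feature columns.
#' @param y factor of class labels (length \code{nrow(x)}).
#' @param n_trees number of trees (default 100).
#' @param seed integer seed controlling the bootstrap draws.
#' @param control an [rpart::rpart.control()] for the individual trees;
#'   the default grows them to full depth.
#' @param bootstrap set \code{FALSE} to train every tree on the full data
#'   (then \code{n_trees = 1} reproduces a plain decision tree).
#' @return object of class \code{bagged_trees} with elements \code{trees},
#'   \code{inbag} (per-tree bootstrap indices), \code{classes},
#'   \code{feature_names}, \code{n_trees}, \code{seed}.
#' @export
bagged_trees <- function(x, y, n_trees = 100, seed = 1,
                         control = rpart::rpart.control(
                           minsplit = 2, minbucket = 1, cp = 0,
                           xval = 0, maxsurrogate = 0, maxcompete = 0),
                         bootstrap = TRUE) {
  stopifnot(is.data.frame(x), nrow(x) == length(y), n_trees >= 1)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    warning("single-class training data; model is a degenerate single leaf",
            call. = FALSE)
  }
  n <- nrow(x)
  dat <- cbind(x, .class = y)
  with_seed(seed, {
    inbag <- lapply(seq_len(n_trees), function(b)
      if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n))
    trees <- lapply(inbag, function(idx)
      rpart::rpart(.class ~ ., data = dat[idx, , drop = FALSE],
                   method = "class", control = control))
  })
  structure(list(trees = trees, inbag = inbag, classes = levels(y),
                 feature_names = names(x), n_trees = n_trees, seed = seed),
            class = "bagged_trees")
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat("<bagged_trees> ", x$n_trees, " trees, ", length(x$classes),
      " classes, ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

# per-tree class predictions as an n x n_trees character matrix
tree_votes <- function(model, newdata, trees = seq_along(model$trees)) {
  vapply(model$trees[trees], function(tr)
    as.character(predict(tr, newdata = newdata, type = "class")),
    character(nrow(newdata)))
}

majority_vote <- function(votes, classes) {
  counts <- vapply(classes, function(cl) rowSums(votes == cl),
                   numeric(nrow(votes)))
  counts <- matrix(counts, nrow = nrow(votes),
                   dimnames = list(NULL, classes))
  # max.col with ties.method "first" = first class in canonical order
  pred <- classes[max.col(counts, ties.method = "first")]
  list(class = factor(pred, levels = classes), votes = counts)
}

#' Predict with a bagged ensemble
#'
#' Simple majority vote over the trees; vote ties are broken
#' deterministically in favour of the earlier class in the model's class
#' order.
#'
#' @param object a [bagged_trees()] model.
#' @param newdata data frame with the training feature columns.
#' @param type \code{"class"} for labels, \code{"votes"} for the per-class
#'   vote-count matrix.
#' @param ... unused.
#' @return factor of predicted classes, or a vote-count matrix.
#' @export
predict.bagged_trees <- function(object, newdata,
                                 type = c("class", "votes"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("newdata lacks feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  votes <- tree_votes(object, newdata)
  if (!is.matrix(votes)) votes <- matrix(votes, nrow = nrow(newdata))
  mv <- majority_vote(votes, object$classes)
  if (type == "class") mv$class else mv$votes
}

confusion_matrix <- function(truth, pred, classes) {
  table(truth = factor(truth, levels = classes),
        predicted = factor(pred, levels = classes))
}

#' K-fold cross-validated evaluation
#'
#' Stratified-by-class, seed-shuffled fold assignment (K = 5 in the study:
#' 80% of windows train, 20% validate per fold); out-of-fold predictions are
#' pooled into an overall accuracy, per-class true-positive rates and a
#' confusion matrix. Stratified pooling of overlapping windows shares
#' adjacent windows across folds; grouped splitting (e.g. by participant)
#' can be imposed via \code{folds}.
#'
#' @inheritParams bagged_trees
#' @param k number of folds.
#' @param folds optional integer vector of pre-assigned folds (overrides the
#'   stratified split).
#' @param ... passed to [bagged_trees()].
#' @return object of class \code{vr_evaluation}: \code{accuracy},
#'   \code{per_class_tpr}, \code{confusion} (rows = true class),
#'   \code{confusion_rownorm}, \code{folds}, \code{predictions}.
#' @export
kfold_evaluate <- function(x, y, k = 5, n_trees = 100, seed = 1,
                           folds = NULL, ...) {
  y <- droplevels(as.factor(y))
  stopifnot(k >= 2, nrow(x) >= k)
  if (is.null(folds)) {
    folds <- integer(nrow(x))
    with_seed(seed, {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
  }
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  for (f in seq_len(k)) {
    test <- folds == f
    model <- bagged_trees(x[!test, , drop = FALSE], y[!test],
                          n_trees = n_trees, seed = seed + f, ...)
    pred[test] <- predict(model, x[test, , drop = FALSE])
  }
  cm <- confusion_matrix(y, pred, levels(y))
  tpr <- diag(cm) / rowSums(cm)
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 per_class_tpr = tpr,
                 confusion = cm,
                 confusion_rownorm = sweep(cm, 1, pmax(rowSums(cm), 1), "/"),
                 folds = folds, predictions = pred),
            class = "vr_evaluation")
}

#' @export
print.vr_evaluation <- function(x, ...) {
  cat("<vr_evaluation> accuracy =", sprintf("%.4f", x$accuracy), "\n")
  print(round(x$per_class_tpr, 4))
  invisible(x)
}

#' Out-of-bag permutation feature importance
#'
#' For every tree, the instances absent from its bootstrap sample (on
#' average a fraction 1/e of the data) are predicted and the error recorded;
#' each feature's out-of-bag values are then permuted and the error
#' recomputed. A feature's importance is the resulting increase in
#' out-of-bag error, summed over trees (also reported as a per-tree mean).
#' Note that exactly duplicated (or heavily correlated) features share
#' importance asymmetrically: the deterministic split tie-break prefers the
#' first-listed column, so a duplicate can score near zero.
#'
#' @param model a [bagged_trees()] model.
#' @param x,y the training data the model was fitted on.
#' @param seed seed for the permutations.
#' @return data frame with columns \code{feature},
#'   \code{importance_sum}, \code{importance_mean}, ordered as the
#'   training features.
#' @export
oob_importance <- function(model, x, y, seed = model$seed + 1L) {
  stopifnot(inherits(model, "bagged_trees"), nrow(x) == length(y))
  x <- x[model$feature_names]
  y <- factor(as.character(y), levels = model$classes)
  p <- length(model$feature_names)
  delta <- matrix(0, model$n_trees, p,
                  dimnames = list(NULL, model$feature_names))
  used <- logical(model$n_trees)
  with_seed(seed, {
    for (b in seq_len(model$n_trees)) {
      oob <- setdiff(seq_len(nrow(x)), model$inbag[[b]])
      if (length(oob) < 2) next
      used[b] <- TRUE
      xo <- x[oob, , drop = FALSE]
      base_err <- mean(tree_votes(model, xo, trees = b) !=
                         as.character(y[oob]))
      for (j in seq_len(p)) {
        xp <- xo
        xp[[j]] <- xp[[j]][sample.int(length(oob))]
        perm_err <- mean(tree_votes(model, xp, trees = b) !=
                           as.character(y[oob]))
        delta[b, j] <- perm_err - base_err
      }
    }
  })
  data.frame(feature = model$feature_names,
             importance_sum = colSums(delta),
             importance_mean = colSums(delta) / max(sum(used), 1),
             row.names = NULL)
}

#' Observed out-of-bag fraction of a model
#'
#' Mean over trees of the fraction of training instances left out of each
#' bootstrap sample; approximately \eqn{e^{-1} \approx 0.368} for large
#' training sets.
#'
#' @param model a [bagged_trees()] model.
#' @return scalar in (0, 1).
#' @export
oob_fraction <- function(model) {
  n <- length(model$inbag[[1]])
  mean(vapply(model$inbag, function(idx)
    1 - length(unique(idx)) / n, numeric(1)))
}

# evaluate/restore RNG state around seeded code
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
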