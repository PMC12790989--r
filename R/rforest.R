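# Minimal random-forest classifier (binary): CART trees grown on bootstrap
# samples with Gini impurity and mtry feature subsampling, out-of-bag
# accuracy and OOB permutation importances. Written in-package because no
# random-forest library is available in the target environment; sized for
# the small pair sets this pipeline classifies (hundreds of rows).

# grow one tree; returns a node table (matrix-backed list)
.grow_tree <- function(X, y, mtry, min_node = 2L, max_depth = 12L) {
  nodes <- list()
  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[id] <<- list(NULL)          # reserve slot (keeps list length)
    n1 <- sum(y[idx]); n <- length(idx)
    if (n < min_node || depth >= max_depth || n1 == 0L || n1 == n) {
      nodes[[id]] <<- list(leaf = TRUE, pred = as.integer(n1 * 2L > n))
      return(id)
    }
    feats <- sample.int(ncol(X), mtry)
    best <- NULL; best_gini <- Inf
    for (j in feats) {
      xv <- X[idx, j]
      ux <- sort(unique(xv))
      if (length(ux) < 2L) next
      cuts <- (ux[-1] + ux[-length(ux)]) / 2
      for (cut in cuts) {
        l <- xv <= cut
        nl <- sum(l); nr <- n - nl
        if (nl == 0L || nr == 0L) next
        p1l <- sum(y[idx][l]) / nl; p1r <- (n1 - sum(y[idx][l])) / nr
        gini <- nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)
        if (gini < best_gini - 1e-12) {
          best_gini <- gini; best <- list(j = j, cut = cut)
        }
      }
    }
    if (is.null(best)) {
      nodes[[id]] <<- list(leaf = TRUE, pred = as.integer(n1 * 2L > n))
      return(id)
    }
    l <- X[idx, best$j] <= best$cut
    left <- build(idx[l], depth + 1L)
    right <- build(idx[!l], depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, j = best$j, cut = best$cut,
                         left = left, right = right)
    id
  }
  build(seq_along(y), 0L)
  nodes
}

.predict_tree <- function(nodes, X) {
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (nd$leaf) return(nd$pred)
      id <- if (X[i, nd$j] <= nd$cut) nd$left else nd$right
    }
  }, integer(1))
}

#' Fit a bagged random forest (binary classification)
#'
#' @param X numeric matrix (rows = observations).
#' @param y 0/1 labels.
#' @param ntree number of trees (default 200).
#' @param mtry features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param min_node minimum node size to attempt a split (default 2).
#' @return `rf` object: trees, bootstrap indices, OOB votes and accuracy.
#' @export
rf_fit <- function(X, y, ntree = 200L, mtry = NULL, min_node = 2L) {
  X <- as.matrix(X); y <- as.integer(y)
  .need(all(y %in% c(0L, 1L)), "y must be binary 0/1")
  n <- nrow(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", ntree)
  boots <- vector("list", ntree)
  votes <- matrix(0, n, 2)
  for (t in seq_len(ntree)) {
    b <- sample.int(n, n, replace = TRUE)
    boots[[t]] <- b
    trees[[t]] <- .grow_tree(X[b, , drop = FALSE], y[b], mtry, min_node)
    oob <- setdiff(seq_len(n), b)
    if (length(oob)) {
      pr <- .predict_tree(trees[[t]], X[oob, , drop = FALSE])
      votes[cbind(oob, pr + 1L)] <- votes[cbind(oob, pr + 1L)] + 1
    }
  }
  seen <- rowSums(votes) > 0
  oob_pred <- ifelse(votes[, 2] > votes[, 1], 1L, 0L)
  structure(list(trees = trees, boots = boots, mtry = mtry, n = n,
                 feature_names = colnames(X),
                 oob_accuracy = mean(oob_pred[seen] == y[seen])),
            class = "rf")
}

#' Predict class labels with a fitted random forest
#'
#' @param forest an `rf` object from [rf_fit()].
#' @param X matrix of observations to classify.
#' @return integer vector of 0/1 majority-vote predictions.
#' @export
rf_predict <- function(forest, X) {
  X <- as.matrix(X)
  votes <- matrix(0, nrow(X), 2)
  for (tr in forest$trees) {
    pr <- .predict_tree(tr, X)
    votes[cbind(seq_len(nrow(X)), pr + 1L)] <- votes[cbind(seq_len(nrow(X)), pr + 1L)] + 1
  }
  ifelse(votes[, 2] > votes[, 1], 1L, 0L)
}

#' OOB permutation feature importance
#'
#' For each feature, permutes its values among each tree's out-of-bag
#' observations and averages the resulting drop in OOB accuracy over trees.
#'
#' @param forest fitted `rf` object.
#' @param X,y the training data.
#' @return named numeric vector of mean accuracy drops.
#' @export
rf_importance <- function(forest, X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  p <- ncol(X)
  drops <- matrix(0, length(forest$trees), p)
  for (t in seq_along(forest$trees)) {
    oob <- setdiff(seq_len(forest$n), forest$boots[[t]])
    if (length(oob) < 2L) next
    base <- mean(.predict_tree(forest$trees[[t]], X[oob, , drop = FALSE]) == y[oob])
    for (j in seq_len(p)) {
      Xp <- X[oob, , drop = FALSE]
      Xp[, j] <- Xp[sample.int(length(oob)), j]
      drops[t, j] <- base -
        mean(.predict_tree(forest$trees[[t]], Xp) == y[oob])
    }
  }
  setNames(colMeans(drops), colnames(X))
}
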