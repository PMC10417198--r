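# Classification random forest: CART trees with Gini splits, bootstrap
# aggregation, out-of-bag permutation importance and Gini importance.
# Authored in-package: profile tables are small (tens of samples, <= 14
# features), so plain R tree growth is fast enough, and no forest package is
# assumed to be available at run time.

# Best Gini split of one feature. Returns NULL when no cut point exists.
# Maximising crit = sum_l p_l^2 * n_l + sum_r p_r^2 * n_r is equivalent to
# minimising the weighted child Gini impurity.
.gini_split <- function(xv, yi, K) {
  m <- length(xv)
  ord <- order(xv)
  xs <- xv[ord]
  ys <- yi[ord]
  cut_ok <- xs[-m] < xs[-1L]
  if (!any(cut_ok)) return(NULL)
  Y <- matrix(0, m, K)
  Y[cbind(seq_len(m), ys)] <- 1
  cl <- apply(Y, 2, cumsum)
  tot <- cl[m, ]
  clh <- cl[-m, , drop = FALSE]
  crh <- matrix(tot, m - 1L, K, byrow = TRUE) - clh
  nl <- seq_len(m - 1L)
  crit <- rowSums(clh^2) / nl + rowSums(crh^2) / (m - nl)
  crit[!cut_ok] <- -Inf
  b <- which.max(crit)
  list(threshold = (xs[b] + xs[b + 1L]) / 2,
       decrease = crit[b] - sum(tot^2) / m)
}

.majority <- function(yi, K) which.max(tabulate(yi, K))

# Grow one CART tree on (x, y); nodes are stored in parallel vectors, leaf
# nodes have var = 0. `imp` accumulates Gini impurity decreases per feature.
.grow_tree <- function(x, y, mtry, K) {
  p <- ncol(x)
  var <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  imp <- numeric(p)
  build <- function(idx) {
    id <- length(var) + 1L
    yi <- y[idx]
    var[id] <<- 0L; split[id] <<- 0; left[id] <<- 0L; right[id] <<- 0L
    pred[id] <<- .majority(yi, K)
    if (length(idx) < 2L || all(yi == yi[1L])) return(id)
    vs <- sample.int(p, min(mtry, p))
    best <- NULL; bj <- 0L
    for (j in vs) {
      s <- .gini_split(x[idx, j], yi, K)
      if (!is.null(s) && (is.null(best) || s$decrease > best$decrease)) {
        best <- s; bj <- j
      }
    }
    if (is.null(best) || best$decrease <= 1e-12) return(id)
    imp[bj] <<- imp[bj] + best$decrease
    goleft <- x[idx, bj] <= best$threshold
    var[id] <<- bj
    split[id] <<- best$threshold
    left[id] <<- build(idx[goleft])
    right[id] <<- build(idx[!goleft])
    id
  }
  build(seq_len(nrow(x)))
  list(var = var, split = split, left = left, right = right, pred = pred,
       imp = imp)
}

.predict_tree <- function(tree, x) {
  cur <- rep(1L, nrow(x))
  repeat {
    v <- tree$var[cur]
    live <- which(v != 0L)
    if (length(live) == 0L) break
    goleft <- x[cbind(live, v[live])] <= tree$split[cur[live]]
    cur[live] <- ifelse(goleft, tree$left[cur[live]], tree$right[cur[live]])
  }
  tree$pred[cur]
}

#' Fit a classification random forest
#'
#' Bagged CART trees grown to purity with `mtry` candidate features per
#' split. Variable importance: mean decrease in Gini impurity (split-based)
#' and mean decrease in accuracy (out-of-bag permutation).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels (coerced to factor).
#' @param ntree number of trees.
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param seed optional RNG seed.
#' @param importance compute importances (default `TRUE`).
#' @return object of class `sep_rf` with elements `trees`, `classes`,
#'   `features`, `mtry`, `ntree`, `oob_accuracy` (%), `importance`
#'   (data frame: `feature`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`).
#' @export
fit_random_forest <- function(x, y, ntree = 500L, mtry = NULL, seed = NULL,
                              importance = TRUE) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  K <- nlevels(y)
  yi <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (mtry > ncol(x)) stop("mtry exceeds the number of features")
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", ntree)
  inbag <- vector("list", ntree)
  gini <- numeric(ncol(x))
  oob_votes <- matrix(0, n, K)
  for (t in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- .grow_tree(x[idx, , drop = FALSE], yi[idx], mtry, K)
    trees[[t]] <- tr
    inbag[[t]] <- idx
    gini <- gini + tr$imp
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) > 0L) {
      pr <- .predict_tree(tr, x[oob, , drop = FALSE])
      oob_votes[cbind(oob, pr)] <- oob_votes[cbind(oob, pr)] + 1
    }
  }
  seen <- rowSums(oob_votes) > 0
  oob_acc <- 100 * mean(max.col(oob_votes[seen, , drop = FALSE],
                                "first") == yi[seen])
  imp_df <- NULL
  if (importance) {
    acc_drop <- numeric(ncol(x))
    n_used <- 0L
    for (t in seq_len(ntree)) {
      oob <- setdiff(seq_len(n), inbag[[t]])
      if (length(oob) < 2L) next
      n_used <- n_used + 1L
      xo <- x[oob, , drop = FALSE]
      base <- mean(.predict_tree(trees[[t]], xo) == yi[oob])
      for (j in seq_len(ncol(x))) {
        xp <- xo
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        acc_drop[j] <- acc_drop[j] +
          (base - mean(.predict_tree(trees[[t]], xp) == yi[oob]))
      }
    }
    imp_df <- data.frame(
      feature = colnames(x),
      mean_decrease_accuracy = acc_drop / max(n_used, 1L),
      mean_decrease_gini = gini / ntree,
      stringsAsFactors = FALSE)
  }
  structure(list(trees = trees, classes = levels(y),
                 features = colnames(x), mtry = mtry, ntree = ntree,
                 oob_accuracy = oob_acc, importance = imp_df),
            class = "sep_rf")
}

#' Class votes of a forest
#'
#' @param object a `sep_rf` forest.
#' @param x feature matrix.
#' @param ntree use only the first `ntree` trees (default all).
#' @return samples x classes vote-count matrix.
#' @export
rf_votes <- function(object, x, ntree = NULL) {
  x <- as.matrix(x)
  if (is.null(ntree)) ntree <- object$ntree
  K <- length(object$classes)
  votes <- matrix(0, nrow(x), K, dimnames = list(NULL, object$classes))
  for (t in seq_len(ntree)) {
    pr <- .predict_tree(object$trees[[t]], x)
    votes[cbind(seq_len(nrow(x)), pr)] <- votes[cbind(seq_len(nrow(x)), pr)] + 1
  }
  votes
}

#' @export
predict.sep_rf <- function(object, newdata, ...) {
  x <- .model_matrix_from(newdata, object$features)
  votes <- rf_votes(object, x)
  factor(object$classes[max.col(votes, "first")], levels = object$classes)
}

# Accept either a bare feature matrix/data.frame or a profile table with
# <El>_ppm columns.
.model_matrix_from <- function(data, features) {
  if (is.matrix(data)) {
    if (!is.null(colnames(data)) && all(features %in% colnames(data))) {
      return(data[, features, drop = FALSE])
    }
    return(data)
  }
  if (all(features %in% names(data))) {
    return(as.matrix(data[, features, drop = FALSE]))
  }
  ppm <- .ppm(features)
  if (all(ppm %in% names(data))) {
    m <- as.matrix(data[, ppm, drop = FALSE])
    colnames(m) <- features
    return(m)
  }
  stop("feature roster mismatch: model expects ",
       paste(features, collapse = ", "))
}
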