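# Provenance modelling: stratified split, tuned random forest, LDA, and
# ordination (PCA, NMDS, canonical discriminant analysis).

#' Stratified train/test split
#'
#' Per group, `round-half-up(train_fraction * n)` samples are retained for
#' training and the remainder go to the test set; if that leaves a group
#' with no test sample, one randomly chosen sample is moved to the test set
#' so every group contributes at least one.
#'
#' @param table profile table with a grouping column.
#' @param train_fraction fraction retained for training (default 0.8).
#' @param seed RNG seed.
#' @param label grouping column name (default `"group"`).
#' @return list: `train`, `test` (disjoint profile tables partitioning the
#'   input).
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L,
                             label = "group") {
  g <- table[[label]]
  if (any(table(g) < 2L)) {
    stop("every group needs >= 2 samples to appear in both sets")
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (lev in unique(g)) {
    idx <- which(g == lev)
    n <- length(idx)
    n_train <- floor(train_fraction * n + 0.5)  # round half up
    if (n_train >= n) n_train <- n - 1L         # guard: >= 1 test sample
    if (n_train < 1L) n_train <- 1L
    test_idx <- c(test_idx, sample(idx, n - n_train))
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# Stratified fold assignment: within each class, shuffled indices get fold
# ids cyclically, so folds are as balanced per class as possible.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Tune a random forest by stratified k-fold cross-validation
#'
#' Every (`mtry`, `ntree`) grid cell is scored by stratified k-fold CV
#' accuracy on the training table; ties are broken towards smaller `ntree`,
#' then smaller `mtry`. The winning cell is refitted on the full training
#' table (with importances). For efficiency, one forest of `max(ntree)`
#' trees is grown per fold and `mtry`, and accuracies are read off at each
#' `ntree` checkpoint from cumulative votes.
#'
#' @param train training profile table.
#' @param elements feature elements (default all `<El>_ppm` columns).
#' @param label grouping column (default `"group"`).
#' @param mtry_grid,ntree_grid tuning grids; the defaults include the
#'   (mtry 3, ntree 600) cell.
#' @param k_folds CV folds (default 5).
#' @param seed RNG seed.
#' @return object of class `sep_rf_report`: `grid` (data frame `mtry`,
#'   `ntree`, `cv_accuracy` in %), `best` (one-row data frame),
#'   `cv_accuracy`, `model` (`sep_rf` fitted on all training data),
#'   `resub_accuracy`, `oob_accuracy`, `seed`.
#' @export
tune_random_forest <- function(train, elements = NULL, label = "group",
                               mtry_grid = c(1, 3, 5, 7),
                               ntree_grid = c(100, 300, 600),
                               k_folds = 5L, seed = 1L) {
  if (is.null(elements)) elements <- profile_elements(train)
  x <- .concentration_matrix(train, elements)
  colnames(x) <- elements
  y <- factor(train[[label]])
  K <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(x)
  if (n < k_folds) stop("fewer samples than folds")
  mtry_grid <- sort(unique(as.integer(mtry_grid)))
  ntree_grid <- sort(unique(as.integer(ntree_grid)))
  skip <- mtry_grid > ncol(x)
  if (any(skip)) {
    warning("skipping mtry > number of elements: ",
            paste(mtry_grid[skip], collapse = ", "))
    mtry_grid <- mtry_grid[!skip]
  }
  if (length(mtry_grid) == 0L || length(ntree_grid) == 0L) {
    stop("empty tuning grid")
  }
  set.seed(seed)
  folds <- .stratified_folds(y, k_folds)
  max_nt <- max(ntree_grid)
  correct <- matrix(0, length(mtry_grid), length(ntree_grid),
                    dimnames = list(mtry_grid, ntree_grid))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    te <- which(!tr)
    if (length(te) == 0L) next
    xt <- x[tr, , drop = FALSE]
    yt <- yi[tr]
    xe <- x[te, , drop = FALSE]
    for (mi in seq_along(mtry_grid)) {
      set.seed(.stream_seed(seed, 1000 + f * 50 + mi))
      votes <- matrix(0, length(te), K)
      ci <- 1L
      for (t in seq_len(max_nt)) {
        idx <- sample.int(nrow(xt), nrow(xt), replace = TRUE)
        tree <- .grow_tree(xt[idx, , drop = FALSE], yt[idx],
                           mtry_grid[mi], K)
        pr <- .predict_tree(tree, xe)
        votes[cbind(seq_along(te), pr)] <- votes[cbind(seq_along(te), pr)] + 1
        if (ci <= length(ntree_grid) && t == ntree_grid[ci]) {
          pred <- max.col(votes, "first")
          correct[mi, ci] <- correct[mi, ci] + sum(pred == yi[te])
          ci <- ci + 1L
        }
      }
    }
  }
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- 100 * as.vector(correct) / n
  ord <- order(-grid$cv_accuracy, grid$ntree, grid$mtry)
  best <- grid[ord[1L], , drop = FALSE]
  rownames(best) <- NULL
  model <- fit_random_forest(x, y, ntree = best$ntree, mtry = best$mtry,
                             seed = .stream_seed(seed, 999),
                             importance = TRUE)
  resub <- 100 * mean(predict(model, x) == y)
  structure(list(grid = grid, best = best,
                 cv_accuracy = best$cv_accuracy, model = model,
                 resub_accuracy = resub, oob_accuracy = model$oob_accuracy,
                 elements = elements, label = label, seed = seed),
            class = "sep_rf_report")
}

#' Evaluate a classifier on a test table
#'
#' @param model a `sep_rf`, `sep_rf_report`, or `sep_lda` object.
#' @param test test profile table (nonempty).
#' @param label grouping column.
#' @return list: `accuracy` (%), `confusion` (true rows x predicted
#'   columns), `misclassified` (data frame `sample_id`, `true`,
#'   `predicted`).
#' @export
evaluate_classifier <- function(model, test, label = "group") {
  if (inherits(model, "sep_rf_report")) model <- model$model
  if (nrow(test) == 0L) stop("empty test set")
  pred <- predict(model, test)
  classes <- if (inherits(model, "sep_rf")) model$classes else model$classes
  truth <- factor(test[[label]], levels = classes)
  if (anyNA(truth)) stop("test set contains unseen class labels")
  confusion <- table(true = truth, predicted = factor(pred, levels = classes))
  wrong <- which(as.character(pred) != as.character(truth))
  mis <- data.frame(sample_id = test$sample_id[wrong],
                    true = as.character(truth)[wrong],
                    predicted = as.character(pred)[wrong],
                    stringsAsFactors = FALSE)
  list(accuracy = 100 * mean(pred == truth), confusion = confusion,
       misclassified = mis)
}

#' Fit a linear discriminant classifier
#'
#' LDA on the element concentrations with the training (resubstitution)
#' accuracy reported. Requires more than one sample per class and a
#' non-singular pooled within-class covariance (run the correlation filter
#' first if it is singular).
#'
#' @param train training profile table (scaled elements recommended).
#' @param elements feature elements (default all).
#' @param label grouping column.
#' @return object of class `sep_lda`: `fit` (the underlying model),
#'   `training_accuracy` (%), `classes`, `features`.
#' @export
fit_lda <- function(train, elements = NULL, label = "group") {
  if (is.null(elements)) elements <- profile_elements(train)
  x <- .concentration_matrix(train, elements)
  colnames(x) <- elements
  y <- factor(train[[label]])
  if (any(table(y) < 2L)) {
    stop("every class needs more than one sample for LDA")
  }
  fit <- tryCatch(
    MASS::lda(x, grouping = y),
    error = function(e) {
      stop("LDA failed (within-class covariance singular? ",
           "apply the correlation filter first): ", conditionMessage(e))
    })
  acc <- 100 * mean(predict(fit, x)$class == y)
  structure(list(fit = fit, training_accuracy = acc, classes = levels(y),
                 features = elements),
            class = "sep_lda")
}

#' @export
predict.sep_lda <- function(object, newdata, ...) {
  x <- .model_matrix_from(newdata, object$features)
  predict(object$fit, x)$class
}

#' Principal component analysis of a scaled profile table
#'
#' @param table scaled profile table.
#' @param n_components components to return (default all; truncated with a
#'   warning if above the matrix rank).
#' @param elements feature elements.
#' @return list: `scores` (data frame with labels + `PC*` columns),
#'   `loadings`, `variance_explained` (% per component, summing to 100
#'   over all components), `n_components`.
#' @export
pca_profile <- function(table, n_components = NULL, elements = NULL) {
  if (is.null(elements)) elements <- profile_elements(table)
  x <- .concentration_matrix(table, elements)
  colnames(x) <- elements
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  varex <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  rank_x <- sum(fit$sdev > fit$sdev[1L] * 1e-10)
  if (is.null(n_components)) n_components <- length(fit$sdev)
  if (n_components > rank_x) {
    warning("n_components above rank; truncated to ", rank_x)
    n_components <- rank_x
  }
  labels <- table[, intersect(c("sample_id", "group", "site", "production",
                                "preparation"), names(table)), drop = FALSE]
  scores <- cbind(labels,
                  as.data.frame(fit$x[, seq_len(n_components), drop = FALSE]))
  list(scores = scores,
       loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
       variance_explained = varex, n_components = n_components)
}

#' Nonmetric multidimensional scaling of a profile table
#'
#' Kruskal NMDS (via \pkg{vegan}) of the chosen distance (default Euclidean
#' on scaled concentrations; Bray-Curtis available for raw concentrations).
#' Multiple seeded random starts; the best configuration is kept.
#'
#' @param table profile table.
#' @param k target dimensionality (default 2).
#' @param distance `"euclidean"` or `"bray"`.
#' @param seed RNG seed.
#' @param trymax maximum random starts.
#' @param elements feature elements.
#' @return list: `coordinates` (labels + `NMDS*` columns), `stress`
#'   (Kruskal stress, 0-1), `converged`.
#' @export
nmds_profile <- function(table, k = 2L, distance = c("euclidean", "bray"),
                         seed = 1L, trymax = 20L, elements = NULL) {
  distance <- match.arg(distance)
  if (is.null(elements)) elements <- profile_elements(table)
  x <- .concentration_matrix(table, elements)
  if (nrow(x) < k + 1L) stop("need at least k + 1 samples")
  d <- if (distance == "bray") vegan::vegdist(x, "bray") else dist(x)
  if (max(d) - min(d) < 1e-12) {
    stop("degenerate distances: all pairwise distances equal")
  }
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = trymax, trace = 0)
  labels <- table[, intersect(c("sample_id", "group", "site", "production",
                                "preparation"), names(table)), drop = FALSE]
  pts <- as.data.frame(fit$points)
  names(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  list(coordinates = cbind(labels, pts), stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Canonical discriminant analysis
#'
#' Canonical variates of the between-group relative to within-group scatter
#' (supervised ordination). At most `min(groups - 1, elements)` axes.
#' Structure coefficients (correlations between each element and each
#' canonical axis) identify which elements load each axis.
#'
#' @param table profile table (scaled elements recommended).
#' @param label grouping column.
#' @param elements feature elements.
#' @return list: `scores` (labels + `CAN*` columns), `structure`
#'   (elements x axes correlation matrix), `centroids` (group means of the
#'   scores), `eigenvalues`, `n_axes`.
#' @export
cda_profile <- function(table, label = "group", elements = NULL) {
  if (is.null(elements)) elements <- profile_elements(table)
  x <- .concentration_matrix(table, elements)
  colnames(x) <- elements
  g <- factor(table[[label]])
  ng <- nlevels(g)
  if (ng < 2L) stop("need at least 2 groups")
  n <- nrow(x)
  p <- ncol(x)
  counts <- as.vector(table(g))
  gm <- rowsum(x, g) / counts
  xc <- x - gm[as.integer(g), , drop = FALSE]
  W <- crossprod(xc)
  mu <- colMeans(x)
  Bm <- sweep(gm, 2, mu) * sqrt(counts)
  B <- crossprod(Bm)
  U <- tryCatch(chol(W), error = function(e) {
    stop("within-group scatter singular (apply the correlation filter ",
         "first): ", conditionMessage(e))
  })
  C <- backsolve(U, B, transpose = TRUE)          # U^-T B
  M <- t(backsolve(U, t(C), transpose = TRUE))    # U^-T B U^-1
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  n_axes <- min(ng - 1L, p)
  A <- backsolve(U, eig$vectors[, seq_len(n_axes), drop = FALSE])
  rownames(A) <- elements
  scores_m <- sweep(x, 2, mu) %*% A
  colnames(scores_m) <- paste0("CAN", seq_len(n_axes))
  structure_m <- cor(x, scores_m)
  labels <- table[, intersect(c("sample_id", "group", "site", "production",
                                "preparation"), names(table)), drop = FALSE]
  centroids <- rowsum(scores_m, g) / counts
  list(scores = cbind(labels, as.data.frame(scores_m)),
       structure = structure_m, centroids = centroids,
       eigenvalues = pmax(eig$values[seq_len(n_axes)], 0),
       coefficients = A, n_axes = n_axes)
}
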