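test_that("stratified split reproduces the 32/8 design", {
  tab <- generate_profile_table(generator_config(seed = 1))
  sp <- stratified_split(tab, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 32L)
  expect_equal(nrow(sp$test), 8L)
  expect_true(all(table(sp$test$group) == 1L))
  expect_equal(sort(c(sp$train$sample_id, sp$test$sample_id)),
               sort(tab$sample_id))
})

test_that("split guard and determinism hold for arbitrary group sizes", {
  sp1 <- stratified_split(generate_profile_table(generator_config(seed = 2)),
                          1.0, seed = 5)
  expect_true(all(table(sp1$test$group) == 1L))
  same <- stratified_split(generate_profile_table(generator_config(seed = 2)),
                           0.8, seed = 6)
  again <- stratified_split(generate_profile_table(generator_config(seed = 2)),
                            0.8, seed = 6)
  expect_identical(same$test$sample_id, again$test$sample_id)
  gd <- data.frame(group = c("a", "b", "c"), site = 1:3,
                   production = "farmed", preparation = "raw",
                   n_samples = c(2L, 4L, 7L))
  tab <- generate_profile_table(generator_config(seed = 3, group_defs = gd))
  for (f in c(0.5, 0.8, 0.95)) {
    sp <- stratified_split(tab, f, seed = 7)
    expect_true(all(table(sp$test$group) >= 1L))
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
  }
  one <- tab[c(1, 3, 4), ]
  expect_error(stratified_split(one, 0.8, seed = 1), ">= 2")
})

test_that("a singleton tuning grid is returned as best", {
  tab <- generate_profile_table(strong_config(seed = 4))
  sp <- stratified_split(tab, 0.8, seed = 1)
  rf <- tune_random_forest(sp$train, mtry_grid = 1, ntree_grid = 10,
                           seed = 2)
  expect_equal(rf$best$mtry, 1L)
  expect_equal(rf$best$ntree, 10L)
  expect_equal(nrow(rf$grid), 1L)
})

test_that("oversized mtry cells are skipped with a warning", {
  tab <- generate_profile_table(strong_config(seed = 4))
  sp <- stratified_split(tab, 0.8, seed = 1)
  expect_warning(
    rf <- tune_random_forest(sp$train, elements = c("P", "S", "Cl"),
                             mtry_grid = c(2, 9), ntree_grid = 10, seed = 2),
    "skipping")
  expect_true(all(rf$grid$mtry == 2L))
})

test_that("strongly separated data reach perfect CV accuracy", {
  tab <- generate_profile_table(strong_config(seed = 6))
  sp <- stratified_split(scale_elements(tab)$table, 0.8, seed = 2)
  rf <- tune_random_forest(sp$train, mtry_grid = 3, ntree_grid = 100,
                           seed = 3)
  expect_gte(max(rf$grid$cv_accuracy), 99)
  ev <- evaluate_classifier(rf, sp$test)
  expect_equal(dim(ev$confusion), c(8L, 8L))
  expect_equal(sum(ev$confusion), 8)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(sp$test$group,
                                             rf$model$classes)))))
})

test_that("evaluation arithmetic and degenerate inputs behave", {
  tab <- generate_profile_table(strong_config(seed = 8))
  sp <- stratified_split(tab, 0.8, seed = 3)
  rf <- tune_random_forest(sp$train, mtry_grid = 3, ntree_grid = 100,
                           seed = 4)
  ev <- evaluate_classifier(rf, sp$test)
  expect_equal(ev$accuracy, 100)
  expect_equal(nrow(ev$misclassified), 0L)
  # corrupt one of the 8 test labels: 7/8 correct = 87.5%
  bad <- sp$test
  bad$group[1] <- setdiff(bad$group, bad$group[1])[1]
  ev2 <- evaluate_classifier(rf, bad)
  expect_equal(ev2$accuracy, 87.5)
  expect_equal(nrow(ev2$misclassified), 1L)
  expect_error(evaluate_classifier(rf, sp$test[0, ]), "empty")
})

test_that("LDA separates, reports resubstitution accuracy, and guards", {
  tab <- scale_elements(generate_profile_table(strong_config(seed = 5)))$table
  sp <- stratified_split(tab, 0.8, seed = 2)
  ld <- fit_lda(sp$train)
  expect_equal(ld$training_accuracy, 100)
  ev <- evaluate_classifier(ld, sp$test)
  expect_gte(ev$accuracy, 87.5)
  single <- sp$train[c(1:4, 5), ]
  expect_error(fit_lda(single), "more than one sample")
  # an exactly duplicated element only triggers the collinearity warning
  dup <- sp$train
  dup$Dup_ppm <- dup$P_ppm
  dup$Dup_err <- dup$P_err
  expect_warning(fit_lda(dup), "collinear")
})

test_that("PCA conserves variance and yields orthogonal loadings", {
  tab <- scale_elements(
    generate_profile_table(generator_config(seed = 9)))$table
  pc <- pca_profile(tab)
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-9)
  L <- pc$loadings
  g <- crossprod(L)
  expect_equal(g, diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-1 data: first component explains everything
  v <- rnorm(20)
  x <- cbind(P = v, S = 2 * v, Cl = -v)
  pr <- pca_profile(profile_from_matrix(x))
  expect_equal(pr$variance_explained[1], 100, tolerance = 1e-9)
  expect_warning(pca_profile(profile_from_matrix(x), n_components = 3),
                 "rank")
})

test_that("NMDS recovers planar configurations and ranks stress by k", {
  set.seed(19)
  xy <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("P", "S")))
  tab <- profile_from_matrix(xy)
  fit2 <- nmds_profile(tab, k = 2, seed = 1)
  expect_lt(fit2$stress, 0.01)
  big <- scale_elements(
    generate_profile_table(generator_config(seed = 10)))$table
  s2 <- nmds_profile(big, k = 2, seed = 2)$stress
  s3 <- nmds_profile(big, k = 3, seed = 2)$stress
  expect_lte(s3, s2 + 1e-6)
  flat <- profile_from_matrix(matrix(5, 4, 2,
                                     dimnames = list(NULL, c("P", "S"))))
  expect_error(nmds_profile(flat, seed = 1), "degenerate")
})

test_that("NMDS keeps cooked-site centroids closer than raw ones", {
  tab <- scale_elements(
    generate_profile_table(generator_config(seed = 1)))$table
  nm <- nmds_profile(tab, k = 2, seed = 3)
  co <- nm$coordinates
  cent <- aggregate(co[, c("NMDS1", "NMDS2")],
                    list(group = co$group, prep = co$preparation), mean)
  cooked <- as.matrix(cent[cent$prep == "cooked", c("NMDS1", "NMDS2")])
  raw <- as.matrix(cent[cent$prep == "raw", c("NMDS1", "NMDS2")])
  d_cc <- mean(dist(cooked))
  d_cr <- mean(as.matrix(dist(rbind(cooked, raw)))[
    seq_len(nrow(cooked)), nrow(cooked) + seq_len(nrow(raw))])
  expect_lt(d_cc, d_cr)
})

test_that("CDA respects the axis bound and detects identical groups", {
  tab <- scale_elements(
    generate_profile_table(generator_config(seed = 11)))$table
  elements <- setdiff(profile_elements(tab), c("As", "Ca", "Fe"))
  cd <- cda_profile(tab, elements = elements)
  expect_lte(cd$n_axes, min(7, length(elements)))
  expect_equal(colnames(cd$structure), paste0("CAN", seq_len(cd$n_axes)))
  # two groups drawn from one distribution: leading eigenvalue near zero
  set.seed(21)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("P", "S")))
  tab2 <- profile_from_matrix(x, group = rep(c("a", "b"), 50))
  cd2 <- cda_profile(tab2)
  expect_lt(cd2$eigenvalues[1], 0.1)
  expect_error(cda_profile(tab2[tab2$group == "a", ]), "2 groups")
})
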