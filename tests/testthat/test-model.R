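# toy feature tables built in code
toy_table <- function(n_per_class = 10, p = 10, sep = 3, seed = 7) {
  set.seed(seed)
  y <- factor(rep(c("A", "B", "C", "D"), each = n_per_class))
  x <- matrix(rnorm(4 * n_per_class * p), ncol = p)
  x[, 1] <- x[, 1] + as.integer(y) * sep
  feature_table(x, y)
}

test_that("feature_table validates its contract", {
  expect_error(feature_table(matrix(NA_real_, 4, 2), c("A", "A", "B", "B")),
               "non-finite")
  expect_error(feature_table(matrix(0, 3, 2), c("A", "A", "B")),
               "at least 2 samples")
  expect_error(feature_table(matrix(0, 3, 2), c("A", "A")), "one label")
})

test_that("stratified split reproduces the 92/24 protocol", {
  tab <- toy_table(29, p = 3)        # 116 samples, 29 per class
  sp <- stratified_split(tab, 0.8, seed = 1)
  expect_equal(nrow(sp$train$matrix), 92)
  expect_equal(nrow(sp$test$matrix), 24)
  expect_equal(unname(table(sp$train$labels)), rep(23L, 4),
               ignore_attr = TRUE)
  # disjoint, exhaustive, reproducible
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:116)
  sp2 <- stratified_split(tab, 0.8, seed = 1)
  expect_identical(sp$train_idx, sp2$train_idx)

  small <- toy_table(5, p = 2, seed = 2)
  idx <- stratified_split(subset_10 <- feature_table(
    small$matrix[c(1:5, 11:15), ], small$labels[c(1:5, 11:15)]), 0.8,
    seed = 3)
  expect_equal(nrow(idx$train$matrix), 8)
  expect_equal(nrow(idx$test$matrix), 2)
})

test_that("degenerate searches return the only candidate", {
  tab <- toy_table(5, p = 4)
  one_cfg <- search_space(iterations = 1, folds = 2,
                          kernels = "radial", C_range = c(2.6, 2.6),
                          gamma_range = c(0.002, 0.002))
  g <- luster_grader(tab, model_kind = "svm", space = one_cfg, seed = 4)
  expect_equal(g$best_params$kernel, "radial")
  expect_equal(g$best_params$cost, 2.6)
  expect_equal(g$best_params$gamma, 0.002)
  # constant space: many iterations still select the same configuration
  g2 <- luster_grader(tab, model_kind = "svm", space = one_cfg, n_iter = 20,
                      seed = 4)
  expect_equal(g2$best_params, g$best_params)
})

test_that("separable clusters reach perfect cross-validated accuracy", {
  tab <- toy_table(8, p = 5, sep = 25, seed = 5)
  g <- luster_grader(tab, model_kind = "svm",
                     space = search_space(iterations = 15, folds = 5),
                     seed = 6)
  expect_equal(g$cv_accuracy, 1.0)
})

test_that("metrics follow the confusion-matrix definitions", {
  lev <- c("A", "B", "C", "D")
  truth <- factor(rep(lev, each = 5), lev)
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  # one A mislabeled as B
  pred <- truth; pred[1] <- "B"
  m <- classification_metrics(truth, pred)
  expect_equal(m$accuracy, 19 / 20)
  expect_equal(m$recall, mean(c(4 / 5, 1, 1, 1)))
  expect_equal(m$precision, mean(c(1, 5 / 6, 1, 1)))
  expect_equal(m$f1, mean(c(2 * (4 / 5) / (9 / 5),
                            2 * (5 / 6) / (11 / 6), 1, 1)))
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)

  # collapsing onto one class on a balanced set
  allA <- classification_metrics(truth, factor(rep("A", 20), lev))
  expect_equal(allA$accuracy, 0.25)
  expect_equal(allA$recall, 0.25)
})

test_that("repeated experiments aggregate and reproduce deterministically", {
  tab <- toy_table(8, p = 5, sep = 10)
  space <- search_space(iterations = 3, folds = 3)
  one <- repeated_experiment(tab, "rfc", n_runs = 1, space = space, seed = 9)
  expect_equal(one$aggregate$max, one$aggregate$min)
  expect_equal(one$aggregate$max, one$aggregate$avg)
  expect_true(all(one$per_run$test_accuracy >= 0 &
                  one$per_run$test_accuracy <= 1))

  two_a <- repeated_experiment(tab, "svm", n_runs = 2, space = space,
                               seed = 10)
  two_b <- repeated_experiment(tab, "svm", n_runs = 2, space = space,
                               seed = 10)
  expect_identical(two_a$per_run, two_b$per_run)
})

test_that("PCA reduction fits on train only and obeys the identities", {
  set.seed(11)
  latent <- matrix(rnorm(40), 20, 2)
  x <- latent %*% matrix(rnorm(20), 2, 10)      # exact 2-D subspace
  tab <- feature_table(x, rep(c("A", "B"), 10))
  r <- pca_reduce(tab$matrix, k = 6, scale = FALSE)
  expect_equal(sum(r$model$explained_variance_ratio[1:2]), 1,
               tolerance = 1e-9)
  expect_lt(max(abs(r$model$explained_variance_ratio[3:10])), 1e-9)
  # train scores are centered; the train mean projects to the origin
  expect_lt(max(abs(colMeans(r$train_scores))), 1e-9)
  center <- matrix(colMeans(x), 1)
  expect_lt(max(abs(pca_reduce(x, center, k = 6,
                               scale = FALSE)$test_scores)), 1e-9)
  # orthonormal loadings
  expect_equal(crossprod(r$model$rotation), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)

  # discarded variance equals the reconstruction error (standardized data)
  set.seed(12)
  xr <- matrix(rnorm(200), 20, 10)
  rr <- pca_reduce(xr, k = 4)
  xs <- scale(xr, center = rr$model$center, scale = rr$model$scale)
  recon <- rr$train_scores %*% t(rr$model$rotation)
  lambda <- rr$model$explained_variance_ratio *
    sum(apply(xs, 2, function(cc) sum(cc^2))) / (nrow(xs) - 1)
  expect_equal(sum((xs - recon)^2) / (nrow(xs) - 1), sum(lambda[5:10]),
               tolerance = 1e-8)

  expect_error(pca_reduce(xr, k = 60), "exceeds")
})

test_that("backward elimination keeps the informative feature", {
  set.seed(13)
  y <- factor(rep(c("A", "B"), each = 12))
  x <- cbind(as.integer(y) + rnorm(24, sd = 0.05), rnorm(24), rnorm(24))
  colnames(x) <- c("sig_1", "noise_1", "noise_2")
  tab <- feature_table(x, y)
  mask <- sequential_select(tab, "rfc", fraction = 1 / 3, folds = 3,
                            seed = 14)
  expect_equal(unname(mask$selected), c(TRUE, FALSE, FALSE))
  expect_equal(sum(mask$family_counts), sum(mask$selected))

  all_kept <- sequential_select(tab, "rfc", fraction = 1, seed = 15)
  expect_true(all(all_kept$selected))
})

test_that("signal-bearing families survive selection preferentially", {
  # 24 features named after six real families, signal only in LAWS
  nms <- feature_names()
  fam <- feature_families(nms)
  pick <- unlist(lapply(c("GLCM", "LBP", "Gabor", "HOG", "LAWS", "CSAC"),
                        function(f) which(fam == f)[1:4]))
  set.seed(16)
  y <- factor(rep(c("A", "B", "C", "D"), each = 10))
  x <- matrix(rnorm(40 * 24), 40, 24)
  laws_cols <- which(startsWith(nms[pick], "laws"))
  for (j in laws_cols[1:3]) x[, j] <- x[, j] + as.integer(y) * 2
  colnames(x) <- nms[pick]
  tab <- feature_table(x, y)
  mask <- sequential_select(tab, "svm", fraction = 0.2, folds = 5, seed = 17)
  share <- mask$family_counts / 4
  expect_true(all(share["LAWS"] > share[setdiff(names(share), "LAWS")]))
})
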