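# Configuration grid, stratified cross-validation, finalization, and
# bootstrap bias correction.

small_grid <- function() {
  make_config_grid(alpha = 0.05, max_features = 10, ridge_lambda = c(0.5, 1),
                   svm_cost = 1, svm_kernel = "linear", rf_max_depth = 0)
}

# separable two-class feature matrix with planted mean shifts
planted_matrix <- function(n_per_class = 40, p = 25, shift = 1.5) {
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("secretory", "cytoplasmic"), each = n_per_class)
  X[y == "secretory", 1:5] <- X[y == "secretory", 1:5] + shift
  list(X = X, y = y)
}

test_that("the configuration grid is the deterministic cartesian product", {
  g <- make_config_grid(alpha = c(0.01, 0.05), max_features = c(25, 50),
                        ridge_lambda = 1, svm_cost = 1, svm_kernel = "linear")
  # 2 alpha x 2 cut-offs x (1 ridge + 1 svm + 2 forests) = 16
  expect_length(g, 16)
  expect_identical(vapply(g, `[[`, "", "id"),
                   vapply(make_config_grid(alpha = c(0.01, 0.05),
                                           max_features = c(25, 50),
                                           ridge_lambda = 1, svm_cost = 1,
                                           svm_kernel = "linear"),
                          `[[`, "", "id"))
  lin <- make_config_grid(linear_only = TRUE)
  fams <- unique(vapply(lin, `[[`, "", "family"))
  expect_setequal(fams, c("ridge", "svm-linear"))
  expect_error(make_config_grid(alpha = numeric(0), ridge_lambda = numeric(0),
                                svm_cost = numeric(0), rf_num_trees = integer(0)),
               "empty")
})

test_that("stratified folds are balanced and reproducible", {
  y <- rep(c("secretory", "cytoplasmic"), times = c(33, 67))
  f1 <- stratified_folds(y, K = 10, seed = 5)
  f2 <- stratified_folds(y, K = 10, seed = 5)
  expect_identical(f1, f2)
  pos <- y == "secretory"
  for (k in 1:10) {
    expect_lte(abs(sum(pos[f1 == k]) - 3.3), 1)  # class balance within 1
  }
  expect_error(stratified_folds(rep(c("secretory", "cytoplasmic"),
                                    times = c(4, 50)), K = 10), "smaller K")
})

test_that("cross-validation separates planted classes and counts fits", {
  set.seed(301)
  d <- planted_matrix()
  cv <- cross_validate(d$X, d$y, small_grid(), K = 5, seed = 3)
  expect_gte(max(cv$mean_auc), 0.95)
  expect_equal(cv$n_fits, length(small_grid()) * 5)
  expect_true(all(!is.na(cv$scores)))  # every sample scored once per config
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(303)
  d <- planted_matrix(n_per_class = 100)
  yperm <- sample(d$y)
  grid <- make_config_grid(alpha = 0.05, max_features = 10, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  cv <- cross_validate(d$X, yperm, grid, K = 5, seed = 7)
  expect_lt(abs(cv$mean_auc[1] - 0.5), 0.1)
})

test_that("fold models never see held-out rows", {
  set.seed(305)
  d <- planted_matrix(n_per_class = 30, p = 10)
  grid <- make_config_grid(alpha = 0.05, max_features = 5, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  cv1 <- cross_validate(d$X, d$y, grid, K = 5, seed = 9, keep_models = TRUE)
  # corrupt fold 1's held-out rows: the model scored on fold 1 is fitted on
  # the other folds only, so its signature, standardization constants and
  # coefficients must not move
  Xc <- d$X
  Xc[cv1$fold == 1, ] <- matrix(rnorm(sum(cv1$fold == 1) * 10) * 50,
                                ncol = 10)
  cv2 <- cross_validate(Xc, d$y, grid, K = 5, seed = 9, keep_models = TRUE)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$models[[1]][[1]], cv2$models[[1]][[1]])
})

test_that("finalization picks the dominating configuration and rescoring works", {
  set.seed(307)
  d <- planted_matrix()
  grid <- small_grid()
  cv <- cross_validate(d$X, d$y, grid, K = 5, seed = 11)
  model <- select_and_finalize(d$X, d$y, cv)
  expect_equal(model$provenance$config$id,
               grid[[which.max(cv$mean_auc)]]$id)
  expect_equal(model$provenance$n_fits, cv$n_fits + 1L)
  pr <- score_model(model, d$X)
  expect_true(all(pr > 0 & pr < 1))
  expect_gte(auc(pr, d$y), 0.95)
  # ties resolve to the earlier configuration
  cv_tie <- cv
  cv_tie$mean_auc <- rep(0.8, length(grid))
  m_tie <- select_and_finalize(d$X, d$y, cv_tie)
  expect_equal(m_tie$provenance$config$id, grid[[1]]$id)
})

test_that("a single-configuration grid needs no bias correction", {
  set.seed(309)
  d <- planted_matrix(n_per_class = 50, shift = 0.8)
  grid <- make_config_grid(alpha = 0.05, max_features = 10, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  cv <- cross_validate(d$X, d$y, grid, K = 5, seed = 13)
  bbc <- bbc_correct(cv, B = 400, seed = 13)
  pooled <- auc(cv$scores[, 1], cv$y)
  expect_lt(abs(bbc$corrected_auc - pooled), 0.03)  # Monte-Carlo error only
})

test_that("bias correction is deterministic given the seed and conservative", {
  set.seed(311)
  d <- planted_matrix()
  cv <- cross_validate(d$X, d$y, small_grid(), K = 5, seed = 15)
  b1 <- bbc_correct(cv, B = 200, seed = 21)
  b2 <- bbc_correct(cv, B = 200, seed = 21)
  expect_identical(b1, b2)
  expect_lte(b1$corrected_auc, max(cv$mean_auc) + 1e-12)
  expect_length(b1$ci, 2)
  expect_lte(b1$ci[1], b1$corrected_auc)
  expect_gte(b1$ci[2], b1$corrected_auc)
})

test_that("the full pipeline fits exactly N x K + 1 models", {
  set.seed(313)
  d <- planted_matrix(n_per_class = 30)
  grid <- small_grid()
  model <- train_model(d$X, d$y, grid = grid, K = 5, seed = 17, B = 50)
  expect_equal(model$provenance$n_fits, length(grid) * 5 + 1L)
  expect_false(is.na(model$performance$corrected_auc))
})

test_that("models round-trip through JSON with identical scores", {
  set.seed(315)
  d <- planted_matrix(n_per_class = 30)
  grid <- make_config_grid(alpha = 0.05, max_features = 10,
                           ridge_lambda = 1, svm_cost = 1,
                           svm_kernel = c("linear", "radial"))
  for (take in c(1, 3)) {  # a linear and a kernel configuration
    cv <- cross_validate(d$X, d$y, grid[take], K = 5, seed = 19)
    model <- select_and_finalize(d$X, d$y, cv)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(model, path)
    back <- read_model(path)
    expect_equal(score_model(back, d$X), score_model(model, d$X),
                 tolerance = 1e-12)
    expect_equal(back$threshold, model$threshold)
    expect_equal(back$features, model$features)
  }
})
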