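# Model scoring, view classification, cleavage estimation, and the combined
# four-way decision.

test_that("linear scoring follows the logistic transform of z", {
  m <- linear_model_fixture(c(f1 = 1, f2 = -1))
  X0 <- matrix(0, 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(score_model(m, X0)), 0.5)
  X <- matrix(c(3, 1), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(score_model(m, X)), 1 / (1 + exp(-2)))
  expect_error(score_model(m, matrix(0, 1, 1, dimnames = list(NULL, "f1"))),
               "missing feature.*f2")
})

test_that("scoring matches a spreadsheet-style evaluation of z", {
  # hand-built 3-feature model with nontrivial standardization constants
  m <- linear_model_fixture(c(a = 0.7, b = -1.2, c = 2.0), intercept = 0.3,
                            center = c(a = 1, b = -2, c = 0.5),
                            scale = c(a = 2, b = 0.5, c = 1))
  set.seed(401)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  manual <- apply(X, 1, function(x) {
    z <- 0.3 + 0.7 * (x["a"] - 1) / 2 - 1.2 * (x["b"] + 2) / 0.5 +
      2.0 * (x["c"] - 0.5) / 1
    1 / (1 + exp(-z))
  })
  expect_equal(unname(score_model(m, X)), unname(manual), tolerance = 1e-12)
})

test_that("scores move monotonically with positively weighted features", {
  m <- linear_model_fixture(c(f1 = 2, f2 = -0.5))
  base <- matrix(c(0.2, 0.1), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  up <- base
  up[1, "f1"] <- up[1, "f1"] + 0.3
  expect_gt(score_model(m, up), score_model(m, base))
  dn <- base
  dn[1, "f2"] <- dn[1, "f2"] + 0.3
  expect_lt(score_model(m, dn), score_model(m, base))
})

test_that("classification uses the stored threshold with >= as positive", {
  set.seed(403)
  d <- generate_dataset(generator_spec(40, 40, seed = 31, effect = 1.5))
  grid <- make_config_grid(alpha = 0.05, max_features = 10, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  m <- train_secretion_model(d, view = "mature",
                             groups = c("bin_individual", "kmer1"),
                             grid = grid, K = 5, seed = 31, B = 50)
  cls <- classify_records(d, m)
  expect_identical(cls$positive, cls$probability >= m$threshold)
  expect_gte(auc(cls$probability, d$label), 0.9)
  expect_error(classify_records(d, m, view = "preprotein"), "view")
})

test_that("an empty-signature fallback model scores a constant probability", {
  set.seed(405)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("secretory", "cytoplasmic"), 30)
  grid <- make_config_grid(alpha = 1e-10, max_features = 5, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  cv <- cross_validate(X, y, grid, K = 5, seed = 33)
  m <- select_and_finalize(X, y, cv)
  expect_length(m$features, 0)
  pr <- score_model(m, X)
  expect_equal(length(unique(pr)), 1L)
})

test_that("cleavage estimation honors the scan range and tie rules", {
  set.seed(407)
  d <- generate_dataset(generator_spec(30, 30, seed = 35, effect = 1.5))
  grid <- make_config_grid(alpha = 0.05, max_features = 10, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  m <- train_secretion_model(d, view = "mature",
                             groups = c("bin_individual", "kmer1"),
                             grid = grid, K = 5, seed = 35, B = 50)
  seq1 <- d$seq[1]
  expect_equal(estimate_cleavage(m, seq1, range = 20:20)$position, 20)
  # flat (empty-signature) model: every candidate scores the same, the
  # smallest position wins
  flat <- m
  flat$features <- character(0)
  flat$payload <- list(type = "linear", family = "ridge",
                       coef = stats::setNames(numeric(0), character(0)),
                       intercept = 0)
  expect_equal(estimate_cleavage(flat, seq1, range = 15:40)$position, 15)
  expect_error(estimate_cleavage(m, "MKTA", range = 15:40), "shorter")
})

test_that("the four verdicts partition all outcomes", {
  # two stub models whose thresholds straddle the constant fallback scores
  mk_stub <- function(view, W, prob) {
    structure(list(
      features = character(0), center = numeric(0), scale = numeric(0),
      payload = list(type = "linear", family = "ridge",
                     coef = stats::setNames(numeric(0), character(0)),
                     intercept = qlogis(prob)),
      threshold = 0.5,
      performance = list(), signature_alternates = list(),
      provenance = list(),
      encoder = list(view = view, W = W, groups = "kmer1",
                     cpseaac_lam = 5L, cpseaac_w = 0.05, energy_P = NULL)
    ), class = "trained_model")
  }
  recs <- seq_set(c("a", "b"), c(random_seq(120), random_seq(150)))
  for (p_pre in c(0.2, 0.8)) {
    for (p_mat in c(0.2, 0.8)) {
      pred <- predict_combined(recs, mk_stub("preprotein", 40, p_pre),
                               mk_stub("mature", 60, p_mat))
      want <- if (p_pre >= 0.5 && p_mat >= 0.5) "secretory-preprotein"
              else if (p_pre >= 0.5) "non-secretory"
              else if (p_mat >= 0.5) "mature"
              else "cytoplasmic"
      expect_equal(pred$verdict, rep(want, 2))
      expect_identical(is.na(pred$est_cleavage), rep(p_pre < 0.5, 2))
    }
  }
})

test_that("prediction output is deterministic to the byte", {
  set.seed(409)
  d <- generate_dataset(generator_spec(15, 15, seed = 37, effect = 1.5))
  grid <- make_config_grid(alpha = 0.05, max_features = 5, ridge_lambda = 1,
                           svm_cost = numeric(0), rf_num_trees = integer(0))
  pre <- train_secretion_model(d, view = "preprotein", W = 40,
                               groups = "bin_individual",
                               grid = grid, K = 3, seed = 37, B = 20)
  mat <- train_secretion_model(d, view = "mature", W = 60,
                               groups = c("bin_individual", "kmer1"),
                               grid = grid, K = 3, seed = 37, B = 20)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(predict_combined(d, pre, mat), p1)
  write_predictions(predict_combined(d, pre, mat), p2)
  expect_identical(readLines(p1), readLines(p2))
})
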