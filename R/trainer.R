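# Model-selection pipeline: configuration grid, stratified K-fold
# cross-validation, best-configuration selection, final model on all data,
# and bootstrap bias-corrected performance estimation. A run fits exactly
# N x K + 1 models (N configurations, K folds, plus the final model).

#' Build the configuration grid
#'
#' A configuration pairs a selector spec (significance level `alpha`,
#' signature cut-off `max_features`) with a classifier spec (family and
#' hyper-parameter values). The grid is the cartesian product of the selector
#' values with the listed classifier settings, in deterministic order
#' (selectors outer, classifiers inner).
#'
#' @param alpha significance levels for the selector.
#' @param max_features signature size cut-offs (default `c(25, 50)`).
#' @param ridge_lambda ridge-logistic penalty values.
#' @param svm_cost SVM cost values.
#' @param svm_kernel SVM kernels among `"linear"`, `"polynomial"` (degree 3),
#'   `"radial"`.
#' @param rf_num_trees random-forest sizes.
#' @param rf_max_depth random-forest depth limits (0 = unlimited).
#' @param linear_only keep only families yielding humanly interpretable
#'   linear models (ridge-logistic and linear SVM).
#' @return list of configuration lists, each with `id`, `alpha`,
#'   `max_features`, `family`, and family-specific parameters.
#' @export
make_config_grid <- function(alpha = c(0.01, 0.05), max_features = c(25L, 50L),
                             ridge_lambda = c(0.1, 1, 10),
                             svm_cost = c(0.1, 1, 10),
                             svm_kernel = c("linear", "polynomial", "radial"),
                             rf_num_trees = 500L, rf_max_depth = c(0L, 8L),
                             linear_only = FALSE) {
  classifiers <- list()
  for (l in ridge_lambda) {
    classifiers[[length(classifiers) + 1L]] <-
      list(family = "ridge", lambda = l, tag = paste0("ridge_l", l))
  }
  for (kern in svm_kernel) {
    if (linear_only && kern != "linear") next
    for (cost in svm_cost) {
      classifiers[[length(classifiers) + 1L]] <-
        list(family = paste0("svm-", kern), cost = cost,
             tag = paste0("svm-", kern, "_c", cost))
    }
  }
  if (!linear_only) {
    for (nt in rf_num_trees) {
      for (d in rf_max_depth) {
        classifiers[[length(classifiers) + 1L]] <-
          list(family = "rf", num_trees = nt, max_depth = d,
               tag = paste0("rf_t", nt, "_d", d))
      }
    }
  }
  grid <- list()
  for (a in alpha) {
    for (mf in max_features) {
      for (cl in classifiers) {
        cfg <- c(list(alpha = a, max_features = as.integer(mf)), cl)
        cfg$id <- paste0("a", a, "_f", mf, "_", cl$tag)
        cfg$tag <- NULL
        grid[[length(grid) + 1L]] <- cfg
      }
    }
  }
  if (length(grid) == 0L) stop("empty configuration grid")
  grid
}

# ---- classifier fits -------------------------------------------------------

# Fit one classifier on an already-standardized matrix of selected features.
# Returns a payload scoring via .score_payload(). Linear payloads (ridge,
# linear SVM, and small-signature fallbacks) carry explicit coefficients and
# score through the logistic transform of z = intercept + sum c_i x_i.
.fit_classifier <- function(Xs, y01, cfg, seed = 1L) {
  p <- ncol(Xs)
  if (p == 0L) {
    pr <- min(max(mean(y01), 1e-6), 1 - 1e-6)
    return(list(type = "linear", family = cfg$family,
                coef = stats::setNames(numeric(0), character(0)),
                intercept = stats::qlogis(pr)))
  }
  if (cfg$family == "ridge") {
    if (p == 1L) {
      # glmnet needs >= 2 predictors; an unpenalized logistic fit stands in
      fit <- suppressWarnings(
        stats::glm(y01 ~ Xs, family = stats::binomial())
      )
      cf <- stats::coef(fit)
      cf[is.na(cf)] <- 0
      return(list(type = "linear", family = "ridge",
                  coef = stats::setNames(cf[-1], colnames(Xs)),
                  intercept = unname(cf[1])))
    }
    fit <- glmnet::glmnet(Xs, y01, family = "binomial", alpha = 0,
                          lambda = cfg$lambda, standardize = FALSE)
    cf <- as.numeric(stats::coef(fit, s = cfg$lambda))
    return(list(type = "linear", family = "ridge",
                coef = stats::setNames(cf[-1], colnames(Xs)),
                intercept = cf[1]))
  }
  if (startsWith(cfg$family, "svm-")) {
    kern <- sub("^svm-", "", cfg$family)
    yf <- factor(y01, levels = c(0, 1))
    fit <- e1071::svm(x = Xs, y = yf, kernel = kern, cost = cfg$cost,
                      degree = 3L, scale = FALSE)
    if (kern == "linear") {
      w <- drop(crossprod(fit$SV, fit$coefs))
      b <- -fit$rho
      z <- drop(Xs %*% w) + b
      if (stats::cov(z, y01) < 0) {
        w <- -w
        b <- -b
      }
      return(list(type = "linear", family = cfg$family,
                  coef = stats::setNames(w, colnames(Xs)), intercept = b))
    }
    d <- attr(stats::predict(fit, Xs, decision.values = TRUE),
              "decision.values")[, 1]
    orient <- sign(stats::cov(d, y01))
    if (orient == 0) orient <- 1
    return(list(type = "svm", family = cfg$family, fit = fit,
                orient = orient, features = colnames(Xs)))
  }
  if (cfg$family == "rf") {
    df <- as.data.frame(Xs)
    fit <- ranger::ranger(
      x = df, y = factor(y01, levels = c(0, 1)),
      num.trees = cfg$num_trees,
      max.depth = if (cfg$max_depth == 0L) NULL else cfg$max_depth,
      probability = TRUE, seed = seed, num.threads = 1L
    )
    return(list(type = "rf", family = "rf", fit = fit,
                features = colnames(Xs)))
  }
  stop("unknown classifier family: ", cfg$family)
}

# Score a payload on standardized features; always returns values in (0, 1).
# SVM decision values are squashed through the logistic so cross-validated,
# threshold-setting and prediction scores share one scale.
.score_payload <- function(payload, Xs) {
  if (payload$type == "linear") {
    z <- rep(payload$intercept, nrow(Xs))
    if (length(payload$coef) > 0L) {
      z <- z + drop(Xs[, names(payload$coef), drop = FALSE] %*% payload$coef)
    }
    return(stats::plogis(z))
  }
  if (payload$type == "svm") {
    d <- attr(stats::predict(payload$fit,
                             Xs[, payload$features, drop = FALSE],
                             decision.values = TRUE), "decision.values")[, 1]
    return(stats::plogis(payload$orient * d))
  }
  if (payload$type == "rf") {
    pr <- stats::predict(payload$fit,
                         data = as.data.frame(Xs[, payload$features,
                                                 drop = FALSE]),
                         num.threads = 1L)$predictions[, "1"]
    return(pmin(pmax(pr, 1e-6), 1 - 1e-6))
  }
  stop("unknown payload type")
}

# standardization constants from a training matrix; zero-variance columns
# get sd 1 so they standardize to constant 0
.standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

.apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

#' Stratified fold assignment
#'
#' Partitions samples into K folds preserving the class proportions within
#' one sample of the global proportions. Deterministic given the seed.
#'
#' @param y binary labels.
#' @param K number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment of length `length(y)`.
#' @export
stratified_folds <- function(y, K = 10L, seed = 1L) {
  pos <- .as_positive(y)
  if (min(sum(pos), sum(!pos)) < K) {
    stop("smallest class has fewer members than K; use a smaller K")
  }
  folds <- integer(length(y))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    folds[sample(idx)] <- rep_len(seq_len(K), length(idx))
  }
  folds
}

#' Cross-validate a configuration grid
#'
#' For each configuration and each held-out fold, standardization constants
#' and the feature signature are computed on the training folds only, the
#' classifier is fitted, and the held-out fold is scored. Configurations
#' sharing a selector spec reuse the same per-fold signature. Out-of-fold
#' scores are pooled (each sample scored exactly once per configuration) and
#' each configuration's CV AUC is the mean of its per-fold AUCs.
#'
#' @param X feature matrix (samples x named features).
#' @param y binary labels (positive = secretory).
#' @param grid list of configurations from [make_config_grid()].
#' @param K number of folds.
#' @param seed run seed; drives fold assignment and forest randomness.
#' @param keep_models also return the per-fold fitted payloads (used to
#'   verify that a fold's model is independent of its held-out rows).
#' @return a `cv_result` list: `scores` (samples x configurations out-of-fold
#'   score matrix), `mean_auc`, `fold`, `grid`, `K`, `seed`, `n_fits`, and
#'   `models` (K x N list) when `keep_models` is `TRUE`.
#' @export
cross_validate <- function(X, y, grid, K = 10L, seed = 1L,
                           keep_models = FALSE) {
  y01 <- as.numeric(.as_positive(y))
  n <- nrow(X)
  N <- length(grid)
  folds <- stratified_folds(y01, K = K, seed = seed)
  sel_key <- vapply(grid, function(g) paste0(g$alpha, "|", g$max_features), "")
  scores <- matrix(NA_real_, n, N,
                   dimnames = list(rownames(X),
                                   vapply(grid, `[[`, "", "id")))
  n_fits <- 0L
  models <- if (keep_models) vector("list", K)
  for (k in seq_len(K)) {
    tr <- folds != k
    std <- .standardizer(X[tr, , drop = FALSE])
    Xtr <- .apply_standardizer(X[tr, , drop = FALSE], std)
    Xte <- .apply_standardizer(X[!tr, , drop = FALSE], std)
    sigs <- new.env(parent = emptyenv())
    for (j in seq_len(N)) {
      cfg <- grid[[j]]
      key <- sel_key[j]
      if (is.null(sigs[[key]])) {
        sigs[[key]] <- select_features(Xtr, y01[tr], cfg)$signature
      }
      sig <- sigs[[key]]
      payload <- .fit_classifier(Xtr[, sig, drop = FALSE], y01[tr], cfg,
                                 seed = seed + 131L * k + j)
      n_fits <- n_fits + 1L
      scores[!tr, j] <- .score_payload(payload, Xte[, sig, drop = FALSE])
      if (keep_models) {
        models[[k]][[j]] <- list(signature = sig, payload = payload,
                                 center = std$center, scale = std$scale)
      }
    }
  }
  fold_auc <- matrix(NA_real_, K, N)
  for (k in seq_len(K)) {
    for (j in seq_len(N)) {
      fold_auc[k, j] <- auc(scores[folds == k, j], y01[folds == k])
    }
  }
  structure(list(scores = scores, mean_auc = colMeans(fold_auc),
                 fold_auc = fold_auc, fold = folds, grid = grid, K = K,
                 seed = seed, n_fits = n_fits, y = y01, models = models),
            class = "cv_result")
}

#' Select the best configuration and train the final model on all data
#'
#' Picks the configuration with the highest mean CV AUC (ties resolve to the
#' earlier configuration), refits selection and classifier on the complete
#' standardized dataset, and sets the decision threshold by
#' [equal_error_threshold()] on the winning configuration's pooled
#' out-of-fold scores.
#'
#' @param X feature matrix used for cross-validation.
#' @param y binary labels.
#' @param cv a `cv_result` from [cross_validate()].
#' @return a `trained_model` list: `features`, `center`, `scale`, `payload`,
#'   `threshold`, `performance` (`cv_auc`, `corrected_auc`, `ci`),
#'   `signature_alternates`, `provenance`.
#' @export
select_and_finalize <- function(X, y, cv) {
  y01 <- as.numeric(.as_positive(y))
  best <- which.max(cv$mean_auc)
  cfg <- cv$grid[[best]]
  std <- .standardizer(X)
  Xs <- .apply_standardizer(X, std)
  sel <- select_features(Xs, y01, cfg)
  sig <- sel$signature
  payload <- .fit_classifier(Xs[, sig, drop = FALSE], y01, cfg,
                             seed = cv$seed + 99991L)
  threshold <- equal_error_threshold(cv$scores[, best], y01)
  structure(list(
    features = sig,
    center = std$center[sig],
    scale = std$scale[sig],
    payload = payload,
    threshold = threshold,
    performance = list(cv_auc = unname(cv$mean_auc[best]),
                       corrected_auc = NA_real_, ci = c(NA_real_, NA_real_)),
    signature_alternates = sel$alternates,
    provenance = list(config = cfg, seed = cv$seed, K = cv$K,
                      n_configs = length(cv$grid), n_fits = cv$n_fits + 1L)
  ), class = "trained_model")
}

#' Bootstrap bias correction of the selected configuration's performance
#'
#' Selecting the best of many configurations makes its cross-validated AUC
#' optimistic. For each of `B` bootstrap resamples of the sample indices, the
#' configuration maximizing AUC on the in-bag indices is chosen and evaluated
#' on the out-of-bag indices; the corrected estimate is the mean of the B
#' out-of-bag AUCs and the confidence interval is the percentile interval.
#' Replicates whose out-of-bag set lacks a class are redrawn (up to 50
#' times), then skipped with a count.
#'
#' @param cv a `cv_result` with a complete out-of-fold score matrix.
#' @param y binary labels (defaults to the labels stored in `cv`).
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return list with `corrected_auc`, `ci`, `raw_best_auc`, `skipped`.
#' @export
bbc_correct <- function(cv, y = cv$y, B = 1000L, seed = 1L, conf = 0.95) {
  y01 <- as.numeric(.as_positive(y))
  S <- cv$scores
  n <- nrow(S)
  set.seed(seed)
  vals <- numeric(0)
  skipped <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(50L)) {
      ib <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(ib))
      if (length(unique(y01[ib])) == 2L && length(unique(y01[oob])) == 2L) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    in_auc <- apply(S[ib, , drop = FALSE], 2L, auc, labels = y01[ib])
    best <- which.max(in_auc)
    vals <- c(vals, auc(S[oob, best], y01[oob]))
  }
  a <- (1 - conf) / 2
  list(corrected_auc = mean(vals),
       ci = unname(stats::quantile(vals, c(a, 1 - a))),
       raw_best_auc = max(cv$mean_auc), skipped = skipped)
}

#' Run the full model-selection pipeline on a feature matrix
#'
#' Convenience wrapper: [cross_validate()] over the grid, [bbc_correct()],
#' then [select_and_finalize()]. The returned model carries the
#' bias-corrected AUC and its confidence interval, and a fit counter equal to
#' `N x K + 1`.
#'
#' @inheritParams cross_validate
#' @param B bootstrap resamples for bias correction.
#' @return a `trained_model`; the `cv_result` is attached as attribute `cv`.
#' @export
train_model <- function(X, y, grid = make_config_grid(), K = 10L, seed = 1L,
                        B = 1000L) {
  cv <- cross_validate(X, y, grid, K = K, seed = seed)
  bbc <- bbc_correct(cv, B = B, seed = seed)
  model <- select_and_finalize(X, y, cv)
  model$performance$corrected_auc <- bbc$corrected_auc
  model$performance$ci <- bbc$ci
  structure(model, cv = cv)
}

#' Train a secretion classifier from sequence records
#'
#' End-to-end training: extracts windows for the requested view, builds the
#' feature matrix, runs [train_model()], and stores the encoder settings
#' (view, window length, groups, pseudo-amino-acid parameters, energy
#' matrix) in the model so prediction reproduces the training pipeline.
#'
#' @param records a labeled [seq_set()] (labels `secretory`/`cytoplasmic`).
#' @param view `"preprotein"` (window from position 1) or `"mature"` (window
#'   from `cleavage_pos + 3`).
#' @param W window length; defaults to 84 for preprotein, 80 for mature.
#' @param groups feature groups, see [build_feature_matrix()].
#' @param energy_model energy model for the `fc` group.
#' @param grid,K,seed,B passed to [train_model()].
#' @param cpseaac_lam,cpseaac_w pseudo-amino-acid composition parameters.
#' @return a `trained_model` with encoder provenance.
#' @export
train_secretion_model <- function(records, view = c("preprotein", "mature"),
                                  W = NULL, groups = "all",
                                  energy_model = NULL,
                                  grid = make_config_grid(), K = 10L,
                                  seed = 1L, B = 1000L,
                                  cpseaac_lam = 5L, cpseaac_w = 0.05) {
  view <- match.arg(view)
  keep <- records$label %in% c("secretory", "cytoplasmic")
  records <- records[keep, , drop = FALSE]
  if (view == "mature") {
    # cytoplasmic records have no cleavage site: their "mature view" window
    # starts at position 1 (the sequence is its own mature domain)
    recs <- records
    recs$cleavage_pos[recs$label == "cytoplasmic"] <- -2L
    if (is.null(W)) W <- 80L
    win <- extract_window(recs, "mature", W = W)
  } else {
    if (is.null(W)) W <- 84L
    win <- extract_window(records, "preprotein", W = W)
  }
  if (identical(groups, "all")) groups <- feature_groups()
  if ("fc" %in% groups && is.null(energy_model)) {
    energy_model <- default_energy_model()
  }
  X <- build_feature_matrix(win, groups = groups, energy_model = energy_model,
                            cpseaac_lam = cpseaac_lam, cpseaac_w = cpseaac_w)
  y <- records$label
  model <- train_model(X, y, grid = grid, K = K, seed = seed, B = B)
  model$encoder <- list(view = view, W = W, groups = groups,
                        cpseaac_lam = cpseaac_lam, cpseaac_w = cpseaac_w,
                        energy_P = if ("fc" %in% groups) energy_model$P)
  model
}
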