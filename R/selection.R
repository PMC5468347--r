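# SES-lite: forward-backward feature selection driven by conditional
# independence tests (Fisher-z on partial correlations), with recording of
# statistically equivalent substitutes.

# two-sided Fisher-z p-value for a (partial) correlation r with ncond
# conditioning variables
.fisher_z_p <- function(r, n, ncond = 0L) {
  df <- n - ncond - 3
  if (df < 1) return(rep(1, length(r)))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  2 * stats::pnorm(-abs(atanh(r)) * sqrt(df))
}

#' Forward-backward selection with statistically equivalent signatures
#'
#' A light re-implementation of statistically-equivalent-signature selection.
#' Features are first screened by unconditional association with the outcome
#' (Fisher-z test on the correlation); the strongest `screen` candidates form
#' the working pool. Forward steps then add the candidate with the strongest
#' partial correlation with the outcome given the currently selected set
#' (computed by residualization), as long as it is significant at `alpha`
#' and the signature is below `max_features`. A backward pass removes
#' features that are no longer significant given the rest. At every forward
#' step, passing candidates nearly collinear with the chosen feature
#' (`|r| >= equiv_r` in the residual space) are recorded as statistically
#' equivalent substitutes; alternate signatures are the primary signature
#' with one substitution applied.
#'
#' @param X numeric feature matrix with column names (standardized or not;
#'   columns are standardized internally, zero-variance columns are inert).
#' @param y binary outcome (0/1, logical or two-level factor/character with
#'   positive class `"secretory"`).
#' @param alpha significance level of the independence tests.
#' @param max_features signature growth stops at this size.
#' @param screen size of the screened candidate pool; default
#'   `max(200, 4 * max_features)`.
#' @param equiv_r absolute residual-correlation at or above which two
#'   features are considered statistically equivalent.
#' @return list with `signature` (character vector, possibly empty),
#'   `equivalents` (named list: selected feature -> equivalent features),
#'   and `alternates` (list of alternate signatures).
#' @export
ses_lite <- function(X, y, alpha = 0.05, max_features = 50L,
                     screen = NULL, equiv_r = 0.99) {
  n <- nrow(X)
  y <- as.numeric(.as_positive(y))
  if (is.null(screen)) screen <- max(200L, 4L * max_features)
  sds <- apply(X, 2L, stats::sd)
  ok <- which(sds > 0 & !is.na(sds))
  empty <- list(signature = character(0), equivalents = list(),
                alternates = list())
  if (length(ok) == 0L) return(empty)
  Xs <- scale(X[, ok, drop = FALSE])
  ys <- (y - mean(y)) / stats::sd(y)
  r0 <- drop(crossprod(Xs, ys)) / (n - 1)
  p0 <- .fisher_z_p(r0, n)
  if (!any(p0 < alpha)) return(empty)
  pool <- order(-abs(r0))[seq_len(min(screen, length(ok)))]
  Xr <- Xs[, pool, drop = FALSE]
  yr <- ys
  active <- rep(TRUE, ncol(Xr))
  selected <- integer(0)
  equivalents <- list()
  while (length(selected) < max_features && any(active)) {
    cols <- which(active)
    cn <- sqrt(colSums(Xr[, cols, drop = FALSE]^2))
    yn <- sqrt(sum(yr^2))
    r <- colSums(Xr[, cols, drop = FALSE] * yr) / (cn * yn)
    r[cn < 1e-8 | yn < 1e-8] <- 0
    p <- .fisher_z_p(r, n, ncond = length(selected))
    if (!any(p < alpha)) break
    j <- cols[which.max(abs(r))]
    u <- Xr[, j]
    # equivalence: passing candidates nearly collinear with the winner
    rj <- colSums(Xr[, cols, drop = FALSE] * u) / (cn * sqrt(sum(u^2)))
    eq <- cols[p < alpha & abs(rj) >= equiv_r & cols != j]
    if (length(eq) > 0L) {
      equivalents[[colnames(Xr)[j]]] <- colnames(Xr)[eq]
    }
    selected <- c(selected, j)
    active[c(j, eq)] <- FALSE
    # residualize pool and outcome on the chosen feature
    uu <- sum(u^2)
    yr <- yr - u * (sum(u * yr) / uu)
    Xr[, active] <- Xr[, active, drop = FALSE] -
      u %*% (crossprod(u, Xr[, active, drop = FALSE]) / uu)
    spent <- active & sqrt(colSums(Xr^2))[seq_along(active)] < 1e-6 * sqrt(n)
    active[spent] <- FALSE
  }
  sig <- colnames(Xr)[selected]
  # backward purge: drop features not significant given the rest
  while (length(sig) > 1L) {
    fit <- stats::lm(ys ~ Xs[, sig, drop = FALSE])
    pv <- summary(fit)$coefficients[-1, 4]
    if (all(pv < alpha, na.rm = TRUE) && !anyNA(pv)) break
    pv[is.na(pv)] <- 1
    sig <- sig[-which.max(pv)]
  }
  equivalents <- equivalents[names(equivalents) %in% sig]
  alternates <- list()
  for (nm in names(equivalents)) {
    for (sub in equivalents[[nm]]) {
      alt <- sig
      alt[alt == nm] <- sub
      alternates[[length(alternates) + 1L]] <- alt
    }
  }
  list(signature = sig, equivalents = equivalents, alternates = alternates)
}

#' Select features under a configuration
#'
#' Applies [ses_lite()] with the selector hyper-parameters of a grid
#' configuration (significance level `alpha`, signature cut-off
#' `max_features`).
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param cfg a configuration from [make_config_grid()].
#' @return see [ses_lite()].
#' @export
select_features <- function(X, y, cfg) {
  ses_lite(X, y, alpha = cfg$alpha, max_features = cfg$max_features)
}
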