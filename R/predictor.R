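# Apply trained models to sequences and combine the preprotein and
# mature-domain views into a four-way verdict.

# window rows at explicit start positions (internal; bypasses the
# cleavage-site arithmetic of extract_window)
.windows_at <- function(ids, seqs, starts, W, kind) {
  res <- substring(seqs, starts, starts + W - 1L)
  pad <- W - nchar(res)
  res <- paste0(res, strrep(GAP_CHAR, pmax(pad, 0L)))
  structure(
    data.frame(source_id = ids, kind = kind, residues = res,
               start_pos = starts, short = (W - pad) < 20L,
               stringsAsFactors = FALSE),
    W = W, kind = kind, class = c("window_set", "data.frame")
  )
}

# rebuild the training feature pipeline recorded in a model
.model_features <- function(model, windows) {
  enc <- model$encoder
  em <- if (!is.null(enc$energy_P)) energy_model(enc$energy_P)
  build_feature_matrix(windows, groups = enc$groups, energy_model = em,
                       cpseaac_lam = enc$cpseaac_lam,
                       cpseaac_w = enc$cpseaac_w)
}

#' Score feature vectors with a trained model
#'
#' Features are standardized with the model's stored constants; linear
#' payloads score through the logistic transform of
#' `z = intercept + sum c_i x_i`.
#'
#' @param model a `trained_model`.
#' @param X numeric matrix (samples x named features) providing at least the
#'   model's selected features on their raw scale.
#' @return probability vector in `(0, 1)`.
#' @export
score_model <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss) > 0L) {
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  }
  if (length(model$features) == 0L) {
    return(.score_payload(model$payload,
                          matrix(0, nrow(X), 0)))
  }
  Xs <- sweep(sweep(X[, model$features, drop = FALSE], 2L, model$center, "-"),
              2L, model$scale, "/")
  .score_payload(model$payload, Xs)
}

#' Classify sequence records under one view
#'
#' Windows and features are computed with the same encoder pipeline the
#' model was trained with. In the `mature` view, unannotated sequences are
#' assumed to already be mature domains and their window starts at
#' position 1; records carrying a cleavage position are windowed from
#' `cleavage_pos + 3`. A record is called positive (secretory for the
#' preprotein view, mature-like for the mature view) when its probability is
#' greater than or equal to the stored threshold.
#'
#' @param model a `trained_model` from [train_secretion_model()].
#' @param records a [seq_set()].
#' @param view view to classify under; must match the model's training view.
#' @return `data.frame` with columns `id`, `probability`, `positive`.
#' @export
classify_records <- function(records, model, view = model$encoder$view) {
  if (is.null(model$encoder)) stop("model carries no encoder provenance")
  if (!identical(view, model$encoder$view)) {
    stop("model was trained for view '", model$encoder$view,
         "', not '", view, "'")
  }
  W <- model$encoder$W
  starts <- if (view == "mature") {
    ifelse(is.na(records$cleavage_pos), 1L, records$cleavage_pos + 3L)
  } else {
    rep(1L, nrow(records))
  }
  win <- .windows_at(records$id, records$seq, starts, W, view)
  pr <- score_model(model, .model_features(model, win))
  data.frame(id = records$id, probability = unname(pr),
             positive = unname(pr) >= model$threshold,
             stringsAsFactors = FALSE)
}

#' Estimate the signal-peptide cleavage position
#'
#' Scans candidate cleavage positions `p` and scores the mature-domain model
#' on the window starting at `p + 3`; returns the position maximizing the
#' mature-model probability (ties resolve to the smallest position). Meant
#' to be called once the preprotein model has fired positive.
#'
#' @param mat_model mature-view `trained_model`.
#' @param seq amino-acid string.
#' @param range integer vector of candidate positions (1-based index of the
#'   last signal-peptide residue), default `15:40`.
#' @return list with `position` and `probability`.
#' @export
estimate_cleavage <- function(mat_model, seq, range = 15:40) {
  range <- sort(unique(as.integer(range)))
  if (nchar(seq) < min(range) + 3L) {
    stop("sequence shorter than the minimal candidate window")
  }
  W <- mat_model$encoder$W
  win <- .windows_at(paste0("p", range), rep(seq, length(range)),
                     range + 3L, W, "mature")
  pr <- score_model(mat_model, .model_features(mat_model, win))
  best <- which.max(pr)  # which.max takes the first (smallest p) on ties
  list(position = range[best], probability = unname(pr[best]))
}

#' Combined preprotein + mature-domain decision
#'
#' Applies the signal-peptide-aware preprotein model and the mature-domain
#' model jointly. Decision table:
#' * preprotein -, mature - (scored from position 1): `cytoplasmic`
#' * preprotein -, mature + (scored from position 1): `mature`
#' * preprotein +, mature + (scored from the estimated cleavage):
#'   `secretory-preprotein`
#' * preprotein +, mature - : `non-secretory` (a signal peptide fused to an
#'   incompatible mature sequence)
#'
#' The estimated cleavage position is reported only when the preprotein
#' model fires.
#'
#' @param records a [seq_set()].
#' @param pre_model preprotein-view `trained_model`.
#' @param mat_model mature-view `trained_model`.
#' @param range candidate cleavage positions for [estimate_cleavage()].
#' @return `data.frame` of class `prediction` with columns `id`, `prob_pre`,
#'   `prob_mature`, `est_cleavage`, `verdict`.
#' @export
predict_combined <- function(records, pre_model, mat_model, range = 15:40) {
  if (!identical(pre_model$encoder$view, "preprotein") ||
      !identical(mat_model$encoder$view, "mature")) {
    stop("pre_model must be preprotein-view and mat_model mature-view")
  }
  pre <- classify_records(records, pre_model)
  # mature view from position 1 for sequences without a fired signal peptide
  recs1 <- records
  recs1$cleavage_pos <- NA_integer_
  recs1$label <- "unknown"
  mat1 <- classify_records(recs1, mat_model)
  n <- nrow(records)
  prob_mat <- mat1$probability
  est <- rep(NA_integer_, n)
  for (i in which(pre$positive)) {
    ec <- estimate_cleavage(mat_model, records$seq[i], range = range)
    est[i] <- ec$position
    prob_mat[i] <- ec$probability
  }
  mat_pos <- prob_mat >= mat_model$threshold
  verdict <- ifelse(pre$positive,
                    ifelse(mat_pos, "secretory-preprotein", "non-secretory"),
                    ifelse(mat_pos, "mature", "cytoplasmic"))
  structure(
    data.frame(id = records$id, prob_pre = pre$probability,
               prob_mature = prob_mat, est_cleavage = est, verdict = verdict,
               stringsAsFactors = FALSE),
    class = c("prediction", "data.frame")
  )
}

#' Write predictions to a TSV file
#'
#' Deterministic, schema'd output: identical predictions produce
#' byte-identical files.
#'
#' @param pred a `prediction` data.frame from [predict_combined()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  out <- pred
  out$prob_pre <- sprintf("%.6f", out$prob_pre)
  out$prob_mature <- sprintf("%.6f", out$prob_mature)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
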