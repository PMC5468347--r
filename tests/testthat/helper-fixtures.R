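# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# random amino-acid sequence from the standard alphabet
random_seq <- function(len) {
  paste(sample(secmature:::AA_STANDARD, len, replace = TRUE), collapse = "")
}

# small seq_set with annotated secretory/cytoplasmic records
tiny_labeled_set <- function() {
  seq_set(
    id = c("p1", "p2", "c1", "c2"),
    seq = c(paste0(strrep("MKALIV", 5), strrep("STNQAG", 20)),
            paste0(strrep("MRLFAV", 5), strrep("TNQSYD", 20)),
            strrep("KEGVRD", 25),
            strrep("ILDAQR", 25)),
    label = c("secretory", "secretory", "cytoplasmic", "cytoplasmic"),
    cleavage_pos = c(21L, 24L, NA, NA)
  )
}

# random symmetric 20x20 matrix
random_symmetric_P <- function() {
  A <- matrix(rnorm(400), 20, 20)
  (A + t(A)) / 2
}

# random composition vector (Dirichlet-ish via normalized exponentials)
random_composition <- function() {
  x <- rexp(20)
  n <- x / sum(x)
  names(n) <- secmature:::AA_STANDARD
  n
}

# write a FASTA file from id/seq vectors, return the path
write_tmp_fasta <- function(ids, seqs, wrap = FALSE) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  if (wrap) {
    body <- unlist(lapply(seq_along(ids), function(i) {
      c(paste0(">", ids[i]),
        substring(seqs[i], seq(1, nchar(seqs[i]), 60),
                  pmin(seq(1, nchar(seqs[i]), 60) + 59, nchar(seqs[i]))))
    }))
  } else {
    body <- paste0(">", ids, "\n", seqs)
  }
  writeLines(body, path)
  path
}

# a hand-built linear trained_model for predictor/logo tests
linear_model_fixture <- function(coef, intercept = 0, threshold = 0.5,
                                 center = NULL, scale = NULL) {
  feats <- names(coef)
  if (is.null(center)) center <- stats::setNames(rep(0, length(feats)), feats)
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(feats)), feats)
  structure(list(
    features = feats, center = center, scale = scale,
    payload = list(type = "linear", family = "ridge", coef = coef,
                   intercept = intercept),
    threshold = threshold,
    performance = list(cv_auc = NA_real_, corrected_auc = NA_real_,
                       ci = c(NA_real_, NA_real_)),
    signature_alternates = list(),
    provenance = list(seed = 0L)
  ), class = "trained_model")
}
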