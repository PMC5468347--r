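# Synthetic labeled datasets with the class structure the classifier is
# built to detect: secretory sequences carry an N-terminal signal peptide
# (n-region with basic residues, hydrophobic h-region, A-x-A style c-region)
# followed by a mature domain depleted of hydrophobics/Arg early and
# enriched in polar/hydroxyl/Asp residues later; cytoplasmic sequences carry
# an early hydrophobic stretch and downstream basic enrichment. All biases
# scale with one effect-size multiplier: at effect 0 both classes are drawn
# from the same background, making the null exactly exchangeable.

#' Specification of the synthetic-data generator
#'
#' @param n_secretory,n_cytoplasmic class counts.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param effect effect-size multiplier, `>= 0`. `0` gives null data (both
#'   classes from the same background); `1` is the default study condition.
#' @param sp_len_range min/max signal-peptide length (cleavage position is
#'   the last signal-peptide residue).
#' @param len_range min/max total sequence length.
#' @param background residue sampling weights (named 20-vector); uniform by
#'   default so the null is exchangeable.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_secretory = 200L, n_cytoplasmic = 200L,
                           seed = 1L, effect = 1,
                           sp_len_range = c(18L, 25L),
                           len_range = c(120L, 400L),
                           background = NULL) {
  stopifnot(n_secretory >= 0L, n_cytoplasmic >= 0L, effect >= 0)
  if (is.null(background)) {
    background <- stats::setNames(rep(1, 20L), AA_STANDARD)
  }
  structure(list(n_secretory = as.integer(n_secretory),
                 n_cytoplasmic = as.integer(n_cytoplasmic),
                 seed = as.integer(seed), effect = effect,
                 sp_len_range = as.integer(sp_len_range),
                 len_range = as.integer(len_range),
                 background = background[AA_STANDARD]),
            class = "generator_spec")
}

# weight helpers: multiply the weights of a residue set
.enrich <- function(w, set, factor) {
  w[strsplit(set, "")[[1]]] <- w[strsplit(set, "")[[1]]] * factor
  w
}

.draw <- function(n, w) {
  if (n <= 0L) return(character(0))
  sample(AA_STANDARD, n, replace = TRUE, prob = w)
}

# residues of a signal peptide of length sp_len (positions 1..sp_len)
.draw_signal_peptide <- function(sp_len, bg, e) {
  n_len <- sample(2:4, 1L)
  h_len <- sp_len - 1L - n_len - 3L
  c(
    "M",
    .draw(n_len, .enrich(bg, "KR", 1 + 3 * e)),                    # n-region
    .draw(h_len, .enrich(bg, "ALIVFM", 1 + 4 * e)),                # h-region
    .draw(1L, .enrich(bg, "A", 1 + 6 * e)),                        # c-region A-x-A
    .draw(1L, bg),
    .draw(1L, .enrich(bg, "A", 1 + 6 * e))
  )
}

# mature-domain residues (m_len positions after the cleavage site)
.draw_mature <- function(m_len, bg, e) {
  w_early <- .enrich(.enrich(bg, "LIVF", 1 / (1 + e)), "R", 1 / (1 + e))
  res <- c(
    .draw(min(3L, m_len), .enrich(w_early, "G", 1 + e)),   # Gly at extreme N-term
    .draw(max(min(15L, m_len) - 3L, 0L), w_early),
    .draw(max(min(80L, m_len) - 15L, 0L), .enrich(bg, "STNQYD", 1 + e)),
    .draw(max(m_len - 80L, 0L), bg)
  )
  res
}

# cytoplasmic-style residues: early hydrophobic stretch + downstream K/R
.draw_cytoplasmic <- function(len, bg, e) {
  res <- .draw(len, bg)
  if (e > 0 && stats::runif(1) < min(0.9 * e, 0.95)) {
    start <- sample(1:8, 1L)
    sl <- sample(6:10, 1L)
    res[start:min(start + sl - 1L, len)] <-
      .draw(min(sl, len - start + 1L), .enrich(bg, "LIVF", 1 + 4 * e))
    dn <- min(start + sl, len):min(start + sl + 29L, len)
    res[dn] <- .draw(length(dn), .enrich(bg, "KR", 1 + e))
  }
  res
}

#' Generate a labeled synthetic dataset
#'
#' Secretory entries are a signal peptide (random length within
#' `sp_len_range`, cleavage position recorded) followed by a biased mature
#' region; cytoplasmic entries are background with a planted N-terminal
#' hydrophobic stretch and downstream basic enrichment. Output is
#' reproducible to the byte from the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @param prefix if non-NULL, write `<prefix>.fasta` and
#'   `<prefix>.labels.tsv`.
#' @return a [seq_set()] with labels and cleavage positions, invisibly when
#'   `prefix` is given.
#' @export
generate_dataset <- function(spec, prefix = NULL) {
  set.seed(spec$seed)
  bg <- spec$background
  e <- spec$effect
  n <- spec$n_secretory + spec$n_cytoplasmic
  ids <- character(n)
  seqs <- character(n)
  labels <- character(n)
  cp <- rep(NA_integer_, n)
  lens <- if (n > 0L) sample(spec$len_range[1]:spec$len_range[2], n,
                             replace = TRUE) else integer(0)
  i <- 0L
  for (s in seq_len(spec$n_secretory)) {
    i <- i + 1L
    sp_len <- sample(spec$sp_len_range[1]:spec$sp_len_range[2], 1L)
    res <- c(.draw_signal_peptide(sp_len, bg, e),
             .draw_mature(lens[i] - sp_len, bg, e))
    ids[i] <- sprintf("sec%04d", s)
    seqs[i] <- paste(res, collapse = "")
    labels[i] <- "secretory"
    cp[i] <- sp_len
  }
  for (s in seq_len(spec$n_cytoplasmic)) {
    i <- i + 1L
    ids[i] <- sprintf("cyt%04d", s)
    seqs[i] <- paste(.draw_cytoplasmic(lens[i], bg, e), collapse = "")
    labels[i] <- "cytoplasmic"
  }
  out <- seq_set(ids, seqs, labels, cp)
  if (!is.null(prefix)) {
    .write_dataset(out, prefix)
    return(invisible(out))
  }
  out
}

#' Generate chimeric "non-secretory" sequences
#'
#' Valid synthetic signal peptides fused to cytoplasmic-style downstream
#' regions: the preprotein model should fire while the mature model rejects
#' the downstream sequence, emulating secretion-incompetent mutant
#' derivatives with intact signal peptides.
#'
#' @param spec a [generator_spec()] (its effect, lengths and seed apply).
#' @param n number of chimeras.
#' @param prefix optional output prefix as in [generate_dataset()].
#' @return a [seq_set()]; labels are `"unknown"` in the object, written as
#'   `non-secretory` ground truth in the label file's `truth` column.
#' @export
generate_chimeras <- function(spec, n, prefix = NULL) {
  set.seed(spec$seed + 1L)
  bg <- spec$background
  e <- spec$effect
  ids <- sprintf("chi%04d", seq_len(n))
  seqs <- character(n)
  cp <- integer(n)
  lens <- if (n > 0L) sample(spec$len_range[1]:spec$len_range[2], n,
                             replace = TRUE) else integer(0)
  for (s in seq_len(n)) {
    sp_len <- sample(spec$sp_len_range[1]:spec$sp_len_range[2], 1L)
    res <- c(.draw_signal_peptide(sp_len, bg, e),
             .draw_cytoplasmic(lens[s] - sp_len, bg, e))
    # force the downstream hydrophobic stretch/basic insertion even when the
    # random gate in .draw_cytoplasmic stayed closed
    if (e > 0) {
      m_len <- lens[s] - sp_len
      ins <- .draw(min(8L, m_len), .enrich(bg, "LIVFKR", 1 + 4 * e))
      res[sp_len + 3L + seq_along(ins)] <- ins
    }
    seqs[s] <- paste(res, collapse = "")
    cp[s] <- sp_len
  }
  out <- seq_set(ids, seqs, label = "unknown", cleavage_pos = cp)
  if (!is.null(prefix)) {
    .write_dataset(out, prefix, truth = "non-secretory")
    return(invisible(out))
  }
  out
}

# deterministic FASTA + label TSV output
.write_dataset <- function(records, prefix, truth = NULL) {
  fa <- paste0(">", records$id, "\n", records$seq)
  writeLines(fa, paste0(prefix, ".fasta"))
  tab <- data.frame(id = records$id, label = records$label,
                    cleavage_pos = ifelse(is.na(records$cleavage_pos), "",
                                          records$cleavage_pos),
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) tab$truth <- truth
  utils::write.table(tab, paste0(prefix, ".labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Strip signal peptides from secretory records
#'
#' Returns mature-domain-only records (sequence from `cleavage_pos + 1`
#' onward, cleavage position dropped), useful for building "mature" fixture
#' sequences that are secreted-like but carry no signal peptide.
#'
#' @param records a [seq_set()] with cleavage positions.
#' @return a [seq_set()] of mature sequences, labels `"unknown"`.
#' @export
strip_signal_peptides <- function(records) {
  stopifnot(all(!is.na(records$cleavage_pos)))
  seq_set(paste0(records$id, "_mat"),
          substring(records$seq, records$cleavage_pos + 1L),
          label = "unknown")
}
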