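# Sequence input, window extraction and redundancy reduction.

#' Construct a sequence set
#'
#' A sequence set is the package's tabular container for protein records: one
#' row per sequence with an identifier, the amino-acid string, a class label
#' (`"secretory"`, `"cytoplasmic"` or `"unknown"`) and, for secretory
#' proteins, the 1-based position of the last signal-peptide residue.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of amino-acid sequences (upper case).
#' @param label class labels; defaults to `"unknown"`.
#' @param cleavage_pos integer vector, 1-based index of the last
#'   signal-peptide residue, `NA` when absent. Must satisfy
#'   `1 <= cleavage_pos < nchar(seq)`; cytoplasmic records must have `NA`.
#' @return a `data.frame` of class `seq_set`.
#' @export
seq_set <- function(id, seq, label = "unknown", cleavage_pos = NA_integer_) {
  stopifnot(length(id) == length(seq))
  label <- rep_len(as.character(label), length(id))
  cleavage_pos <- rep_len(as.integer(cleavage_pos), length(id))
  bad <- !label %in% c("secretory", "cytoplasmic", "unknown")
  if (any(bad)) {
    stop("unknown label token(s): ", paste(unique(label[bad]), collapse = ", "))
  }
  if (any(nchar(seq) < 1L)) stop("empty sequence(s) in set")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  has_cp <- !is.na(cleavage_pos)
  if (any(has_cp & (cleavage_pos < 1L | cleavage_pos >= nchar(seq)))) {
    stop("cleavage_pos out of range: must satisfy 1 <= cleavage_pos < sequence length")
  }
  if (any(label == "cytoplasmic" & has_cp)) {
    stop("cytoplasmic records cannot carry a cleavage position")
  }
  structure(
    data.frame(id = as.character(id), seq = as.character(seq),
               label = label, cleavage_pos = cleavage_pos,
               stringsAsFactors = FALSE),
    class = c("seq_set", "data.frame")
  )
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and trailing `*` stop symbols stripped. Labels
#' are set to `"unknown"`; attach them with [read_labels()].
#'
#' @param path path to a FASTA file.
#' @return a [seq_set()] with one row per FASTA entry, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aas) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(aas), "[ \t]"), `[`, "", 1L)
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  seq_set(id = ids, seq = seqs)
}

#' Attach class labels and cleavage positions from a TSV table
#'
#' The label file is tab-separated with a header line `id label cleavage_pos`;
#' `cleavage_pos` may be empty for cytoplasmic or unannotated rows. Rows whose
#' id is absent from `records` are reported with a warning.
#'
#' @param path path to the TSV label file.
#' @param records a [seq_set()], typically from [read_fasta()].
#' @return `records` with labels and cleavage positions attached.
#' @export
read_labels <- function(path, records) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "")
  need <- c("id", "label", "cleavage_pos")
  if (!all(need %in% names(tab))) {
    stop("label file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in label file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  bad <- !tab$label %in% c("secretory", "cytoplasmic", "unknown")
  if (any(bad)) {
    stop("unknown label token(s) in label file: ",
         paste(unique(tab$label[bad]), collapse = ", "))
  }
  missing_ids <- setdiff(tab$id, records$id)
  if (length(missing_ids) > 0L) {
    warning("label file ids absent from the sequence set: ",
            paste(missing_ids, collapse = ", "))
  }
  m <- match(records$id, tab$id)
  hit <- !is.na(m)
  records$label[hit] <- tab$label[m[hit]]
  cp <- suppressWarnings(as.integer(tab$cleavage_pos[m[hit]]))
  records$cleavage_pos[hit] <- cp
  # revalidate invariants after attachment
  seq_set(records$id, records$seq, records$label, records$cleavage_pos)
}

#' Extract fixed-length N-terminal windows
#'
#' The `preprotein` view starts at position 1. The `mature` view starts at
#' `cleavage_pos + 3`: position +1 of the mature domain is `cleavage_pos + 1`,
#' and the first two mature positions are skipped to avoid conserved motifs
#' around the cleavage site (e.g. the lipoprotein +1 Cys). Windows running
#' past the end of the sequence are right-padded with `-`.
#'
#' @param records a [seq_set()].
#' @param kind `"preprotein"` or `"mature"`.
#' @param W window length in residues.
#' @param min_useful minimum number of non-gap residues below which a window
#'   is flagged `short = TRUE`.
#' @return a `data.frame` of class `window_set` with columns `source_id`,
#'   `kind`, `residues` (length exactly `W`), `start_pos`, `short`; attributes
#'   `W` and `kind`.
#' @export
extract_window <- function(records, kind = c("preprotein", "mature"),
                           W = if (kind == "preprotein") 84L else 80L,
                           min_useful = 20L) {
  kind <- match.arg(kind)
  W <- as.integer(W)
  stopifnot(W >= 1L)
  if (kind == "mature") {
    miss <- is.na(records$cleavage_pos)
    if (any(miss)) {
      stop("mature windows require a cleavage position; missing for: ",
           paste(utils::head(records$id[miss], 5L), collapse = ", "))
    }
    start <- records$cleavage_pos + 3L
  } else {
    start <- rep(1L, nrow(records))
  }
  res <- substring(records$seq, start, start + W - 1L)
  pad <- W - nchar(res)
  res <- paste0(res, strrep(GAP_CHAR, pmax(pad, 0L)))
  short <- (W - pad) < min_useful
  structure(
    data.frame(source_id = records$id, kind = kind, residues = res,
               start_pos = start, short = short, stringsAsFactors = FALSE),
    W = W, kind = kind, class = c("window_set", "data.frame")
  )
}

# identity substitution matrix over A..Z: match 1, mismatch 0
.identity_submat <- local({
  m <- diag(1, 26L)
  dimnames(m) <- list(LETTERS, LETTERS)
  m
})

#' Percent identity between two sequences over their N-terminal span
#'
#' Computes a deterministic global alignment of the first `span` residues of
#' each sequence (match = 1, mismatch = 0, linear gap penalty -1) and returns
#' `100 * identical positions / alignment length`.
#'
#' @param a,b amino-acid strings.
#' @param span number of N-terminal residues compared (default 100).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, span = 100L) {
  if (nchar(a) < 1L || nchar(b) < 1L) stop("empty sequence")
  a <- substr(a, 1L, span)
  b <- substr(b, 1L, span)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .identity_submat,
    gapOpening = 0, gapExtension = 1
  )
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Redundancy reduction by neighbor elimination (Hobohm algorithm 2)
#'
#' Builds the neighbor graph over a sequence set (edge when pairwise identity
#' over the first `span` residues exceeds `cutoff` percent) and repeatedly
#' removes the record with the most neighbors until no edges remain.
#' Secretory and cytoplasmic records are reduced separately, as are records
#' with unknown labels. Among records with equal neighbor counts the
#' latest-index one is removed, so earliest occurrences are retained
#' deterministically. Output preserves input order.
#'
#' @param records a [seq_set()].
#' @param cutoff percent identity above which two sequences are neighbors.
#' @param span N-terminal span for [pairwise_identity()].
#' @return the retained subset, a [seq_set()].
#' @export
hobohm2_reduce <- function(records, cutoff = 40, span = 100L) {
  stopifnot(nrow(records) >= 1L)
  keep <- logical(nrow(records))
  for (grp in unique(records$label)) {
    idx <- which(records$label == grp)
    n <- length(idx)
    adj <- matrix(FALSE, n, n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          pid <- pairwise_identity(records$seq[idx[i]], records$seq[idx[j]], span)
          adj[i, j] <- adj[j, i] <- pid > cutoff
        }
      }
    }
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE]) * alive
      if (all(deg == 0)) break
      worst <- max(which(deg == max(deg)))  # remove latest index on ties
      alive[worst] <- FALSE
      adj[worst, ] <- FALSE
      adj[, worst] <- FALSE
    }
    keep[idx[alive]] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("seq_set", "data.frame"))
}
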