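# Interaction-energy features: composition vectors, the quadratic energy
# estimate n' P n, and the eigendecomposition of the predictor matrix into
# folding components.

#' Amino-acid composition vector
#'
#' Residue frequencies `n_i = N_i / L` over the 20 standard residues, with
#' `L` the number of standard residues counted. Gaps and nonstandard codes
#' are excluded from both numerator and denominator.
#'
#' @param seq residue string.
#' @return named 20-vector summing to 1.
#' @export
composition <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, AA_STANDARD)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("no standard residues in sequence")
  n <- tabulate(idx, nbins = 20L) / length(idx)
  names(n) <- AA_STANDARD
  n
}

#' Construct an energy model from a 20x20 predictor matrix
#'
#' Element `P[i, j]` tells how the energy of residue type i depends on the
#' occurrences of residue type j. The matrix is symmetrized as
#' `(P + t(P)) / 2` when the maximal asymmetry is below `1e-6` (an error
#' otherwise) and eigendecomposed. Eigenvectors ("folding components") are
#' ordered by decreasing eigenvalue (ties broken by the first differing
#' coordinate after sign fixing) and sign-fixed so that each vector's
#' largest-magnitude coordinate is positive, making the decomposition
#' deterministic. Spectral reconstruction and orthonormality are asserted at
#' construction within `1e-8`.
#'
#' @param P symmetric 20x20 numeric matrix, rows/cols in [AA_STANDARD] order.
#' @return an `energy_model` list with fields `P`, `values`, `vectors`
#'   (columns are folding components), `residues`.
#' @export
energy_model <- function(P) {
  if (!is.matrix(P) || !is.numeric(P) || any(dim(P) != 20L)) {
    stop("P must be a numeric 20x20 matrix")
  }
  if (max(abs(P - t(P))) >= 1e-6) stop("P is not symmetric (asymmetry >= 1e-6)")
  P <- (P + t(P)) / 2
  dimnames(P) <- list(AA_STANDARD, AA_STANDARD)
  eg <- eigen(P, symmetric = TRUE)
  V <- eg$vectors
  for (k in seq_len(20L)) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  # decreasing eigenvalue; degenerate blocks ordered by the first differing
  # eigenvector coordinate (descending), which keeps diagonal matrices in
  # natural residue order
  ord <- do.call(order, c(list(-eg$values), lapply(seq_len(20L), function(i) -V[i, ])))
  values <- eg$values[ord]
  V <- V[, ord, drop = FALSE]
  rownames(V) <- AA_STANDARD
  colnames(V) <- paste0("FC", seq_len(20L))
  recon <- V %*% diag(values) %*% t(V)
  if (max(abs(recon - P)) > 1e-8) stop("spectral reconstruction failed")
  if (max(abs(crossprod(V) - diag(20L))) > 1e-8) {
    stop("eigenvectors not orthonormal")
  }
  structure(list(P = P, values = values, vectors = V, residues = AA_STANDARD),
            class = "energy_model")
}

#' Load an energy predictor matrix from a text file
#'
#' Expected format: one header row with the 20 one-letter residue codes
#' giving the row/column order, then 20 rows of 20 whitespace-separated
#' numbers. The matrix is reordered internally to [AA_STANDARD] order.
#'
#' @param path file path.
#' @return an [energy_model()].
#' @export
load_energy_matrix <- function(path) {
  if (!file.exists(path)) stop("energy matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 20L || !setequal(header, AA_STANDARD)) {
    stop("header must list the 20 standard one-letter residue codes")
  }
  if (length(lines) != 21L) stop("expected 20 matrix rows after the header")
  vals <- suppressWarnings(
    lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  )
  if (any(vapply(vals, length, 0L) != 20L) || anyNA(unlist(vals))) {
    stop("matrix rows must each hold 20 numeric values")
  }
  P <- do.call(rbind, vals)
  dimnames(P) <- list(header, header)
  P <- P[AA_STANDARD, AA_STANDARD]
  energy_model(P)
}

#' The bundled energy predictor matrix
#'
#' Loads the package's bundled 20x20 matrix. This matrix is a synthetic
#' stand-in with hydrophobic-attraction structure (see the file header and
#' the methods vignette); substitute a published predictor matrix via
#' [load_energy_matrix()] for real analyses.
#'
#' @return an [energy_model()].
#' @export
default_energy_model <- function() {
  load_energy_matrix(system.file("extdata", "energy_matrix_synthetic.txt",
                                 package = "secmature", mustWork = TRUE))
}

#' Estimated interaction energy per residue
#'
#' The quadratic form `E/L = sum_ij n_i P_ij n_j`.
#'
#' @param n composition vector from [composition()].
#' @param model an [energy_model()].
#' @return scalar energy per residue (arbitrary units).
#' @export
interaction_energy <- function(n, model) {
  drop(t(n) %*% model$P %*% n)
}

#' Per-folding-component energies
#'
#' For each folding component k, `e_k = sign(lambda_k) * (V_k . n)`. The
#' quadratic spectral contribution `lambda_k * (V_k . n)^2` (whose sum equals
#' the total interaction energy) is returned alongside as a diagnostic.
#'
#' @param n composition vector.
#' @param model an [energy_model()].
#' @return list with `e` (named 20-vector, components in decreasing
#'   eigenvalue order), `total` (`n' P n`), and `quadratic`
#'   (per-component `lambda_k (V_k . n)^2`).
#' @export
folding_energies <- function(n, model) {
  proj <- drop(crossprod(model$vectors, n))
  e <- sign(model$values) * proj
  names(e) <- paste0("fc:e", seq_len(20L))
  list(e = e, total = interaction_energy(n, model),
       quadratic = model$values * proj^2)
}
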