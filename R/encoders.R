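# Feature encoders: position-specific binary representations, k-mer
# fractions, and hydrophobicity-customized pseudo-amino-acid composition.

#' Construct an encoding scheme
#'
#' An encoding scheme is an ordered list of (symbol, residue set) groups used
#' by [encode_binary()]. Groups may overlap: a residue with several
#' physicochemical characters (e.g. Phe is hydrophobic, aromatic and bulky)
#' can belong to several groups, so more than one bit can be set per position.
#'
#' @param name scheme name.
#' @param groups named list mapping group symbol to a character vector of
#'   standard residues (or a single string like `"KR"`).
#' @return an `encoding_scheme` object.
#' @export
encoding_scheme <- function(name, groups) {
  if (length(groups) == 0L) stop("encoding scheme needs at least one group")
  groups <- lapply(groups, function(g) {
    g <- unlist(strsplit(paste(g, collapse = ""), ""))
    if (length(g) == 0L || !all(g %in% AA_STANDARD)) {
      stop("groups must be non-empty subsets of the 20 standard residues")
    }
    g
  })
  structure(list(name = name, groups = groups), class = "encoding_scheme")
}

#' Built-in binary encoding schemes
#'
#' Four alternative residue groupings for position-specific binary encoding:
#' * `individual`: 20 singleton groups, one bit per residue type.
#' * `relaxed`: overlapping physicochemical property groups
#'   (`@` acidic D/E, `+` basic K/R, `sml` small V/G/A/P, `sm` tiny A/G,
#'   `h` hydrophobic I/L/V/M, `ph` L/I/F, `b` bulky aromatic Y/W/F,
#'   `o-` hydroxyl T/S, `x` Y/T/S, `pol` polar N/Q/C, `q` N/Q/H).
#' * `compact`: a coarse partition (acidic, basic, hydrophobic, polar,
#'   small/turn).
#' * `disorder_order`: disorder-promoting \{A,R,G,Q,S,P,E,K\},
#'   order-promoting \{W,C,F,I,Y,V,L,N\}, neutral \{H,M,T,D\}.
#'
#' Schemes are replaceable: see [read_scheme_json()].
#'
#' @return named list of [encoding_scheme()] objects.
#' @export
builtin_schemes <- function() {
  ind <- as.list(AA_STANDARD)
  names(ind) <- AA_STANDARD
  list(
    individual = encoding_scheme("individual", ind),
    relaxed = encoding_scheme("relaxed", list(
      "@" = "DE", "+" = "KR", "sml" = "VGAP", "sm" = "AG", "h" = "ILVM",
      "ph" = "LIF", "b" = "YWF", "o-" = "TS", "x" = "YTS", "pol" = "NQC",
      "q" = "NQH"
    )),
    compact = encoding_scheme("compact", list(
      "@" = "DE", "+" = "KRH", "h" = "AVLIMFW", "pol" = "STNQCY", "sm" = "GP"
    )),
    disorder_order = encoding_scheme("disorder_order", list(
      "dis" = "ARGQSPEK", "ord" = "WCFIYVLN", "neu" = "HMTD"
    ))
  )
}

#' Load encoding schemes from a JSON config
#'
#' The file maps scheme name to an object mapping group symbol to a residue
#' string, e.g. `{"relaxed": {"@": "DE", "+": "KR"}}`.
#'
#' @param path JSON file path.
#' @return named list of [encoding_scheme()] objects.
#' @export
read_scheme_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mapply(function(nm, groups) encoding_scheme(nm, as.list(groups)),
         names(cfg), cfg, SIMPLIFY = FALSE)
}

#' Position-specific binary encoding of windows
#'
#' Bit (i, g) is 1 iff the residue at window position i belongs to group g of
#' the scheme. Gap padding and nonstandard residues give all-zero columns.
#'
#' @param windows a `window_set` from [extract_window()].
#' @param scheme an [encoding_scheme()].
#' @return 0/1 matrix, one row per window, `W * length(groups)` columns named
#'   `bin_<scheme>:pos<i>:<symbol>`.
#' @export
encode_binary <- function(windows, scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  W <- attr(windows, "W")
  n <- nrow(windows)
  ch <- matrix(unlist(strsplit(windows$residues, "")), nrow = n, byrow = TRUE)
  G <- length(scheme$groups)
  out <- matrix(0, n, W * G)
  syms <- names(scheme$groups)
  for (g in seq_len(G)) {
    memb <- matrix(ch %in% scheme$groups[[g]], nrow = n)  # n x W
    out[, (seq_len(W) - 1L) * G + g] <- memb + 0
  }
  colnames(out) <- paste0("bin_", scheme$name, ":pos",
                          rep(seq_len(W), each = G), ":", rep(syms, W))
  rownames(out) <- windows$source_id
  out
}

# all k-mers over the standard alphabet, in fixed lexicographic order
.all_kmers <- function(k) {
  if (k == 1L) return(AA_STANDARD)
  grid <- do.call(expand.grid,
                  c(rep(list(AA_STANDARD), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

#' Overlapping k-mer fractions
#'
#' For each sequence, the fraction of each residue (`k = 1`), di-peptide
#' (`k = 2`) or tri-peptide (`k = 3`): `count(m) / (L - k + 1)` with `L` the
#' gap-stripped length. k-mers containing a nonstandard residue are excluded
#' from the numerator (they terminate k-mer windows), so entries sum to 1
#' only when no nonstandard residue interrupts the sequence.
#'
#' @param seqs character vector of residue strings (gaps allowed, stripped).
#' @param k k-mer size, 1, 2 or 3.
#' @return matrix, one row per sequence, `20^k` columns named `kmer<k>:<mer>`.
#' @export
kmer_fractions <- function(seqs, k = 1L) {
  k <- as.integer(k)
  stopifnot(k %in% 1:3)
  mers <- .all_kmers(k)
  seqs <- gsub(GAP_CHAR, "", seqs, fixed = TRUE)
  L <- nchar(seqs)
  if (any(L < k)) stop("sequence shorter than k after removing gaps")
  out <- matrix(0, length(seqs), length(mers))
  for (s in seq_along(seqs)) {
    nw <- L[s] - k + 1L
    words <- substring(seqs[s], seq_len(nw), seq_len(nw) + k - 1L)
    idx <- match(words, mers)          # NA for words touching nonstandard codes
    tab <- tabulate(idx[!is.na(idx)], nbins = length(mers))
    out[s, ] <- tab / nw
  }
  colnames(out) <- paste0("kmer", k, ":", mers)
  rownames(out) <- names(seqs)
  out
}

#' Hydrophobicity scales
#'
#' Named per-residue hydrophobicity tables used by [cpseaac()]. Currently the
#' Kyte-Doolittle scale (abbreviation `K/D`). Scales are standardized to zero
#' mean and unit variance across the 20 residues before use.
#'
#' @return named list; each element a named 20-vector with an `abbr` attribute.
#' @export
hydrophobicity_scales <- function() {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  attr(kd, "abbr") <- "K/D"
  list(kyte_doolittle = kd)
}

#' Hydrophobicity-customized pseudo-amino-acid composition
#'
#' Classic type-I pseudo-amino-acid composition restricted to a single
#' hydrophobicity property. With `h` the standardized scale value of residue
#' at position i and `f` the residue frequencies, the lag-j correlation term
#' is `theta_j = mean over i of (h[i+j] - h[i])^2`. The output is
#' `c(f, w * theta) / (sum(f) + w * sum(theta))`: 20 composition entries
#' followed by `lam` lag entries. Gaps and nonstandard residues are removed
#' before computation.
#'
#' @param seqs character vector of residue strings.
#' @param scale name of a scale in [hydrophobicity_scales()], or a named
#'   20-vector with an `abbr` attribute.
#' @param lam maximum lag (sequence-order depth); must be `<` sequence length.
#' @param w weight of the sequence-order terms (`w = 0` reduces the vector to
#'   pure composition).
#' @return matrix, one row per sequence, `20 + lam` columns named
#'   `cpseaac:<residue>` and `cpseaac:<abbr>.<lag>`.
#' @export
cpseaac <- function(seqs, scale = "kyte_doolittle", lam = 5L, w = 0.05) {
  lam <- as.integer(lam)
  stopifnot(lam >= 0L, w >= 0)
  if (is.character(scale)) scale <- hydrophobicity_scales()[[scale]]
  if (is.null(scale) || !all(AA_STANDARD %in% names(scale))) {
    stop("scale must cover all 20 standard residues")
  }
  abbr <- attr(scale, "abbr")
  if (is.null(abbr)) abbr <- "H"
  h <- (scale[AA_STANDARD] - mean(scale[AA_STANDARD])) / stats::sd(scale[AA_STANDARD])
  names(h) <- AA_STANDARD
  clean <- gsub(paste0("[", GAP_CHAR, paste(AA_NONSTANDARD, collapse = ""), "]"),
                "", seqs)
  L <- nchar(clean)
  if (any(L <= lam)) stop("lam must be smaller than the sequence length")
  out <- matrix(0, length(seqs), 20L + lam)
  for (s in seq_along(seqs)) {
    hv <- h[strsplit(clean[s], "")[[1]]]
    f <- tabulate(match(names(hv), AA_STANDARD), nbins = 20L) / L[s]
    theta <- vapply(seq_len(lam), function(j) {
      mean((hv[seq_len(L[s] - j) + j] - hv[seq_len(L[s] - j)])^2)
    }, 0)
    out[s, ] <- c(f, w * theta) / (sum(f) + w * sum(theta))
  }
  colnames(out) <- c(paste0("cpseaac:", AA_STANDARD),
                     if (lam > 0L) paste0("cpseaac:", abbr, ".", seq_len(lam)))
  rownames(out) <- names(seqs)
  out
}

#' The nine feature groups
#'
#' @return character vector of valid group selectors for
#'   [build_feature_matrix()].
#' @export
feature_groups <- function() {
  c("bin_individual", "bin_relaxed", "bin_compact", "bin_disorder_order",
    "kmer1", "kmer2", "kmer3", "cpseaac", "fc")
}

#' Assemble a named feature matrix from windows
#'
#' Concatenates the selected feature groups in a fixed order (the order of
#' [feature_groups()]) into one samples-by-features matrix. A per-group column
#' manifest is attached so accounting of the merged feature space is explicit.
#'
#' @param windows a `window_set`; all windows share one kind and length.
#' @param groups group selectors from [feature_groups()], or `"all"`.
#' @param energy_model an [energy_model()]; required for the `fc` group
#'   (defaults to the bundled matrix via [default_energy_model()]).
#' @param schemes encoding schemes used by the `bin_*` groups.
#' @param cpseaac_scale,cpseaac_lam,cpseaac_w parameters of [cpseaac()].
#' @return numeric matrix of class `feature_matrix` with attributes
#'   `manifest` (named per-group column counts), `kind`, `W`.
#' @export
build_feature_matrix <- function(windows, groups = "all", energy_model = NULL,
                                 schemes = builtin_schemes(),
                                 cpseaac_scale = "kyte_doolittle",
                                 cpseaac_lam = 5L, cpseaac_w = 0.05) {
  if (length(unique(windows$kind)) > 1L) stop("mixed window kinds")
  if (identical(groups, "all")) groups <- feature_groups()
  bad <- setdiff(groups, feature_groups())
  if (length(bad) > 0L) stop("unknown feature group(s): ", paste(bad, collapse = ", "))
  groups <- feature_groups()[feature_groups() %in% groups]
  degapped <- gsub(GAP_CHAR, "", windows$residues, fixed = TRUE)
  names(degapped) <- windows$source_id
  if ("fc" %in% groups && is.null(energy_model)) {
    energy_model <- default_energy_model()
  }
  blocks <- lapply(groups, function(g) {
    if (startsWith(g, "bin_")) {
      encode_binary(windows, schemes[[sub("^bin_", "", g)]])
    } else if (g %in% c("kmer1", "kmer2", "kmer3")) {
      kmer_fractions(degapped, k = as.integer(sub("kmer", "", g)))
    } else if (g == "cpseaac") {
      cpseaac(degapped, scale = cpseaac_scale, lam = cpseaac_lam, w = cpseaac_w)
    } else {
      fc <- t(vapply(degapped,
                     function(s) folding_energies(composition(s), energy_model)$e,
                     numeric(20L)))
      colnames(fc) <- paste0("fc:e", seq_len(20L))
      fc
    }
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- windows$source_id
  manifest <- vapply(blocks, ncol, 0L)
  names(manifest) <- groups
  stopifnot(ncol(X) == sum(manifest))  # bookkeeping identity
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  structure(X, manifest = manifest, kind = attr(windows, "kind"),
            W = attr(windows, "W"), class = c("feature_matrix", class(X)))
}
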