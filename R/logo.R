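# Logo-like representation of a linear model's position-specific weights.
#
# Coefficients c_k are first normalized by the feature's standard deviation,
# w_ik = c_k / sd_k. Per position i the per-sign cumulative weights are
# s_i- = sum of negative w_ik and s_i+ = sum of positive w_ik; these are
# rescaled by the maximal per-sign absolute sum over positions,
# S_i+- = s_i+- / max_i |s_i+-|, so S_i+ lies in [0, 1] and S_i- in [-1, 0].
# Within a stack, each feature's height is its share of the per-sign sum:
# H_ik = (w_ik / s_i(sign)) * |S_i(sign)|.

#' Logo stacks from a linear model's positional coefficients
#'
#' Only position-specific binary features (names `bin_<scheme>:pos<i>:<sym>`)
#' enter the logo; other selected features (k-mer, pseudo-amino-acid,
#' folding-component) are listed separately by [nonpositional_features()].
#' Positive stacks are normalized to `[0, 1]`, negative stacks to `[-1, 0]`,
#' and all quantities are invariant to positive rescaling of the
#' coefficients.
#'
#' @param model a `trained_model` with a linear payload.
#' @return `data.frame` of class `logo_stacks` with columns `position`,
#'   `symbol`, `sign` (+1/-1), `height` (non-negative), `stack_total`
#'   (the signed `S_i` of the entry's sign at that position). Empty when the
#'   model selected no positional features.
#' @export
normalize_weights <- function(model) {
  if (!identical(model$payload$type, "linear")) {
    stop("logo export requires a linear model payload")
  }
  cf <- model$payload$coef
  m <- regmatches(names(cf),
                  regexec("^bin_[^:]+:pos([0-9]+):(.+)$", names(cf)))
  keep <- vapply(m, length, 0L) == 3L & cf != 0
  cf <- cf[keep]
  if (length(cf) == 0L) {
    return(structure(
      data.frame(position = integer(0), symbol = character(0),
                 sign = integer(0), height = numeric(0),
                 stack_total = numeric(0)),
      class = c("logo_stacks", "data.frame")))
  }
  m <- m[keep]
  pos <- vapply(m, function(x) as.integer(x[2]), 0L)
  sym <- vapply(m, function(x) x[3], "")
  w <- cf / model$scale[names(cf)]
  sgn <- ifelse(w > 0, 1L, -1L)
  key <- paste0(pos, "/", sgn)
  s <- tapply(w, key, sum)                       # per-position per-sign sums
  smax <- c(`1` = max(abs(s[grepl("/1$", names(s))]), 0),
            `-1` = max(abs(s[grepl("/-1$", names(s))]), 0))
  S <- s / ifelse(grepl("/1$", names(s)), smax["1"], smax["-1"])
  H <- (w / s[key]) * abs(S[key])
  out <- data.frame(position = pos, symbol = sym, sign = sgn,
                    height = unname(H), stack_total = unname(S[key]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, -out$sign, -out$height), ]
  rownames(out) <- NULL
  structure(out, class = c("logo_stacks", "data.frame"))
}

#' Non-positional selected features of a linear model
#'
#' The side table accompanying a logo: selected features that do not map to
#' a single window position, with their sd-normalized weights.
#'
#' @param model a `trained_model` with a linear payload.
#' @return `data.frame` with columns `feature`, `weight`.
#' @export
nonpositional_features <- function(model) {
  if (!identical(model$payload$type, "linear")) {
    stop("requires a linear model payload")
  }
  cf <- model$payload$coef
  positional <- grepl("^bin_[^:]+:pos[0-9]+:", names(cf))
  cf <- cf[!positional]
  data.frame(feature = names(cf),
             weight = unname(cf / model$scale[names(cf)]),
             stringsAsFactors = FALSE)
}

#' Render logo stacks to a file
#'
#' TSV output is the tested, bit-exact surface (columns `position`, `symbol`,
#' `sign`, `height`, `stack_total`). SVG output draws stacked symbols above
#' (positive) and below (negative) a zero axis with heights proportional to
#' the stack entries.
#'
#' @param stacks a `logo_stacks` data.frame from [normalize_weights()].
#' @param path output file path.
#' @param format `"tsv"` or `"svg"`.
#' @return `path`, invisibly.
#' @export
render_logo <- function(stacks, path, format = c("tsv", "svg")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- stacks
    out$height <- sprintf("%.12f", out$height)
    out$stack_total <- sprintf("%.12f", out$stack_total)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(stacks) == 0L) stop("no stacks to draw")
  px <- 14          # x pixels per position
  scale_y <- 90     # pixels per unit height
  mid <- 100
  wd <- (max(stacks$position) + 2) * px
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="200">', wd),
    sprintf('<line x1="0" y1="%d" x2="%d" y2="%d" stroke="black"/>', mid, wd, mid)
  )
  for (i in unique(stacks$position)) {
    for (sg in c(1L, -1L)) {
      rows <- stacks[stacks$position == i & stacks$sign == sg, , drop = FALSE]
      y0 <- 0
      for (r in seq_len(nrow(rows))) {
        h <- rows$height[r] * scale_y
        ytext <- if (sg > 0) mid - y0 - 2 else mid + y0 + h - 2
        lines <- c(lines, sprintf(
          '<text x="%d" y="%.1f" font-size="%.1f" text-anchor="middle">%s</text>',
          i * px, ytext, max(h, 1), rows$symbol[r]))
        y0 <- y0 + h
      }
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
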