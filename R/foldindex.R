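#' FoldIndex score of a single sequence window
#'
#' FoldIndex combines mean hydrophobicity and mean net charge into a
#' fold/unfold propensity: `I = 2.785 * H - |R| - 1.151`, where `H` is the
#' Kyte-Doolittle hydropathy rescaled to `[0, 1]` via `(KD + 4.5) / 9` and
#' averaged over the window, and `R` is the mean net charge (K, R = +1;
#' D, E = -1; H = 0). Positive scores predict ordered, negative disordered
#' sequence. Values are bounded by `[-2.151, 1.634]`.
#'
#' @param window_seq amino-acid string (standard 20 letters).
#' @param on_unknown policy for non-standard letters: "error" or "skip".
#' @return numeric score.
#' @export
foldindex_window <- function(window_seq, on_unknown = c("error", "skip")) {
  aa <- split_residues(window_seq, on_unknown)
  H <- mean((.KD[aa] + 4.5) / 9)
  R <- mean(.CHARGE[aa])
  2.785 * H - abs(R) - 1.151
}

#' Per-position FoldIndex profile
#'
#' Computes the FoldIndex score of a length-`window` segment around every
#' position. Windows are full width everywhere: near the termini the window
#' is shifted inward (clamped) rather than truncated, so each reported value
#' is a genuine `window`-residue score and `window = nchar(sequence)` yields
#' a constant profile equal to the whole-sequence score.
#'
#' @param sequence amino-acid string.
#' @param window window size in residues, `1 <= window <= nchar(sequence)`.
#' @param on_unknown see [foldindex_window()].
#' @return numeric vector, one score per sequence position.
#' @export
foldindex_profile <- function(sequence, window, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  aa <- split_residues(sequence, on_unknown)
  L <- length(aa)
  window <- as.integer(window)
  sk_assert(window >= 1L, "window must be >= 1", "bad-window")
  sk_assert(window <= L, "window exceeds sequence length", "bad-window")
  h <- (.KD[aa] + 4.5) / 9
  q <- .CHARGE[aa]
  # rolling sums over all length-`window` segments via cumulative sums
  ch <- c(0, cumsum(h)); cq <- c(0, cumsum(q))
  starts_all <- seq_len(L - window + 1L)
  Hs <- (ch[starts_all + window] - ch[starts_all]) / window
  Rs <- (cq[starts_all + window] - cq[starts_all]) / window
  seg <- 2.785 * Hs - abs(Rs) - 1.151
  # clamp each position's centered window into the sequence
  pos <- seq_len(L)
  start <- pmin(pmax(pos - (window - 1L) %/% 2L, 1L), L - window + 1L)
  unname(seg[start])
}

#' Composite multi-window disorder profile
#'
#' Stacks FoldIndex profiles computed at several window sizes, each scaled by
#' the reciprocal of its window size so that profiles of different windows
#' are comparable on one plot. Scaling by a positive constant preserves the
#' sign of every value (positive = ordered, negative = disordered).
#'
#' @param sequence amino-acid string.
#' @param windows integer vector of window sizes (default 10, 20, 50, 100).
#' @param on_unknown see [foldindex_window()].
#' @return object of class `disorder_profile`: list with `windows`,
#'   `scores` (matrix, windows x positions, normalized), and
#'   `normalized = TRUE`.
#' @export
composite_disorder <- function(sequence, windows = c(10L, 20L, 50L, 100L),
                               on_unknown = c("error", "skip")) {
  sk_assert(length(windows) > 0, "window list must be non-empty", "bad-window")
  m <- vapply(as.integer(windows),
              function(w) foldindex_profile(sequence, w, on_unknown) / w,
              numeric(nchar(sequence)))
  m <- t(matrix(m, ncol = length(windows)))
  rownames(m) <- as.character(windows)
  structure(list(windows = as.integer(windows), scores = m, normalized = TRUE),
            class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf("<disorder_profile> %d positions, windows: %s (1/w normalized)\n",
              ncol(x$scores), paste(x$windows, collapse = ", ")))
  invisible(x)
}
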