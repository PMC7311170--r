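#' Per-column sum-of-pairs conservation of an alignment
#'
#' For each alignment column the sum-of-pairs score
#' `SP(c) = 2 / (N_c (N_c - 1)) * sum_{j<k} M(a_j, a_k)` is computed over the
#' `N_c` non-gap residues of the column using substitution matrix `M`
#' (BLOSUM62 by default, no sequence weighting). Pairs involving gaps are
#' excluded; a column with fewer than two residues yields `NA` and is listed
#' in the `undefined` attribute. A column of identical residues scores the
#' matrix diagonal entry (11 for all-W, 4 for all-A under BLOSUM62).
#'
#' @param msa aligned sequences: character vector of equal-length gapped
#'   strings (gaps "-" or "."), or a `Biostrings::AAStringSet` /
#'   `AAMultipleAlignment`.
#' @param matrix substitution matrix id ("BLOSUM62") or an explicit matrix.
#' @param znorm z-normalize the scores across columns (off by default).
#' @return numeric vector of per-column scores, with attribute `undefined`
#'   (integer positions of flagged columns).
#' @export
conservation_sp <- function(msa, matrix = "BLOSUM62", znorm = FALSE) {
  msa <- as_aligned_strings(msa)
  sk_assert(length(msa) >= 2, "alignment needs at least 2 sequences", "too-few-sequences")
  L <- unique(nchar(msa))
  sk_assert(length(L) == 1, "ragged alignment: sequences differ in length", "ragged-msa")
  M <- get_substitution_matrix(matrix)
  chars <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  chars[chars %in% c("-", ".")] <- NA
  sp <- apply(chars, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2) return(NA_real_)
    tab <- table(col)
    aa <- names(tab); cnt <- as.numeric(tab)
    sub <- M[aa, aa, drop = FALSE]
    # sum over unordered pairs from residue-type counts
    tot <- (sum(outer(cnt, cnt) * sub) - sum(cnt * diag(sub))) / 2
    2 * tot / (n * (n - 1))
  })
  undef <- which(is.na(sp))
  if (znorm) {
    mu <- mean(sp, na.rm = TRUE); s <- stats::sd(sp, na.rm = TRUE)
    sk_assert(is.finite(s) && s > 0, "cannot z-normalize a constant profile", "degenerate")
    sp <- (sp - mu) / s
  }
  attr(sp, "undefined") <- undef
  sp
}

as_aligned_strings <- function(msa) {
  if (inherits(msa, "AAMultipleAlignment")) msa <- methods::as(msa, "AAStringSet")
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  sk_assert(is.character(msa), "msa must be character or a Biostrings set", "bad-msa")
  unname(msa)
}

#' Centered moving-average smoothing
#'
#' Mean over a window centered on each position; at the termini the window is
#' truncated to the available positions, so the output has the input's length
#' and a constant input is returned unchanged. `NA` values are dropped from
#' each window mean.
#'
#' @param values numeric vector.
#' @param window window size in positions (>= 1).
#' @return numeric vector, same length as `values`.
#' @export
sliding_smooth <- function(values, window) {
  sk_assert(length(values) > 0, "empty input", "empty-input")
  window <- as.integer(window)
  sk_assert(window >= 1L, "window must be >= 1", "bad-window")
  if (window == 1L) return(as.numeric(values))
  L <- length(values)
  v <- as.numeric(values)
  ok <- !is.na(v)
  cs <- c(0, cumsum(ifelse(ok, v, 0)))
  cn <- c(0, cumsum(as.numeric(ok)))
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  lo <- pmax(seq_len(L) - half_lo, 1L)
  hi <- pmin(seq_len(L) + half_hi, L)
  n <- cn[hi + 1L] - cn[lo]
  out <- (cs[hi + 1L] - cs[lo]) / n
  out[n == 0] <- NA_real_
  out
}

#' Smoothed conservation profile
#'
#' Convenience wrapper combining [conservation_sp()] and [sliding_smooth()]
#' with the 100-residue window used for full-length conservation plots.
#'
#' @inheritParams conservation_sp
#' @param window smoothing window in residues (default 100).
#' @return list of class `conservation_profile`: `raw_sp`, `smoothed`,
#'   `window`.
#' @export
conservation_profile <- function(msa, window = 100L, matrix = "BLOSUM62",
                                 znorm = FALSE) {
  raw <- conservation_sp(msa, matrix = matrix, znorm = znorm)
  structure(list(raw_sp = as.numeric(raw), smoothed = sliding_smooth(raw, window),
                 window = as.integer(window),
                 undefined = attr(raw, "undefined")),
            class = "conservation_profile")
}

#' Sequence length and average molecular mass
#'
#' @param sequence amino-acid string (standard residues).
#' @return list with `length` (residues) and `mass_kda` (average isotopic
#'   mass including one water, in kDa). The full-length mouse RNF213
#'   sequence, for example, has 5148 residues and a mass of about 584 kDa.
#' @export
sequence_stats <- function(sequence) {
  aa <- split_residues(sequence, on_unknown = "error")
  list(length = length(aa),
       mass_kda = (sum(.RESIDUE_MASS[aa]) + .WATER_MASS) / 1000)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file (plain or aligned).
#' @return named character vector of sequences (gaps retained if present).
#' @export
read_fasta <- function(path) {
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  s <- Biostrings::readBStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  s <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
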