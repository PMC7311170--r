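# Shared fixtures, all built in code at test time.

rot_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3, byrow = TRUE)
}

# Random proper rotation (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Noiseless five-point NADH standard line: 100 a.u. per uM, 50 a.u. offset.
demo_calibration <- function() {
  conc <- c(0, 25, 50, 75, 100)
  fit_calibration(conc, 100 * conc + 50)
}

# Fixed-width PDB ATOM/HETATM line.
pdb_line <- function(record, serial, name, resn, chain, resno, x, y, z, elem) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resn, chain, resno, x, y, z, elem)
}

# Tiny PDB: 3 GLY with CA + 1 GLY backbone-only (no CA) + one HETATM ligand.
write_mixed_pdb <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3, 4, 0, "C"),
    pdb_line("ATOM", 3, "CA", "LYS", "A", 3, 6, 8, 0, "C"),
    pdb_line("ATOM", 4, "N",  "GLY", "A", 4, 9, 9, 0, "N"),  # no CA
    pdb_line("HETATM", 5, "MG", " MG", "A", 900, 1, 1, 1, "MG"),
    "END")
  writeLines(lines, path)
  path
}

# Brute-force FoldIndex profile: recompute every clamped window from scratch.
bf_foldindex_profile <- function(sequence, window) {
  L <- nchar(sequence)
  sapply(seq_len(L), function(i) {
    start <- min(max(1, i - (window - 1) %/% 2), L - window + 1)
    foldindex_window(substr(sequence, start, start + window - 1))
  })
}

# Brute-force sum-of-pairs over explicit residue pairs of one column.
bf_sp_column <- function(col, mat) {
  col <- col[!col %in% c("-", ".")]
  n <- length(col)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (j in seq_len(n - 1))
    for (k in (j + 1):n) tot <- tot + mat[col[j], col[k]]
  2 * tot / (n * (n - 1))
}

random_sequence <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

# Exhaustive global alignment score by plain Needleman-Wunsch DP with affine
# gaps (gap of length L costs open + L * extend), independent of Biostrings.
bf_global_score <- function(a, b, M, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  Md <- matrix(NEG, n + 1, m + 1)  # ends in match
  Ix <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)
  Md[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- M[A[i - 1], B[j - 1]]
    Md[i, j] <- max(Md[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(Md[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                    Iy[i - 1, j] - open - ext)
    Iy[i, j] <- max(Md[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                    Ix[i, j - 1] - open - ext)
  }
  max(Md[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}
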