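# Residue-level constant tables.
#
# Kyte-Doolittle hydropathy, formal side-chain charges at neutral pH, average
# residue (i.e. water-subtracted) masses in Da, and 3<->1 letter codes.
# These are standard published constants; they are data, not tunables.

.KD <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Charge model used by FoldIndex-style net-charge averaging: K/R = +1,
# D/E = -1, H = 0 (histidine treated as neutral; configurable upstream).
.CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Average residue masses (Da), i.e. amino-acid mass minus one water.
.RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

.WATER_MASS <- 18.01528

.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA1_TO_3 <- setNames(names(.AA3), unname(.AA3))

# Three-letter HGVS spellings, e.g. "Arg" -> "R".
.AA3_MIXED <- setNames(unname(.AA3),
                       paste0(substr(names(.AA3), 1, 1),
                              tolower(substr(names(.AA3), 2, 3))))

aa3_to_1 <- function(x) {
  out <- .AA3[toupper(x)]
  unname(out)
}

aa1_to_3 <- function(x) unname(.AA1_TO_3[toupper(x)])

# Split a sequence string into single-residue letters, validating alphabet.
split_residues <- function(sequence, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  sk_assert(is.character(sequence) && length(sequence) == 1L && nzchar(sequence),
            "sequence must be a single non-empty string", "empty-sequence")
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  unknown <- !aa %in% names(.KD)
  if (any(unknown)) {
    if (on_unknown == "error")
      sk_stop(sprintf("unknown residue letter(s): %s",
                      paste(unique(aa[unknown]), collapse = ", ")),
              "unknown-residue")
    aa <- aa[!unknown]
    sk_assert(length(aa) > 0, "no standard residues left after skipping",
              "empty-sequence")
  }
  aa
}

# BLOSUM62 from Biostrings (the canonical distribution of the matrix).
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

get_substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  sk_assert(identical(matrix, "BLOSUM62"),
            "only BLOSUM62 (or an explicit matrix) is supported", "bad-matrix")
  blosum62()
}
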