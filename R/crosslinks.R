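#' Construct a table of link-level crosslink records
#'
#' @param pos_a,pos_b residue positions (author numbering, >= 1).
#' @param res_a,res_b 1-letter residue codes of the linked residues.
#' @param fdr link-level false-discovery rate, in `[0, 1]`.
#' @param score optional search score.
#' @return data.frame of class `crosslink_records` with a logical `duplicate`
#'   column flagging repeated (unordered) residue pairs.
#' @export
crosslink_records <- function(pos_a, pos_b, res_a, res_b, fdr, score = NA_real_) {
  d <- data.frame(pos_a = as.integer(pos_a), pos_b = as.integer(pos_b),
                  res_a = toupper(as.character(res_a)),
                  res_b = toupper(as.character(res_b)),
                  score = as.numeric(score), fdr = as.numeric(fdr),
                  stringsAsFactors = FALSE)
  sk_assert(all(d$pos_a >= 1L) && all(d$pos_b >= 1L), "positions must be >= 1",
            "bad-position")
  sk_assert(all(d$fdr >= 0 & d$fdr <= 1), "fdr must lie in [0, 1]", "bad-fdr")
  sk_assert(all(d$pos_a != d$pos_b), "self-links (pos_a == pos_b) are not allowed",
            "self-link")
  key <- paste(pmin(d$pos_a, d$pos_b), pmax(d$pos_a, d$pos_b))
  d$duplicate <- duplicated(key)
  class(d) <- c("crosslink_records", "data.frame")
  d
}

#' Load a link-level crosslink table from TSV
#'
#' Reads tables in the layout produced by link-level FDR post-processing of a
#' crosslink search (one row per unique residue pair). Rows violating basic
#' invariants (position < 1, fdr outside `[0, 1]`, self-links) are dropped
#' and reported with their line numbers via the `rejected` attribute and a
#' warning; duplicated residue pairs are kept and flagged.
#'
#' @param path TSV file path.
#' @param col_map named character vector mapping the required fields
#'   (`pos_a`, `pos_b`, `res_a`, `res_b`, `fdr`, optionally `score`) to the
#'   file's column names.
#' @return a [crosslink_records()] table with attribute `rejected`
#'   (data.frame: line, reason).
#' @export
load_crosslinks <- function(path, col_map = c(pos_a = "pos_a", pos_b = "pos_b",
                                              res_a = "res_a", res_b = "res_b",
                                              fdr = "fdr", score = "score")) {
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos_a", "pos_b", "res_a", "res_b", "fdr")
  sk_assert(all(col_map[need] %in% names(raw)),
            paste("missing required columns:",
                  paste(setdiff(col_map[need], names(raw)), collapse = ", ")),
            "bad-columns")
  get <- function(field, default = NA) {
    cn <- col_map[field]
    if (!is.na(cn) && cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  d <- data.frame(pos_a = suppressWarnings(as.integer(get("pos_a"))),
                  pos_b = suppressWarnings(as.integer(get("pos_b"))),
                  res_a = toupper(as.character(get("res_a"))),
                  res_b = toupper(as.character(get("res_b"))),
                  score = suppressWarnings(as.numeric(get("score", NA_real_))),
                  fdr = suppressWarnings(as.numeric(get("fdr"))),
                  stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(d))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(d$pos_a) | is.na(d$pos_b) | is.na(d$fdr), "unparseable field")
  reason <- bad(!is.na(d$pos_a) & !is.na(d$pos_b) & (d$pos_a < 1 | d$pos_b < 1),
                "position < 1")
  reason <- bad(!is.na(d$fdr) & (d$fdr < 0 | d$fdr > 1), "fdr outside [0, 1]")
  reason <- bad(!is.na(d$pos_a) & !is.na(d$pos_b) & d$pos_a == d$pos_b, "self-link")
  keep <- is.na(reason)
  rejected <- data.frame(line = which(!keep) + 1L, reason = reason[!keep])
  if (nrow(rejected) > 0)
    warning(sprintf("%d malformed row(s) rejected (see attr 'rejected')",
                    nrow(rejected)))
  out <- crosslink_records(d$pos_a[keep], d$pos_b[keep], d$res_a[keep],
                           d$res_b[keep], d$fdr[keep], d$score[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Write crosslink records as TSV
#'
#' @param records a [crosslink_records()] table.
#' @param path output path.
#' @export
write_crosslinks <- function(records, path) {
  write.table(as.data.frame(records)[, c("pos_a", "pos_b", "res_a", "res_b",
                                         "score", "fdr")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter crosslinks by link-level FDR
#'
#' @param records a [crosslink_records()] table.
#' @param threshold FDR threshold in `(0, 1]`; records with `fdr <= threshold`
#'   are retained (5% link-level FDR by default).
#' @return filtered records.
#' @export
fdr_filter <- function(records, threshold = 0.05) {
  sk_assert(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]",
            "bad-threshold")
  records[records$fdr <= threshold, , drop = FALSE]
}

#' Map crosslinks onto a structure model
#'
#' Computes the Calpha-Calpha distance of each crosslink on `model`. Links
#' are first restricted by `residue_filter` (both ends must match; the
#' lysine-only filter reproduces the headline DSS statistic, since DSS also
#' reacts with S/T/Y at lower specificity). Links whose ends are not modeled
#' are retained with a status recording which end is missing; they never
#' enter distance statistics.
#'
#' @param records a [crosslink_records()] table.
#' @param model a [structure_model()].
#' @param residue_filter character vector of 1-letter codes (default `"K"`),
#'   or `"all"`.
#' @param band inclusive distance band `c(dmin, dmax)` in Angstrom used to
#'   set the `in_band` flag (default `c(15, 30)`, the expected Calpha
#'   separation of DSS-linked lysines).
#' @param chain chain of `model` to map onto (default: first chain).
#' @return data.frame of class `crosslink_mappings`: record columns plus
#'   `distance` (NA when not mapped), `status` (mapped / unmodeled_a /
#'   unmodeled_b / unmodeled_both / no_calpha) and `in_band` (NA when not
#'   mapped).
#' @export
map_crosslinks <- function(records, model, residue_filter = "K",
                           band = c(15, 30), chain = NULL) {
  sk_assert(inherits(model, "structure_model"), "not a structure_model", "bad-model")
  if (is.null(chain)) chain <- model$residues$chain[1]
  if (!identical(residue_filter, "all")) {
    keep <- records$res_a %in% residue_filter & records$res_b %in% residue_filter
    records <- records[keep, , drop = FALSE]
  }
  r <- model$residues[model$residues$chain == chain, , drop = FALSE]
  idx <- match(records$pos_a, r$resnum)
  idy <- match(records$pos_b, r$resnum)
  status <- rep("mapped", nrow(records))
  status[is.na(idx) & !is.na(idy)] <- "unmodeled_a"
  status[!is.na(idx) & is.na(idy)] <- "unmodeled_b"
  status[is.na(idx) & is.na(idy)] <- "unmodeled_both"
  both <- status == "mapped"
  noca <- both & (!r$has_ca[idx] | !r$has_ca[idy])
  noca[is.na(noca)] <- FALSE
  status[noca] <- "no_calpha"
  dist <- rep(NA_real_, nrow(records))
  m <- status == "mapped"
  if (any(m)) {
    dx <- r$x[idx[m]] - r$x[idy[m]]
    dy <- r$y[idx[m]] - r$y[idy[m]]
    dz <- r$z[idx[m]] - r$z[idy[m]]
    dist[m] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  out <- as.data.frame(records)
  out$distance <- dist
  out$status <- status
  out$in_band <- ifelse(m, dist >= band[1] & dist <= band[2], NA)
  class(out) <- c("crosslink_mappings", "data.frame")
  attr(out, "band") <- band
  out
}

#' Distance-band satisfaction statistics
#'
#' Fraction of mapped crosslinks whose Calpha separation lies inside the
#' (inclusive) band; links excluded by mapping status are counted separately
#' and never enter the denominator.
#'
#' @param mappings output of [map_crosslinks()].
#' @param band inclusive `c(dmin, dmax)` in Angstrom; use `c(0, Inf)` for a
#'   pass-everything band or `c(0, 30)` for a conventional single-cutoff mode.
#' @return list: `fraction_in_band` (NA with `undefined = TRUE` if nothing
#'   mapped), `n_mapped`, `n_in_band`, `n_excluded_by_status`.
#' @export
satisfaction_stats <- function(mappings, band = c(15, 30)) {
  sk_assert(band[1] <= band[2], "band must satisfy dmin <= dmax", "bad-band")
  m <- mappings$status == "mapped"
  n_mapped <- sum(m)
  n_in <- sum(mappings$distance[m] >= band[1] & mappings$distance[m] <= band[2])
  list(fraction_in_band = if (n_mapped > 0) n_in / n_mapped else NA_real_,
       n_mapped = n_mapped, n_in_band = n_in,
       n_excluded_by_status = sum(!m),
       undefined = n_mapped == 0)
}

#' Per-domain-pair crosslink breakdown
#'
#' Assigns each mapped crosslink's endpoints to domains and tabulates mapped
#' counts, in-band counts and satisfaction fractions per unordered domain
#' pair, with intra- vs inter-domain totals. Useful for cross-checking the
#' assignment of chain regions during model building.
#'
#' @param mappings output of [map_crosslinks()].
#' @param table a [domain_table()].
#' @param level hierarchy level for the assignment.
#' @param band inclusive distance band in Angstrom.
#' @return list: `pairs` (data.frame domain_a, domain_b, n_mapped, n_in_band,
#'   fraction), `intra` and `inter` totals.
#' @export
domain_breakdown <- function(mappings, table, level = "module", band = c(15, 30)) {
  m <- mappings[mappings$status == "mapped", , drop = FALSE]
  doms <- assign_domain(c(m$pos_a, m$pos_b), table, level)
  da <- doms[seq_len(nrow(m))]
  db <- doms[-seq_len(nrow(m))]
  lo <- pmin(da, db); hi <- pmax(da, db)
  inb <- m$distance >= band[1] & m$distance <= band[2]
  key <- paste(lo, hi, sep = "\r")
  agg_n <- tapply(rep(1L, nrow(m)), key, sum)
  agg_in <- tapply(as.integer(inb), key, sum)
  if (nrow(m) == 0) {
    pairs <- data.frame(domain_a = character(0), domain_b = character(0),
                        n_mapped = integer(0), n_in_band = integer(0),
                        fraction = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(names(agg_n), "\r", fixed = TRUE))
    pairs <- data.frame(domain_a = parts[, 1], domain_b = parts[, 2],
                        n_mapped = as.integer(agg_n),
                        n_in_band = as.integer(agg_in),
                        fraction = as.numeric(agg_in / agg_n),
                        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
  }
  intra <- pairs$domain_a == pairs$domain_b
  list(pairs = pairs,
       intra = list(n_mapped = sum(pairs$n_mapped[intra]),
                    n_in_band = sum(pairs$n_in_band[intra])),
       inter = list(n_mapped = sum(pairs$n_mapped[!intra]),
                    n_in_band = sum(pairs$n_in_band[!intra])))
}
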