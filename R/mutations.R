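#' Parse HGVS protein-level variant notation
#'
#' Handles missense substitutions in one- or three-letter form
#' (`p.R4810K`, `p.Arg4753Lys`) and recognizes delins records
#' (`p.3941_3999delinsGSGSG`) as typed non-missense entries that downstream
#' clustering steps skip, matching a missense-only curation policy.
#'
#' @param x character vector of HGVS p. strings.
#' @return data.frame of class `mutation_records`: `hgvs_p`, `type`
#'   ("missense" or "delins"), `ref_aa`, `position`, `alt_aa` (NA for
#'   non-missense), plus empty `cadd`, `mapped_position`, `domain`,
#'   `severity_bin` columns to be filled by later steps.
#' @export
parse_hgvs_p <- function(x) {
  x <- as.character(x)
  one <- "^p\\.([A-Z])(\\d+)([A-Z])$"
  three <- "^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$"
  delins <- "^p\\.(\\d+)_(\\d+)delins([A-Za-z]+)$"
  n <- length(x)
  out <- data.frame(hgvs_p = x, type = NA_character_, ref_aa = NA_character_,
                    position = NA_integer_, alt_aa = NA_character_,
                    stringsAsFactors = FALSE)
  m1 <- grepl(one, x); m3 <- grepl(three, x); md <- grepl(delins, x)
  bad <- !(m1 | m3 | md)
  if (any(bad))
    sk_stop(paste("malformed HGVS p. string(s):",
                  paste(unique(x[bad]), collapse = ", ")), "bad-hgvs")
  if (any(m1)) {
    out$type[m1] <- "missense"
    out$ref_aa[m1] <- sub(one, "\\1", x[m1])
    out$position[m1] <- as.integer(sub(one, "\\2", x[m1]))
    out$alt_aa[m1] <- sub(one, "\\3", x[m1])
  }
  if (any(m3)) {
    r <- .AA3_MIXED[sub(three, "\\1", x[m3])]
    a <- .AA3_MIXED[sub(three, "\\3", x[m3])]
    sk_assert(!anyNA(r) && !anyNA(a), "unknown three-letter residue code", "bad-hgvs")
    out$type[m3] <- "missense"
    out$ref_aa[m3] <- unname(r)
    out$position[m3] <- as.integer(sub(three, "\\2", x[m3]))
    out$alt_aa[m3] <- unname(a)
  }
  if (any(md)) {
    out$type[md] <- "delins"
    out$position[md] <- as.integer(sub(delins, "\\1", x[md]))
  }
  mis <- out$type == "missense"
  sk_assert(all(out$ref_aa[mis] != out$alt_aa[mis]),
            "missense records must change the residue (ref != alt)", "bad-hgvs")
  sk_assert(all(out$position >= 1L),
            "positions must be >= 1", "bad-hgvs")
  out$cadd <- NA_real_
  out$mapped_position <- NA_integer_
  out$domain <- NA_character_
  out$severity_bin <- NA_character_
  class(out) <- c("mutation_records", "data.frame")
  out
}

#' Format missense records back to HGVS one-letter strings
#'
#' @param records a `mutation_records` table.
#' @return character vector (`NA` for non-missense rows).
#' @export
format_hgvs_p <- function(records) {
  ifelse(records$type == "missense",
         paste0("p.", records$ref_aa, records$position, records$alt_aa),
         NA_character_)
}

#' Check missense records against a reference sequence
#'
#' @param records a `mutation_records` table (source numbering).
#' @param sequence reference amino-acid string in the same numbering.
#' @return character vector per record: `"ok"` when the reference residue
#'   matches, `"mismatch"` when it does not, `"out_of_range"` when the
#'   position exceeds the sequence.
#' @export
validate_reference <- function(records, sequence) {
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pos <- records$position
  out <- rep("ok", nrow(records))
  oor <- pos > length(aa)
  out[oor] <- "out_of_range"
  chk <- !oor & records$type == "missense"
  out[chk][aa[pos[chk]] != records$ref_aa[chk]] <- "mismatch"
  out
}

#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch global alignment with affine gaps, computed with
#' `Biostrings::pairwiseAlignment()` (BLOSUM62, gap open 11, extend 1 by
#' default, Biostrings' deterministic traceback). A curated alignment can be
#' supplied directly via [as_alignment()] instead.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param matrix substitution matrix id or matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`.
#' @export
pairwise_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  sk_assert(nzchar(seq_a) && nzchar(seq_b), "sequences must be non-empty",
            "empty-sequence")
  M <- get_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = M, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  as_alignment(as.character(Biostrings::alignedPattern(pa)),
               as.character(Biostrings::alignedSubject(pa)),
               score = Biostrings::score(pa))
}

#' Wrap a pre-computed gapped sequence pair as an alignment
#'
#' @param aligned_a,aligned_b equal-length gapped strings ("-" gaps).
#' @param score optional alignment score.
#' @return a `pairwise_alignment`.
#' @export
as_alignment <- function(aligned_a, aligned_b, score = NA_real_) {
  sk_assert(nchar(aligned_a) == nchar(aligned_b),
            "aligned strings must have equal length", "ragged-alignment")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b, score = score),
            class = "pairwise_alignment")
}

#' Transfer residue numbering through an alignment
#'
#' Maps source positions (ungapped numbering of one aligned sequence) to the
#' corresponding positions of the other sequence. Positions aligned to a gap
#' return `NA` ("gapped"). The mapping is strictly monotone over non-gapped
#' positions and round-trips with the reverse direction.
#'
#' @param position integer vector of source positions.
#' @param alignment a `pairwise_alignment`.
#' @param from which aligned sequence the positions refer to: `"a"` or `"b"`.
#' @return integer vector of target positions (`NA` where gapped).
#' @export
transfer_numbering <- function(position, alignment, from = c("a", "b")) {
  from <- match.arg(from)
  src <- strsplit(if (from == "a") alignment$aligned_a else alignment$aligned_b,
                  "", fixed = TRUE)[[1]]
  tgt <- strsplit(if (from == "a") alignment$aligned_b else alignment$aligned_a,
                  "", fixed = TRUE)[[1]]
  src_res <- !src %in% c("-", ".")
  tgt_res <- !tgt %in% c("-", ".")
  tgt_num <- cumsum(tgt_res)
  col_of <- which(src_res)            # column of the i-th source residue
  position <- as.integer(position)
  sk_assert(all(position >= 1L & position <= sum(src_res)),
            "position outside the source sequence", "out-of-range")
  cols <- col_of[position]
  ifelse(tgt_res[cols], tgt_num[cols], NA_integer_)
}

#' Bin CADD scores into severity classes
#'
#' Left-closed bins matching the conventional structure-coloring scheme:
#' `[0, 15)` low (green), `[15, 20)` mid (cyan), `[20, Inf)` high (blue).
#' Note that the severe-mutation *clustering* count uses the strict
#' `cadd > threshold` rule (see [domain_cluster_counts()]); the coloring bin
#' of exactly 20 is "high" while the clustering rule excludes it.
#'
#' @param cadd numeric vector of CADD scores (>= 0).
#' @param edges two increasing bin edges (default 15, 20).
#' @return character vector: "low", "mid" or "high".
#' @export
bin_severity <- function(cadd, edges = c(15, 20)) {
  sk_assert(all(cadd >= 0, na.rm = TRUE), "CADD scores must be >= 0", "bad-cadd")
  sk_assert(length(edges) == 2 && edges[1] < edges[2], "need two increasing edges",
            "bad-edges")
  out <- rep(NA_character_, length(cadd))
  out[cadd < edges[1]] <- "low"
  out[cadd >= edges[1] & cadd < edges[2]] <- "mid"
  out[cadd >= edges[2]] <- "high"
  out
}

#' Load a mutation table (HGVS + CADD) from TSV
#'
#' @param path TSV with columns `hgvs_p` and `cadd` (extra columns ignored).
#' @return `mutation_records` with `cadd` and `severity_bin` filled.
#' @export
load_mutation_table <- function(path) {
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  d <- read.delim(path, stringsAsFactors = FALSE)
  sk_assert(all(c("hgvs_p", "cadd") %in% names(d)),
            "mutation TSV must have columns hgvs_p and cadd", "bad-columns")
  rec <- parse_hgvs_p(d$hgvs_p)
  rec$cadd <- as.numeric(d$cadd)
  rec$severity_bin <- ifelse(is.na(rec$cadd), NA_character_, bin_severity(rec$cadd))
  rec
}

#' Count severe mutations and their clustering in target domains
#'
#' Severe mutations are those with `cadd > severity_threshold` (strict, as in
#' the printed "CADD-score >20" convention). Of these, the count whose
#' mapped position falls in any of the target domains is reported, mirroring
#' the observation that 21 of 28 severe mutations localize in the four E3
#' sub-domains.
#'
#' @param records `mutation_records` with `mapped_position` and `cadd` set.
#' @param table a [domain_table()].
#' @param severity_threshold strict CADD threshold (default 20).
#' @param target_domains character vector of domain names
#'   (default [e3_subdomains()]).
#' @param level hierarchy level of the target domains.
#' @return list: `n_severe`, `n_in_target`, `per_domain` (data.frame of
#'   severe counts by domain), `n_unmapped` (severe records lacking a mapped
#'   position, reported separately).
#' @export
domain_cluster_counts <- function(records, table, severity_threshold = 20,
                                  target_domains = e3_subdomains(),
                                  level = "subdomain") {
  mis <- records[records$type == "missense", , drop = FALSE]
  sev <- mis[!is.na(mis$cadd) & mis$cadd > severity_threshold, , drop = FALSE]
  unmapped <- is.na(sev$mapped_position)
  mapped <- sev[!unmapped, , drop = FALSE]
  dom <- assign_domain(mapped$mapped_position, table, level)
  if (length(dom)) {
    per <- as.data.frame(table(domain = dom), stringsAsFactors = FALSE)
    names(per) <- c("domain", "n_severe")
  } else {
    per <- data.frame(domain = character(0), n_severe = integer(0))
  }
  list(n_severe = nrow(sev),
       n_in_target = sum(dom %in% target_domains),
       per_domain = per,
       n_unmapped = sum(unmapped))
}

#' Enrichment of severe mutations in target domains
#'
#' Compares the placement of severe mutations against a residue-length
#' proportional expectation: drawing `n_severe` positions uniformly from the
#' protein, the chance of at least the observed number landing in the target
#' domains follows the hypergeometric distribution over residues. Reported
#' are the sample odds ratio of the 2x2 table (severe in/out of target vs
#' residue counts in/out) and the exact upper hypergeometric tail.
#'
#' @inheritParams domain_cluster_counts
#' @param protein_length total residue count of the protein (defaults to the
#'   largest end coordinate in `table`).
#' @return list: `odds_ratio`, `p_value`, `n_severe`, `n_in_target`,
#'   `target_residues`, `protein_length`, `degenerate` flag.
#' @export
domain_enrichment <- function(records, table, severity_threshold = 20,
                              target_domains = e3_subdomains(),
                              level = "subdomain", protein_length = NULL) {
  cc <- domain_cluster_counts(records, table, severity_threshold,
                              target_domains, level)
  if (is.null(protein_length)) protein_length <- max(table$end)
  K <- length(domain_residues(table, target_domains, level))
  n <- cc$n_severe - cc$n_unmapped
  k <- cc$n_in_target
  if (n == 0 || K == 0 || K == protein_length)
    return(list(odds_ratio = NA_real_, p_value = NA_real_, n_severe = cc$n_severe,
                n_in_target = k, target_residues = K,
                protein_length = protein_length, degenerate = TRUE))
  p <- phyper(k - 1, K, protein_length - K, n, lower.tail = FALSE)
  or <- (k / max(n - k, 0.5)) / (K / (protein_length - K))
  list(odds_ratio = or, p_value = p, n_severe = cc$n_severe, n_in_target = k,
       target_residues = K, protein_length = protein_length, degenerate = FALSE)
}
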