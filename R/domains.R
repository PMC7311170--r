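#' Construct a domain table
#'
#' Named, 1-based inclusive residue ranges at two hierarchy levels:
#' `"module"` (the large structural components) and `"subdomain"` (inserted
#' or internal features). Within one level ranges must not overlap and names
#' must be unique.
#'
#' @param name character vector of domain names.
#' @param start,end integer vectors, 1-based inclusive.
#' @param level "module" or "subdomain", recycled.
#' @return data.frame of class `domain_table`.
#' @export
domain_table <- function(name, start, end, level = "module") {
  d <- data.frame(name = as.character(name), start = as.integer(start),
                  end = as.integer(end),
                  level = rep_len(as.character(level), length(name)),
                  stringsAsFactors = FALSE)
  sk_assert(all(d$level %in% c("module", "subdomain")),
            "level must be 'module' or 'subdomain'", "bad-level")
  sk_assert(all(d$start >= 1L) && all(d$start <= d$end),
            "ranges must satisfy 1 <= start <= end", "bad-range")
  for (lv in unique(d$level)) {
    e <- d[d$level == lv, ]
    sk_assert(!anyDuplicated(e$name),
              paste("duplicate domain names at level", lv), "duplicate-name")
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      sk_stop(paste("overlapping ranges at level", lv), "overlap")
  }
  class(d) <- c("domain_table", "data.frame")
  d
}

#' Domain architecture of mouse RNF213
#'
#' The module-level ranges follow the published architecture of the
#' 5148-residue mouse protein: N-arm 1-1290, linker 1291-1774, AAA core
#' 1775-3405, hinge 3406-3588, E3 module 3589-4926, and the CTD, whose range
#' is not printed explicitly and is inferred as 4927-5148 (from the E3-module
#' end to the model C-terminus).
#'
#' At subdomain level the table carries the regulatory AAA insertions IR3
#' (2487-2538) and IR5 (3063-3103), the E3-RING (3940-3999), the CTD, and an
#' approximate split of the remaining E3 scaffold into E3-back / E3-shell /
#' E3-core. Only the RING boundaries inside the E3 module are published; the
#' back/shell/core split is an editable placeholder whose union
#' (E3 module minus RING, plus CTD) is what matters for the severe-mutation
#' clustering statistic.
#'
#' @return a [domain_table()] with both levels.
#' @export
rnf213_domains <- function() {
  mod <- domain_table(
    name  = c("N-arm", "linker", "AAA core", "hinge", "E3 module", "CTD"),
    start = c(1, 1291, 1775, 3406, 3589, 4927),
    end   = c(1290, 1774, 3405, 3588, 4926, 5148),
    level = "module")
  sub <- domain_table(
    name  = c("IR3", "IR5", "E3-back", "E3-RING", "E3-shell", "E3-core", "CTD"),
    start = c(2487, 3063, 3589, 3940, 4000, 4450, 4927),
    end   = c(2538, 3103, 3939, 3999, 4449, 4926, 5148),
    level = "subdomain")
  out <- rbind(mod, sub)
  class(out) <- c("domain_table", "data.frame")
  out
}

#' The four E3 sub-domains used for mutation clustering
#'
#' @return character vector of subdomain names (E3-back, E3-shell, E3-core,
#'   CTD). Whether the RING counts as part of the E3 fold for clustering is
#'   controlled by `include_ring`.
#' @param include_ring add "E3-RING" to the set.
#' @export
e3_subdomains <- function(include_ring = FALSE) {
  out <- c("E3-back", "E3-shell", "E3-core", "CTD")
  if (include_ring) out <- c(out, "E3-RING")
  out
}

#' Assign residue numbers to domains
#'
#' @param resnum integer vector of residue numbers (author numbering).
#' @param table a [domain_table()].
#' @param level hierarchy level to query.
#' @return character vector: domain name, or `"unassigned"` when no range at
#'   the requested level contains the residue.
#' @export
assign_domain <- function(resnum, table, level = c("module", "subdomain")) {
  level <- match.arg(level)
  resnum <- as.integer(resnum)
  sk_assert(all(resnum >= 1L, na.rm = TRUE), "residue numbers must be >= 1",
            "bad-resnum")
  e <- table[table$level == level, , drop = FALSE]
  out <- rep("unassigned", length(resnum))
  for (i in seq_len(nrow(e)))
    out[!is.na(resnum) & resnum >= e$start[i] & resnum <= e$end[i]] <- e$name[i]
  out[is.na(resnum)] <- NA_character_
  out
}

#' Report gaps and overlaps in a domain table
#'
#' @param table a [domain_table()] (or plain data.frame in the same layout;
#'   overlap checking is done here, so unvalidated tables are acceptable).
#' @param full_range optional `c(min, max)` residue range a level should
#'   cover; defaults to the span of the level's own entries.
#' @param strict raise an error on any same-level overlap.
#' @return list with per-level data.frames `gaps` (uncovered intervals) and
#'   `overlaps` (pairs of overlapping entries).
#' @export
validate_domain_table <- function(table, full_range = NULL, strict = FALSE) {
  out <- list()
  for (lv in unique(table$level)) {
    e <- table[table$level == lv, , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    rng <- if (is.null(full_range)) c(min(e$start), max(e$end)) else as.integer(full_range)
    gaps <- data.frame(start = integer(0), end = integer(0))
    cur <- rng[1]
    for (i in seq_len(nrow(e))) {
      if (e$start[i] > cur)
        gaps <- rbind(gaps, data.frame(start = cur, end = e$start[i] - 1L))
      cur <- max(cur, e$end[i] + 1L)
    }
    if (cur <= rng[2]) gaps <- rbind(gaps, data.frame(start = cur, end = rng[2]))
    ov <- data.frame(a = character(0), b = character(0))
    if (nrow(e) > 1)
      for (i in seq_len(nrow(e) - 1))
        for (j in (i + 1):nrow(e))
          if (e$start[j] <= e$end[i])
            ov <- rbind(ov, data.frame(a = e$name[i], b = e$name[j]))
    if (strict && nrow(ov) > 0)
      sk_stop(sprintf("overlapping domains at level %s: %s", lv,
                      paste(ov$a, ov$b, sep = "/", collapse = ", ")), "overlap")
    out[[lv]] <- list(gaps = gaps, overlaps = ov)
  }
  out
}

#' Read / write a domain table as TSV
#'
#' Plain four-column TSV: `name`, `start`, `end`, `level`.
#'
#' @param path file path.
#' @return a [domain_table()].
#' @export
read_domain_table <- function(path) {
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "level")
  sk_assert(all(need %in% names(d)),
            paste("domain TSV must have columns:", paste(need, collapse = ", ")),
            "bad-columns")
  domain_table(d$name, d$start, d$end, d$level)
}

#' @rdname read_domain_table
#' @param table a [domain_table()] to serialize.
#' @export
write_domain_table <- function(table, path) {
  write.table(as.data.frame(table)[, c("name", "start", "end", "level")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Residue numbers covered by the named domains at one level.
domain_residues <- function(table, names, level = "module") {
  e <- table[table$level == level & table$name %in% names, , drop = FALSE]
  sk_assert(nrow(e) == length(unique(names)),
            "some requested domains are absent from the table", "missing-domain")
  sort(unique(unlist(Map(seq.int, e$start, e$end))))
}
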