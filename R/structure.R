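#' Construct a Calpha-level structure model
#'
#' A `structure_model` is the light-weight container used throughout the
#' package: an ordered table of protein residues in author numbering, each
#' carrying its Calpha coordinate (in Angstrom) when one is modeled.
#' Hetero/non-polymer records (ATP, Zn, Mg in the RNF213 depositions) are
#' never part of a model.
#'
#' @param residues data.frame with columns `chain` (character), `resnum`
#'   (integer, author numbering), `resname` (3-letter code), `x`, `y`, `z`
#'   (numeric, NA when no Calpha), `has_ca` (logical). An optional `insert`
#'   column holds insertion codes ("" when absent); it is part of the residue
#'   identity.
#' @param id identifier string.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(residues, id = "model") {
  need <- c("chain", "resnum", "resname", "x", "y", "z", "has_ca")
  sk_assert(is.data.frame(residues) && all(need %in% names(residues)),
            paste("residues must contain columns:", paste(need, collapse = ", ")),
            "bad-residues")
  if (is.null(residues$insert)) residues$insert <- ""
  residues$insert[is.na(residues$insert)] <- ""
  residues$resnum <- as.integer(residues$resnum)
  key <- paste(residues$chain, residues$resnum, residues$insert, sep = "|")
  sk_assert(!anyDuplicated(key), "(chain, resnum, insert) must be unique",
            "duplicate-residue")
  co <- as.matrix(residues[, c("x", "y", "z")])
  sk_assert(all(is.finite(co[residues$has_ca, , drop = FALSE])),
            "Calpha coordinates must be finite", "bad-coordinates")
  sk_assert(any(residues$has_ca), "model must contain at least one Calpha",
            "empty-model")
  rownames(residues) <- NULL
  structure(list(id = id, residues = residues), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  r <- x$residues
  cat(sprintf("<structure_model> %s: %d residues (%d with Calpha), chains: %s, resnum %d-%d\n",
              x$id, nrow(r), sum(r$has_ca),
              paste(unique(r$chain), collapse = ","),
              min(r$resnum), max(r$resnum)))
  invisible(x)
}

#' Number of residues in a model
#'
#' Counts protein residues (author-numbered polymer records); hetero records
#' are excluded at read time, so this matches a deposition's "protein
#' residues" bookkeeping line.
#'
#' @param model a `structure_model`.
#' @param with_ca if TRUE, count only residues with a modeled Calpha.
#' @return integer count.
#' @export
n_residues <- function(model, with_ca = FALSE) {
  sk_assert(inherits(model, "structure_model"), "not a structure_model", "bad-model")
  if (with_ca) sum(model$residues$has_ca) else nrow(model$residues)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses coordinates with bio3d and reduces them to a Calpha-level
#' [structure_model()]. Only polymer (`ATOM`) records enter the residue table;
#' `HETATM` ligands are dropped. Residues lacking a Calpha are kept and
#' flagged `has_ca = FALSE`. For multi-model PDB files the first model is
#' read unless `model` says otherwise.
#'
#' @param path file path.
#' @param format "pdb", "cif", or "auto" (by extension).
#' @param model 1-based model number (PDB only).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), model = 1L) {
  format <- match.arg(format)
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     sk_stop(paste("cannot infer format from extension:", ext),
                             "unknown-format"))
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = model > 1L, verbose = FALSE)
    xyz <- pdb$xyz
    if (model > 1L) {
      sk_assert(nrow(xyz) >= model,
                sprintf("file has %d model(s); model %d requested", nrow(xyz), model),
                "missing-model")
      co <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
      pdb$atom$x <- co[, 1]; pdb$atom$y <- co[, 2]; pdb$atom$z <- co[, 3]
    }
  } else {
    sk_assert(model == 1L, "model selection is supported for PDB input only",
              "missing-model")
    pdb <- bio3d::read.cif(path, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  sk_assert(nrow(at) > 0, "no polymer ATOM records in file", "empty-model")
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(chain = at$chain[first], resnum = at$resno[first],
                    insert = at$insert[first], resname = at$resid[first],
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    has_ca = FALSE, stringsAsFactors = FALSE)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), , drop = FALSE]
  idx <- match(paste(ca$chain, ca$resno, ca$insert, sep = "|"), key[first])
  res$x[idx] <- ca$x; res$y[idx] <- ca$y; res$z[idx] <- ca$z
  res$has_ca[idx] <- TRUE
  structure_model(res, id = basename(path))
}

#' Write a Calpha-only model as PDB
#'
#' Serializes a [structure_model()] through `bio3d::write.pdb()`, one CA atom
#' per residue with a Calpha. Generated fixtures therefore round-trip through
#' the same parser used for deposited models.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  sk_assert(inherits(model, "structure_model"), "not a structure_model", "bad-model")
  r <- model$residues[model$residues$has_ca, , drop = FALSE]
  xyz <- as.numeric(t(as.matrix(r[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(r)),
                   resno = r$resnum, resid = r$resname, chain = r$chain,
                   insert = ifelse(nzchar(r$insert), r$insert, ""),
                   eleno = seq_len(nrow(r)), elety = rep("CA", nrow(r)),
                   elesy = rep("C", nrow(r)))
  invisible(path)
}

# Locate one residue; returns the row index or fails with a typed error.
resolve_residue <- function(model, chain, resnum, insert = "") {
  r <- model$residues
  i <- which(r$chain == chain & r$resnum == resnum & r$insert == insert)
  if (length(i) == 0)
    sk_stop(sprintf("residue %s/%s%s is not modeled", chain, resnum, insert),
            "unmodeled")
  if (!r$has_ca[i])
    sk_stop(sprintf("residue %s/%s%s has no Calpha", chain, resnum, insert),
            "no-calpha")
  i
}

#' Calpha-Calpha distance between two residues
#'
#' @param model a `structure_model`.
#' @param a,b residue selectors: `list(chain =, resnum =)` or a bare residue
#'   number (first chain assumed).
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(model, a, b) {
  sel <- function(s) {
    if (is.list(s)) list(chain = s$chain, resnum = as.integer(s$resnum))
    else list(chain = model$residues$chain[1], resnum = as.integer(s))
  }
  a <- sel(a); b <- sel(b)
  ia <- resolve_residue(model, a$chain, a$resnum)
  ib <- resolve_residue(model, b$chain, b$resnum)
  r <- model$residues
  sqrt(sum((c(r$x[ia], r$y[ia], r$z[ia]) - c(r$x[ib], r$y[ib], r$z[ib]))^2))
}

# Matrix of Calpha coordinates (rows: residues with CA, in table order).
ca_coords <- function(model) {
  r <- model$residues[model$residues$has_ca, , drop = FALSE]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- paste(r$chain, r$resnum, r$insert, sep = "|")
  m
}
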