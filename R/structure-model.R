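# Structure parsing and writing.  Coordinate files are parsed with bio3d
# (PDB and mmCIF); the model keeps polymer ATOM records only, the first
# model of multi-model files, and the highest-occupancy alternate conformer.

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Read a protein structure
#'
#' Parses an mmCIF or PDB coordinate file into a [StructureModel-class].
#' Heteroatoms and waters are excluded, the first model is kept for
#' multi-model files, alternate locations are resolved to the
#' highest-occupancy conformer, and author residue numbering is preserved
#' (insertion codes become part of the position key downstream).
#'
#' @param path coordinate file (`.cif` or `.pdb`/`.ent`).
#' @param chain optional chain selector (character vector); default all.
#' @param format "auto" (by extension), "cif" or "pdb".
#' @param proteinId identifier; defaults to the file base name, lowercased.
#' @param provenance "experimental" or "predicted".
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, chain = NULL, format = c("auto", "cif", "pdb"),
                          proteinId = NULL,
                          provenance = c("experimental", "predicted")) {
  format <- match.arg(format)
  provenance <- match.arg(provenance)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stopf("cannot parse %s as %s: %s", path, format,
                              conditionMessage(e)))
  a <- parsed$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% WATER_RESIDUES), , drop = FALSE]
  if (nrow(a) == 0) stopf("%s contains no polymer ATOM records", path)
  if (!is.null(chain)) {
    a <- a[a$chain %in% chain, , drop = FALSE]
    if (nrow(a) == 0)
      stopf("chain selection '%s' matches no atoms in %s",
            paste(chain, collapse = ","), path)
  }
  # highest-occupancy altloc per atom slot
  occ <- if ("o" %in% names(a)) ifelse(is.na(a$o), 1, a$o) else rep(1, nrow(a))
  ins <- if ("insert" %in% names(a)) ifelse(is.na(a$insert), "", a$insert)
         else rep("", nrow(a))
  idx0 <- seq_len(nrow(a))
  ord <- order(a$chain, a$resno, ins, a$elety, -occ)
  a <- a[ord, , drop = FALSE]; ins <- ins[ord]; idx0 <- idx0[ord]
  keep <- !duplicated(data.frame(a$chain, a$resno, ins, a$elety))
  a <- a[keep, , drop = FALSE]; ins <- ins[keep]; idx0 <- idx0[keep]
  back <- order(idx0)   # restore original file order after dedup
  a <- a[back, , drop = FALSE]; ins <- ins[back]
  ele <- if ("elesy" %in% names(a)) toupper(trimws(a$elesy)) else rep("", nrow(a))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", a$elety)), 1, 1))
  ele[is.na(ele) | ele == ""] <- guess[is.na(ele) | ele == ""]
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      insert = ins, resid = a$resid, elety = a$elety,
                      element = ele, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  methods::new("StructureModel",
               proteinId = proteinId %||%
                 tolower(sub("\\.[^.]+$", "", basename(path))),
               atoms = atoms, provenance = provenance)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z.
#' @param proteinId identifier string.
#' @param provenance "experimental" or "predicted".
#' @return a [StructureModel-class].
#' @export
structureModel <- function(atoms, proteinId = "xxxx",
                           provenance = "experimental") {
  if (is.null(atoms$insert)) atoms$insert <- ""
  methods::new("StructureModel", proteinId = proteinId, atoms = atoms,
               provenance = provenance)
}

# residue table: one row per residue, in file order
residueTable <- function(model) {
  a <- model@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], resid = a$resid[idx],
             key = key[idx], stringsAsFactors = FALSE)
}

# named coordinates of one backbone atom per residue; NA rows when absent
atomCoords <- function(model, elety) {
  a <- model@atoms
  res <- residueTable(model)
  sel <- a[a$elety == elety, , drop = FALSE]
  m <- matrix(NA_real_, nrow(res), 3)
  i <- match(paste(sel$chain, sel$resno, sel$insert, sep = "\r"), res$key)
  m[i, ] <- cbind(sel$x, sel$y, sel$z)
  m
}

#' Number of residues per chain
#' @param model a [StructureModel-class].
#' @return named integer vector (chain -> residue count).
#' @export
chainLengths <- function(model) {
  res <- residueTable(model)
  vapply(split(res$key, res$chain), length, integer(1))
}

#' One-letter sequence of a chain
#' @param model a [StructureModel-class].
#' @param chain chain identifier.
#' @return character scalar; unknown residue types become "X".
#' @export
chainSequence <- function(model, chain) {
  res <- residueTable(model)
  res <- res[res$chain == chain, , drop = FALSE]
  one <- AA_THREE_TO_ONE[res$resid]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

setMethod("show", "StructureModel", function(object) {
  res <- residueTable(object)
  cat(sprintf("StructureModel '%s' (%s): %d atoms, %d residues, chains %s\n",
              object@proteinId, object@provenance, nrow(object@atoms),
              nrow(res), paste(unique(res$chain), collapse = ",")))
})

#' Write a structure model as PDB
#'
#' Minimal fixed-width ATOM-record writer used by the synthetic fixture
#' generators; output is parseable by [readStructure()].
#'
#' @param model a [StructureModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
  a <- model@atoms
  name <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as mmCIF
#'
#' Minimal `_atom_site` loop writer; output is parseable by
#' [readStructure()].
#'
#' @param model a [StructureModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructureCIF <- function(model, path) {
  a <- model@atoms
  hdr <- c(sprintf("data_%s", model@proteinId), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  seqres <- cumsum(!duplicated(paste(a$chain, a$resno, a$insert)))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, seqres,
    ifelse(a$insert == "", "?", a$insert), a$x, a$y, a$z,
    a$resno, a$resid, a$chain, a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
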