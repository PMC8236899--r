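#' @title Uniform structural model for pMHC analysis
#' @description
#' A `pmhc_structure` holds one macromolecular model as a flat atom table plus
#' an identifier. Atom records keep author chain/residue numbering (with
#' insertion codes), occupancy, altloc and element so that every downstream
#' stage (hydrogen bonds, SASA, contacts) works from the same container.
#' Waters are kept in the table but flagged, and excluded from polymer
#' operations.
#' @name pmhc_structure
NULL

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M")

new_structure <- function(id, atoms) {
  need <- c("chain", "resno", "icode", "resname", "elety", "element",
            "x", "y", "z", "o", "het", "alt")
  stopifnot(all(need %in% names(atoms)))
  atoms$resno <- as.integer(atoms$resno)
  atoms$water <- atoms$het & atoms$resname %in% WATER_NAMES
  atoms$reskey <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  structure(list(id = id, atoms = atoms), class = "pmhc_structure")
}

residue_key <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

#' Parse a coordinate file into a structure
#'
#' Reads PDB or mmCIF content (text or a file path) into a [pmhc_structure]
#' atom table. Parsing of both dialects is delegated to \pkg{bio3d}; PDB input
#' is pre-validated line by line so that malformed ATOM/HETATM records are
#' reported with their line number. Alternate locations are reduced to a
#' single conformer per atom: the highest-occupancy altloc is kept, ties
#' broken by altloc letter order, so downstream geometry is deterministic.
#'
#' @param text character; either coordinate-file content (possibly a vector of
#'   lines) or, when `is_path = TRUE`, a file path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @param id structure identifier; defaults to `"structure"`.
#' @param is_path logical; treat `text` as a path.
#' @return a `pmhc_structure`.
#' @export
parse_structure <- function(text, dialect = c("pdb", "mmcif"),
                            id = "structure", is_path = FALSE) {
  dialect <- match.arg(dialect)
  if (is_path) {
    path <- text
    if (!file.exists(path)) stop("no such coordinate file: ", path)
  } else {
    if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    if (!any(nzchar(text))) stop("empty coordinate input: no atoms")
    path <- tempfile(fileext = if (dialect == "pdb") ".pdb" else ".cif")
    writeLines(text, path)
    on.exit(unlink(path))
  }
  if (dialect == "pdb") validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- if (dialect == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                                     verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, rm.insert = FALSE,
                                     verbose = FALSE))
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atom records")
  element <- trimws(ifelse(is.na(at$elesy) | at$elesy == "", NA, at$elesy))
  miss <- is.na(element)
  if (any(miss)) element[miss] <- guess_element(at$elety[miss])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    elety = at$elety,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  new_structure(id, atoms)
}

validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("malformed PDB record at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

guess_element <- function(elety) {
  e <- gsub("[0-9']", "", trimws(elety))
  two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "CA", "SE")
  out <- substr(e, 1, 1)
  isel <- toupper(e) %in% two & nchar(e) >= 2
  out[isel] <- substr(e[isel], 1, 2)
  toupper(out)
}

# Keep one conformer per (residue, atom name): highest occupancy, ties broken
# by altloc letter order ("" sorts first and wins over lettered ties).
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$het, atoms$chain, atoms$resno, atoms$icode,
              match(atoms$elety, c("N", "CA", "C", "O", "CB"))), ,
        drop = FALSE]
}

#' Write a structure as PDB text
#'
#' Minimal fixed-width PDB writer used for fixtures and transformed
#' coordinates; output round-trips through [parse_structure()].
#'
#' @param st a `pmhc_structure`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_structure_pdb <- function(st, path = NULL) {
  at <- st$atoms
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)), name4,
    substr(paste0(at$alt, " "), 1, 1), at$resname, substr(paste0(at$chain, " "), 1, 1),
    at$resno, substr(paste0(at$icode, " "), 1, 1),
    at$x, at$y, at$z, at$o, 0, at$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.pmhc_structure <- function(x, ...) {
  at <- x$atoms
  pol <- at[!at$het, , drop = FALSE]
  cat("pmhc_structure '", x$id, "': ", nrow(at), " atoms, ",
      length(unique(pol$reskey)), " polymer residues in chains [",
      paste(unique(pol$chain), collapse = ", "), "], ",
      sum(at$water), " water atoms\n", sep = "")
  invisible(x)
}

# Residue-level table: one row per residue, polymer only unless het = TRUE.
residue_table <- function(st, het = FALSE) {
  at <- st$atoms
  if (!het) at <- at[!at$het, , drop = FALSE]
  keep <- !duplicated(at$reskey)
  at[keep, c("chain", "resno", "icode", "resname", "reskey"), drop = FALSE]
}

# Coordinates of one named atom for a set of residue keys; rows of NA where
# the atom is absent.
atom_coords <- function(st, reskeys, atom = "CA") {
  at <- st$atoms[st$atoms$elety == atom, , drop = FALSE]
  idx <- match(reskeys, at$reskey)
  m <- cbind(at$x[idx], at$y[idx], at$z[idx])
  rownames(m) <- reskeys
  m
}

# All atoms belonging to a set of residue keys.
atoms_of <- function(st, reskeys) {
  st$atoms[st$atoms$reskey %in% reskeys, , drop = FALSE]
}

# Apply a rigid transform, returning a modified copy.
transform_structure <- function(st, R, t) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  xyz <- apply_rigid(xyz, R, t)
  st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  st
}
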