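#' Read a protein structure from a PDB file
#'
#' Parses `ATOM` and `HETATM` records of a PDB file into a
#' `protein_structure` object.  Only the first model of a multi-model file
#' is kept.  When alternate locations are present, the highest-occupancy
#' altloc is retained (ties go to the first record).  The element symbol is
#' taken from columns 77-78 when present, otherwise from the first
#' alphabetic character of the atom name.
#'
#' @param path Path to a PDB file containing at least one `ATOM` record.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A `protein_structure`: a list with `id`, an `atoms` data frame
#'   (serial, atom_name, element, residue_name, residue_seq, chain_id,
#'   x, y, z, is_hetero, occupancy), `ligand_groups` (hetero residues
#'   grouped by residue name/chain/number) and `chain_sequences`
#'   (1-letter sequence per chain).
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # model 1 only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(rec == "ATOM  "))
    stopf("PDB format error: no ATOM records in %s", path)
  idx <- which(keep)
  ln <- lines[idx]
  fw <- function(a, b) trimws(substr(ln, a, b))
  num <- function(a, b, what) {
    raw <- substr(ln, a, b)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & trimws(raw) != "")
    bad2 <- which(trimws(raw) == "")
    bad <- sort(c(bad, bad2))
    if (length(bad) > 0)
      stopf("PDB format error: unparseable %s field at line %d of %s",
            what, idx[bad[1]], path)
    v
  }
  atoms <- data.frame(
    serial = as.integer(num(7, 11, "serial")),
    atom_name = fw(13, 16),
    altloc = substr(ln, 17, 17),
    residue_name = fw(18, 20),
    chain_id = substr(ln, 22, 22),
    residue_seq = as.integer(num(23, 26, "residue number")),
    icode = substr(ln, 27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    is_hetero = substr(ln, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1.0
  atoms$occupancy <- occ
  elem <- trimws(substr(ln, 77, 78))
  fallback <- toupper(sub("[^A-Za-z].*$", "",
                          sub("^[^A-Za-z]*", "", atoms$atom_name)))
  fallback <- substr(fallback, 1, 1)
  elem <- ifelse(elem == "", fallback, toupper(elem))
  if (any(elem == ""))
    stopf("PDB format error: atom with empty element and atom name in %s", path)
  atoms$element <- elem

  # altloc resolution: keep highest occupancy per atom site, ties -> first
  site <- paste(atoms$atom_name, atoms$residue_name, atoms$chain_id,
                atoms$residue_seq, atoms$icode, atoms$is_hetero, sep = "|")
  if (anyDuplicated(site) && any(atoms$altloc != " ")) {
    ord <- order(site, -atoms$occupancy, seq_len(nrow(atoms)))
    keep_row <- ord[!duplicated(site[ord])]
    atoms <- atoms[sort(keep_row), , drop = FALSE]
  }
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("PDB format error: non-finite coordinates in %s", path)

  new_structure(id %||% sub("\\.[^.]*$", "", basename(path)), atoms)
}

# Assemble a protein_structure from an atom table, deriving ligand groups
# and per-chain 1-letter sequences.
new_structure <- function(id, atoms) {
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1.0, nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- rep(" ", nrow(atoms))
  if (!any(!atoms$is_hetero))
    stopf("structure %s has no polymer (ATOM) atoms", id)
  het <- atoms[atoms$is_hetero, , drop = FALSE]
  ligand_groups <- list()
  if (nrow(het) > 0) {
    key <- paste(het$residue_name, het$chain_id, het$residue_seq, sep = "|")
    ligand_groups <- split(seq_len(nrow(atoms))[atoms$is_hetero], key)
    ligand_groups <- ligand_groups[unique(key)]
  }
  pol <- atoms[!atoms$is_hetero, , drop = FALSE]
  chains <- unique(pol$chain_id)
  chain_sequences <- vapply(chains, function(ch) {
    sub <- pol[pol$chain_id == ch, , drop = FALSE]
    res <- sub[!duplicated(paste(sub$residue_seq, sub$icode)), , drop = FALSE]
    paste(aa_three_to_one(res$residue_name), collapse = "")
  }, character(1))
  names(chain_sequences) <- chains
  structure(list(id = id, atoms = atoms, ligand_groups = ligand_groups,
                 chain_sequences = chain_sequences),
            class = "protein_structure")
}

#' Write a protein structure to a PDB file
#'
#' Emits `ATOM`/`HETATM` records in fixed-width PDB format.  Coordinates
#' that do not fit the 8.3 fixed-width field raise an error rather than
#' being silently truncated.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  if (any(abs(c(a$x, a$y, a$z)) > 9999.999))
    stopf("coordinates exceed the PDB fixed-width field (|v| > 9999.999)")
  name4 <- ifelse(nchar(a$atom_name) <= 3 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
  lines <- sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_hetero, "HETATM", "ATOM"),
                   a$serial, name4, a$residue_name, a$chain_id, a$residue_seq,
                   a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d atoms (%d hetero), %d chain(s)\n",
              x$id, nrow(x$atoms), sum(x$atoms$is_hetero),
              length(x$chain_sequences)))
  if (length(x$ligand_groups) > 0)
    cat("  hetero groups:", paste(names(x$ligand_groups), collapse = ", "), "\n")
  invisible(x)
}

# Heavy, non-hetero atoms eligible for pocket detection (hydrogens and
# water are always excluded).
heavy_atom_indices <- function(structure) {
  a <- structure$atoms
  which(!a$is_hetero & !(a$element %in% c("H", "D")) &
          a$residue_name != "HOH")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
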