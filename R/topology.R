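#' Residue-name classification dictionary
#'
#' Maps residue names to molecule classes. Every residue of a [Topology] is
#' assigned exactly one class through this dictionary; unknown names are
#' classified `"unknown"` with a warning (never dropped).
#'
#' @return Named list of character vectors, one per molecule class:
#'   `protein`, `water`, `cholesterol-like`, `lipid`, `ion`.
#' @export
default_residue_classes <- function() {
  list(
    protein = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL",
                "HSD", "HSE", "HSP", "HID", "HIE", "HIP"),
    water = c("HOH", "TIP3", "TIP", "SOL", "WAT", "SPC", "W"),
    `cholesterol-like` = c("CHL", "CHL1", "CLR", "CHOL", "CHS", "ERG"),
    lipid = c("POPC", "POPE", "POPS", "DPPC", "DOPC", "DMPC", "POP", "PC"),
    ion = c("SOD", "CLA", "POT", "MG", "CAL", "ZN2", "NA", "CL", "K")
  )
}

classify_residues <- function(resid, dict = default_residue_classes()) {
  cls <- rep("unknown", length(resid))
  for (k in names(dict)) cls[resid %in% dict[[k]]] <- k
  unk <- unique(resid[cls == "unknown"])
  if (length(unk) > 0) {
    warning(sprintf("unknown residue name(s) classified 'unknown': %s",
                    paste(unk, collapse = ", ")), call. = FALSE)
  }
  cls
}

#' Standard atomic masses (u) by element symbol
#' @return Named numeric vector.
#' @export
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    `NA` = 22.990, CL = 35.45, K = 39.098, MG = 24.305, CA = 40.078,
    ZN = 65.38, FE = 55.845, F = 18.998, BR = 79.904, I = 126.904)
}

#' Van der Waals radii (Angstrom) by element, Bondi set
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

#' Construct a Topology
#'
#' A `Topology` holds the static atom and residue tables of a system: atom
#' identities, author (1-based, verbatim) residue numbers, chain ids, and a
#' molecule class per residue. Optionally carries reference coordinates.
#'
#' @param atoms data.frame with columns `eleno` (atom serial), `name` (atom
#'   name, e.g. `"CA"`), `element` (symbol), `resno` (author residue number),
#'   `resid` (residue name), `chain` (chain/segment id).
#' @param xyz Optional reference coordinates, `nrow(atoms)` x 3 matrix (Å).
#' @param residue_classes Classification dictionary, see
#'   [default_residue_classes()].
#' @return Object of class `Topology`: list with `atoms` (atom table with a
#'   `resind` index into the residue table), `residues` (resno, resid, chain,
#'   class), `natoms`, and `xyz`.
#' @export
topology <- function(atoms, xyz = NULL,
                     residue_classes = default_residue_classes()) {
  req <- c("eleno", "name", "element", "resno", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop(mp_error("format", "atom table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  resind <- match(key, unique(key))
  residues <- atoms[!duplicated(key), c("resno", "resid", "chain")]
  rownames(residues) <- NULL
  # author numbering must be strictly increasing within one chain
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0)) {
      stop(mp_error("format",
        "residue numbers not strictly increasing in chain '%s'", ch))
    }
  }
  residues$class <- classify_residues(residues$resid, residue_classes)
  atoms$resind <- resind
  if (!is.null(xyz)) {
    xyz <- as_coord_matrix(xyz, nrow(atoms))
  }
  structure(list(atoms = atoms, residues = residues,
                 natoms = nrow(atoms), xyz = xyz),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              x$natoms, nrow(x$residues), length(unique(x$residues$chain))))
  print(table(x$residues$class))
  invisible(x)
}

#' Read a topology (and reference coordinates) from a PDB file
#'
#' Author residue numbers are preserved verbatim (gaps included, no
#' renumbering); each residue is assigned a molecule class through the
#' residue-name dictionary.
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @param residue_classes Dictionary, see [default_residue_classes()].
#' @return A [topology()] with `xyz` set to the first-model coordinates.
#' @export
read_topology <- function(path, format = c("pdb"),
                          residue_classes = default_residue_classes()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(mp_error("io", "file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) {
                    stop(mp_error("format", "cannot parse PDB '%s': %s",
                                  path, conditionMessage(e)))
                  })
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  if (any(is.na(elem) | elem == "")) {
    guess <- suppressWarnings(bio3d::atom2ele(pdb, rescue = TRUE))
    bad <- is.na(elem) | elem == ""
    elem[bad] <- toupper(guess[bad])
  }
  atoms <- data.frame(eleno = at$eleno, name = trimws(at$elety),
                      element = elem, resno = at$resno,
                      resid = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), " ", at$chain),
                      stringsAsFactors = FALSE)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  topology(atoms, xyz = xyz, residue_classes = residue_classes)
}

# internal: coerce N x 3 matrix or length-3N vector to N x 3
as_coord_matrix <- function(x, natoms) {
  if (is.matrix(x) && ncol(x) == 3) {
    m <- x
  } else {
    m <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  }
  if (nrow(m) != natoms) {
    stop(mp_error("shape", "coordinate count %d does not match atom count %d",
                  nrow(m), natoms))
  }
  unname(m)
}

# internal: classed condition constructor; class drives CLI exit codes
mp_error <- function(class, fmt, ...) {
  structure(class = c(paste0("memprobe_", class, "_error"),
                      "memprobe_error", "error", "condition"),
            list(message = sprintf(fmt, ...), call = sys.call(-1)))
}

#' Atom masses for a topology
#'
#' @param top A [topology()].
#' @param indices Atom indices (default all).
#' @return Numeric vector of masses (u).
#' @export
atom_masses <- function(top, indices = seq_len(top$natoms)) {
  el <- top$atoms$element[indices]
  m <- atomic_masses()[el]
  if (anyNA(m)) {
    stop(mp_error("mass", paste0(
      "no mass for element(s): %s; use weighting = 'geometry' or extend ",
      "the mass table"), paste(unique(el[is.na(m)]), collapse = ", ")))
  }
  unname(m)
}

# heavy (non-hydrogen) atom indices, optionally restricted to classes
heavy_atoms <- function(top, classes = NULL, indices = seq_len(top$natoms)) {
  keep <- top$atoms$element[indices] != "H"
  if (!is.null(classes)) {
    cls <- top$residues$class[top$atoms$resind[indices]]
    keep <- keep & cls %in% classes
  }
  indices[keep]
}
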