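#' @keywords internal
"_PACKAGE"

# Three-letter residue codes accepted as amino acids when selecting C-alpha
# atoms. Covers the standard 20 plus common variants/protonation states; a
# calcium HETATM named "CA" must not slip through this list.
.AA_CODES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL", "CYX", "HID", "HIE", "HIP", "HSD", "HSE", "HSP",
  "ASX", "GLX", "UNK"
)

#' Construct an atomic model
#'
#' An `atom_model` is an ordered table of atoms with coordinates in Angstrom.
#' It is the container passed between PDB I/O, the elastic network builder,
#' mode augmentation, map simulation and the fitting engine. Atom order is
#' stable across a read/write round trip.
#'
#' @param atoms data frame with columns `serial` (integer), `name` (atom
#'   name, e.g. `"CA"`), `resname` (three-letter residue code), `chain`
#'   (chain identifier), `resno` (residue sequence number), `x`, `y`, `z`
#'   (coordinates, Angstrom) and optionally `weight` (non-negative, default 1).
#' @return object of class `atom_model`.
#' @export
atom_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("an atom_model needs at least one atom")
  if (is.null(atoms$weight)) atoms$weight <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(!is.finite(atoms$weight)) || any(atoms$weight < 0)) {
    stop("atom weights must be finite and non-negative")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  n <- n_atoms(x)
  nca <- sum(is_calpha(x))
  cat(sprintf("atom_model: %d atoms (%d C-alpha), %d residue(s), chain(s): %s\n",
              n, nca, length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an `atom_model`
#' @return integer count
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#' @param model an `atom_model`
#' @return numeric n-by-3 matrix (Angstrom)
#' @export
coords <- function(model) {
  unname(as.matrix(model$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a model
#' @param model an `atom_model`
#' @param xyz n-by-3 matrix of new coordinates (Angstrom)
#' @return a new `atom_model`; the input is not modified
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n_atoms(model), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

is_calpha <- function(model) {
  trimws(model$atoms$name) == "CA" & trimws(model$atoms$resname) %in% .AA_CODES
}

# Per-atom mapping to the index of the owning residue's C-alpha within the
# C-alpha subset; NA for atoms of residues without one (ligands, waters).
ca_mapping <- function(model) {
  a <- model$atoms
  res_key <- paste(a$chain, a$resno, a$resname, sep = "|")
  ca <- is_calpha(model)
  ca_keys <- res_key[ca]
  # first C-alpha wins if a residue improbably carries two
  first <- !duplicated(ca_keys)
  idx <- stats::setNames(seq_len(sum(first)), ca_keys[first])
  out <- unname(idx[res_key])
  as.integer(out)
}
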