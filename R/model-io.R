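#' Read an atomic model from a PDB file
#'
#' Parses all ATOM/HETATM records (via bio3d) in file order. Alternate
#' locations are resolved by keeping the first-seen locator per atom name per
#' residue, the common single-conformer convention. Hydrogens and heteroatoms
#' are retained; they ride along during deformation.
#'
#' @param path path to a PDB file
#' @return an [atom_model]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not a parsable PDB file (", conditionMessage(e), "): ", path)
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  ins <- a$insert
  ins[is.na(ins)] <- ""
  key <- paste(a$chain, a$resno, ins, a$resid, a$elety, sep = "|")
  # first record of each (residue, atom-name) pair wins: first-seen alt-loc
  keep <- !duplicated(key)
  a <- a[keep, , drop = FALSE]
  atom_model(data.frame(
    serial = as.integer(a$eleno),
    name = a$elety,
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    weight = 1,
    stringsAsFactors = FALSE
  ))
}

#' Write an atomic model to a PDB file
#'
#' Fixed-column PDB output (coordinates rounded to 3 decimals, occupancy 1.00,
#' B-factor 0.00). Coordinates outside the representable column width
#' (|coordinate| >= 10000) raise an error rather than producing a corrupt file.
#'
#' @param model an [atom_model]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "atom_model"))
  xyz <- coords(model)
  if (any(abs(xyz) >= 10000)) {
    stop("coordinate magnitude >= 10000 Angstrom exceeds the PDB column width")
  }
  a <- model$atoms
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(xyz)),
      type = rep("ATOM", nrow(a)),
      resno = a$resno,
      resid = a$resname,
      eleno = a$serial,
      elety = a$name,
      chain = a$chain,
      o = rep(1, nrow(a)),
      b = rep(0, nrow(a))
    )
    TRUE
  }, error = function(e) stop("cannot write PDB to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Select the C-alpha subset of a model
#'
#' Keeps atoms named `CA` belonging to amino-acid residues (a residue-name
#' whitelist excludes e.g. calcium ions), preserving residue order. The
#' resulting model defines the nodes of the elastic network.
#'
#' @param model an [atom_model]
#' @return an [atom_model] containing only C-alpha atoms
#' @export
select_calpha <- function(model) {
  stopifnot(inherits(model, "atom_model"))
  ca <- is_calpha(model)
  if (!any(ca)) stop("model contains no C-alpha atoms of amino-acid residues")
  atom_model(model$atoms[ca, , drop = FALSE])
}

#' Root-mean-square deviation between two matched models
#'
#' Computed over matched atom pairs in the common frame; no superposition is
#' performed.
#'
#' @param a,b `atom_model`s with equal atom counts and matched order
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b) {
  stopifnot(inherits(a, "atom_model"), inherits(b, "atom_model"))
  if (n_atoms(a) != n_atoms(b)) {
    stop("models differ in atom count (", n_atoms(a), " vs ", n_atoms(b), ")")
  }
  d <- coords(a) - coords(b)
  sqrt(mean(rowSums(d^2)))
}
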