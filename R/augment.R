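#' Extend C-alpha mode displacements to all atoms of a full model
#'
#' The elastic network lives on C-alpha nodes only; deforming a full atomic
#' model requires a displacement for every atom. Two schemes are offered:
#'
#' * `per-residue` (default): every atom of residue r moves with the
#'   displacement of r's C-alpha node. Preserves residue-internal geometry
#'   exactly and conserves rigid motions.
#' * `inverse-distance`: an atom's displacement is the 1/d-weighted average of
#'   the displacements of all C-alpha nodes within `radius` (d measured
#'   atom-to-node, clamped below at 1e-6 Angstrom so an atom sitting on a node
#'   inherits that node's displacement). A smoother field across residue
#'   boundaries; a convex combination of neighboring node displacements.
#'
#' Atoms of residues with no C-alpha (ligands, waters), or with no node inside
#' `radius` under `inverse-distance`, fall back to the nearest node, with a
#' warning, so they move with their surroundings instead of tearing away.
#'
#' @param modes a `mode_set` whose node coordinates match the full model's
#'   C-alpha subset (node-for-node, within 1e-3 Angstrom)
#' @param full the full [atom_model]
#' @param scheme `"per-residue"` or `"inverse-distance"`
#' @param radius interpolation radius for `inverse-distance`, Angstrom;
#'   defaults to the network cutoff
#' @return object of class `all_atom_modes`: fields `n_atoms`, `vectors`
#'   (3 n_atoms-by-n_modes), `mode_indices` (original 1-based mode numbers),
#'   `eigenvalues`, `scheme`, `source_mode_count`
#' @export
augment_modes <- function(modes, full,
                          scheme = c("per-residue", "inverse-distance"),
                          radius = NULL) {
  stopifnot(inherits(modes, "mode_set"), inherits(full, "atom_model"))
  scheme <- match.arg(scheme)
  if (is.null(radius)) radius <- modes$cutoff
  ca <- select_calpha(full)
  if (n_atoms(ca) != modes$n_nodes) {
    stop("C-alpha count of the full model (", n_atoms(ca),
         ") does not match the mode set (", modes$n_nodes, ")")
  }
  dev <- max(abs(coords(ca) - modes$node_coords))
  if (dev > 1e-3) {
    stop("C-alpha coordinates deviate from the mode set's nodes by ",
         format(dev), " Angstrom (> 1e-3); wrong model for this archive?")
  }
  n_at <- n_atoms(full)
  n_modes <- ncol(modes$vectors)
  xyz <- coords(full)
  nodes <- modes$node_coords
  # n_at x n_modes weights are implicit; build a sparse row-stochastic
  # interpolation operator A (n_at x n_nodes), then vectors_all = kron-apply.
  A <- matrix(0, n_at, modes$n_nodes)
  if (scheme == "per-residue") {
    map <- ca_mapping(full)
    unmapped <- which(is.na(map))
    if (length(unmapped) > 0) {
      warning(length(unmapped),
              " atom(s) in residues without a C-alpha; using nearest node")
      for (i in unmapped) {
        d2 <- colSums((t(nodes) - xyz[i, ])^2)
        map[i] <- which.min(d2)
      }
    }
    A[cbind(seq_len(n_at), map)] <- 1
  } else {
    n_fallback <- 0
    for (i in seq_len(n_at)) {
      d <- sqrt(colSums((t(nodes) - xyz[i, ])^2))
      inside <- which(d <= radius)
      if (length(inside) == 0) {
        n_fallback <- n_fallback + 1
        A[i, which.min(d)] <- 1
      } else if (min(d) <= 1e-6) {
        # at the clamp distance the node's weight dominates completely;
        # assign exactly so C-alpha atoms reproduce the source field
        A[i, which.min(d)] <- 1
      } else {
        w <- 1 / pmax(d[inside], 1e-6)
        A[i, inside] <- w / sum(w)
      }
    }
    if (n_fallback > 0) {
      warning(n_fallback, " atom(s) with no C-alpha node within ", radius,
              " Angstrom; using nearest node")
    }
  }
  # apply A to each coordinate component of each mode
  W <- matrix(0, 3 * n_at, n_modes)
  for (c in 1:3) {
    rows_node <- seq(c, 3 * modes$n_nodes, by = 3)
    rows_atom <- seq(c, 3 * n_at, by = 3)
    W[rows_atom, ] <- A %*% modes$vectors[rows_node, , drop = FALSE]
  }
  structure(list(
    n_atoms = n_at,
    vectors = W,
    mode_indices = seq_len(n_modes),
    eigenvalues = modes$eigenvalues,
    scheme = scheme,
    source_mode_count = as.integer(n_modes),
    cutoff = modes$cutoff
  ), class = "all_atom_modes")
}

#' @export
print.all_atom_modes <- function(x, ...) {
  cat(sprintf("all_atom_modes: %d atoms, modes %s of %d (%s scheme)\n",
              x$n_atoms,
              if (length(x$mode_indices) > 6)
                sprintf("%d..%d", min(x$mode_indices), max(x$mode_indices))
              else paste(x$mode_indices, collapse = ","),
              x$source_mode_count, x$scheme))
  invisible(x)
}

#' Restrict an all-atom mode field to a 1-based inclusive mode range
#'
#' Mode numbering follows the frequency order of the source mode set: modes
#' 1-6 are the rigid-body block, mode 7 is the first internal mode. Starting
#' inside the rigid block (start in 2..6) splits a null-space basis that has
#' no individual meaning and triggers a warning; the rigid modes are only
#' useful as a complete subset.
#'
#' @param modes an `all_atom_modes`
#' @param start,end 1-based inclusive original mode indices
#' @return an `all_atom_modes` retaining modes `start..end`, keeping the
#'   original index labels
#' @export
restrict_range <- function(modes, start, end) {
  stopifnot(inherits(modes, "all_atom_modes"))
  if (!(start >= 1 && start <= end && end <= modes$source_mode_count)) {
    stop("invalid mode range [", start, ", ", end, "] for a set of ",
         modes$source_mode_count, " modes")
  }
  if (start >= 2 && start <= 6) {
    warning("mode range starts inside the rigid-body block (modes 1-6), ",
            "which is only meaningful as a complete subset")
  }
  sel <- which(modes$mode_indices >= start & modes$mode_indices <= end)
  if (length(sel) == 0) stop("no retained mode falls in [", start, ", ", end, "]")
  modes$vectors <- modes$vectors[, sel, drop = FALSE]
  modes$mode_indices <- modes$mode_indices[sel]
  modes$eigenvalues <- modes$eigenvalues[sel]
  modes
}
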