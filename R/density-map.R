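#' Construct a density map
#'
#' A 3D voxel grid with isotropic spacing. The world position of voxel
#' (i, j, k) (0-based) is `origin + c(i, j, k) * spacing`, i.e. `origin` is
#' the coordinate of the center of the first voxel. Values are stored x
#' fastest (the native R array layout `values[ix, iy, iz]`).
#'
#' @param values 3D numeric array of densities
#' @param spacing isotropic voxel width, Angstrom (> 0)
#' @param origin length-3 numeric, Angstrom coordinates of the center of
#'   voxel (0, 0, 0)
#' @return object of class `density_map`
#' @export
density_map <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a 3D array")
  }
  if (!all(is.finite(values))) stop("map values must be finite")
  stopifnot(length(spacing) == 1, spacing > 0, length(origin) == 3,
            all(is.finite(origin)))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, spacing %g A, origin (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  sum %.6g, range [%.6g, %.6g]\n", sum(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

map_dims <- function(map) dim(map$values)

# voxel-center coordinates along one axis (1 = x, 2 = y, 3 = z)
axis_coords <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 1) * map$spacing
}

same_lattice <- function(x, y, tol = 1e-6) {
  identical(dim(x$values), dim(y$values)) &&
    abs(x$spacing - y$spacing) <= tol &&
    all(abs(x$origin - y$origin) <= tol)
}

#' Zero-pad a density map
#'
#' Adds a margin of zero voxels at each face. The original data keep their
#' world coordinates: dimensions grow by `2 * margin` per axis and the origin
#' shifts by `-margin * spacing`. A fixed margin lets deformed structures
#' leave the original footprint without being cropped by the scored volume,
#' which matters for the Pearson correlation (not invariant under padding);
#' the inner product is exactly invariant and needs no margin.
#'
#' @param map a [density_map]
#' @param margin non-negative integer, voxels per face
#' @return padded [density_map]
#' @export
zero_pad <- function(map, margin) {
  stopifnot(inherits(map, "density_map"))
  if (length(margin) != 1 || margin < 0 || margin != round(margin)) {
    stop("margin must be a non-negative integer number of voxels")
  }
  margin <- as.integer(margin)
  if (margin == 0) return(map)
  d <- dim(map$values)
  out <- array(0, d + 2L * margin)
  out[margin + seq_len(d[1]), margin + seq_len(d[2]), margin + seq_len(d[3])] <-
    map$values
  density_map(out, map$spacing, map$origin - margin * map$spacing)
}

#' Zone-mask a density map around an atomic model
#'
#' Sets to zero every voxel whose center lies farther than `radius` from all
#' atoms of `model` (the zone operation used to strip neighboring-chain
#' density before fitting). With `minimal_bounds`, the grid is additionally
#' cropped to the smallest box containing all voxels within `radius` of any
#' atom.
#'
#' @param map a [density_map]
#' @param model an [atom_model] defining the zone
#' @param radius zone radius, Angstrom (> 0); 5 is the usual choice for
#'   single-chain masking
#' @param minimal_bounds crop the grid to the zone's bounding box
#' @return masked (and possibly cropped) [density_map]
#' @export
mask_zone <- function(map, model, radius = 5, minimal_bounds = FALSE) {
  stopifnot(inherits(map, "density_map"), inherits(model, "atom_model"),
            radius > 0)
  d <- dim(map$values)
  xyz <- coords(model)
  keep <- array(FALSE, d)
  sp <- map$spacing
  o <- map$origin
  r2 <- radius^2
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    lo <- pmax(1L, as.integer(ceiling((p - radius - o) / sp)) + 1L)
    hi <- pmin(d, as.integer(floor((p + radius - o) / sp)) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (o[1] + (ix - 1) * sp - p[1])^2
    dy2 <- (o[2] + (iy - 1) * sp - p[2])^2
    dz2 <- (o[3] + (iz - 1) * sp - p[3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    keep[ix, iy, iz] <- keep[ix, iy, iz] | within
  }
  if (!any(keep)) stop("mask_zone: no voxel center within ", radius,
                       " Angstrom of any atom")
  vals <- map$values
  vals[!keep] <- 0
  if (!minimal_bounds) return(density_map(vals, sp, o))
  rng <- lapply(1:3, function(ax) range(which(apply(keep, ax, any))))
  vals <- vals[rng[[1]][1]:rng[[1]][2],
               rng[[2]][1]:rng[[2]][2],
               rng[[3]][1]:rng[[3]][2], drop = FALSE]
  new_o <- o + (c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) - 1) * sp
  density_map(vals, sp, new_o)
}

#' Build an empty map lattice covering a model
#'
#' Convenience for constructing a simulation template: a zero-valued grid
#' whose voxel centers cover the model's bounding box plus `pad` Angstrom on
#' every side.
#'
#' @param model an [atom_model]
#' @param spacing voxel width, Angstrom
#' @param pad margin around the bounding box, Angstrom
#' @return a zero-filled [density_map]
#' @export
map_lattice <- function(model, spacing = 1, pad = 8) {
  xyz <- coords(model)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  density_map(array(0, dims), spacing, lo)
}
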