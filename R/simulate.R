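#' Map-simulation configuration
#'
#' Controls how an atomic model is lowered to a density map at a stated
#' resolution. Each atom deposits a 3D Gaussian of width
#' `sigma = sigma_factor * resolution` (the Situs-style resolution
#' convention, resolution = 2 sigma, is the default; `sigma_factor` makes
#' other kernel-width conventions reachable). The kernel is evaluated at
#' voxel centers within `kernel_truncation * sigma` per axis and normalized
#' over that discrete support, so an atom fully inside the grid contributes
#' exactly its weight to the map sum.
#'
#' @param resolution nominal map resolution, Angstrom (> 0)
#' @param sigma_factor kernel width as a fraction of the resolution
#'   (default 0.5, i.e. sigma = resolution / 2)
#' @param kernel_truncation kernel support half-width in sigma multiples
#'   (>= 2; default 3)
#' @param atom_weighting `"unit"` (default) or `"mass"` (approximate atomic
#'   mass from the element inferred from the atom name)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(resolution, sigma_factor = 0.5,
                              kernel_truncation = 3,
                              atom_weighting = c("unit", "mass")) {
  stopifnot(resolution > 0, sigma_factor > 0, kernel_truncation >= 2)
  atom_weighting <- match.arg(atom_weighting)
  structure(list(resolution = resolution, sigma_factor = sigma_factor,
                 kernel_truncation = kernel_truncation,
                 atom_weighting = atom_weighting),
            class = "simulation_config")
}

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                   S = 32.06, SE = 78.971, FE = 55.845, ZN = 65.38,
                   MG = 24.305, CA = 40.078, NA. = 22.99, K = 39.098)

atom_masses <- function(model) {
  # element from the leading letters of the atom name; crude but only used
  # for optional mass weighting, to which correlation measures are largely
  # insensitive
  el <- toupper(substr(trimws(model$atoms$name), 1, 1))
  m <- .ELEMENT_MASS[el]
  m[is.na(m)] <- 12
  unname(m)
}

#' Simulate a density map from an atomic model
#'
#' Deposits a truncated, discretely normalized Gaussian kernel for every atom
#' onto the template lattice (the output grid is identical to the template's;
#' the template's values are ignored). Atoms outside the grid contribute only
#' to in-grid voxels. The Gaussian is separable, so per-atom deposition costs
#' three 1D kernel evaluations plus an outer product.
#'
#' @param model an [atom_model]
#' @param template a [density_map] providing spacing, origin and dimensions
#' @param cfg a [simulation_config]
#' @return a [density_map] on the template lattice
#' @export
simulate_map <- function(model, template, cfg) {
  stopifnot(inherits(model, "atom_model"), inherits(template, "density_map"),
            inherits(cfg, "simulation_config"))
  if (n_atoms(model) < 1) stop("cannot simulate a map from an empty model")
  sigma <- cfg$sigma_factor * cfg$resolution
  sp <- template$spacing
  if (sigma < 0.4 * sp) {
    stop("kernel width sigma = ", format(sigma), " Angstrom is below 0.4 * ",
         "spacing; the Gaussian would alias on this grid (refine the grid or ",
         "lower the resolution)")
  }
  half <- cfg$kernel_truncation * sigma
  d <- dim(template$values)
  o <- template$origin
  xyz <- coords(model)
  w <- model$atoms$weight
  if (cfg$atom_weighting == "mass") w <- w * atom_masses(model)
  vals <- array(0, d)
  inv2s2 <- 1 / (2 * sigma^2)
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    # full truncation window on the (unbounded) lattice, for normalization
    lo_all <- as.integer(ceiling((p - half - o) / sp))   # 0-based
    hi_all <- as.integer(floor((p + half - o) / sp))
    kx <- exp(-((o[1] + (lo_all[1]:hi_all[1]) * sp - p[1])^2) * inv2s2)
    ky <- exp(-((o[2] + (lo_all[2]:hi_all[2]) * sp - p[2])^2) * inv2s2)
    kz <- exp(-((o[3] + (lo_all[3]:hi_all[3]) * sp - p[3])^2) * inv2s2)
    norm <- sum(kx) * sum(ky) * sum(kz)
    if (norm <= 0) next
    # clip to the grid
    lo <- pmax(lo_all, 0L)
    hi <- pmin(hi_all, d - 1L)
    if (any(lo > hi)) next
    sx <- kx[(lo[1] - lo_all[1] + 1):(hi[1] - lo_all[1] + 1)]
    sy <- ky[(lo[2] - lo_all[2] + 1):(hi[2] - lo_all[2] + 1)]
    sz <- kz[(lo[3] - lo_all[3] + 1):(hi[3] - lo_all[3] + 1)]
    ix <- (lo[1]:hi[1]) + 1L
    iy <- (lo[2]:hi[2]) + 1L
    iz <- (lo[3]:hi[3]) + 1L
    vals[ix, iy, iz] <- vals[ix, iy, iz, drop = FALSE] +
      (w[a] / norm) * outer(outer(sx, sy), sz)
  }
  density_map(vals, sp, o)
}
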