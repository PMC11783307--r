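# Synthetic fixtures with known ground truth: idealized C-alpha chains, a
# "true" structure deformed along known modes, and its simulated target map.
# They stand in for experimental model/map pairs so the whole pipeline is
# testable offline, with the generator itself acting as the oracle.

#' Ideal alpha-helical C-alpha chain
#'
#' Residue i sits at angle `(i-1) * twist` on a cylinder of radius `radius`,
#' rising `rise` per residue. The defaults (rise 1.5 A, twist 100 degrees,
#' radius 2.3 A) give the canonical consecutive C-alpha distance of ~3.8 A.
#'
#' @param n_res number of residues (>= 10)
#' @param rise rise per residue, Angstrom
#' @param twist rotation per residue, degrees
#' @param radius helix radius, Angstrom
#' @return a C-alpha-only [atom_model]
#' @export
make_helix_chain <- function(n_res, rise = 1.5, twist = 100, radius = 2.3) {
  if (n_res < 10) stop("a helix fixture needs at least 10 residues")
  i <- seq_len(n_res)
  theta <- (i - 1) * twist * pi / 180
  atom_model(data.frame(
    serial = i,
    name = "CA",
    resname = "ALA",
    chain = "A",
    resno = i,
    x = radius * cos(theta),
    y = radius * sin(theta),
    z = (i - 1) * rise,
    weight = 1,
    stringsAsFactors = FALSE
  ))
}

# connected components of the cutoff graph; TRUE if a single component
network_connected <- function(xyz, cutoff) {
  n <- nrow(xyz)
  adj <- as.matrix(stats::dist(xyz)) <= cutoff
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Multi-segment helical chain with short linkers
#'
#' Antiparallel helical segments packed side by side (axis separation
#' `2 * radius + hinge_gap`), joined by up to two linker C-alphas at 3.8 A
#' spacing along the terminus-to-terminus line. Emulates the small
#' multi-helix chain topology whose inter-segment placement flexible fitting
#' must correct. The resulting network must be connected under the stated
#' elastic-network cutoff; a hinge gap too wide to bridge raises an error.
#'
#' @param n_segments number of helices (>= 2)
#' @param n_res_each residues per helix (>= 10)
#' @param hinge_gap lateral packing gap between consecutive segments,
#'   Angstrom (default 4)
#' @param cutoff connectivity check cutoff, Angstrom (default 12, the
#'   network default)
#' @return a C-alpha-only [atom_model]
#' @export
make_multisegment <- function(n_segments, n_res_each = 20, hinge_gap = 4,
                              cutoff = 12) {
  if (n_segments < 2) stop("need at least 2 segments")
  radius <- 2.3
  rise <- 1.5
  d_ax <- 2 * radius + hinge_gap
  coords_list <- list()
  for (s in seq_len(n_segments) - 1) {
    seg <- make_helix_chain(n_res_each, rise = rise, radius = radius)
    xyz <- coords(seg)
    if (s %% 2 == 1) xyz[, 3] <- max(xyz[, 3]) - xyz[, 3]  # antiparallel
    xyz[, 1] <- xyz[, 1] + s * d_ax
    coords_list[[length(coords_list) + 1]] <- xyz
    if (s < n_segments - 1) {
      # short linker toward the next segment's first residue
      nxt_theta <- 0
      nxt_start <- c(radius * cos(nxt_theta) + (s + 1) * d_ax,
                     radius * sin(nxt_theta),
                     if ((s + 1) %% 2 == 1) (n_res_each - 1) * rise else 0)
      from <- xyz[nrow(xyz), ]
      u <- nxt_start - from
      len <- sqrt(sum(u^2))
      n_link <- min(2, max(0, floor((len - 0.1) / 3.8)))
      if (n_link > 0) {
        for (jl in seq_len(n_link)) {
          coords_list[[length(coords_list) + 1]] <-
            matrix(from + u * (jl * 3.8 / len), 1, 3)
        }
      }
    }
  }
  xyz <- do.call(rbind, coords_list)
  n <- nrow(xyz)
  model <- atom_model(data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
    resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    weight = 1, stringsAsFactors = FALSE
  ))
  if (!network_connected(xyz, cutoff)) {
    stop("segments are disconnected under the ", cutoff,
         " Angstrom cutoff; reduce hinge_gap (currently ", hinge_gap, ")")
  }
  model
}

#' Build a synthetic fitting case with known ground truth
#'
#' Computes the normal modes of `base`, deforms it by the given elongation
#' coefficients on the given modes to obtain the "true" structure, and
#' simulates the target map from the truth at the stated resolution. The map
#' is optionally zone-masked to the truth (radius 5 A, minimal bounds) or,
#' for the harder box-style scenario, contaminated with the density of a
#' displaced decoy copy emulating a neighboring chain. Everything is
#' deterministic given the arguments, so the case doubles as an oracle: the
#' true elongation must score (near-)perfectly against its own map, and the
#' recorded initial RMSD is the yardstick for recovery.
#'
#' @param base a C-alpha [atom_model] (connected under the 12 A cutoff)
#' @param mode_indices integer vector of 1-based mode numbers to deform along
#' @param amplitudes elongation coefficients, same length as `mode_indices`
#' @param resolution simulated map resolution, Angstrom (default 5)
#' @param spacing voxel width, Angstrom (default 1)
#' @param mask zone-mask the target to the true structure (default TRUE)
#' @param decoy_density add a displaced copy's density (default FALSE;
#'   incompatible with `mask`'s minimal-bounds crop, so masking is skipped
#'   when set)
#' @param seed integer recorded with the case (the construction itself is
#'   deterministic)
#' @return object of class `fixture_case`: `predicted` (= `base`),
#'   `true_model`, `a_star`, `mode_indices`, `modes` (the `mode_set`),
#'   `target_map`, `resolution`, `spacing`, `initial_rmsd`, `masked`,
#'   `decoy`, `seed`
#' @export
make_case <- function(base, mode_indices, amplitudes, resolution = 5,
                      spacing = 1, mask = TRUE, decoy_density = FALSE,
                      seed = 0) {
  stopifnot(inherits(base, "atom_model"))
  if (length(mode_indices) != length(amplitudes)) {
    stop("amplitudes length must match mode_indices length")
  }
  modes <- compute_modes(base)
  am <- augment_modes(modes, base, scheme = "per-residue")
  a_full <- rep(0, ncol(am$vectors))
  a_full[mode_indices] <- amplitudes
  true_model <- deform(base, am, a_full)
  # reject unphysical deformations: consecutive C-alpha bond stretch > 50%
  d0 <- consecutive_distances(base)
  d1 <- consecutive_distances(true_model)
  stretch <- max(abs(d1 - d0) / d0)
  if (stretch > 0.5) {
    stop("amplitudes stretch a C-alpha bond by ",
         sprintf("%.0f%%", 100 * stretch), " (> 50%); unphysical fixture")
  }
  sim_cfg <- simulation_config(resolution)
  pad <- sim_cfg$kernel_truncation * sim_cfg$sigma_factor * resolution + 2
  both <- rbind(coords(base), coords(true_model))
  lo <- apply(both, 2, min) - pad
  hi <- apply(both, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  lattice <- density_map(array(0, dims), spacing, lo)
  target <- simulate_map(true_model, lattice, sim_cfg)
  masked <- FALSE
  if (decoy_density) {
    # a neighboring-chain copy clipped by the box: shift it along +x so only
    # a few Angstrom of its density enter at the face, the way rectangular
    # cropping leaves fringe density of adjacent chains
    shift <- (hi[1] - 4) - min(coords(true_model)[, 1])
    decoy <- set_coords(true_model,
                        sweep(coords(true_model), 2, c(shift, 0, 0), `+`))
    decoy_map <- simulate_map(decoy, lattice, sim_cfg)
    target$values <- target$values + decoy_map$values
  } else if (mask) {
    target <- mask_zone(target, true_model, radius = 5, minimal_bounds = TRUE)
    masked <- TRUE
  }
  structure(list(
    predicted = base,
    true_model = true_model,
    a_star = stats::setNames(as.numeric(amplitudes),
                             paste0("mode", mode_indices)),
    mode_indices = as.integer(mode_indices),
    modes = modes,
    target_map = target,
    resolution = resolution,
    spacing = spacing,
    initial_rmsd = rmsd(base, true_model),
    masked = masked,
    decoy = isTRUE(decoy_density),
    seed = as.integer(seed)
  ), class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat(sprintf(paste0("fixture_case: %d C-alpha atoms, modes %s, initial rmsd ",
                     "%.2f A, %s map at %g A\n"),
              n_atoms(x$predicted),
              paste(range(x$mode_indices), collapse = "-"),
              x$initial_rmsd,
              if (x$masked) "masked" else if (x$decoy) "decoy-contaminated"
              else "plain", x$resolution))
  invisible(x)
}

#' Draw low-frequency-dominant elongation amplitudes at a target RMSD
#'
#' Samples coefficients for the given internal modes with weights
#' proportional to \eqn{\lambda_k^{-3/2}} (smoother, lower-frequency modes
#' dominate, as in real collective discrepancies) and rescales them so the
#' implied C-alpha displacement RMSD equals `target_rmsd`: for orthonormal
#' mode fields the displacement norm is the coefficient norm, so
#' `rmsd = ||a|| / sqrt(N)`.
#'
#' @param modes a `mode_set`
#' @param mode_indices 1-based internal mode numbers to use (default 7:12)
#' @param target_rmsd desired C-alpha RMSD of the deformation, Angstrom
#' @param seed RNG seed for the draw
#' @return numeric amplitude vector, one per mode index
#' @export
recovery_amplitudes <- function(modes, mode_indices = 7:12, target_rmsd = 3,
                                seed = 1) {
  stopifnot(inherits(modes, "mode_set"), target_rmsd > 0,
            all(mode_indices > modes$n_rigid))
  lambda <- modes$eigenvalues[mode_indices]
  raw <- with_seed(seed, stats::rnorm(length(mode_indices))) / lambda^1.5
  raw * (target_rmsd * sqrt(modes$n_nodes) / sqrt(sum(raw^2)))
}

consecutive_distances <- function(model) {
  xyz <- coords(model)
  sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}
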