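# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# minimal C-alpha-only model from a coordinate matrix
ca_model <- function(xyz, resname = "ALA") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atom_model(data.frame(
    serial = seq_len(n), name = "CA", resname = resname, chain = "A",
    resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    weight = 1, stringsAsFactors = FALSE
  ))
}

# connected random 3D cluster: a self-avoiding-ish random walk with ~3.8 A
# steps, guaranteed connected under the 12 A cutoff and (almost surely)
# non-degenerate
random_cluster <- function(n, seed) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    d <- stats::rnorm(3)
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * d / sqrt(sum(d^2))
  }
  xyz
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# pairwise harmonic network energy at displaced coordinates, springs fixed at
# the reference geometry; the independent oracle for the Hessian
network_energy <- function(xyz, ref, cutoff = 12, k = 1) {
  d_ref <- as.matrix(stats::dist(ref))
  adj <- d_ref <= cutoff & upper.tri(d_ref)
  d <- as.matrix(stats::dist(xyz))
  0.5 * k * sum((d[adj] - d_ref[adj])^2)
}

# central finite-difference Hessian of network_energy
fd_hessian <- function(ref, cutoff = 12, k = 1, h = 1e-5) {
  n3 <- 3 * nrow(ref)
  x0 <- as.vector(t(ref))
  E <- function(v) network_energy(matrix(v, ncol = 3, byrow = TRUE), ref,
                                  cutoff, k)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) {
    for (b in a:n3) {
      ea <- eb <- rep(0, n3)
      ea[a] <- h
      eb[b] <- h
      H[a, b] <- (E(x0 + ea + eb) - E(x0 + ea - eb) -
                  E(x0 - ea + eb) + E(x0 - ea - eb)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# uniform translation and infinitesimal-rotation displacement fields
# (unit norm) spanning the rigid space of a coordinate set
rigid_fields <- function(xyz) {
  n <- nrow(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  fields <- list(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.vector(t(cbind(0, -cen[, 3], cen[, 2]))),
    as.vector(t(cbind(cen[, 3], 0, -cen[, 1]))),
    as.vector(t(cbind(-cen[, 2], cen[, 1], 0)))
  )
  lapply(fields, function(v) v / sqrt(sum(v^2)))
}

# three-residue PDB text used by the model-io tests
three_res_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       7.000   8.000   9.000  1.00  0.00           C",
    "END"
  ), path)
  path
}

# small helix fitting problem: truth deformed on modes 7:9, simulated target
tiny_fit_problem <- function(n_res = 14, astar = c(2, -1.5, 1), res = 5) {
  h <- make_helix_chain(n_res)
  ms <- compute_modes(h)
  am <- augment_modes(ms, h)
  amr <- restrict_range(am, 7, 9)
  truth <- deform(h, amr, astar)
  tpl <- map_lattice(truth, spacing = 1, pad = 9)
  sim_cfg <- simulation_config(res)
  list(model = h, modes = ms, allatom = am, restricted = amr, truth = truth,
       target = simulate_map(truth, tpl, sim_cfg), sim_cfg = sim_cfg,
       astar = astar)
}
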