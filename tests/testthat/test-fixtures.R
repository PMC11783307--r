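test_that("the ideal helix has canonical geometry and is deterministic", {
  h <- make_helix_chain(30)
  expect_equal(n_atoms(h), 30)
  d <- sqrt(rowSums(diff(coords(h))^2))
  # closed form: sqrt(rise^2 + 2 r^2 (1 - cos(twist)))
  expected <- sqrt(1.5^2 + 2 * 2.3^2 * (1 - cos(100 * pi / 180)))
  expect_equal(d, rep(expected, 29), tolerance = 1e-12)
  expect_equal(expected, 3.83, tolerance = 1e-2)
  expect_identical(coords(make_helix_chain(30)), coords(h))
  expect_error(make_helix_chain(5), "at least 10")
})

test_that("multi-segment chains are connected under the cutoff or rejected", {
  m3 <- make_multisegment(3, 20)
  expect_gte(n_atoms(m3), 60)          # 60 helix residues + linkers
  expect_lte(n_atoms(m3), 66)
  # connected: modes exist with exactly 6 rigid modes
  expect_equal(compute_modes(m3)$n_rigid, 6)
  m2 <- make_multisegment(2, 12)
  expect_s3_class(m2, "atom_model")
  expect_error(make_multisegment(3, 20, hinge_gap = 30), "disconnected")
})

test_that("fixture cases record ground truth and reject unphysical
           amplitudes", {
  h <- make_helix_chain(12)
  z <- make_case(h, 7:9, c(0, 0, 0), mask = FALSE)
  expect_equal(z$initial_rmsd, 0)
  case <- make_case(h, 7:9, c(3, -2, 1), mask = TRUE)
  expect_gt(case$initial_rmsd, 1)
  expect_lt(case$initial_rmsd, 5)
  expect_equal(rmsd(case$predicted, case$true_model), case$initial_rmsd)
  # a* reproduces the truth through deform()
  am <- restrict_range(augment_modes(case$modes, h), 7, 9)
  expect_equal(coords(deform(h, am, case$a_star)), coords(case$true_model))
  # huge amplitudes stretch bonds beyond 50% and are rejected
  expect_error(make_case(h, 7:9, c(40, 0, 0)), "unphysical")
})

test_that("fixture construction is bit-deterministic", {
  h <- make_multisegment(2, 12)
  c1 <- make_case(h, 7:10, c(2, -1, 1.5, 0.5), seed = 3)
  c2 <- make_case(h, 7:10, c(2, -1, 1.5, 0.5), seed = 3)
  expect_identical(c1$target_map$values, c2$target_map$values)
  expect_identical(coords(c1$true_model), coords(c2$true_model))
  expect_identical(c1$initial_rmsd, c2$initial_rmsd)
})

test_that("the truth scores near-perfectly against its own map", {
  h <- make_multisegment(2, 12)
  ms <- compute_modes(h)
  a <- recovery_amplitudes(ms, 7:9, target_rmsd = 0.4, seed = 2)
  am <- restrict_range(augment_modes(ms, h), 7, 9)
  # unmasked: the target is exactly the truth's simulated map
  plain <- make_case(h, 7:9, a, mask = FALSE)
  obj_p <- make_objective(h, am, plain$target_map, simulation_config(5),
                          "pearson")
  expect_gte(-obj_p(plain$a_star), 0.999)
  # masked: the zone mask (radius 5 A = 2 sigma at 5 A resolution) clips the
  # outermost Gaussian tails that the simulated truth still carries, so the
  # self-score sits just below the unmasked ideal
  case <- make_case(h, 7:9, a, mask = TRUE)
  obj_m <- make_objective(h, am, case$target_map, simulation_config(5),
                          "pearson")
  expect_gte(-obj_m(case$a_star), 0.995)
})

test_that("initial RMSD grows monotonically with the amplitude scale and
           matches the orthonormal-mode arithmetic", {
  h <- make_multisegment(2, 12)
  ms <- compute_modes(h)
  base_a <- recovery_amplitudes(ms, 7:9, target_rmsd = 0.15, seed = 4)
  rmsds <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(s) {
    make_case(h, 7:9, s * base_a, mask = FALSE)$initial_rmsd
  }, numeric(1))
  expect_true(all(diff(rmsds) > 0))
  # rmsd = ||a|| / sqrt(N) for orthonormal C-alpha modes
  expect_equal(rmsds[1], 0.5 * sqrt(sum(base_a^2)) / sqrt(n_atoms(h)),
               tolerance = 1e-10)
  # recovery_amplitudes hits its target exactly
  expect_equal(sqrt(sum(base_a^2)) / sqrt(n_atoms(h)), 0.15, tolerance = 1e-12)
})

test_that("decoy density adds neighboring-chain weight to the target", {
  h <- make_multisegment(2, 12)
  ms <- compute_modes(h)
  a <- recovery_amplitudes(ms, 7:9, target_rmsd = 0.4, seed = 6)
  masked <- make_case(h, 7:9, a, mask = TRUE)
  decoy <- make_case(h, 7:9, a, mask = FALSE, decoy_density = TRUE)
  expect_gt(sum(decoy$target_map$values), sum(masked$target_map$values))
  expect_true(decoy$decoy)
  expect_false(decoy$masked)
})
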