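test_that("deformation is linear in the elongation vector and exact on the
           rigid subspace", {
  h <- make_helix_chain(14)
  ms <- compute_modes(h)
  am <- augment_modes(ms, h)
  a0 <- rep(0, ncol(am$vectors))
  expect_equal(coords(deform(h, am, a0)), coords(h))
  # rigid-subspace projection of a uniform 2 A x-translation
  tfield <- rep(c(2, 0, 0), n_atoms(h))
  coef <- as.vector(crossprod(ms$vectors[, 1:6], tfield))
  def <- deform(h, restrict_range(am, 1, 6), coef)
  expect_equal(coords(def), sweep(coords(h), 2, c(2, 0, 0), `+`),
               tolerance = 1e-8)
  # additivity: deform by a then -a returns the original coordinates
  amr <- restrict_range(am, 7, 9)
  a <- c(1.3, -0.7, 2.1)
  back <- deform(deform(h, amr, a), amr, -a)
  expect_equal(coords(back), coords(h), tolerance = 1e-10)
  expect_error(deform(h, amr, c(1, 2)), "length")
  expect_error(deform(make_helix_chain(15), amr, a), "atoms")
})

test_that("target preparation applies the measure-dependent margin once", {
  m <- density_map(array(stats::runif(8000), c(20, 20, 20)), 1)
  inner_cfg <- fit_config(measure = "inner")
  expect_identical(prepare_target(m, inner_cfg), m)       # margin 0
  pearson_cfg <- fit_config(measure = "pearson")
  p <- prepare_target(m, pearson_cfg)
  expect_identical(dim(p$values), c(40L, 40L, 40L))       # margin 10
  expect_identical(prepare_target(p, inner_cfg), p)       # idempotent at 0
})

test_that("the objective is the negative similarity of the simulated map", {
  prob <- tiny_fit_problem()
  target_self <- simulate_map(prob$model, prob$target, prob$sim_cfg)
  obj_p <- make_objective(prob$model, prob$restricted, target_self,
                          prob$sim_cfg, "pearson")
  expect_equal(obj_p(c(0, 0, 0)), -1, tolerance = 1e-12)
  obj_i <- make_objective(prob$model, prob$restricted, prob$target,
                          prob$sim_cfg, "inner")
  two_step <- -inner_product(simulate_map(prob$model, prob$target,
                                          prob$sim_cfg), prob$target)
  expect_equal(obj_i(c(0, 0, 0)), two_step)
})

test_that("a 1D objective scan brackets the optimizer's minimum", {
  h <- make_helix_chain(14)
  ms <- compute_modes(h)
  amr <- restrict_range(augment_modes(ms, h), 7, 7)
  truth <- deform(h, amr, 2.5)
  tpl <- map_lattice(truth, 1, pad = 9)
  sim_cfg <- simulation_config(5)
  target <- simulate_map(truth, tpl, sim_cfg)
  obj <- make_objective(h, amr, target, sim_cfg, "pearson")
  grid <- seq(-4, 4, by = 0.05)
  fs <- vapply(grid, function(t) obj(t), numeric(1))
  res <- flex_fit(h, amr, target, sim_cfg,
                  fit_config(measure = "pearson", optimizer = "powell"))
  expect_lt(abs(res$best_elongation[[1]] - grid[which.min(fs)]), 0.05)
})

test_that("fitting a self-target is already optimal and the engine tracks the
           best-ever point", {
  prob <- tiny_fit_problem()
  target_self <- simulate_map(prob$model, prob$target, prob$sim_cfg)
  res <- flex_fit(prob$model, prob$restricted, target_self, prob$sim_cfg,
                  fit_config(measure = "pearson", optimizer = "powell"))
  expect_equal(res$best_cc, 1, tolerance = 1e-6)
  expect_lt(max(abs(res$best_elongation)), 0.05)
  # monotone improvement over the start
  expect_gte(res$best_cc, -res$trace$objective[1] - 1e-12)
  # best_cc is consistent with the recorded optimum
  expect_equal(res$best_cc, -min(res$trace$objective), tolerance = 1e-10)
})

test_that("the evaluation budget returns the best point found with a
           budget-exhausted status", {
  prob <- tiny_fit_problem()
  res <- flex_fit(prob$model, prob$restricted, prob$target, prob$sim_cfg,
                  fit_config(measure = "inner", optimizer = "powell",
                             max_evals = 20))
  expect_identical(res$optimizer_status, "budget-exhausted")
  expect_identical(res$n_evaluations, 20L)
  expect_equal(res$best_cc, -min(res$trace$objective), tolerance = 1e-12)
})

test_that("the end-to-end pipeline fits, improves the score, writes a
           parseable PDB and is deterministic", {
  dir <- withr::local_tempdir()
  h <- make_multisegment(2, 12)
  ms <- compute_modes(h)
  am <- augment_modes(ms, h)
  astar <- recovery_amplitudes(ms, 7:9, target_rmsd = 1.2, seed = 5)
  truth <- deform(h, restrict_range(am, 7, 9), astar)
  target <- mask_zone(simulate_map(truth, map_lattice(truth, 1, pad = 9),
                                   simulation_config(5)),
                      truth, 5, minimal_bounds = TRUE)
  pdb <- file.path(dir, "model.pdb")
  arc <- file.path(dir, "modes.arc")
  mrc <- file.path(dir, "target.mrc")
  write_pdb(h, pdb)
  save_modes(am, arc)
  write_mrc(target, mrc)
  out1 <- file.path(dir, "fit1.pdb")
  msgs <- capture.output(
    res <- run_flexfit(pdb, mrc, resolution = 5, modes_path = arc,
                       out_path = out1, mode_start = 1, mode_end = 9,
                       measure = "inner", optimizer = "powell"),
    type = "message")
  expect_true(file.exists(out1))
  fitted <- read_pdb(out1)
  expect_equal(n_atoms(fitted), n_atoms(h))
  expect_gt(res$best_cc, -res$trace$objective[1])   # improved over start
  expect_true(any(grepl("best inner", msgs)))
  # objective consistency from the written file (PDB precision only)
  target_mem <- read_mrc(mrc)
  cc_file <- inner_product(simulate_map(fitted, target_mem,
                                        simulation_config(5)), target_mem)
  expect_equal(cc_file, res$best_cc, tolerance = 1e-4)
  # identical invocation gives identical bytes
  out2 <- file.path(dir, "fit2.pdb")
  suppressMessages(
    run_flexfit(pdb, mrc, resolution = 5, modes_path = arc, out_path = out2,
                mode_start = 1, mode_end = 9, measure = "inner",
                optimizer = "powell", verbose = FALSE))
  expect_identical(readLines(out1), readLines(out2))
  # argument validation happens before any computation
  expect_error(run_flexfit(pdb, mrc, 5, arc, out1, mode_start = 7,
                           mode_end = 6), "exceeds")
})
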