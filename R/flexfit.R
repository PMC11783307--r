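#' Flexible-fitting configuration
#'
#' @param measure similarity used as the fitting objective: `"inner"`
#'   (unnormalized inner product, padding-invariant, default) or `"pearson"`.
#' @param optimizer `"powell"` (default), `"nelder-mead"`, `"dual-annealing"`
#'   or `"differential-evolution"`. The local methods start from the zero
#'   elongation vector; the global methods search within `bounds` and honor
#'   `seed`.
#' @param mode_start,mode_end 1-based inclusive mode range to retain (the
#'   widest tested range, 1-12, is the default; modes 1-6 are the rigid
#'   block).
#' @param margin zero-padding margin in voxels applied to the target before
#'   optimization; `NULL` resolves to 10 for `pearson` and 0 for `inner`.
#' @param bounds length-2 numeric, elongation-coefficient bounds for the
#'   global optimizers (default c(-9, 9)).
#' @param seed integer seed for the stochastic optimizers.
#' @param max_evals cap on objective evaluations; when exhausted the best
#'   point found so far is returned with status `"budget-exhausted"`.
#' @param reltol relative objective tolerance for the local optimizers.
#' @return object of class `fit_config`
#' @export
fit_config <- function(measure = c("inner", "pearson"),
                       optimizer = c("powell", "nelder-mead",
                                     "dual-annealing",
                                     "differential-evolution"),
                       mode_start = 1, mode_end = 12, margin = NULL,
                       bounds = c(-9, 9), seed = 0, max_evals = 10000,
                       reltol = 1e-6) {
  measure <- match.arg(measure)
  optimizer <- match.arg(optimizer)
  stopifnot(mode_start >= 1, mode_start <= mode_end,
            length(bounds) == 2, bounds[1] < bounds[2], max_evals > 0)
  if (is.null(margin)) margin <- if (measure == "pearson") 10 else 0
  stopifnot(margin >= 0)
  structure(list(measure = measure, optimizer = optimizer,
                 mode_start = as.integer(mode_start),
                 mode_end = as.integer(mode_end),
                 margin = as.integer(margin), bounds = as.numeric(bounds),
                 seed = as.integer(seed), max_evals = as.integer(max_evals),
                 reltol = reltol),
            class = "fit_config")
}

#' Deform a model along a mode-elongation vector
#'
#' New positions are \eqn{x_i' = x_i + \sum_k a_k w_{k,i}}: the elongation
#' coefficients multiply the orthonormal all-atom mode fields directly. All
#' other atom attributes are unchanged; the input model is not mutated.
#'
#' @param model an [atom_model]
#' @param modes an `all_atom_modes` matching the model's atom count
#' @param a numeric elongation vector, one coefficient per retained mode
#' @return the deformed [atom_model]
#' @export
deform <- function(model, modes, a) {
  stopifnot(inherits(model, "atom_model"), inherits(modes, "all_atom_modes"))
  if (modes$n_atoms != n_atoms(model)) {
    stop("mode field is for ", modes$n_atoms, " atoms but the model has ",
         n_atoms(model))
  }
  if (length(a) != ncol(modes$vectors)) {
    stop("elongation vector length (", length(a),
         ") does not match the retained mode count (", ncol(modes$vectors), ")")
  }
  if (any(!is.finite(a))) stop("non-finite elongation coefficients")
  disp <- modes$vectors %*% a
  xyz <- coords(model) + matrix(disp, ncol = 3, byrow = TRUE)
  set_coords(model, xyz)
}

#' Prepare a target map for fitting
#'
#' Applies the zero-padding margin exactly once, before optimization. The
#' Pearson correlation is not invariant under padding, so its margin (default
#' 10 voxels) must be fixed up front and large enough to embed the deformed
#' intermediates; the inner product is padding-invariant and defaults to no
#' margin.
#'
#' @param map the target [density_map]
#' @param cfg a [fit_config]
#' @return the padded [density_map]
#' @export
prepare_target <- function(map, cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  zero_pad(map, cfg$margin)
}

similarity_fun <- function(measure) {
  switch(measure,
         pearson = pearson_cc,
         inner = inner_product,
         situs = situs_cc,
         stop("unknown measure: ", measure))
}

#' Build the fitting objective
#'
#' Returns the function of the elongation vector that the optimizers
#' minimize: the negative similarity between the simulated map of the
#' deformed model (on the target lattice) and the target map. A degenerate
#' evaluation (deformation pushed all density off-grid, making the similarity
#' undefined) returns +1, the worst possible score, with a warning, so global
#' optimizers survive pathological corners of the search space.
#'
#' @param model an [atom_model]
#' @param modes an `all_atom_modes` (already restricted to the fitted range)
#' @param target the prepared target [density_map]
#' @param sim_cfg a [simulation_config]
#' @param measure `"inner"`, `"pearson"` or `"situs"`
#' @return function `a -> scalar`
#' @export
make_objective <- function(model, modes, target, sim_cfg,
                           measure = "inner") {
  sim_fun <- similarity_fun(measure)
  force(model); force(modes); force(target); force(sim_cfg)
  function(a) {
    sim <- simulate_map(deform(model, modes, a), target, sim_cfg)
    s <- tryCatch(sim_fun(sim, target), error = function(e) {
      warning("degenerate similarity during search (", conditionMessage(e),
              "); scoring as worst", call. = FALSE)
      -1
    })
    -s
  }
}

budget_exhausted <- function() {
  structure(class = c("flexmode_budget", "condition"),
            list(message = "evaluation budget exhausted", call = NULL))
}

#' Fit a model to a density map along its normal modes
#'
#' The engine: minimizes the negative similarity over the elongation vector
#' with the configured optimizer, tracking the best-ever evaluated point so
#' that a result is returned even on non-convergence or budget exhaustion.
#' Local optimizers start from the zero vector (the undeformed model); global
#' optimizers sample within `cfg$bounds` under `cfg$seed` (same seed, same
#' result).
#'
#' @param model an [atom_model] (the structure to deform)
#' @param modes an `all_atom_modes` already restricted to the fitted mode
#'   range (see [restrict_range])
#' @param target the prepared target [density_map] (see [prepare_target])
#' @param sim_cfg a [simulation_config] matching the target's resolution
#' @param cfg a [fit_config]
#' @return object of class `flexfit_result`: `best_elongation` (named by
#'   original mode index), `best_cc` (the maximized similarity),
#'   `deformed_model`, `n_evaluations`, `optimizer_status`, `trace`
#'   (data frame of evaluation index and objective)
#' @export
flex_fit <- function(model, modes, target, sim_cfg, cfg = fit_config()) {
  stopifnot(inherits(modes, "all_atom_modes"), inherits(cfg, "fit_config"))
  n_modes <- ncol(modes$vectors)
  raw_obj <- make_objective(model, modes, target, sim_cfg, cfg$measure)
  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$best_f <- Inf
  state$best_a <- rep(0, n_modes)
  state$trace_f <- numeric(0)
  obj <- function(a) {
    if (state$n >= cfg$max_evals) stop(budget_exhausted())
    f <- raw_obj(a)
    state$n <- state$n + 1L
    state$trace_f[state$n] <- f
    if (is.finite(f) && f < state$best_f) {
      state$best_f <- f
      state$best_a <- a
    }
    f
  }
  x0 <- rep(0, n_modes)
  f0 <- tryCatch(obj(x0), error = function(e) {
    if (inherits(e, "flexmode_budget")) stop(e)
    stop("objective failed at the initial point: ", conditionMessage(e))
  })
  status <- "converged"
  run <- function() {
    switch(cfg$optimizer,
      "powell" = powell_minimize(obj, x0, reltol = cfg$reltol),
      "nelder-mead" = nelder_mead_minimize(obj, x0, reltol = cfg$reltol,
                                           maxit = cfg$max_evals),
      "dual-annealing" = dual_annealing_minimize(
        obj, rep(cfg$bounds[1], n_modes), rep(cfg$bounds[2], n_modes),
        seed = cfg$seed),
      "differential-evolution" = diff_evolution_minimize(
        obj, rep(cfg$bounds[1], n_modes), rep(cfg$bounds[2], n_modes),
        seed = cfg$seed)
    )
  }
  tryCatch(run(), flexmode_budget = function(e) status <<- "budget-exhausted")
  best_a <- state$best_a
  deformed <- deform(model, modes, best_a)
  best_sim <- similarity_fun(cfg$measure)(
    simulate_map(deformed, target, sim_cfg), target)
  structure(list(
    best_elongation = stats::setNames(as.numeric(best_a),
                                      paste0("mode", modes$mode_indices)),
    mode_indices = modes$mode_indices,
    best_cc = best_sim,
    measure = cfg$measure,
    optimizer = cfg$optimizer,
    deformed_model = deformed,
    n_evaluations = state$n,
    optimizer_status = status,
    trace = data.frame(evaluation = seq_len(state$n),
                       objective = state$trace_f)
  ), class = "flexfit_result")
}

#' @export
print.flexfit_result <- function(x, ...) {
  cat(sprintf("flexfit_result: %s/%s, modes %s\n", x$optimizer, x$measure,
              paste(range(x$mode_indices), collapse = "-")))
  cat(sprintf("  best %s = %.6g after %d evaluations (%s)\n", x$measure,
              x$best_cc, x$n_evaluations, x$optimizer_status))
  cat("  elongation: ",
      paste(sprintf("%.3g", x$best_elongation), collapse = " "), "\n")
  invisible(x)
}

#' End-to-end flexible fitting from files
#'
#' Loads an atomic model, an all-atom mode archive and a target map (MRC or
#' Situs, by file extension), restricts the mode range, prepares the target,
#' runs the fit and writes the deformed structure as PDB.
#'
#' @param pdb_path input model (PDB)
#' @param map_path target map (`.mrc`/`.map` or `.situs`/`.sit`)
#' @param resolution target map resolution, Angstrom
#' @param modes_path mode archive from [save_modes]; a C-alpha archive is
#'   augmented to the model with the per-residue scheme on the fly
#' @param out_path output PDB for the fitted structure
#' @param mode_start,mode_end fitted mode range (1-based inclusive)
#' @param margin zero-padding margin (voxels); `NULL` = measure default
#' @param measure,optimizer,seed,max_evals see [fit_config]
#' @param verbose log configuration and progress with [message()]
#' @return the `flexfit_result`, invisibly
#' @export
run_flexfit <- function(pdb_path, map_path, resolution, modes_path, out_path,
                        mode_start = 1, mode_end = 12, margin = NULL,
                        measure = "inner", optimizer = "powell", seed = 0,
                        max_evals = 10000, verbose = TRUE) {
  if (mode_start > mode_end) {
    stop("mode_start (", mode_start, ") exceeds mode_end (", mode_end, ")")
  }
  say <- function(...) if (verbose) message(...)
  cfg <- fit_config(measure = measure, optimizer = optimizer,
                    mode_start = mode_start, mode_end = mode_end,
                    margin = margin, seed = seed, max_evals = max_evals)
  model <- read_pdb(pdb_path)
  modes <- load_modes(modes_path)
  if (inherits(modes, "mode_set")) {
    modes <- augment_modes(modes, model, scheme = "per-residue")
  }
  if (!inherits(modes, "all_atom_modes")) {
    stop("mode archive stage: not a usable mode archive: ", modes_path)
  }
  modes <- restrict_range(modes, mode_start, mode_end)
  ext <- tolower(tools::file_ext(map_path))
  map <- if (ext %in% c("situs", "sit")) read_situs(map_path)
         else read_mrc(map_path)
  target <- prepare_target(map, cfg)
  sim_cfg <- simulation_config(resolution)
  say(sprintf("flexmode fit: %d atoms, modes %d-%d, %s/%s, margin %d, seed %d",
              n_atoms(model), mode_start, mode_end, measure, optimizer,
              cfg$margin, cfg$seed))
  initial_cc <- similarity_fun(measure)(
    simulate_map(model, target, sim_cfg), target)
  res <- flex_fit(model, modes, target, sim_cfg, cfg)
  say(sprintf("  initial %s = %.6g; best %s = %.6g (%d evaluations, %s)",
              measure, initial_cc, measure, res$best_cc, res$n_evaluations,
              res$optimizer_status))
  write_pdb(res$deformed_model, out_path)
  say("  fitted structure written to ", out_path)
  invisible(res)
}
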