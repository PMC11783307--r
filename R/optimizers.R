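# Derivative-free minimizers used by the fitting engine.
#
# Powell's conjugate-direction method and the two bounded global methods
# (fast-simulated-annealing variant, classic DE/rand/1/bin) are implemented
# here; Nelder-Mead delegates to stats::optim. All of them only ever call the
# objective through the closure they are handed, so the engine's best-ever
# bookkeeping sees every evaluation.

# Evaluate expr with a private, seeded RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Bracket-and-Brent line minimization of fn along dir from x.
# Returns list(x, f). step0 sets the initial bracketing step.
line_minimize <- function(fn, x, dir, f0, step0 = 0.5, tol = 1e-4,
                          max_expand = 40) {
  g <- function(t) fn(x + t * dir)
  s <- step0
  fp <- g(s)
  fm <- g(-s)
  if (fp >= f0 && fm >= f0) {
    interval <- c(-s, s)
  } else {
    sgn <- if (fp < fm) 1 else -1
    f_mid <- min(fp, fm)
    t_lo <- 0
    t_mid <- sgn * s
    t_hi <- 2 * t_mid
    for (i in seq_len(max_expand)) {
      f_hi <- g(t_hi)
      if (f_hi > f_mid) break
      t_lo <- t_mid
      t_mid <- t_hi
      f_mid <- f_hi
      t_hi <- 2 * t_hi
    }
    interval <- sort(c(t_lo, t_hi))
  }
  opt <- stats::optimize(g, interval = interval, tol = tol)
  if (opt$objective <= f0) {
    list(x = x + opt$minimum * dir, f = opt$objective, t = opt$minimum)
  } else {
    list(x = x, f = f0, t = 0)
  }
}

# Powell's method (conjugate directions with the standard direction-replacement
# criterion). reltol is on the objective decrease per full cycle.
powell_minimize <- function(fn, x0, reltol = 1e-6, max_cycles = 60,
                            step0 = 0.5) {
  n <- length(x0)
  dirs <- diag(n)
  x <- x0
  f <- fn(x)
  for (cycle in seq_len(max_cycles)) {
    f_start <- f
    x_start <- x
    biggest <- 0
    ibig <- 1
    for (i in seq_len(n)) {
      res <- line_minimize(fn, x, dirs[, i], f, step0 = step0)
      if (f - res$f > biggest) {
        biggest <- f - res$f
        ibig <- i
      }
      x <- res$x
      f <- res$f
    }
    if (2 * (f_start - f) <= reltol * (abs(f_start) + abs(f)) + 1e-20) break
    # extrapolated point and direction-replacement test
    xe <- 2 * x - x_start
    fe <- fn(xe)
    if (fe < f_start) {
      t <- 2 * (f_start - 2 * f + fe) * (f_start - f - biggest)^2 -
        biggest * (f_start - fe)^2
      if (t < 0) {
        new_dir <- x - x_start
        nd <- sqrt(sum(new_dir^2))
        if (nd > 0) {
          res <- line_minimize(fn, x, new_dir / nd, f, step0 = step0)
          x <- res$x
          f <- res$f
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- new_dir / nd
        }
      }
    }
  }
  list(par = x, value = f)
}

nelder_mead_minimize <- function(fn, x0, reltol = 1e-6, maxit = 5000) {
  res <- stats::optim(x0, fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  list(par = res$par, value = res$value)
}

# reflect a proposal back into [lower, upper]
reflect_into <- function(x, lower, upper) {
  span <- upper - lower
  y <- (x - lower) %% (2 * span)
  lower + ifelse(y > span, 2 * span - y, y)
}

# Bounded fast-simulated-annealing with Cauchy visiting steps whose scale
# shrinks with temperature, followed by a local Powell polish from the best
# visited point. Seeded and deterministic for a given seed.
dual_annealing_minimize <- function(fn, lower, upper, seed = 0,
                                    maxiter = 120, polish = TRUE) {
  d <- length(lower)
  span <- upper - lower
  with_seed(seed, {
    x <- lower + stats::runif(d) * span
    f <- fn(x)
    best_x <- x
    best_f <- f
    t0 <- max(abs(f), 1)
    for (it in seq_len(maxiter)) {
      frac <- 1 / (1 + 9 * (it - 1) / max(1, maxiter - 1))  # 1 -> 0.1
      temp <- t0 * frac
      for (j in seq_len(2 * d)) {
        step <- tan(pi * (stats::runif(d) - 0.5)) * span * 0.1 * frac
        xp <- reflect_into(x + step, lower, upper)
        fp <- fn(xp)
        if (fp < f || stats::runif(1) < exp(-(fp - f) / temp)) {
          x <- xp
          f <- fp
        }
        if (fp < best_f) {
          best_x <- xp
          best_f <- fp
        }
      }
      # occasional restart from the incumbent best, as in dual annealing's
      # local-search interludes
      if (it %% 25 == 0) {
        x <- best_x
        f <- best_f
      }
    }
    if (polish) {
      res <- powell_minimize(fn, best_x, reltol = 1e-6, max_cycles = 20)
      if (res$value < best_f) {
        best_x <- res$par
        best_f <- res$value
      }
    }
    list(par = best_x, value = best_f)
  })
}

# Classic differential evolution (DE/rand/1/bin) within bounds, with an
# optional local polish of the final best member. Seeded.
diff_evolution_minimize <- function(fn, lower, upper, seed = 0,
                                    popsize = NULL, maxgen = 60,
                                    F = 0.8, CR = 0.9, polish = TRUE) {
  d <- length(lower)
  span <- upper - lower
  if (is.null(popsize)) popsize <- min(10 * d, 40)
  popsize <- max(popsize, 5)
  with_seed(seed, {
    pop <- matrix(stats::runif(popsize * d), popsize, d)
    pop <- sweep(sweep(pop, 2, span, `*`), 2, lower, `+`)
    fit <- apply(pop, 1, fn)
    for (gen in seq_len(maxgen)) {
      for (i in seq_len(popsize)) {
        idx <- sample(setdiff(seq_len(popsize), i), 3)
        mutant <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        mutant <- reflect_into(mutant, lower, upper)
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        ft <- fn(trial)
        if (ft <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- ft
        }
      }
    }
    ibest <- which.min(fit)
    best_x <- pop[ibest, ]
    best_f <- fit[ibest]
    if (polish) {
      res <- powell_minimize(fn, best_x, reltol = 1e-6, max_cycles = 20)
      if (res$value < best_f) {
        best_x <- res$par
        best_f <- res$value
      }
    }
    list(par = best_x, value = best_f)
  })
}
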