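#' Elastic-network configuration
#'
#' Parameters of the C-alpha elastic network: all pairs of nodes within
#' `cutoff` are connected by identical Hookean springs of stiffness `k`.
#' The recommended cutoff for protein C-alpha networks is 12 Angstrom.
#' Masses are unit, so eigenvalues are squared frequencies in units of `k`.
#'
#' @param cutoff spring cutoff distance, Angstrom (> 0)
#' @param k uniform spring constant, energy/Angstrom^2 (> 0)
#' @param zero_mode_rel_tol relative eigenvalue threshold below which a mode
#'   counts as a zero (rigid-body) mode: `lambda < tol * max(lambda)`
#' @return object of class `enm_config`
#' @export
enm_config <- function(cutoff = 12, k = 1, zero_mode_rel_tol = 1e-8) {
  stopifnot(cutoff > 0, k > 0, zero_mode_rel_tol > 0, zero_mode_rel_tol < 1)
  structure(list(cutoff = cutoff, k = k, zero_mode_rel_tol = zero_mode_rel_tol),
            class = "enm_config")
}

#' Build the elastic-network Hessian of a C-alpha model
#'
#' For every node pair (i, j) with distance d <= cutoff the 3x3 off-diagonal
#' block is \eqn{-(k/d^2)\, r r^T} with \eqn{r = x_j - x_i}; diagonal blocks
#' are minus the sum of the row's off-diagonal blocks. The result is the
#' second-derivative matrix of the pairwise harmonic network energy at its
#' minimum: symmetric, positive semi-definite, annihilating rigid motions.
#'
#' @param ca C-alpha [atom_model] (N >= 2 nodes)
#' @param cfg an [enm_config]
#' @return symmetric 3N-by-3N matrix with the network metadata attached as
#'   attributes (`coords`, `cutoff`, `k`, `zero_mode_rel_tol`)
#' @export
build_hessian <- function(ca, cfg = enm_config()) {
  stopifnot(inherits(ca, "atom_model"), inherits(cfg, "enm_config"))
  xyz <- coords(ca)
  n <- nrow(xyz)
  if (n < 2) stop("elastic network needs at least 2 nodes")
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cfg$cutoff
  diag(adj) <- FALSE
  if (!any(adj)) stop("disconnected network: no node pair within the ", cfg$cutoff,
                      " Angstrom cutoff")
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- xyz[j, ] - xyz[i, ]
    blk <- -(cfg$k / sum(r * r)) * tcrossprod(r)
    bi <- (3 * i - 2):(3 * i)
    bj <- (3 * j - 2):(3 * j)
    H[bi, bj] <- H[bi, bj] + blk
    H[bj, bi] <- H[bj, bi] + blk
    H[bi, bi] <- H[bi, bi] - blk
    H[bj, bj] <- H[bj, bj] - blk
  }
  attr(H, "coords") <- xyz
  attr(H, "cutoff") <- cfg$cutoff
  attr(H, "k") <- cfg$k
  attr(H, "zero_mode_rel_tol") <- cfg$zero_mode_rel_tol
  H
}

#' Diagonalize an elastic-network Hessian into a mode set
#'
#' Full symmetric eigendecomposition; eigenvalues ascending, eigenvectors
#' orthonormal. A deterministic sign convention is applied (the
#' largest-magnitude component of each eigenvector is made positive) so that
#' archives and results are reproducible. The count of numerically-zero
#' modes is checked: a connected, non-degenerate 3D network has exactly 6
#' (three translations + three rotations, spanning a null space rather than
#' resolving individually). More than 6 signals degenerate geometry
#' (collinear/planar nodes) and warns; fewer than 6 is a numerical failure.
#'
#' @param hessian matrix from [build_hessian] (with its attributes)
#' @return object of class `mode_set` with fields `n_nodes`, `eigenvalues`,
#'   `vectors` (3N-by-3N, columns are modes), `n_rigid`, `node_coords`,
#'   `cutoff`, `k`
#' @export
diagonalize <- function(hessian) {
  xyz <- attr(hessian, "coords")
  if (is.null(xyz)) stop("hessian lacks network metadata; use build_hessian()")
  tol <- attr(hessian, "zero_mode_rel_tol")
  e <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_along(e$values))      # eigen() returns descending
  lambda <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-|component| positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  lmax <- max(lambda)
  if (lmax <= 0) stop("degenerate spectrum: no positive eigenvalue")
  if (min(lambda) < -tol * lmax) {
    stop("numerical failure: eigenvalue significantly below zero (",
         format(min(lambda)), ")")
  }
  n_rigid <- sum(lambda < tol * lmax)
  # a collinear node set (rank-1 centered coordinates) has no rotation about
  # its own axis: the rigid space is 5-dimensional, not 6
  centered <- sweep(xyz, 2, colMeans(xyz))
  geo_rank <- qr(centered, tol = 1e-8)$rank
  expected_rigid <- if (geo_rank <= 1) 5L else 6L
  if (n_rigid > 6) {
    warning("degenerate geometry: ", n_rigid,
            " zero modes (> 6); nodes may be collinear or planar")
  } else if (n_rigid < expected_rigid) {
    stop("numerical failure: only ", n_rigid, " zero modes found (expected ",
         expected_rigid, ")")
  }
  structure(list(
    n_nodes = nrow(xyz),
    eigenvalues = lambda,
    vectors = V,
    n_rigid = as.integer(n_rigid),
    node_coords = xyz,
    cutoff = attr(hessian, "cutoff"),
    k = attr(hessian, "k"),
    zero_mode_rel_tol = tol
  ), class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d nodes, %d modes (%d rigid), cutoff %g A, k = %g\n",
              x$n_nodes, length(x$eigenvalues), x$n_rigid, x$cutoff, x$k))
  invisible(x)
}

#' Compute elastic-network normal modes of a C-alpha model
#'
#' Convenience wrapper: [build_hessian] followed by [diagonalize].
#'
#' @inheritParams build_hessian
#' @return a `mode_set`
#' @export
compute_modes <- function(ca, cfg = enm_config()) {
  diagonalize(build_hessian(ca, cfg))
}

#' Mode frequencies
#'
#' For unit masses the angular frequency of mode k is
#' \eqn{\omega_k = \sqrt{\max(\lambda_k, 0)}} (arbitrary units set by the
#' spring constant). Order matches the ascending eigenvalue order.
#'
#' @param modes a `mode_set`
#' @return numeric vector of frequencies
#' @export
frequencies <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  sqrt(pmax(modes$eigenvalues, 0))
}
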