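#' Pearson product-moment correlation between two maps
#'
#' \deqn{CC = \sum_i (x_i - \bar x)(y_i - \bar y) /
#'   \sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}
#' over all n voxels of the common lattice. Centering makes the value
#' sensitive to zero-padding (adding zero voxels changes the means), which is
#' why fitting with this measure uses a fixed padding margin chosen before
#' optimization.
#'
#' @param x,y [density_map]s on identical lattices
#' @return correlation in \[-1, 1\]
#' @export
pearson_cc <- function(x, y) {
  check_lattices(x, y)
  vx <- as.vector(x$values)
  vy <- as.vector(y$values)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop("undefined correlation: a map has zero variance")
  }
  stats::cor(vx, vy)
}

#' Unnormalized inner product between two maps
#'
#' \deqn{CC = \sum_i x_i y_i} with no centering and no normalization. Exactly
#' invariant under zero-padding of both maps (added zeros contribute nothing),
#' so density protruding beyond the scored volume is simply ignored; this is
#' the cheapest fitting objective.
#'
#' @param x,y [density_map]s on identical lattices
#' @return the inner product (arbitrary units)
#' @export
inner_product <- function(x, y) {
  check_lattices(x, y)
  sum(as.vector(x$values) * as.vector(y$values))
}

#' Normalized uncentered (Situs-style) correlation
#'
#' \deqn{CC = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}}: the inner
#' product divided by the product of uncentered norms. Scale invariant and,
#' like the inner product, exactly invariant under zero-padding.
#'
#' @param x,y [density_map]s on identical lattices, both of nonzero norm
#' @return correlation in \[-1, 1\]
#' @export
situs_cc <- function(x, y) {
  check_lattices(x, y)
  vx <- as.vector(x$values)
  vy <- as.vector(y$values)
  nx <- sqrt(sum(vx^2))
  ny <- sqrt(sum(vy^2))
  if (nx == 0 || ny == 0) stop("undefined correlation: a map has zero norm")
  sum(vx * vy) / (nx * ny)
}

check_lattices <- function(x, y) {
  stopifnot(inherits(x, "density_map"), inherits(y, "density_map"))
  if (!same_lattice(x, y)) {
    stop("maps are on different lattices (dims ",
         paste(dim(x$values), collapse = "x"), " vs ",
         paste(dim(y$values), collapse = "x"),
         ", spacing ", x$spacing, " vs ", y$spacing, ")")
  }
  invisible(TRUE)
}
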