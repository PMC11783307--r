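# Mode archives: a self-describing plain-text container for mode sets and
# all-atom mode fields. Layout (whitespace separated, one logical record per
# line, doubles printed with "%.17g" so round trips are exact at double
# precision):
#
#   FLEXMODE_MODES 1
#   type ca|allatom
#   <scalar metadata: key value>
#   mode_indices  <n_modes ints>
#   eigenvalues   <n_modes doubles>
#   coords        <3*n_nodes doubles, node-major>      (type ca only)
#   vectors       <3N doubles per line, one line per mode>
#   END

.fmt <- function(x) sprintf("%.17g", x)

#' Save a mode set or all-atom mode field to a text archive
#'
#' The archive is self-describing (versioned header, shapes, provenance such
#' as the network cutoff) and round-trips eigenvalues, eigenvectors and node
#' coordinates exactly at double precision.
#'
#' @param modes a `mode_set` (from [compute_modes]) or `all_atom_modes`
#'   (from [augment_modes])
#' @param path output file path
#' @return invisibly, `path`
#' @export
save_modes <- function(modes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  if (inherits(modes, "mode_set")) {
    n_modes <- length(modes$eigenvalues)
    w("FLEXMODE_MODES", "1")
    w("type", "ca")
    w("n_nodes", modes$n_nodes)
    w("n_modes", n_modes)
    w("n_rigid", modes$n_rigid)
    w("cutoff", .fmt(modes$cutoff))
    w("spring_k", .fmt(modes$k))
    w("zero_mode_rel_tol", .fmt(modes$zero_mode_rel_tol))
    w("mode_indices", paste(seq_len(n_modes), collapse = " "))
    w("eigenvalues", paste(.fmt(modes$eigenvalues), collapse = " "))
    w("coords", paste(.fmt(as.vector(t(modes$node_coords))), collapse = " "))
    w("vectors")
    for (j in seq_len(n_modes)) {
      writeLines(paste(.fmt(modes$vectors[, j]), collapse = " "), con)
    }
    w("END")
  } else if (inherits(modes, "all_atom_modes")) {
    n_modes <- length(modes$mode_indices)
    w("FLEXMODE_MODES", "1")
    w("type", "allatom")
    w("n_atoms", modes$n_atoms)
    w("n_modes", n_modes)
    w("scheme", modes$scheme)
    w("source_mode_count", modes$source_mode_count)
    w("cutoff", .fmt(modes$cutoff))
    w("mode_indices", paste(modes$mode_indices, collapse = " "))
    w("eigenvalues", paste(.fmt(modes$eigenvalues), collapse = " "))
    w("vectors")
    for (j in seq_len(n_modes)) {
      writeLines(paste(.fmt(modes$vectors[, j]), collapse = " "), con)
    }
    w("END")
  } else {
    stop("save_modes: expected a mode_set or all_atom_modes object")
  }
  invisible(path)
}

#' Load a mode archive
#'
#' @param path archive written by [save_modes]
#' @return a `mode_set` or `all_atom_modes`, matching what was saved
#' @export
load_modes <- function(path) {
  if (!file.exists(path)) stop("mode archive not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bad <- function(why) stop("corrupt mode archive (", why, "): ", path)
  if (length(lines) < 3) bad("truncated")
  head1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (!identical(head1, c("FLEXMODE_MODES", "1"))) bad("bad magic/version")
  kv <- list()
  i <- 2
  while (i <= length(lines) && !startsWith(lines[i], "vectors")) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) >= 2) kv[[parts[1]]] <- parts[-1]
    i <- i + 1
  }
  if (i > length(lines)) bad("missing vectors section")
  need <- function(key) {
    if (is.null(kv[[key]])) bad(paste0("missing field ", key))
    kv[[key]]
  }
  type <- need("type")
  n_modes <- as.integer(need("n_modes"))
  idx <- as.integer(need("mode_indices"))
  lambda <- as.numeric(need("eigenvalues"))
  if (length(idx) != n_modes || length(lambda) != n_modes) bad("shape mismatch")
  vec_lines <- lines[(i + 1):length(lines)]
  end_at <- which(trimws(vec_lines) == "END")
  if (length(end_at) == 0) bad("missing END")
  vec_lines <- vec_lines[seq_len(end_at[1] - 1)]
  if (length(vec_lines) != n_modes) bad("vector count mismatch")
  V <- vapply(vec_lines,
              function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
              numeric(length(strsplit(trimws(vec_lines[1]), "\\s+")[[1]])))
  V <- unname(as.matrix(V))
  if (any(!is.finite(V))) bad("non-numeric vector data")
  if (type == "ca") {
    n_nodes <- as.integer(need("n_nodes"))
    if (nrow(V) != 3 * n_nodes) bad("vector length mismatch")
    xyz <- matrix(as.numeric(need("coords")), ncol = 3, byrow = TRUE)
    if (nrow(xyz) != n_nodes) bad("coords shape mismatch")
    structure(list(
      n_nodes = n_nodes,
      eigenvalues = lambda,
      vectors = V,
      n_rigid = as.integer(need("n_rigid")),
      node_coords = xyz,
      cutoff = as.numeric(need("cutoff")),
      k = as.numeric(need("spring_k")),
      zero_mode_rel_tol = as.numeric(need("zero_mode_rel_tol"))
    ), class = "mode_set")
  } else if (type == "allatom") {
    n_at <- as.integer(need("n_atoms"))
    if (nrow(V) != 3 * n_at) bad("vector length mismatch")
    structure(list(
      n_atoms = n_at,
      vectors = V,
      mode_indices = idx,
      eigenvalues = lambda,
      scheme = need("scheme"),
      source_mode_count = as.integer(need("source_mode_count")),
      cutoff = as.numeric(need("cutoff"))
    ), class = "all_atom_modes")
  } else {
    bad("unknown type")
  }
}
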