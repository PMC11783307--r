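# MRC2014 and Situs ASCII volume I/O.
#
# MRC: little-endian, mode 2 (float32), axis order column=x, row=y,
# section=z (mapc/mapr/maps = 1/2/3). Voxel spacing is cella/mx and must be
# isotropic. Origin precedence on read: the ORIGIN record if any component is
# nonzero, else nstart * spacing.
#
# Situs: one ASCII header line "width ox oy oz nx ny nz" followed by the
# values, x fastest; the origin is the coordinate of the first voxel center,
# matching this package's convention.

#' Read an MRC2014 density map
#'
#' Supports mode 2 (float32) and mode 0/1 (int8/int16) volumes with standard
#' axis order; anisotropic voxels are rejected.
#'
#' @param path MRC file path
#' @return a [density_map]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  if (length(hdr_raw) < 1024) stop("not an MRC file (truncated header): ", path)
  int_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "integer", 1, 4, endian = "little")
  num_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "numeric", 1, 4, endian = "little")
  magic <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(magic, 1, 3), "MAP")) {
    stop("not an MRC2014 file (missing MAP magic): ", path)
  }
  dims <- c(int_at(1), int_at(2), int_at(3))
  mode <- int_at(4)
  nstart <- c(int_at(5), int_at(6), int_at(7))
  m <- c(int_at(8), int_at(9), int_at(10))
  cella <- c(num_at(11), num_at(12), num_at(13))
  mapcrs <- c(int_at(17), int_at(18), int_at(19))
  origin_rec <- c(num_at(50), num_at(51), num_at(52))
  if (any(dims < 1) || any(m < 1)) stop("invalid MRC dimensions in ", path)
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    stop("unsupported MRC axis order (mapc/mapr/maps = ",
         paste(mapcrs, collapse = "/"), "); only 1/2/3 is supported")
  }
  sp <- cella / m
  if (max(sp) - min(sp) > 1e-4 * max(sp)) {
    stop("anisotropic voxels (", paste(format(sp), collapse = ", "),
         ") are not supported")
  }
  spacing <- mean(sp)
  n <- prod(dims)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n, 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " (expected 0, 1 or 2)")
  )
  if (length(vals) < n) stop("truncated MRC data section in ", path)
  origin <- if (any(origin_rec != 0)) origin_rec else nstart * spacing
  density_map(array(vals, dims), spacing, origin)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' @param map a [density_map]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  vals <- as.vector(map$values)
  wi(d)                                    # nx ny nz
  wi(2)                                    # mode 2 = float32
  wi(c(0, 0, 0))                           # nstart
  wi(d)                                    # mx my mz
  wf(d * map$spacing)                      # cella
  wf(c(90, 90, 90))                        # cellb
  wi(c(1, 2, 3))                           # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))  # dmin dmax dmean
  wi(1)                                    # ispg (volume)
  wi(0)                                    # nsymbt
  wi(c(0, 0))                              # extra (words 25-26)
  wi(0)                                    # exttyp (word 27)
  wi(20140)                                # nversion (word 28)
  wi(rep(0, 21))                           # remaining extra (words 29-49)
  wf(map$origin)                           # origin x y z (words 50-52)
  writeBin(charToRaw("MAP "), con)         # map magic
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(vals))                      # rms
  wi(1)                                    # nlabl
  lab <- sprintf("%-80s", "flexmode density map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(720), con)                  # labels 2-10
  wf(vals)
  invisible(path)
}

#' Read a Situs ASCII density map
#'
#' @param path Situs map file path
#' @return a [density_map]
#' @export
read_situs <- function(path) {
  if (!file.exists(path)) stop("Situs file not found: ", path)
  tokens <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tokens) < 8) stop("not a Situs map (truncated header): ", path)
  spacing <- tokens[1]
  origin <- tokens[2:4]
  dims <- as.integer(tokens[5:7])
  vals <- tokens[-(1:7)]
  if (any(dims < 1) || spacing <= 0) stop("invalid Situs header in ", path)
  if (length(vals) != prod(dims)) {
    stop("Situs value count (", length(vals), ") does not match dimensions ",
         paste(dims, collapse = "x"), " in ", path)
  }
  density_map(array(vals, dims), spacing, origin)
}

#' Write a density map in Situs ASCII format
#'
#' Values are written with 6 significant digits, 10 per line, x fastest.
#'
#' @param map a [density_map]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_situs <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(format(map$spacing, digits = 6),
                     format(map$origin, digits = 6), d), collapse = " "), con)
  vals <- sprintf("%.6g", as.vector(map$values))
  starts <- seq(1, length(vals), by = 10)
  lines <- vapply(starts, function(s) {
    paste(vals[s:min(s + 9, length(vals))], collapse = " ")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
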