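#' Volumetric grid I/O (OpenDX, Gaussian cube)
#'
#' Writers for regular grids in the two formats molecular viewers expect.
#' OpenDX headers record the origin and per-axis delta in Angstrom; values
#' are emitted three per line with the last index (z) varying fastest, the
#' standard ordering both formats share. The cube writer converts lengths
#' to Bohr as the format requires (1 Angstrom = 1.889726125 Bohr).
#'
#' @name volio
NULL

BOHR_PER_ANGSTROM <- 1.889726125

#' Write a grid in OpenDX format
#'
#' @param grid a [density_grid()] (or [evaluate_lattice()] output).
#' @param path file path.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n <- length(vals)
  body <- vapply(seq_len(ceiling(n / 3)), function(i) {
    idx <- ((i - 1) * 3 + 1):min(i * 3, n)
    paste(sprintf("%.6e", vals[idx]), collapse = " ")
  }, character(1))
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n),
    body,
    'attribute "dep" string "positions"',
    'object "density" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3')
  writeLines(lines, path)
  invisible(path)
}

#' Read an OpenDX regular grid
#'
#' Counterpart of [write_dx()]; assumes axis-aligned deltas.
#'
#' @param path file path.
#' @return a [density_grid()] (state "loaded").
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("parse error: no gridpositions object in ", path)
  d <- as.integer(strsplit(sub(".*counts +", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("^origin", "",
         grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- lapply(grep("^delta", lines, value = TRUE)[1:3], function(s)
    as.numeric(strsplit(trimws(sub("^delta", "", s)), "\\s+")[[1]]))
  spacing <- deltas[[1]][1]
  istart <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > istart], length(lines) + 1L)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(istart + 1):(iend - 1)]), "\\s+")))
  vals <- vals[is.finite(vals)]
  if (length(vals) != prod(d)) stop("parse error: value count mismatch")
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  density_grid(org, spacing, d, arr, state = "loaded")
}

#' Write a grid in Gaussian cube format
#'
#' Lengths are converted to Bohr. If no molecule is supplied a single
#' placeholder carbon at the grid origin is written, since many readers
#' reject zero-atom cubes.
#'
#' @param grid a [density_grid()].
#' @param path file path.
#' @param mol optional [molecule()] whose atoms head the cube.
#' @export
write_cube <- function(grid, path, mol = NULL) {
  b <- BOHR_PER_ANGSTROM
  d <- grid$dims
  at_n <- if (is.null(mol)) 1L else n_atoms(mol)
  z_of <- function(el) {
    z <- match(toupper(el), toupper(c("H", "HE", "LI", "BE", "B", "C", "N",
                                      "O", "F", "NE", "NA", "MG", "AL", "SI",
                                      "P", "S", "CL")))
    z[is.na(z)] <- 6L
    z
  }
  atom_lines <- if (is.null(mol)) {
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 6L, 0,
            grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b)
  } else {
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z_of(mol$elements), 0,
            mol$coords[, 1] * b, mol$coords[, 2] * b, mol$coords[, 3] * b)
  }
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  body <- vapply(seq_len(ceiling(length(vals) / 6)), function(i) {
    idx <- ((i - 1) * 6 + 1):min(i * 6, length(vals))
    paste(sprintf("%13.5e", vals[idx]), collapse = " ")
  }, character(1))
  lines <- c(
    "mifkit volumetric grid",
    "values on a regular lattice (lengths in Bohr)",
    sprintf("%5d %11.6f %11.6f %11.6f", at_n,
            grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b),
    sprintf("%5d %11.6f %11.6f %11.6f", d[1], grid$spacing * b, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, grid$spacing * b, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, grid$spacing * b),
    atom_lines,
    body)
  writeLines(lines, path)
  invisible(path)
}
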