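#' Construct a molecule
#'
#' A minimal molecular container: element symbols, Cartesian coordinates in
#' Angstrom, optional ring-atom index sets, and per-ring aromatic flags.
#' Atoms are indexed 1..n in the order given (file readers preserve file
#' order, so 1-based file indices map directly onto atom indices).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of positions (Angstrom).
#' @param rings optional list of integer vectors, each a ring-atom index set.
#' @param aromatic optional logical vector, one flag per ring in `rings`.
#' @return an object of class `mif_molecule`.
#' @export
molecule <- function(elements, coords, rings = list(), aromatic = logical(0)) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  if (length(elements) != nrow(coords))
    stop("elements and coords disagree on atom count")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates")
  rings <- lapply(rings, as.integer)
  for (r in rings) {
    if (any(r < 1L | r > nrow(coords)))
      stop("ring index out of range")
  }
  if (length(aromatic) == 0L) aromatic <- rep(TRUE, length(rings))
  if (length(aromatic) != length(rings))
    stop("one aromatic flag per ring required")
  structure(
    list(elements = as.character(elements), coords = coords,
         rings = rings, aromatic = as.logical(aromatic)),
    class = "mif_molecule")
}

#' @export
print.mif_molecule <- function(x, ...) {
  cat(sprintf("<mif_molecule> %d atoms (%s), %d ring set(s)\n",
              nrow(x$coords), paste(unique(x$elements), collapse = ","),
              length(x$rings)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$coords)

is_heavy <- function(element) toupper(element) != "H"

#' Read an XYZ file
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` records.
#'
#' @param path file path.
#' @param rings,aromatic optional ring annotation passed to [molecule()].
#' @return a `mif_molecule`.
#' @export
read_xyz <- function(path, rings = list(), aromatic = logical(0)) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ header is not an atom count: ", path)
  if (length(lines) < 2 + n) stop("XYZ file shorter than declared atom count")
  rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(rec, `[[`, "", 1L)
  xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("malformed coordinate record in ", path)
  molecule(el, xyz, rings = rings, aromatic = aromatic)
}

#' Write an XYZ file
#' @param mol a `mif_molecule`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "written by mifkit") {
  lines <- c(as.character(n_atoms(mol)), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f",
                     mol$elements, mol$coords[, 1], mol$coords[, 2],
                     mol$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read the coordinate block of a V2000 SDF/MOL file
#'
#' Parses elements and coordinates only (counts line + atom block); bonds,
#' properties and charges are ignored.
#'
#' @inheritParams read_xyz
#' @return a `mif_molecule`.
#' @export
read_sdf <- function(path, rings = list(), aromatic = logical(0)) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("truncated SDF file: ", path)
  counts <- lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(n))  # some writers use whitespace-delimited counts
    n <- suppressWarnings(as.integer(strsplit(trimws(counts), "\\s+")[[1]][1]))
  if (is.na(n) || n < 1) stop("cannot parse V2000 counts line in ", path)
  if (length(lines) < 4 + n) stop("SDF atom block shorter than counts line")
  blk <- lines[5:(4 + n)]
  fields <- strsplit(trimws(blk), "\\s+")
  xyz <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  el <- vapply(fields, `[[`, "", 4L)
  if (any(!is.finite(xyz))) stop("malformed SDF atom record in ", path)
  molecule(el, xyz, rings = rings, aromatic = aromatic)
}
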