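#' Contact-density maps
#'
#' Fragment scatter clouds (contact-atom positions around a central
#' substructure, expressed in its molecular frame) are binned onto a
#' regular grid, optionally expanded by the substructure's point symmetry,
#' smoothed by averaging each node with its 26 neighbours, and reported as
#' percent of the maximum density with iso-level masks (75/50/25 for
#' database-style maps, 80/50 for comparison maps).
#'
#' @name densmap
NULL

#' Construct a fragment scatter
#'
#' @param positions n x 3 matrix of contact-atom positions (Angstrom,
#'   molecular frame).
#' @param source per-point structure identifier (recycled).
#' @param role which contact atom the positions refer to: densities differ
#'   by selected atom, so the role is always recorded, never inferred.
#' @return data.frame of class `fragment_scatter` with columns u, v, w,
#'   source; role in `attr(, "role")`.
#' @export
fragment_scatter <- function(positions,
                             source = "synthetic",
                             role = c("donor_carbon", "donor_hydrogen")) {
  role <- match.arg(role)
  P <- if (length(positions) == 0) matrix(numeric(0), 0, 3)
       else as.matrix(positions)
  if (ncol(P) != 3) stop("positions must be n x 3")
  if (nrow(P) > 0 && !all(is.finite(P))) stop("non-finite scatter positions")
  out <- data.frame(u = P[, 1], v = P[, 2], w = P[, 3],
                    source = rep_len(as.character(source), nrow(P)))
  attr(out, "role") <- role
  class(out) <- c("fragment_scatter", "data.frame")
  out
}

scatter_coords <- function(scatter) unname(as.matrix(scatter[, c("u", "v", "w")]))

#' Select contact atoms around a central substructure
#'
#' Returns the positions of atoms matching `selection_spec` that lie
#' within `range_cutoff` of any central-substructure atom. The structure
#' must already be aligned into the reference molecular frame.
#'
#' @param structure data.frame with columns `element`, `resname`, `name`
#'   (atom name), `u`, `v`, `w`, and optionally `source`.
#' @param central_atoms matrix of central-substructure positions (frame
#'   coordinates).
#' @param selection_spec list with optional `resnames` (character),
#'   optional `atom_pattern` (regex on atom names), optional `elements`,
#'   and `role` ("donor_carbon" or "donor_hydrogen").
#' @param range_cutoff contact search range (Angstrom), default 7.
#' @return a [fragment_scatter()].
#' @export
select_contact_atoms <- function(structure, central_atoms, selection_spec,
                                 range_cutoff = 7) {
  central_atoms <- as.matrix(central_atoms)
  if (nrow(central_atoms) == 0) stop("empty central substructure")
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(selection_spec$resnames))
    keep <- keep & structure$resname %in% selection_spec$resnames
  if (!is.null(selection_spec$elements))
    keep <- keep & toupper(structure$element) %in%
      toupper(selection_spec$elements)
  if (!is.null(selection_spec$atom_pattern))
    keep <- keep & grepl(selection_spec$atom_pattern, structure$name)
  cand <- structure[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(fragment_scatter(matrix(numeric(0), 0, 3),
                            role = selection_spec$role %||% "donor_carbon"))
  P <- as.matrix(cand[, c("u", "v", "w")])
  d2min <- apply(P, 1, function(p)
    min(rowSums(sweep(central_atoms, 2, p)^2)))
  inrange <- d2min <= range_cutoff^2
  fragment_scatter(P[inrange, , drop = FALSE],
                   source = if ("source" %in% names(cand))
                     cand$source[inrange] else "structure",
                   role = selection_spec$role %||% "donor_carbon")
}

#' Expand a scatter by point-symmetry operations
#'
#' Applies each operation (3 x 3 orthogonal matrix in the molecular frame)
#' to every point; supply the identity among `ops` to keep the original
#' points. Output size is |ops| * |points|.
#'
#' @param scatter a [fragment_scatter()].
#' @param ops list of 3 x 3 orthogonal matrices (det +1 or -1).
#' @return the expanded `fragment_scatter`.
#' @export
expand_symmetry <- function(scatter, ops) {
  for (M in ops) {
    if (max(abs(M %*% t(M) - diag(3))) > 1e-10)
      stop("symmetry operation is not orthogonal")
  }
  P <- scatter_coords(scatter)
  out <- do.call(rbind, lapply(ops, function(M) P %*% t(M)))
  fragment_scatter(out, source = rep(scatter$source, length(ops)),
                   role = attr(scatter, "role"))
}

#' Construct a density grid
#'
#' @param origin position of the first node / voxel corner (Angstrom).
#' @param spacing node spacing (Angstrom).
#' @param dims integer node counts per axis.
#' @param values array of dimension `dims`.
#' @param state one of "counts", "smoothed", "percent-of-max",
#'   "function-values".
#' @return object of class `density_grid`.
#' @export
density_grid <- function(origin, spacing, dims, values, state = "counts") {
  stopifnot(length(origin) == 3, length(dims) == 3,
            all(dim(values) == dims), spacing > 0)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims), values = values, state = state),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d @ %.2f A, state=%s, max=%.4g\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$state,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Bin scatter points into voxel counts
#'
#' Origin-anchored, half-open voxels \[edge, edge + spacing): each point
#' increments exactly one voxel, and a point exactly on a boundary goes to
#' the higher-index voxel. Points outside the extent are dropped with a
#' warning.
#'
#' @param scatter a [fragment_scatter()].
#' @param spacing voxel size (Angstrom); 0.5 for database-style maps, 0.4
#'   for comparison maps.
#' @param extent half-width of the cubic extent centred on the origin;
#'   NULL grows it to cover the scatter.
#' @return a `density_grid` in state "counts".
#' @export
bin_density <- function(scatter, spacing, extent = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  P <- scatter_coords(scatter)
  if (is.null(extent)) {
    extent <- if (nrow(P) == 0) spacing
              else max(abs(P)) + spacing
  }
  nvox <- max(1L, as.integer(ceiling(2 * extent / spacing - 1e-9)))
  origin <- rep(-extent, 3)
  vals <- array(0, dim = rep(nvox, 3))
  if (nrow(P) > 0) {
    idx <- floor(sweep(P, 2, origin) / spacing) + 1L
    inside <- rowSums(idx >= 1L & idx <= nvox) == 3L
    if (any(!inside))
      warning(sum(!inside), " point(s) outside the grid extent dropped")
    idx <- idx[inside, , drop = FALSE]
    if (nrow(idx) > 0) {
      lin <- (idx[, 3] - 1L) * nvox^2 + (idx[, 2] - 1L) * nvox + idx[, 1]
      tab <- table(lin)
      vals[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  density_grid(origin, spacing, rep(nvox, 3), vals, state = "counts")
}

#' 27-point box smoothing
#'
#' Each node becomes the mean of itself and its (up to) 26 adjacent
#' nodes. Boundary nodes average over the neighbours that exist;
#' `pad_zero = TRUE` instead treats missing neighbours as zeros (divide by
#' 27 everywhere).
#'
#' @param grid a `density_grid`.
#' @param pad_zero boundary handling flag.
#' @return the smoothed `density_grid`.
#' @export
smooth27 <- function(grid, pad_zero = FALSE) {
  d <- grid$dims
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    acc[sx - dx, sy - dy, sz - dz] <-
      acc[sx - dx, sy - dy, sz - dz] + grid$values[sx, sy, sz]
    cnt[sx - dx, sy - dy, sz - dz] <- cnt[sx - dx, sy - dy, sz - dz] + 1
  }
  vals <- if (pad_zero) acc / 27 else acc / cnt
  density_grid(grid$origin, grid$spacing, d, vals, state = "smoothed")
}

#' Percent-of-max normalization and iso-level masks
#'
#' Scales the grid so its maximum is 100 (an all-zero grid stays zero).
#' `iso_mask` returns the logical mask of nodes at or above a percent
#' threshold.
#'
#' @param grid a `density_grid`.
#' @return the rescaled `density_grid` (state "percent-of-max").
#' @export
percent_of_max <- function(grid) {
  mx <- if (length(grid$values)) max(grid$values) else 0
  vals <- if (mx > 0) grid$values * (100 / mx) else grid$values
  density_grid(grid$origin, grid$spacing, grid$dims, vals,
               state = "percent-of-max")
}

#' @rdname percent_of_max
#' @param threshold percent-of-max level, e.g. 75, 50, 25 (database-style)
#'   or 80, 50 (comparison-style).
#' @export
iso_mask <- function(grid, threshold) {
  if (grid$state != "percent-of-max") grid <- percent_of_max(grid)
  grid$values >= threshold
}

#' Seeded structure subsampling
#'
#' Uniformly samples `n` entries (for example structure identifiers) with
#' a fixed seed, recording the seed in the result's attributes.
#'
#' @param x vector to sample from.
#' @param n sample size (capped at `length(x)`).
#' @param seed RNG seed.
#' @export
subsample_structures <- function(x, n = 500, seed = 1L) {
  n <- min(n, length(x))
  out <- with_local_seed(seed, sample(x, n))
  attr(out, "seed") <- seed
  out
}

# run expr under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Read a TRIPOS MOL2 scatter file
#'
#' Parses coordinates (and atom names) from the @<TRIPOS>ATOM section
#' only. Malformed records raise a parse error naming the line.
#'
#' @param path file path.
#' @param role recorded contact-atom role.
#' @return a [fragment_scatter()].
#' @export
read_scatter_mol2 <- function(path, role = "donor_carbon") {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^@<TRIPOS>ATOM", lines)
  if (length(start) == 0) {
    warning("no @<TRIPOS>ATOM section in ", path, "; empty scatter")
    return(fragment_scatter(matrix(numeric(0), 0, 3), role = role))
  }
  i <- start[1] + 1L
  pos <- list()
  while (i <= length(lines) && !grepl("^@<TRIPOS>", lines[i])) {
    ln <- trimws(lines[i])
    if (nzchar(ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 5)
        stop("parse error at line ", i, " of ", path, ": too few fields")
      xyz <- suppressWarnings(as.numeric(f[3:5]))
      if (any(!is.finite(xyz)))
        stop("parse error at line ", i, " of ", path,
             ": non-numeric coordinates")
      pos[[length(pos) + 1L]] <- xyz
    }
    i <- i + 1L
  }
  if (length(pos) == 0) {
    warning("empty @<TRIPOS>ATOM section in ", path)
    return(fragment_scatter(matrix(numeric(0), 0, 3), role = role))
  }
  fragment_scatter(do.call(rbind, pos), source = basename(path), role = role)
}

#' Write a scatter as TRIPOS MOL2
#'
#' Positions become dummy carbon atom records, so the file round-trips
#' through [read_scatter_mol2()] and external viewers.
#'
#' @param scatter a [fragment_scatter()].
#' @param path file path.
#' @export
write_scatter_mol2 <- function(scatter, path) {
  P <- scatter_coords(scatter)
  n <- nrow(P)
  lines <- c("@<TRIPOS>MOLECULE", "mifkit scatter",
             sprintf("%d 0 0 0 0", n), "SMALL", "NO_CHARGES", "",
             "@<TRIPOS>ATOM",
             if (n > 0)
               sprintf("%7d C%-6d %10.4f %10.4f %10.4f C.3     1  FRAG1",
                       seq_len(n), seq_len(n), P[, 1], P[, 2], P[, 3]))
  writeLines(lines, path)
  invisible(path)
}
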