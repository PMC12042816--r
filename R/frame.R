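#' Molecular coordinate frames (o-uvw)
#'
#' The frame places its origin at the centroid of a ring-atom set, the w axis
#' along the least-squares normal of the ring plane, the u axis from the
#' origin toward a designated heavy atom (projected into the ring plane), and
#' v = w x u so that (u, v, w) is right-handed. The rotation matrix has rows
#' u, v, w and maps lab-frame displacements to (u, v, w) components.
#'
#' @name molecular_frame
NULL

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a near-zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_frame <- function(origin, u, v, w) {
  rot <- rbind(u = u, v = v, w = w)
  colnames(rot) <- c("x", "y", "z")
  f <- structure(list(origin = as.numeric(origin), u = u, v = v, w = w,
                      rotation = rot),
                 class = "molecular_frame")
  validate_frame(f)
  f
}

validate_frame <- function(frame) {
  R <- frame$rotation
  if (max(abs(R %*% t(R) - diag(3))) > 1e-10)
    stop("frame rotation is not orthonormal")
  if (max(abs(cross3(frame$u, frame$v) - frame$w)) > 1e-10)
    stop("frame is not right-handed")
  invisible(frame)
}

#' Build a molecular frame on a ring
#'
#' Origin at the ring-atom centroid; w along the least-squares plane normal
#' (its sign fixed so the normal's largest-magnitude component is positive,
#' making the output deterministic); u toward `u_atom`, projected into the
#' plane orthogonal to w; v = w x u.
#'
#' @param mol a [molecule()].
#' @param ring_atoms integer indices of the ring atoms (>= 3, non-collinear).
#' @param u_atom index of the heavy atom the u axis points toward.
#' @return a `molecular_frame`.
#' @export
build_frame <- function(mol, ring_atoms, u_atom) {
  ring_atoms <- as.integer(ring_atoms)
  if (length(ring_atoms) < 3) stop("need at least 3 ring atoms")
  P <- mol$coords[ring_atoms, , drop = FALSE]
  origin <- colMeans(P)
  C <- sweep(P, 2, origin)
  sv <- svd(C)
  # collinear ring atoms have (at most) one non-trivial singular value
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-8))
    stop("degenerate ring plane: ring atoms are collinear")
  w <- sv$v[, 3]
  imax <- which.max(abs(w))
  if (w[imax] < 0) w <- -w
  if (!is_heavy(mol$elements[u_atom]))
    stop("u_atom must be a heavy atom")
  d <- mol$coords[u_atom, ] - origin
  d_in_plane <- d - sum(d * w) * w
  if (sqrt(sum(d_in_plane^2)) < 1e-8)
    stop("undefined u axis: u_atom coincides with the origin (or lies on w)")
  u <- unit(d_in_plane)
  v <- cross3(w, u)
  new_frame(origin, u, v, w)
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat("<molecular_frame>\n origin:", sprintf("%.4f", x$origin), "\n")
  cat(" u:", sprintf("%+.4f", x$u), "  v:", sprintf("%+.4f", x$v),
      "  w:", sprintf("%+.4f", x$w), "\n")
  invisible(x)
}

#' Transform lab coordinates into frame coordinates and back
#'
#' `to_frame` maps lab positions to (u, v, w) components relative to the
#' frame origin; `from_frame` is its exact inverse.
#'
#' @param frame a `molecular_frame`.
#' @param points numeric vector of length 3 or an n x 3 matrix.
#' @return coordinates of matching shape.
#' @export
to_frame <- function(frame, points) {
  validate_frame(frame)
  single <- is.null(dim(points))
  P <- if (single) matrix(points, 1) else as.matrix(points)
  out <- sweep(P, 2, frame$origin) %*% t(frame$rotation)
  colnames(out) <- c("u", "v", "w")
  if (single) drop(out) else out
}

#' @rdname to_frame
#' @export
from_frame <- function(frame, points) {
  validate_frame(frame)
  single <- is.null(dim(points))
  P <- if (single) matrix(points, 1) else as.matrix(points)
  out <- sweep(P %*% frame$rotation, 2, frame$origin, `+`)
  colnames(out) <- c("x", "y", "z")
  if (single) drop(out) else out
}

# jsonlite may hand back a row-list or an already-simplified matrix
rotation_rows <- function(x) {
  if (is.matrix(x)) return(unname(x))
  do.call(rbind, lapply(x, as.numeric))
}

#' Serialize / restore a frame as JSON
#' @param frame a `molecular_frame`.
#' @param path file path.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(
    list(origin = frame$origin,
         rotation = lapply(seq_len(3), function(i) frame$rotation[i, ])),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_frame_json
#' @export
read_frame_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- rotation_rows(x$rotation)
  new_frame(as.numeric(x$origin), R[1, ], R[2, ], R[3, ])
}
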