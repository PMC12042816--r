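#' Protein/ligand complex mapping
#'
#' A fitted field lives in the molecular frame of its reference molecule.
#' To project it into a crystal structure, the ligand substructure is
#' superposed onto the reference (Kabsch least-squares, rotations only),
#' giving a rigid transform from laboratory coordinates into the frame;
#' lattice nodes and protein-atom positions are transformed and evaluated
#' under the fitted function, and residues inside interaction-formable
#' areas (values at or above 0.8/0.6/0.4 by default) are reported.
#'
#' @name complexmap
NULL

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R (det = +1, reflections never returned) and
#' translation t minimizing ||R x_mobile + t - x_reference||^2.
#'
#' @param mobile,reference matching n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @return list with `rotation`, `translation`, `rmsd`; apply with
#'   [apply_transform()].
#' @export
superpose <- function(mobile, reference) {
  X <- as.matrix(mobile); Y <- as.matrix(reference)
  if (nrow(X) != nrow(Y)) stop("point sets differ in size")
  if (nrow(X) < 3) stop("need at least 3 corresponding points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))              # H = Xc' Yc ; R = V S U'
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-10))
    stop("degenerate point set: collinear or coincident points")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t_vec <- cy - drop(R %*% cx)
  fitted <- sweep(Xc %*% t(R), 2, cy, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform
#' @param transform a [superpose()] result.
#' @param points length-3 vector or n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  P <- if (single) matrix(points, 1) else as.matrix(points)
  out <- sweep(P %*% t(transform$rotation), 2, transform$translation, `+`)
  if (single) drop(out) else out
}

#' Build a complex scene
#'
#' Pairs `lig_idx` ligand atoms with `ref_idx` atoms of the reference
#' molecule (a bijection on >= 3 non-collinear atoms), superposes the
#' ligand substructure onto the reference expressed in its own molecular
#' frame, and stores the resulting lab-to-frame transform.
#'
#' @param protein data.frame of protein atoms with columns `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`.
#' @param ligand data.frame of ligand atoms (same coordinate columns).
#' @param lig_idx,ref_idx matching atom indices in `ligand` and in the
#'   reference molecule.
#' @param ref_mol the reference [molecule()].
#' @param ref_frame its [build_frame()] frame.
#' @return object of class `complex_scene` with the transform (lab ->
#'   frame) and superposition RMSD.
#' @export
complex_scene <- function(protein, ligand, lig_idx, ref_idx, ref_mol,
                          ref_frame) {
  lig_idx <- as.integer(lig_idx); ref_idx <- as.integer(ref_idx)
  if (length(lig_idx) != length(ref_idx) || anyDuplicated(lig_idx) ||
      anyDuplicated(ref_idx))
    stop("correspondence must be a bijection")
  if (length(lig_idx) < 3) stop("need >= 3 corresponding atoms")
  mob <- as.matrix(ligand[lig_idx, c("x", "y", "z")])
  ref_lab <- ref_mol$coords[ref_idx, , drop = FALSE]
  ref_uvw <- to_frame(ref_frame, ref_lab)
  tr <- superpose(mob, ref_uvw)
  structure(list(protein = protein, ligand = ligand,
                 lig_idx = lig_idx, ref_idx = ref_idx,
                 transform = tr, rmsd = tr$rmsd,
                 lig_centroid = colMeans(as.matrix(
                   ligand[lig_idx, c("x", "y", "z")]))),
            class = "complex_scene")
}

#' @export
print.complex_scene <- function(x, ...) {
  cat(sprintf("<complex_scene> %d protein atoms, %d ligand atoms, substructure RMSD %.3g A\n",
              nrow(x$protein), nrow(x$ligand), x$rmsd))
  invisible(x)
}

#' Read a protein/ligand complex from PDB
#'
#' Standard-column PDB reading (via bio3d) with the first-altloc rule;
#' HETATM records of `ligand_resname` become the ligand, everything else
#' with standard protein residues stays protein.
#'
#' @param path PDB file path.
#' @param ligand_resname 3-letter residue name of the ligand.
#' @return list with `protein` and `ligand` data.frames as needed by
#'   [complex_scene()].
#' @export
read_complex_pdb <- function(path, ligand_resname) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$alt %in% c("", "A", NA), , drop = FALSE]   # first conformer
  el <- at$elesy
  missing_el <- is.na(el) | el == ""
  el[missing_el] <- substr(trimws(at$elety[missing_el]), 1, 1)
  df <- data.frame(element = trimws(el), name = trimws(at$elety),
                   resname = trimws(at$resid), resno = at$resno,
                   chain = at$chain, x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  is_lig <- df$resname == ligand_resname
  list(protein = df[!is_lig & at$type == "ATOM", , drop = FALSE],
       ligand = df[is_lig, , drop = FALSE])
}

#' Project a fitted field into a complex
#'
#' A cubic lab-frame lattice centred on the ligand-substructure centroid
#' (an even node count cannot be exactly origin-symmetric with inclusive
#' endpoints; nodes sit at centroid + (i - (n-1)/2) * spacing). Each node
#' is transformed to (u, v, w) and evaluated under `fn`. The standard
#' 200-per-axis, 0.1-A lattice requests 8,000,000 evaluations.
#'
#' @param fn an `approx_function`.
#' @param scene a [complex_scene()].
#' @param spacing lattice spacing (Angstrom), default 0.1.
#' @param nodes_per_axis nodes per axis, default 200.
#' @param clamp,chunk passed to [evaluate_function()].
#' @return a [density_grid()] in laboratory coordinates.
#' @export
map_function <- function(fn, scene, spacing = 0.1, nodes_per_axis = 200,
                         clamp = FALSE, chunk = 20000L) {
  if (is.null(scene$transform)) stop("scene has no lab-to-frame transform")
  if (spacing <= 0) stop("spacing must be positive")
  n <- as.integer(nodes_per_axis)
  off <- (seq_len(n) - 1 - (n - 1) / 2) * spacing
  ctr <- scene$lig_centroid
  lab <- as.matrix(expand.grid(x = ctr[1] + off, y = ctr[2] + off,
                               z = ctr[3] + off, KEEP.OUT.ATTRS = FALSE))
  uvw <- apply_transform(scene$transform, lab)
  vals <- evaluate_function(fn, uvw, clamp = clamp, chunk = chunk)
  density_grid(origin = ctr - (n - 1) / 2 * spacing, spacing = spacing,
               dims = rep(n, 3), values = array(vals, rep(n, 3)),
               state = "function-values")
}

#' Report protein atoms inside interaction-formable areas
#'
#' Protein-atom positions (heavy atoms; crystal structures usually lack
#' hydrogens) are transformed into the molecular frame and evaluated under
#' `fn` directly -- never interpolated from a lattice. For each threshold
#' the atoms at or above it are listed with their residues; atoms below
#' the top threshold but at or above the lowest are annotated with their
#' value and the distance to the nearest lattice node reaching the top
#' threshold. Optionally each atom position can be extended by an
#' idealized 1.09-A C-H step toward the frame origin before evaluation.
#'
#' @param scene a [complex_scene()].
#' @param fn an `approx_function`.
#' @param thresholds decreasing normalized-field levels, default
#'   c(0.8, 0.6, 0.4).
#' @param extend_h if TRUE, evaluate at idealized hydrogen positions
#'   (heavy atom + 1.09 A toward the frame origin); off by default.
#' @param near_spacing,near_extent lattice used only for the
#'   nearest-top-area annotation.
#' @return list of class `contact_report`: `atoms` (data.frame with value
#'   and per-threshold flags), one data.frame per threshold in `hits`, and
#'   `near_misses`.
#' @export
contact_report <- function(scene, fn, thresholds = c(0.8, 0.6, 0.4),
                           extend_h = FALSE,
                           near_spacing = 0.25, near_extent = 8) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  prot <- scene$protein
  P <- as.matrix(prot[, c("x", "y", "z")])
  uvw <- apply_transform(scene$transform, P)
  if (extend_h) {
    d <- -uvw / pmax(sqrt(rowSums(uvw^2)), 1e-8)
    uvw <- uvw + 1.09 * d
  }
  vals <- evaluate_function(fn, uvw)
  atoms <- cbind(prot,
                 data.frame(value = vals, u = uvw[, 1], v = uvw[, 2],
                            w = uvw[, 3]))
  for (th in thresholds)
    atoms[[sprintf("ge_%g", th)]] <- vals >= th
  hits <- lapply(thresholds, function(th)
    atoms[vals >= th, , drop = FALSE])
  names(hits) <- sprintf("%g", thresholds)
  top <- thresholds[1]; low <- thresholds[length(thresholds)]
  nm_idx <- which(vals < top & vals >= low)
  near_misses <- atoms[nm_idx, , drop = FALSE]
  if (nrow(near_misses) > 0) {
    lat <- evaluate_lattice(fn, near_spacing, near_extent)
    ax <- seq(-near_extent, near_extent, by = near_spacing)
    hot <- which(lat$values >= top, arr.ind = TRUE)
    near_misses$dist_to_top <- if (nrow(hot) == 0) NA_real_ else {
      hotxyz <- cbind(ax[hot[, 1]], ax[hot[, 2]], ax[hot[, 3]])
      vapply(nm_idx, function(i)
        sqrt(min(rowSums(sweep(hotxyz, 2, uvw[i, ])^2))), numeric(1))
    }
  }
  structure(list(atoms = atoms, hits = hits, near_misses = near_misses,
                 thresholds = thresholds),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat("<contact_report>\n")
  for (th in names(x$hits)) {
    h <- x$hits[[th]]
    res <- unique(sprintf("%s%s", h$resname, h$resno))
    cat(sprintf("  >= %s: %d atom(s) [%s]\n", th, nrow(h),
                paste(utils::head(res, 8), collapse = ", ")))
  }
  invisible(x)
}
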