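#' Seeded synthetic fixtures
#'
#' Generators producing inputs with the structure the pipeline assumes --
#' ring molecules, fields with known generating coefficients, scatter
#' clouds with CH/pi-like lobes, and toy protein/ligand scenes -- so every
#' stage is testable without external data. All generators are seeded and
#' bit-reproducible, and every ground truth is attached to the output.
#' The default scatter lobes sit at |w| = 3.6 A, the typical CH/pi
#' optimum, so end-to-end demos resemble real contact maps qualitatively.
#'
#' @name fixtures
NULL

#' Regular planar ring molecule
#'
#' `n_ring` carbons on a circle of `radius` in the xy-plane, centroid at
#' the origin, each carrying an outward H at 1.08 A; the ring is flagged
#' aromatic (so a dummy site appears at the origin).
#'
#' @param n_ring ring size (default 6).
#' @param radius ring radius in Angstrom (1.39 matches a benzene-like
#'   C-C bond of 1.39 A for n = 6).
#' @return a [molecule()].
#' @export
toy_ring_molecule <- function(n_ring = 6, radius = 1.39) {
  ang <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  ring <- radius * cbind(cos(ang), sin(ang), 0)
  hh <- (radius + 1.08) * cbind(cos(ang), sin(ang), 0)
  molecule(c(rep("C", n_ring), rep("H", n_ring)), rbind(ring, hh),
           rings = list(seq_len(n_ring)), aromatic = TRUE)
}

#' Synthetic field with known ground truth
#'
#' Normalized values are clamp(sum c_true g(r_n) + noise, 0, 1) on the
#' supplied grid; the generating coefficients and basis ride along in
#' `ground_truth` for recovery tests.
#'
#' @param basis generating [build_basis()] terms.
#' @param coefficients true coefficients (one per term).
#' @param grid a [make_spherical_grid()] data.frame.
#' @param noise Gaussian noise s.d. added before clamping (default 0).
#' @param seed RNG seed.
#' @return a `mif_field`-shaped object with `ground_truth` attached.
#' @export
synthetic_field <- function(basis, coefficients, grid, noise = 0, seed = 1L) {
  stopifnot(length(coefficients) == nrow(basis))
  pts <- grid_coords(grid)
  clean <- drop(cgf_design(basis, pts) %*% coefficients)
  eps <- if (noise > 0) with_local_seed(seed, stats::rnorm(nrow(pts), 0, noise))
         else numeric(nrow(pts))
  vals <- pmin(pmax(clean + eps, 0), 1)
  structure(list(frame = NULL, grid = grid, raw = -vals,
                 normalized = vals, de_max = -1,
                 probe = "synthetic",
                 ground_truth = list(basis = basis,
                                     coefficients = coefficients,
                                     noise = noise, seed = seed)),
            class = "mif_field")
}

#' Synthetic fragment scatter
#'
#' Draws `n` points from a two-lobe Gaussian mixture above and below the
#' ring plane (lobe centres at w = +/- `lobe_w`, isotropic s.d.
#' `lobe_sd`), mimicking CH/pi contact clouds, then applies the supplied
#' symmetry operations.
#'
#' @param ops list of 3 x 3 symmetry matrices (identity for none).
#' @param n points to draw before expansion.
#' @param seed RNG seed.
#' @param lobe_w lobe height above/below the plane (default 3.6 A).
#' @param lobe_sd lobe spread (default 0.5 A).
#' @return a [fragment_scatter()] (expanded by `ops` when given).
#' @export
synthetic_scatter <- function(ops = list(diag(3)), n = 200, seed = 1L,
                              lobe_w = 3.6, lobe_sd = 0.5) {
  if (n == 0)
    return(fragment_scatter(matrix(numeric(0), 0, 3)))
  P <- with_local_seed(seed, {
    side <- sample(c(-1, 1), n, replace = TRUE)
    cbind(stats::rnorm(n, 0, lobe_sd), stats::rnorm(n, 0, lobe_sd),
          side * lobe_w + stats::rnorm(n, 0, lobe_sd))
  })
  sc <- fragment_scatter(P, source = "synthetic")
  if (length(ops) > 0) sc <- expand_symmetry(sc, ops)
  sc
}

#' Toy protein/ligand complex scene
#'
#' Places a ring ligand at a random rigid pose and surrounds it with a
#' spherical shell of "protein" carbon atoms (random directions at radii
#' 4-8 A from the ring centroid, in the lab frame). The generating
#' rotation and translation are attached as `ground_truth` so the
#' recovered superposition can be checked against them.
#'
#' @param seed RNG seed.
#' @param n_protein shell atom count.
#' @param ref_mol reference molecule (default [toy_ring_molecule()]).
#' @return a [complex_scene()] with `ground_truth` attached.
#' @export
toy_complex <- function(seed = 1L, n_protein = 40, ref_mol = toy_ring_molecule()) {
  ref_frame <- build_frame(ref_mol, ring_atoms = ref_mol$rings[[1]],
                           u_atom = 1L)
  gt <- with_local_seed(seed, {
    ax <- unit(stats::rnorm(3))
    list(R = rotation_about_axis(ax, stats::runif(1, 0, 2 * pi)),
         t = stats::rnorm(3, 0, 5),
         dirs = matrix(stats::rnorm(3 * n_protein), ncol = 3),
         radii = stats::runif(n_protein, 4, 8))
  })
  lig_xyz <- sweep(ref_mol$coords %*% t(gt$R), 2, gt$t, `+`)
  ligand <- data.frame(element = ref_mol$elements,
                       name = sprintf("%s%d", ref_mol$elements,
                                      seq_along(ref_mol$elements)),
                       resname = "LIG", resno = 1L, chain = "X",
                       x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3])
  ctr <- colMeans(lig_xyz[ref_mol$rings[[1]], , drop = FALSE])
  dirs <- gt$dirs / sqrt(rowSums(gt$dirs^2))
  shell <- sweep(dirs * gt$radii, 2, ctr, `+`)
  protein <- data.frame(element = "C",
                        name = sprintf("CB%d", seq_len(n_protein)),
                        resname = "ALA", resno = seq_len(n_protein),
                        chain = "A",
                        x = shell[, 1], y = shell[, 2], z = shell[, 3])
  sc <- complex_scene(protein, ligand,
                      lig_idx = seq_len(n_atoms(ref_mol)),
                      ref_idx = seq_len(n_atoms(ref_mol)),
                      ref_mol = ref_mol, ref_frame = ref_frame)
  sc$ground_truth <- list(rotation = gt$R, translation = gt$t, seed = seed,
                          ref_frame = ref_frame)
  sc
}

#' Place extra protein atoms at chosen frame positions
#'
#' Utility for constructed contact-report cases: appends carbon atoms to a
#' scene's protein at given (u, v, w) frame coordinates (converted back to
#' the lab frame through the scene's transform).
#'
#' @param scene a [complex_scene()].
#' @param uvw n x 3 matrix of frame coordinates.
#' @param resname residue label for the planted atoms.
#' @return the augmented scene.
#' @export
plant_atoms <- function(scene, uvw, resname = "PLT") {
  uvw <- if (is.null(dim(uvw))) matrix(uvw, 1) else as.matrix(uvw)
  tr <- scene$transform
  # invert lab -> frame: x = R^T (u - t)
  lab <- sweep(uvw, 2, tr$translation) %*% tr$rotation
  n0 <- nrow(scene$protein)
  add <- data.frame(element = "C",
                    name = sprintf("CP%d", seq_len(nrow(lab))),
                    resname = resname,
                    resno = n0 + seq_len(nrow(lab)), chain = "Z",
                    x = lab[, 1], y = lab[, 2], z = lab[, 3])
  scene$protein <- rbind(scene$protein, add)
  scene
}
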