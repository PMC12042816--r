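#' Probe scanning: pose generation, energy backends, field assembly
#'
#' A scan places a probe at every spherical grid point, aims its donor C-H
#' vector M at the nearest target site (real atom or aromatic ring-center
#' dummy), evaluates the dimer interaction energy through a backend
#' contract, and normalizes the resulting field to \[0, 1\] on the most
#' stable (most negative) raw energy.
#'
#' @name probescan
NULL

rotation_about_axis <- function(axis, theta) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# minimal rotation mapping unit vector a onto unit vector b; the
# antiparallel case rotates 180 deg about unit(a x e), e being the lab axis
# least aligned with a
minimal_rotation <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-14) return(diag(3))
  if (d < -1 + 1e-12) {
    e <- diag(3)[, which.min(abs(a))]
    return(rotation_about_axis(cross3(a, e), pi))
  }
  cv <- cross3(a, b)
  K <- matrix(c(0, cv[3], -cv[2], -cv[3], 0, cv[1], cv[2], -cv[1], 0), 3, 3)
  diag(3) + K + (K %*% K) / (1 + d)
}

#' Ring-center dummy sites
#'
#' One dummy per flagged aromatic ring, at the centroid of that ring's
#' atoms. Dummies are treated as equivalent to real atoms when choosing the
#' nearest target site, and are ordered after the real atoms.
#'
#' @param mol a [molecule()].
#' @return a matrix of dummy positions (0 rows if no aromatic rings).
#' @export
dummy_sites <- function(mol) {
  rings <- mol$rings[mol$aromatic]
  if (length(rings) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(rings, function(r)
    colMeans(mol$coords[r, , drop = FALSE])))
}

#' Nearest target site and aiming vector
#'
#' Finds the site (real atom or dummy) closest to `point` and returns the
#' unit vector G from the point toward it. Exact ties resolve to the
#' lowest site index (atoms before dummies).
#'
#' @param sites matrix of candidate site positions (atoms first, then
#'   dummies), e.g. `rbind(mol$coords, dummy_sites(mol))`.
#' @param point position (length-3).
#' @return list with `site` (index), `distance`, and unit vector `g`.
#' @export
nearest_site <- function(sites, point) {
  if (nrow(sites) == 0) stop("no target sites")
  d2 <- rowSums(sweep(sites, 2, point)^2)
  i <- which.min(d2)            # ties resolve to the lowest index
  dist <- sqrt(d2[i])
  if (dist < 1e-8)
    stop("degenerate direction: grid point coincides with a target site")
  list(site = i, distance = dist, g = (sites[i, ] - point) / dist)
}

#' Pose a probe at a grid point
#'
#' Translates the probe so its donor carbon sits exactly at `point`, then
#' rigidly rotates it about that carbon by the minimal rotation taking the
#' M vector onto `g`. The residual torsion about the aligned axis is fixed
#' by rotating the probe's secondary reference vector as close as possible
#' to the `up` direction (the target frame's w axis when scanning in frame
#' coordinates); linear probes skip this step.
#'
#' @param probe a [probe_geometry()].
#' @param point grid-point position.
#' @param g unit aiming vector (grid point toward nearest site).
#' @param up torsion reference direction, default the frame w axis (0,0,1).
#' @return list of class `probe_pose` with `coords`, `elements`, `g`,
#'   `rotation` (the applied 3x3 rotation) and `point`.
#' @export
orient_probe <- function(probe, point, g, up = c(0, 0, 1)) {
  ng <- sqrt(sum(g^2))
  if (abs(ng - 1) > 1e-8) stop("g must be a unit vector")
  g <- g / ng
  R <- minimal_rotation(probe$m_vector, g)
  if (!is.null(probe$secondary)) {
    s <- drop(R %*% probe$secondary)
    s_perp <- s - sum(s * g) * g
    up_perp <- up - sum(up * g) * g
    if (sqrt(sum(s_perp^2)) > 1e-8 && sqrt(sum(up_perp^2)) > 1e-8) {
      theta <- atan2(sum(cross3(s_perp, up_perp) * g), sum(s_perp * up_perp))
      R <- rotation_about_axis(g, theta) %*% R
    }
  }
  local <- sweep(probe$coords, 2, probe$coords[probe$m_origin, ])
  posed <- sweep(local %*% t(R), 2, point, `+`)
  structure(list(coords = posed, elements = probe$elements, g = g,
                 rotation = R, point = point,
                 m_rotated = drop(R %*% probe$m_vector)),
            class = "probe_pose")
}

#' Normalize raw scan energies
#'
#' Attractive points are scaled on the most stable raw energy so the field
#' spans \[0, 1\]: E_n = raw_n / min(raw) where raw_n < 0, and 0 where the
#' raw energy is non-negative or the backend failed. The normalization
#' anchor dE_max = min(raw) is returned (NA when no energy is attractive).
#'
#' @param raw numeric vector of raw energies (kcal/mol); NA marks backend
#'   failures.
#' @return list with `normalized` and `de_max`.
#' @export
normalize_field <- function(raw) {
  if (length(raw) == 0) stop("need at least one raw energy")
  ok <- is.finite(raw)
  de_max <- if (any(ok) && min(raw[ok]) < 0) min(raw[ok]) else NA_real_
  normalized <- numeric(length(raw))
  if (!is.na(de_max)) {
    att <- ok & raw < 0
    normalized[att] <- raw[att] / de_max
  }
  list(normalized = normalized, de_max = de_max)
}

#' Scan a probe over a grid
#'
#' The target is transformed into the molecular frame, ring-center dummies
#' are added, and for every grid point the probe is posed ([orient_probe()])
#' and handed to the backend together with the frame-coordinate target. A
#' backend error or non-finite return records a failure marker (normalized
#' to 0); the scan never aborts.
#'
#' @param target a [molecule()].
#' @param frame its [build_frame()] frame.
#' @param grid a [make_spherical_grid()] data.frame.
#' @param probe a [probe_geometry()].
#' @param backend an energy backend, e.g. [classical_backend()]: a function
#'   `(target_elements, target_coords, probe_elements, probe_coords) ->
#'   kcal/mol` (attractive negative) or NA on failure.
#' @param up torsion reference passed to [orient_probe()].
#' @return object of class `mif_field`: the frame, grid, `raw` and
#'   `normalized` energies, `de_max`, and the probe name.
#' @export
scan_field <- function(target, frame, grid, probe, backend, up = c(0, 0, 1)) {
  tc <- to_frame(frame, target$coords)
  dm <- dummy_sites(target)
  if (nrow(dm) > 0) dm <- to_frame(frame, dm)
  sites <- rbind(unname(tc), unname(dm))
  pts <- grid_coords(grid)
  raw <- vapply(seq_len(nrow(pts)), function(i) {
    tryCatch({
      ns <- nearest_site(sites, pts[i, ])
      pose <- orient_probe(probe, pts[i, ], ns$g, up = up)
      e <- backend(target$elements, tc, pose$elements, pose$coords)
      if (!is.finite(e)) NA_real_ else as.numeric(e)
    }, error = function(e) NA_real_)
  }, numeric(1))
  nz <- normalize_field(raw)
  structure(list(frame = frame, grid = grid, raw = raw,
                 normalized = nz$normalized, de_max = nz$de_max,
                 probe = probe$name),
            class = "mif_field")
}

#' @export
print.mif_field <- function(x, ...) {
  cat(sprintf("<mif_field> probe=%s, %d grid points, %d failures, dE_max=%s kcal/mol\n",
              x$probe, length(x$raw), sum(!is.finite(x$raw)),
              ifelse(is.na(x$de_max), "NA", sprintf("%.3f", x$de_max))))
  invisible(x)
}

#' Save / load a scanned field as JSON
#'
#' The field format stores the frame (origin + rotation rows), the grid
#' (spherical coordinates and frame positions), raw energies (failures as
#' null) and normalized energies.
#'
#' @param field a `mif_field`.
#' @param path file path.
#' @export
write_field_json <- function(field, path) {
  jsonlite::write_json(
    list(probe = field$probe,
         frame = if (is.null(field$frame)) NULL else
           list(origin = field$frame$origin,
                rotation = lapply(1:3, function(i) field$frame$rotation[i, ])),
         grid = field$grid,
         raw = field$raw,
         normalized = field$normalized,
         de_max = field$de_max),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns",
    na = "null")
  invisible(path)
}

#' @rdname write_field_json
#' @export
read_field_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- as.data.frame(x$grid)
  frame <- if (!is.null(x$frame)) {
    R <- rotation_rows(x$frame$rotation)
    new_frame(as.numeric(x$frame$origin), R[1, ], R[2, ], R[3, ])
  }
  raw <- as.numeric(x$raw)
  structure(list(frame = frame, grid = grid, raw = raw,
                 normalized = as.numeric(x$normalized),
                 de_max = if (is.null(x$de_max)) NA_real_
                          else as.numeric(x$de_max),
                 probe = x$probe),
            class = "mif_field")
}

lj_defaults <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "F", "P", "S", "CL"),
    eps = c(0.0157, 0.0860, 0.1700, 0.2100, 0.0610, 0.2000, 0.2500, 0.2650),
    sigma = c(2.500, 3.400, 3.250, 2.960, 3.118, 3.740, 3.500, 3.400))
}

#' Classical test backend (Lennard-Jones + Coulomb)
#'
#' A deterministic desk-scale energy backend for exercising the scan
#' machinery: pairwise 12-6 Lennard-Jones with Lorentz-Berthelot mixing
#' plus Coulomb terms over all intermolecular pairs, in kcal/mol. Any
#' intermolecular pair closer than 0.1 A returns a failure marker (NA),
#' mirroring the clash rule that clamps failed points to zero after
#' normalization.
#'
#' @param lj data.frame with columns element, eps (kcal/mol), sigma (A);
#'   defaults are standard transferable values.
#' @param charges named numeric vector of per-element partial charges (e);
#'   default all zero.
#' @param k_e Coulomb constant, kcal A / (mol e^2).
#' @return a backend function for [scan_field()].
#' @export
classical_backend <- function(lj = lj_defaults(), charges = NULL,
                              k_e = 332.0636) {
  eps <- stats::setNames(lj$eps, toupper(lj$element))
  sig <- stats::setNames(lj$sigma, toupper(lj$element))
  q_of <- function(el) {
    if (is.null(charges)) return(numeric(length(el)))
    q <- charges[toupper(el)]
    q[is.na(q)] <- 0
    unname(q)
  }
  function(t_el, t_xyz, p_el, p_xyz) {
    te <- toupper(t_el); pe <- toupper(p_el)
    if (!all(te %in% names(eps)) || !all(pe %in% names(eps)))
      stop("element missing from LJ parameter table")
    d2 <- outer(rowSums(t_xyz^2), rowSums(p_xyz^2), `+`) -
      2 * t_xyz %*% t(p_xyz)
    d <- sqrt(pmax(d2, 0))
    if (any(d < 0.1)) return(NA_real_)
    e_ij <- sqrt(outer(eps[te], eps[pe]))
    s_ij <- outer(sig[te], sig[pe], `+`) / 2
    sr6 <- (s_ij / d)^6
    qq <- outer(q_of(t_el), q_of(p_el))
    sum(4 * e_ij * (sr6^2 - sr6) + k_e * qq / d)
  }
}

#' Counterpoise dimer job text
#'
#' Emits a two-fragment counterpoise single-point job description in a
#' Gaussian-style template: route line (passed through verbatim, with
#' `counterpoise=2` appended), blank line, title, blank line, a
#' charge/multiplicity line for the supermolecule and both fragments, then
#' one atom line per atom as `El(Fragment=i) x y z` with coordinates to 6
#' decimals (fragment 1 = target, fragment 2 = probe). No engine is run.
#'
#' @param target a [molecule()] (fragment 1).
#' @param pose a [orient_probe()] pose or any list with `elements` and
#'   `coords` (fragment 2).
#' @param method_spec list with `route` (e.g. "M06-2X/aug-cc-pVDZ"),
#'   optional `title`, and optional `charges`/`mults` (length-3 integer
#'   vectors: supermolecule, fragment 1, fragment 2).
#' @return the job text as a single character string.
#' @export
write_cp_inputs <- function(target, pose, method_spec) {
  if (is.null(target) || n_atoms(target) == 0) stop("empty target fragment")
  if (is.null(pose) || length(pose$elements) == 0) stop("empty probe fragment")
  ch <- method_spec$charges %||% c(0L, 0L, 0L)
  mu <- method_spec$mults %||% c(1L, 1L, 1L)
  atom_line <- function(el, xyz, frag)
    sprintf("%s(Fragment=%d) %14.6f %14.6f %14.6f", el, frag,
            xyz[, 1], xyz[, 2], xyz[, 3])
  paste(c(
    sprintf("# %s counterpoise=2", method_spec$route),
    "",
    method_spec$title %||% "counterpoise single point",
    "",
    paste(ch[1], mu[1], ch[2], mu[2], ch[3], mu[3]),
    atom_line(target$elements, target$coords, 1L),
    atom_line(pose$elements, as.matrix(pose$coords), 2L),
    ""), collapse = "\n")
}

#' Three-energy counterpoise combiner
#'
#' Combines user-supplied energies E(dimer), E(fragment 1 in dimer basis),
#' E(fragment 2 in dimer basis) into the counterpoise-corrected interaction
#' energy E_int = E_dimer - E_frag1 - E_frag2. No engine output is parsed.
#'
#' @param e_dimer,e_frag1,e_frag2 energies in consistent units.
#' @return the interaction energy.
#' @export
cp_interaction_energy <- function(e_dimer, e_frag1, e_frag2) {
  e_dimer - e_frag1 - e_frag2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
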