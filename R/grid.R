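#' Specify a spherical scan grid
#'
#' Shells of grid points around the frame origin: radii from `r_min` to
#' `r_max` in steps of `r_step`, polar angle 0-180 degrees (measured from
#' +w), azimuth 0-360 degrees (from +u toward +v). Angle steps must divide
#' their ranges evenly. The default spec reproduces the standard scan
#' geometry of 2-7 Angstrom shells at 0.2 Angstrom with 10-degree angular
#' resolution (15,964 points after pole/wrap deduplication).
#'
#' @param r_min,r_max radial range (Angstrom). `r_max < r_min` gives an
#'   empty grid.
#' @param r_step radial increment (Angstrom), > 0.
#' @param polar_step,azimuth_step angular increments in degrees.
#' @return an object of class `spherical_grid_spec`.
#' @export
spherical_grid_spec <- function(r_min = 2, r_max = 7, r_step = 0.2,
                                polar_step = 10, azimuth_step = 10) {
  if (r_step <= 0) stop("r_step must be positive")
  if (polar_step <= 0 || azimuth_step <= 0) stop("angle steps must be positive")
  divides <- function(range, step) abs(range / step - round(range / step)) < 1e-9
  if (!divides(180, polar_step)) stop("polar_step must divide 180 evenly")
  if (!divides(360, azimuth_step)) stop("azimuth_step must divide 360 evenly")
  if (r_max >= r_min && !divides(r_max - r_min, r_step))
    stop("r_step must divide the radial range evenly")
  structure(list(r_min = r_min, r_max = r_max, r_step = r_step,
                 polar_step = polar_step, azimuth_step = azimuth_step),
            class = "spherical_grid_spec")
}

grid_radii <- function(spec) {
  if (spec$r_max < spec$r_min) return(numeric(0))
  spec$r_min + spec$r_step * seq(0, round((spec$r_max - spec$r_min) / spec$r_step))
}

#' Enumerate spherical grid points
#'
#' Enumerates all (radius, polar, azimuth) combinations with coincident
#' points merged: azimuth 360 is identified with 0, and the poles (polar 0
#' and 180) contribute exactly one point per radius (the azimuth = 0
#' representative). Ordering is radius-major, then polar, then azimuth.
#'
#' @param spec a [spherical_grid_spec()].
#' @return a data.frame with columns `n` (1-based point index), `radius`,
#'   `polar`, `azimuth` (degrees) and frame coordinates `u`, `v`, `w`.
#' @export
make_spherical_grid <- function(spec) {
  radii <- grid_radii(spec)
  empty <- data.frame(n = integer(0), radius = numeric(0), polar = numeric(0),
                      azimuth = numeric(0), u = numeric(0), v = numeric(0),
                      w = numeric(0))
  if (length(radii) == 0) return(empty)
  polars <- seq(0, 180, by = spec$polar_step)
  azims <- seq(0, 360 - spec$azimuth_step, by = spec$azimuth_step)
  ang <- do.call(rbind, lapply(polars, function(th) {
    if (th < 1e-12 || abs(th - 180) < 1e-12)
      cbind(polar = th, azimuth = 0)           # pole: single representative
    else
      cbind(polar = th, azimuth = azims)
  }))
  g <- data.frame(radius = rep(radii, each = nrow(ang)),
                  polar = rep(ang[, "polar"], length(radii)),
                  azimuth = rep(ang[, "azimuth"], length(radii)))
  th <- g$polar * pi / 180
  ph <- g$azimuth * pi / 180
  g$u <- g$radius * sin(th) * cos(ph)
  g$v <- g$radius * sin(th) * sin(ph)
  g$w <- g$radius * cos(th)
  g <- cbind(n = seq_len(nrow(g)), g)
  g
}

#' Closed-form grid size
#'
#' For r radii, p polar values including both poles and a azimuth values the
#' deduplicated grid has r * ((p - 2) * a + 2) points.
#'
#' @param spec a [spherical_grid_spec()].
#' @return integer point count.
#' @export
grid_point_count <- function(spec) {
  r <- length(grid_radii(spec))
  p <- length(seq(0, 180, by = spec$polar_step))
  a <- length(seq(0, 360 - spec$azimuth_step, by = spec$azimuth_step))
  as.integer(r * ((p - 2) * a + 2))
}

grid_coords <- function(grid) as.matrix(grid[, c("u", "v", "w")])
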