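#' Probe molecule geometries
#'
#' Rigid probe monomers built from standard experimental geometries:
#' methane (r_CH 1.087 A, tetrahedral), ethylene (r_CC 1.339 A, r_CH
#' 1.086 A, HCC 121.3 deg), benzene (r_CC 1.397 A, r_CH 1.084 A) and
#' acetylene (r_CC 1.203 A, r_CH 1.063 A). Each probe carries the donor
#' vector M along a chosen C-H axis with its origin at the donor carbon
#' (the choices are equivalent by molecular symmetry: methane's first C-H,
#' one in-plane C-H for ethylene and benzene, one terminal C-H for
#' acetylene), plus a secondary reference vector used to fix the residual
#' torsion about M deterministically (NULL for linear probes, where torsion
#' is immaterial).
#'
#' @param name one of "methane", "ethylene", "benzene", "acetylene".
#' @return an object of class `probe_geometry` with fields `name`,
#'   `elements`, `coords`, `m_origin` (donor-carbon index), `m_vector`
#'   (unit C-H direction) and `secondary` (torsion reference or NULL).
#' @export
probe_geometry <- function(name = c("methane", "ethylene", "benzene",
                                    "acetylene")) {
  name <- match.arg(name)
  geo <- switch(name,
    methane = {
      r <- 1.087 / sqrt(3)
      list(el = c("C", "H", "H", "H", "H"),
           xyz = rbind(c(0, 0, 0),
                       r * c(1, 1, 1), r * c(1, -1, -1),
                       r * c(-1, 1, -1), r * c(-1, -1, 1)),
           m_origin = 1L, m_to = 2L, sec_to = 3L)
    },
    ethylene = {
      a <- (180 - 121.3) * pi / 180
      h <- 1.086 * c(cos(a), sin(a), 0)
      c1 <- c(1.339 / 2, 0, 0); c2 <- c(-1.339 / 2, 0, 0)
      list(el = c("C", "C", "H", "H", "H", "H"),
           xyz = rbind(c1, c2,
                       c1 + h, c1 + h * c(1, -1, 1),
                       c2 + h * c(-1, 1, 1), c2 + h * c(-1, -1, 1)),
           m_origin = 1L, m_to = 3L, sec_to = 2L)
    },
    benzene = {
      ang <- (0:5) * pi / 3
      cc <- 1.397 * cbind(cos(ang), sin(ang), 0)
      hh <- (1.397 + 1.084) * cbind(cos(ang), sin(ang), 0)
      list(el = c(rep("C", 6), rep("H", 6)), xyz = rbind(cc, hh),
           m_origin = 1L, m_to = 7L, sec_to = 2L)
    },
    acetylene = {
      z <- 1.203 / 2
      list(el = c("C", "C", "H", "H"),
           xyz = rbind(c(0, 0, z), c(0, 0, -z),
                       c(0, 0, z + 1.063), c(0, 0, -z - 1.063)),
           m_origin = 1L, m_to = 3L, sec_to = NA_integer_)
    })
  m_vec <- unit(geo$xyz[geo$m_to, ] - geo$xyz[geo$m_origin, ])
  sec <- if (is.na(geo$sec_to)) NULL else
    geo$xyz[geo$sec_to, ] - geo$xyz[geo$m_origin, ]
  structure(list(name = name, elements = geo$el, coords = geo$xyz,
                 m_origin = geo$m_origin, m_vector = m_vec,
                 secondary = sec),
            class = "probe_geometry")
}

#' Build a custom probe
#'
#' @param elements,coords atoms of the probe.
#' @param m_origin index of the donor carbon.
#' @param m_h index of the hydrogen defining the M direction.
#' @param secondary optional torsion reference vector from the donor carbon.
#' @return a `probe_geometry`.
#' @export
custom_probe <- function(elements, coords, m_origin, m_h, secondary = NULL) {
  coords <- as.matrix(coords)
  if (toupper(elements[m_origin]) != "C")
    stop("M origin must be a carbon atom")
  m_vec <- unit(coords[m_h, ] - coords[m_origin, ])
  structure(list(name = "custom", elements = as.character(elements),
                 coords = coords, m_origin = as.integer(m_origin),
                 m_vector = m_vec, secondary = secondary),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %s: %d atoms, M from atom %d along [%s]\n",
              x$name, nrow(x$coords), x$m_origin,
              paste(sprintf("%.3f", x$m_vector), collapse = ", ")))
  invisible(x)
}
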