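#' Cartesian Gaussian contraction of interaction fields
#'
#' A scanned field is contracted into a closed-form approximation
#' E(r) = sum_i c_i g_i(r) over Cartesian Gaussian functions (CGFs)
#' g(u,v,w) = u^k v^l w^m exp(-alpha r^2), with coefficients obtained by
#' sigmoid-weighted linear least squares (normal equations A c = B). The
#' angular type letters s, p, d, f, g, h, i, j denote total order
#' k+l+m = 0..7.
#'
#' @name cgfit
NULL

cgf_type_letters <- c("s", "p", "d", "f", "g", "h", "i", "j")

#' Exponent from peak distance
#'
#' For a CGF of total order n >= 1 the optimal-direction radial profile is
#' r^n exp(-alpha r^2), which peaks at r = sqrt(n / (2 alpha)); inverting
#' gives alpha = n / (2 r_max^2) so the function's maximum sits exactly at
#' `r_max`, the intended optimal interaction distance. s-type functions
#' (n = 0) have no radial maximum; they reuse the n = 1 rule
#' alpha = 1 / (2 r_max^2) so s terms share the p-type decay scale.
#'
#' @param n total angular order (0..7).
#' @param r_max peak distance (Angstrom), > 0.
#' @return exponent alpha in Angstrom^-2.
#' @export
alpha_from_rmax <- function(n, r_max) {
  if (any(r_max <= 0)) stop("r_max must be positive")
  if (any(n < 0 | n > 7)) stop("total order must be in 0..7")
  pmax(n, 1) / (2 * r_max^2)
}

#' Default peak distances
#'
#' Five r_max values (Angstrom) bracketing typical weak-hydrogen-bond
#' optima (3.4 A for CH/N, 3.6 A for CH/pi).
#' @export
default_rmax <- function() c(2.4, 3.0, 3.6, 4.2, 4.8)

#' Enumerate a CGF basis
#'
#' Every (k, l, m) with k + l + m <= `max_order` is crossed with every
#' r_max. Ordering: total order ascending; within an order, k descending,
#' then l descending; within each (k, l, m), r_max in the order supplied.
#' With max_order 7 and five r_max values this gives the standard 600-term
#' basis (5 s, 15 p, 30 d, 50 f, 75 g, 105 h, 140 i, 180 j).
#'
#' @param max_order maximum total order (default 7, type j).
#' @param r_max_list positive, distinct peak distances.
#' @return data.frame of class `cgf_basis` with columns k, l, m, alpha,
#'   r_max, type.
#' @export
build_basis <- function(max_order = 7, r_max_list = default_rmax()) {
  if (length(r_max_list) == 0) stop("r_max_list must be non-empty")
  if (any(r_max_list <= 0)) stop("r_max values must be positive")
  if (anyDuplicated(r_max_list)) stop("duplicate r_max values")
  rows <- list()
  for (n in 0:max_order) {
    for (k in n:0) for (l in (n - k):0) {
      m <- n - k - l
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, l = l, m = m,
                   alpha = alpha_from_rmax(n, r_max_list),
                   r_max = r_max_list,
                   type = cgf_type_letters[n + 1L])
    }
  }
  basis <- do.call(rbind, rows)
  rownames(basis) <- NULL
  class(basis) <- c("cgf_basis", "data.frame")
  basis
}

#' Evaluate a single CGF
#'
#' g(u,v,w) = u^k v^l w^m exp(-alpha (u^2+v^2+w^2)).
#'
#' @param term one-row slice of a [build_basis()] basis (or a list with k,
#'   l, m, alpha).
#' @param points length-3 vector or n x 3 matrix of (u,v,w) coordinates.
#' @return numeric value(s).
#' @export
eval_cgf <- function(term, points) {
  P <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  r2 <- rowSums(P^2)
  v <- P[, 1]^term$k * P[, 2]^term$l * P[, 3]^term$m * exp(-term$alpha * r2)
  if (is.null(dim(points))) drop(v) else v
}

# design matrix: one column per basis term, chunk-size rows at a time
cgf_design <- function(basis, points) {
  P <- as.matrix(points)
  n <- nrow(P)
  r2 <- rowSums(P^2)
  maxdeg <- max(basis$k, basis$l, basis$m)
  pows <- lapply(1:3, function(ax) {
    out <- matrix(1, n, maxdeg + 1L)
    for (d in seq_len(maxdeg)) out[, d + 1L] <- out[, d] * P[, ax]
    out
  })
  alphas <- unique(basis$alpha)
  expo <- vapply(alphas, function(a) exp(-a * r2), numeric(n))
  if (n == 1) expo <- matrix(expo, 1)
  G <- matrix(0, n, nrow(basis))
  ai <- match(basis$alpha, alphas)
  for (i in seq_len(nrow(basis))) {
    G[, i] <- pows[[1]][, basis$k[i] + 1L] * pows[[2]][, basis$l[i] + 1L] *
      pows[[3]][, basis$m[i] + 1L] * expo[, ai[i]]
  }
  G
}

#' Sigmoid weighting function
#'
#' w(E) = d + (a - d) / (1 + exp(-b (E - c))): a four-parameter logistic
#' that up-weights high (near-1) normalized energies so the fit reproduces
#' the most favourable interaction regions preferentially. Defaults a = 5,
#' b = 15, c = 0.5, d = 1 give low-energy points unit weight and the best
#' points five-fold weight, switching at E = 0.5.
#'
#' @param a,b,c,d sigmoid parameters: `a` the high-E asymptote, `d` the
#'   low-E asymptote, `c` the midpoint, `b` the steepness.
#' @return function of class `weight_function` mapping E in \[0,1\] to a
#'   positive weight; parameters kept in `attr(, "params")`.
#' @export
weight_function <- function(a = 5, b = 15, c = 0.5, d = 1) {
  f <- function(e) d + (a - d) / (1 + exp(-b * (e - c)))
  if (any(f(seq(0, 1, length.out = 101)) <= 0))
    stop("configuration error: weights must be positive on [0, 1]")
  structure(f, params = c(a = a, b = b, c = c, d = d),
            class = c("weight_function", "function"))
}

pinv_solve <- function(A, B, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep])
}

#' Fit a CGF expansion to a field
#'
#' Minimizes Delta = sum_n w(E_n) (E_n - E(r_n))^2 over the expansion
#' coefficients via the weighted normal equations A c = B with
#' A_ji = sum_n w(E_n) g_j(r_n) g_i(r_n) (+ lambda on the diagonal) and
#' B_j = sum_n w(E_n) g_j(r_n) E_n, solved symmetrically with a
#' pseudo-inverse fallback on rank deficiency (relative tolerance 1e-10).
#'
#' @param field a `mif_field` from [scan_field()] or [synthetic_field()],
#'   or any list with `grid` and `normalized`.
#' @param basis a [build_basis()] basis.
#' @param weightfn a [weight_function()]; NULL means uniform weights.
#' @param lambda optional ridge penalty (default 0) for the ill-conditioned
#'   large-basis case.
#' @return list of class `approx_function` with `basis`, `coefficients`
#'   and `provenance`, plus a `report` (class `fit_report`) holding the
#'   objective `delta`, matrices `A` and `B`, `r2` against the source
#'   field, and the condition diagnostic `rank`/`cond`.
#' @export
fit_cgf <- function(field, basis, weightfn = weight_function(), lambda = 0) {
  E <- field$normalized
  if (any(!is.finite(E))) stop("non-finite field values")
  pts <- grid_coords(field$grid)
  if (nrow(pts) < nrow(basis))
    warning("fewer grid points than basis terms; fit is underdetermined")
  w <- if (is.null(weightfn)) rep(1, length(E)) else weightfn(E)
  if (all(w == 0)) stop("all-zero weights")
  G <- cgf_design(basis, pts)
  A <- crossprod(G, w * G)
  A <- (A + t(A)) / 2
  B <- drop(crossprod(G, w * E))
  Areg <- A + diag(lambda, nrow(A))
  coef <- tryCatch(drop(solve(Areg, B)),
                   error = function(e) drop(pinv_solve(Areg, B)))
  fitted <- drop(G %*% coef)
  delta <- sum(w * (E - fitted)^2)
  r2 <- if (stats::sd(E) == 0 || stats::sd(fitted) == 0) NA_real_
        else stats::cor(E, fitted)^2
  sv <- svd(Areg, nu = 0, nv = 0)$d
  report <- structure(
    list(delta = delta, A = A, B = B, r2 = r2,
         rank = sum(sv > 1e-10 * sv[1]), cond = sv[1] / sv[length(sv)],
         weights_params = if (is.null(weightfn)) NULL
                          else attr(weightfn, "params"),
         lambda = lambda),
    class = "fit_report")
  structure(list(basis = basis, coefficients = coef,
                 provenance = list(
                   probe = field$probe %||% NA_character_,
                   n_points = nrow(pts), lambda = lambda,
                   weights_params = report$weights_params),
                 report = report),
            class = "approx_function")
}

#' @export
print.approx_function <- function(x, ...) {
  cat(sprintf("<approx_function> %d CGF terms; fit r2 = %s, Delta = %s\n",
              nrow(x$basis),
              if (is.null(x$report)) "?" else sprintf("%.4f", x$report$r2),
              if (is.null(x$report)) "?" else sprintf("%.3g", x$report$delta)))
  invisible(x)
}

#' Evaluate a fitted expansion
#'
#' E(r) = sum_i c_i g_i(r), evaluated in chunks so large lattices stay
#' within memory. Values are raw by default; `clamp = TRUE` gives the
#' display view clipped to \[0, 1\].
#'
#' @param fn an `approx_function`.
#' @param points length-3 vector or n x 3 matrix of (u,v,w) coordinates.
#' @param clamp clip values to \[0, 1\] for display.
#' @param chunk rows per evaluation block.
#' @return numeric value(s).
#' @export
evaluate_function <- function(fn, points, clamp = FALSE, chunk = 20000L) {
  single <- is.null(dim(points))
  P <- if (single) matrix(points, 1) else as.matrix(points)
  n <- nrow(P)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e] <- cgf_design(fn$basis, P[s:e, , drop = FALSE]) %*% fn$coefficients
  }
  if (clamp) out <- pmin(pmax(out, 0), 1)
  if (single) drop(out) else out
}

#' Evaluate on a cubic lattice
#'
#' A lattice centred on the frame origin with inclusive endpoints:
#' 2 (half_extent / spacing) + 1 nodes per axis (0.1 A spacing with 8 A
#' half-extent gives the standard 161 x 161 x 161 = 4,173,281 nodes).
#'
#' @param fn an `approx_function`.
#' @param spacing node spacing (Angstrom), > 0.
#' @param half_extent half-width of the cube (Angstrom); must be an
#'   integer multiple of `spacing`.
#' @param clamp,chunk passed to [evaluate_function()].
#' @return a [density_grid()]-shaped object whose values are the raw
#'   (or clamped) function values.
#' @export
evaluate_lattice <- function(fn, spacing, half_extent, clamp = FALSE,
                             chunk = 20000L) {
  dims <- lattice_dims(spacing, half_extent)
  ax <- seq(-half_extent, half_extent, by = spacing)
  pts <- as.matrix(expand.grid(u = ax, v = ax, w = ax,
                               KEEP.OUT.ATTRS = FALSE))
  vals <- evaluate_function(fn, pts, clamp = clamp, chunk = chunk)
  density_grid(origin = rep(-half_extent, 3), spacing = spacing,
               dims = rep(dims, 3),
               values = array(vals, dim = rep(dims, 3)),
               state = "function-values")
}

#' Lattice node arithmetic
#' @param spacing,half_extent as in [evaluate_lattice()].
#' @return nodes per axis.
#' @export
lattice_dims <- function(spacing, half_extent) {
  if (spacing <= 0) stop("spacing must be positive")
  k <- half_extent / spacing
  if (abs(k - round(k)) > 1e-9)
    stop("half_extent must be an integer multiple of spacing")
  as.integer(2 * round(k) + 1)
}

#' Save / load a fitted expansion as JSON
#'
#' Lossless round trip of basis (k, l, m, alpha, r_max), coefficients and
#' provenance.
#'
#' @param fn an `approx_function`.
#' @param path file path.
#' @export
save_function_json <- function(fn, path) {
  jsonlite::write_json(
    list(basis = fn$basis[, c("k", "l", "m", "alpha", "r_max", "type")],
         coefficients = fn$coefficients,
         provenance = fn$provenance),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname save_function_json
#' @export
load_function_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(x$basis) || length(x$basis$k) == 0)
    stop("parse error: empty or missing basis")
  basis <- data.frame(k = as.integer(x$basis$k), l = as.integer(x$basis$l),
                      m = as.integer(x$basis$m),
                      alpha = as.numeric(x$basis$alpha),
                      r_max = as.numeric(x$basis$r_max),
                      type = as.character(x$basis$type))
  class(basis) <- c("cgf_basis", "data.frame")
  coef <- as.numeric(x$coefficients)
  if (length(coef) != nrow(basis))
    stop("parse error: coefficients/basis length mismatch")
  structure(list(basis = basis, coefficients = coef,
                 provenance = x$provenance, report = NULL),
            class = "approx_function")
}
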