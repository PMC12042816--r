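test_that("exponents place the radial maximum at r_max", {
  expect_equal(alpha_from_rmax(2, 3.0), 1 / 9)
  expect_equal(alpha_from_rmax(1, 1 / sqrt(2)), 1.0)
  # doubling r_max quarters alpha at fixed order
  expect_equal(alpha_from_rmax(3, 6.0), alpha_from_rmax(3, 3.0) / 4)
  # numeric maximization oracle: r^n exp(-alpha r^2) peaks at r_max
  for (n in c(1, 2, 5, 7)) {
    a <- alpha_from_rmax(n, 3.0)
    peak <- optimize(function(r) r^n * exp(-a * r^2), c(0.1, 10),
                     maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(peak, 3.0, tolerance = 1e-6)
  }
  expect_error(alpha_from_rmax(2, -1), "positive")
})

test_that("basis enumeration gives the standard term counts", {
  b <- build_basis(7, default_rmax())
  expect_equal(nrow(b), 600)
  counts <- table(b$type)[c("s", "p", "d", "f", "g", "h", "i", "j")]
  expect_equal(as.integer(counts), c(5, 15, 30, 50, 75, 105, 140, 180))
  expect_equal(anyDuplicated(b[, c("k", "l", "m", "alpha")]), 0L)
  expect_equal(nrow(build_basis(1, 3.0)), 4)       # 1 s + 3 p
  expect_equal(nrow(build_basis(0, c(2, 3, 4))), 3)
  expect_error(build_basis(7, c(3, 3)), "duplicate")
  expect_error(build_basis(7, numeric(0)), "non-empty")
})

test_that("CGF evaluation matches direct substitution and parity", {
  s <- list(k = 0, l = 0, m = 0, alpha = 0.37)
  expect_equal(eval_cgf(s, c(0, 0, 0)), 1)
  p <- list(k = 1, l = 0, m = 0, alpha = 0.25)
  expect_equal(eval_cgf(p, c(2, 0, 0)), 2 * exp(-1))
  set.seed(9)
  b <- build_basis(7, c(2.5, 3.5))
  for (i in 1:100) {
    t <- b[sample(nrow(b), 1), ]
    pt <- rnorm(3, 0, 3)
    expect_equal(eval_cgf(t, -pt),
                 (-1)^(t$k + t$l + t$m) * eval_cgf(t, pt),
                 tolerance = 1e-12)
  }
})

test_that("the sigmoid weight behaves as a 4-parameter logistic", {
  wf <- weight_function()
  p <- attr(wf, "params")
  expect_equal(wf(p["c"]), (p["a"] + p["d"]) / 2, ignore_attr = TRUE)
  wf0 <- weight_function(b = 0)
  ee <- seq(0, 1, length.out = 11)
  expect_equal(wf0(ee), rep((5 + 1) / 2, 11))
  sweep101 <- wf(seq(0, 1, length.out = 101))
  expect_true(all(diff(sweep101) >= 0))
  expect_gt(wf(1), wf(0))
  expect_error(weight_function(a = -5, d = -1), "configuration error")
})

test_that("exact fields are recovered exactly", {
  set.seed(21)
  basis <- build_basis(1, 3.0)[c(1, 3), ]      # one s and one p term
  pts <- matrix(rnorm(1500, 0, 3), ncol = 3)
  grid <- data.frame(u = pts[, 1], v = pts[, 2], w = pts[, 3])
  vals <- drop(naive_design(basis, pts) %*% c(0.7, 0.2))
  field <- list(grid = grid, normalized = vals)
  fit <- fit_cgf(field, basis, weightfn = NULL)
  expect_equal(fit$coefficients, c(0.7, 0.2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(fit$report$delta, 1e-12)
  expect_lt(max(abs(fit$report$A - t(fit$report$A))), 1e-9)
})

test_that("weighted fits equal a brute-force pseudo-inverse oracle", {
  set.seed(31)
  full <- build_basis(3, c(2.4, 3.6))
  for (rep in 1:20) {
    basis <- full[sample(nrow(full), 20), ]
    pts <- matrix(rnorm(900, 0, 2.5), ncol = 3)
    grid <- data.frame(u = pts[, 1], v = pts[, 2], w = pts[, 3])
    E <- pmin(pmax(rnorm(300, 0.4, 0.3), 0), 1)
    wf <- weight_function(a = runif(1, 2, 8), b = runif(1, 5, 25),
                          c = runif(1, 0.3, 0.7), d = runif(1, 0.5, 2))
    fit <- fit_cgf(list(grid = grid, normalized = E), basis, wf)
    expect_equal(fit$coefficients, oracle_wls(basis, pts, E, wf(E)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("fit edge cases behave per contract", {
  set.seed(41)
  basis <- build_basis(1, 3.0)
  pts <- matrix(rnorm(600, 0, 3), ncol = 3)
  grid <- data.frame(u = pts[, 1], v = pts[, 2], w = pts[, 3])
  E <- pmin(pmax(rnorm(200, 0.5, 0.2), 0), 1)
  field <- list(grid = grid, normalized = E)
  # ridge limit: huge lambda shrinks all coefficients toward zero
  big <- fit_cgf(field, basis, NULL, lambda = 1e12)
  expect_lt(max(abs(big$coefficients)), 1e-6)
  # all-zero weights and non-finite fields are rejected
  expect_error(fit_cgf(field, basis, function(e) 0 * e), "all-zero")
  bad <- field; bad$normalized[5] <- NA
  expect_error(fit_cgf(bad, basis, NULL), "non-finite")
  # permuting grid-point order leaves coefficients unchanged
  fit1 <- fit_cgf(field, basis, weight_function())
  perm <- sample(200)
  fit2 <- fit_cgf(list(grid = grid[perm, ], normalized = E[perm]),
                  basis, weight_function())
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  # objective optimality: perturbing any coefficient never decreases Delta
  G <- naive_design(basis, pts)
  w <- weight_function()(E)
  delta_of <- function(cf) sum(w * (E - drop(G %*% cf))^2)
  d0 <- delta_of(fit1$coefficients)
  for (j in seq_along(fit1$coefficients)) {
    for (s in c(-1e-3, 1e-3)) {
      cf <- fit1$coefficients; cf[j] <- cf[j] + s
      expect_gte(delta_of(cf), d0)
    }
  }
})

test_that("underdetermined fits fall back to the pseudo-inverse", {
  set.seed(51)
  basis <- build_basis(2, c(2.4, 3.0, 3.6))    # 30 terms
  pts <- matrix(rnorm(60, 0, 3), ncol = 3)     # 20 points < 30 terms
  grid <- data.frame(u = pts[, 1], v = pts[, 2], w = pts[, 3])
  E <- runif(20)
  expect_warning(fit <- fit_cgf(list(grid = grid, normalized = E),
                                basis, NULL),
                 "underdetermined")
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(fit$report$rank, nrow(basis))
})

test_that("lattice evaluation matches direct evaluation and the node count", {
  expect_equal(lattice_dims(0.1, 8.0), 161L)
  expect_equal(as.numeric(lattice_dims(0.1, 8.0))^3, 4173281)
  expect_error(lattice_dims(-0.1, 8), "positive")
  basis <- build_basis(0, 3.0)
  fn <- structure(list(basis = basis, coefficients = 1.0,
                       provenance = list()), class = "approx_function")
  lat <- evaluate_lattice(fn, 0.5, 2.0)
  expect_equal(lat$dims, rep(9L, 3))
  # centre node is the origin: an s-term with c = 1 evaluates to 1 there
  expect_equal(lat$values[5, 5, 5], 1)
  ax <- seq(-2, 2, by = 0.5)
  direct <- eval_cgf(basis[1, ], as.matrix(expand.grid(ax, ax, ax)))
  expect_equal(as.vector(lat$values), direct, tolerance = 1e-12)
  # clamped view stays within [0, 1]
  fn2 <- structure(list(basis = basis, coefficients = 3.0,
                        provenance = list()), class = "approx_function")
  lat2 <- evaluate_lattice(fn2, 0.5, 2.0, clamp = TRUE)
  expect_lte(max(lat2$values), 1)
})

test_that("residuals at the source grid are consistent with Delta", {
  set.seed(61)
  basis <- build_basis(2, c(2.4, 3.6))
  pts <- matrix(rnorm(1200, 0, 3), ncol = 3)
  grid <- data.frame(u = pts[, 1], v = pts[, 2], w = pts[, 3])
  E <- pmin(pmax(rnorm(400, 0.4, 0.25), 0), 1)
  wf <- weight_function()
  fit <- fit_cgf(list(grid = grid, normalized = E), basis, wf)
  pred <- evaluate_function(fit, pts)
  expect_equal(sum(wf(E) * (E - pred)^2), fit$report$delta,
               tolerance = 1e-9)
})

test_that("coefficient files round-trip losslessly", {
  set.seed(71)
  basis <- build_basis(7, default_rmax())
  fn <- structure(list(basis = basis, coefficients = rnorm(600),
                       provenance = list(probe = "methane")),
                  class = "approx_function")
  path <- withr::local_tempfile(fileext = ".json")
  save_function_json(fn, path)
  back <- load_function_json(path)
  pts <- matrix(rnorm(300, 0, 4), ncol = 3)
  expect_equal(evaluate_function(back, pts), evaluate_function(fn, pts),
               tolerance = 1e-12)
  # schema violations are parse errors
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines('{"basis": {"k": []}, "coefficients": []}', empty)
  expect_error(load_function_json(empty), "parse error")
  mismatch <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"basis": {"k": [0], "l": [0], "m": [0],',
                    ' "alpha": [0.1], "r_max": [2.2], "type": ["s"]},',
                    ' "coefficients": [1.0, 2.0]}'), mismatch)
  expect_error(load_function_json(mismatch), "mismatch")
})
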