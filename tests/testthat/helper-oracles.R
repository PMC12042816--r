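# Independent oracles and small constructed fixtures shared across tests.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# random proper rotation via Gram-Schmidt on two Gaussian vectors
rand_rotation <- function() {
  repeat {
    a <- rnorm(3); b <- rnorm(3)
    a <- a / sqrt(sum(a^2))
    b <- b - sum(a * b) * a
    if (sum(b^2) > 1e-6) break
  }
  b <- b / sqrt(sum(b^2))
  cbind(a, b, c(a[2] * b[3] - a[3] * b[2],
                a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1]))
}

# brute-force spherical grid size: enumerate every combination including
# both poles and the wrapped azimuth, then deduplicate cartesian positions
brute_grid_count <- function(r_min, r_max, r_step, polar_step, azimuth_step) {
  radii <- if (r_max < r_min) numeric(0) else seq(r_min, r_max, by = r_step)
  if (length(radii) == 0) return(0L)
  combos <- expand.grid(r = radii,
                        th = seq(0, 180, by = polar_step),
                        ph = seq(0, 360, by = azimuth_step))
  th <- combos$th * pi / 180; ph <- combos$ph * pi / 180
  xyz <- round(cbind(combos$r * sin(th) * cos(ph),
                     combos$r * sin(th) * sin(ph),
                     combos$r * cos(th)), 6)
  nrow(unique(as.data.frame(xyz)))
}

# term-by-term CGF design matrix, independent of cgf_design's vectorization
naive_design <- function(basis, pts) {
  sapply(seq_len(nrow(basis)), function(i) {
    t <- basis[i, ]
    pts[, 1]^t$k * pts[, 2]^t$l * pts[, 3]^t$m *
      exp(-t$alpha * rowSums(pts^2))
  })
}

# brute-force weighted least squares through a thin-QR / pseudo-inverse of
# the weighted design (no normal equations)
oracle_wls <- function(basis, pts, E, w) {
  G <- naive_design(basis, pts)
  sw <- sqrt(w)
  qr.solve(G * sw, E * sw)
}

# explicit 3x3x3 box convolution with boundary truncation (triple loop)
oracle_smooth27 <- function(vals) {
  d <- dim(vals)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    out[i, j, k] <- mean(vals[ii, jj, kk])
  }
  out
}

# minimal OpenDX parser used only to cross-check the package writer
independent_read_dx <- function(path) {
  txt <- readLines(path)
  counts <- as.integer(strsplit(sub(".*counts +", "", txt[1]), " ")[[1]])
  data_line <- grep("data follows", txt)
  stop_line <- grep("^attribute", txt)[1]
  vals <- as.numeric(unlist(strsplit(trimws(
    txt[(data_line + 1):(stop_line - 1)]), "\\s+")))
  list(counts = counts, values = vals)  # z-fastest flat order
}

# planar pyridine-like ring: 5 C + 1 N + 5 H (on the carbons), 11 atoms
toy_pyridine <- function() {
  ang <- (0:5) * pi / 3
  ring <- 1.35 * cbind(cos(ang), sin(ang), 0)
  hpos <- 2.43 * cbind(cos(ang[2:6]), sin(ang[2:6]), 0)
  molecule(c("N", rep("C", 5), rep("H", 5)), rbind(ring, hpos),
           rings = list(1:6), aromatic = TRUE)
}

# tiny scan setup reused by several scan tests
toy_scan_setup <- function(r_min = 3, r_max = 4, r_step = 1,
                           polar_step = 90, azimuth_step = 90) {
  mol <- toy_ring_molecule()
  frame <- build_frame(mol, 1:6, 1)
  grid <- make_spherical_grid(
    spherical_grid_spec(r_min, r_max, r_step, polar_step, azimuth_step))
  list(mol = mol, frame = frame, grid = grid)
}
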