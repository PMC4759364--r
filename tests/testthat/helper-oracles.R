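# Independent oracles and fixture builders used across the suite.

# rotation matrix from unit axis + angle (radians)
rot_axis_angle <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# brute-force minimum RMSD over rotations: random rotation grid followed by
# Nelder-Mead polish on axis-angle parameters; independent of the SVD path
oracle_min_rmsd <- function(mobile, reference, n_grid = 400) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rmsd_rot <- function(par) {
    th <- sqrt(sum(par^2))
    R <- if (th < 1e-12) diag(3) else rot_axis_angle(par / th, th)
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  best <- c(0, 0, 0); best_v <- rmsd_rot(best)
  for (g in seq_len(n_grid)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, pi)
    par <- ax * th
    v <- rmsd_rot(par)
    if (v < best_v) { best <- par; best_v <- v }
  }
  for (k in 1:3) {
    o <- optim(best, rmsd_rot, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 2000))
    best <- o$par; best_v <- o$value
  }
  best_v
}

# analytic exposed area of sphere 1 (radius R1) partially covered by
# sphere 2 (radius R2) at center distance d (spherical-cap formula)
lens_exposed_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d <= abs(R1 - R2)) {
    return(if (R1 > R2) 4 * pi * R1^2 else 0)
  }
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# bare frame with CA-only atoms at given coordinates
ca_frame <- function(xyz, residue_name = "ALA") {
  n <- nrow(xyz)
  frame(data.frame(residue_index = seq_len(n),
                   residue_name = residue_name,
                   atom_name = "CA", stringsAsFactors = FALSE),
        xyz)
}

ar1_series <- function(n, rho, sd_innov = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, sd_innov)
  x
}

# reduced-unit 2D double-well used for Boltzmann-recovery checks
double_well_u <- function(x, y) 4 * (x^2 - 1)^2 + 1.5 * x + 2 * y^2

# half-plane partition functions of double_well_u by quadrature
double_well_dg_oracle <- function(kt) {
  f <- function(x, y) exp(-double_well_u(x, y) / kt)
  zx <- function(lo, hi) {
    integrate(Vectorize(function(x) {
      integrate(function(y) f(x, y), -4, 4, rel.tol = 1e-10)$value
    }), lo, hi, rel.tol = 1e-9)$value
  }
  -kt * log(zx(0, 3) / zx(-3, 0))
}
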