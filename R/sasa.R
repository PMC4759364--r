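#' @title Solvent-accessible surface area (Shrake-Rupley)
#' @description Numerical SASA: each atom's sphere (vdW radius + probe) is
#'   covered with a deterministic Fibonacci lattice of test points and the
#'   exposed fraction is converted to area. Hydrogens are not part of the
#'   surface model (united-atom convention); the CB pseudo-atom carries a
#'   per-residue radius standing in for the whole side chain.
#' @name sasa
NULL

# Bondi-type radii (nm) for backbone atoms; side chains are represented by
# the CB pseudo-atom in one of three size classes.
SASA_RADII <- c(N = 0.155, C = 0.170, CA = 0.170, O = 0.152)
CB_SMALL <- c("ALA", "SER", "CYS")
CB_LARGE <- c("PHE", "TYR", "TRP", "HIS", "LYS", "ARG")
CB_RADII <- c(small = 0.20, medium = 0.25, large = 0.30)

sasa_radius <- function(atom_name, residue_name) {
  r <- numeric(length(atom_name))
  for (k in seq_along(atom_name)) {
    a <- atom_name[k]
    if (a == "CB") {
      cls <- if (residue_name[k] %in% CB_SMALL) "small"
             else if (residue_name[k] %in% CB_LARGE) "large" else "medium"
      r[k] <- CB_RADII[[cls]]
    } else if (a %in% names(SASA_RADII)) {
      r[k] <- SASA_RADII[[a]]
    } else {
      stop("missing radius for atom name: ", a)
    }
  }
  r
}

#' Deterministic Fibonacci sphere lattice
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley SASA of one frame
#'
#' Per-atom area is `(exposed points / n_points) * 4 pi (r_i + probe)^2`.
#' A test point on atom i is buried if it lies inside any neighbor's
#' expanded sphere. Hydrogens are skipped.
#'
#' @param frm A `hp_frame`.
#' @param probe_radius Probe radius in nm (water: 0.14).
#' @param n_points Test points per atom (>= 16).
#' @return List of class `sasa_result`: `per_atom` (nm^2, 0 for skipped H),
#'   `total` (nm^2), `probe_radius`, `n_points`, `atom_index` of surface
#'   atoms.
#' @export
shrake_rupley <- function(frm, probe_radius = 0.14, n_points = 960) {
  stopifnot(inherits(frm, "hp_frame"), n_points >= 16)
  heavy <- which(frm$atoms$atom_name != "H")
  xyz <- frm$xyz[heavy, , drop = FALSE]
  radii <- sasa_radius(frm$atoms$atom_name[heavy],
                       frm$atoms$residue_name[heavy]) + probe_radius
  n_atoms <- length(heavy)
  sphere <- fibonacci_sphere(n_points)
  per_atom_all <- numeric(nrow(frm$atoms))
  # pairwise center distances once
  d2 <- as.matrix(dist(xyz))^2
  for (a in seq_len(n_atoms)) {
    nb <- which(d2[a, ] < (radii[a] + radii)^2 & seq_len(n_atoms) != a)
    if (length(nb) == 0L) {
      exposed <- n_points
    } else {
      pts <- sweep(sphere * radii[a], 2, xyz[a, ], `+`)
      buried <- rep(FALSE, n_points)
      for (b in nb) {
        db2 <- (pts[, 1] - xyz[b, 1])^2 + (pts[, 2] - xyz[b, 2])^2 +
          (pts[, 3] - xyz[b, 3])^2
        buried <- buried | (db2 < radii[b]^2)
        if (all(buried)) break
      }
      exposed <- sum(!buried)
    }
    per_atom_all[heavy[a]] <- (exposed / n_points) * 4 * pi * radii[a]^2
  }
  structure(list(per_atom = per_atom_all, total = sum(per_atom_all),
                 probe_radius = probe_radius, n_points = n_points,
                 atom_index = heavy),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.4f nm^2 (%d surface atoms, %d points, probe %.2f nm)\n",
              x$total, length(x$atom_index), x$n_points, x$probe_radius))
  invisible(x)
}

#' SASA time series with summary statistics
#'
#' @param traj A `hp_trajectory`.
#' @inheritParams shrake_rupley
#' @param stride Analyze every `stride`-th frame.
#' @return List of class `sasa_series`: `values` (total nm^2 per analyzed
#'   frame), `times`, `mean`, `sd`.
#' @export
sasa_series <- function(traj, probe_radius = 0.14, n_points = 240,
                        stride = 1L) {
  stopifnot(inherits(traj, "hp_trajectory"))
  ks <- seq(1L, n_frames(traj), by = stride)
  vals <- vapply(ks, function(k) {
    shrake_rupley(get_frame(traj, k), probe_radius, n_points)$total
  }, numeric(1))
  structure(list(values = vals, times = traj$times[ks],
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) sd(vals) else 0),
            class = "sasa_series")
}

#' @export
print.sasa_series <- function(x, ...) {
  cat(sprintf("<sasa_series> %d frames: %.3f (%.3f) nm^2\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}
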