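#' @title Superposition and structural descriptors
#' @description Kabsch optimal superposition and the descriptors built on
#'   it: RMSD time series against a reference, radius of gyration, and
#'   per-atom RMSF about the (iterated) mean structure, including the
#'   strand-split fitting mode used to compare the two halves of a hairpin.
#' @name geometry
NULL

ATOM_MASSES <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999)

atom_masses <- function(atom_names) {
  unname(ATOM_MASSES[substr(atom_names, 1L, 1L)])
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD of `mobile` onto `reference`; the reflection branch of the SVD is
#' corrected so the rotation determinant is +1.
#'
#' @param mobile,reference Numeric n x 3 matrices (nm), equal row counts,
#'   n >= 3.
#' @param weights Optional non-negative weights, length n.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (nm). Applying `sweep(mobile, 2, cm) %*% rotation` then adding the
#'   translation maps mobile onto reference; use [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point-count mismatch")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm_mob <- colSums(mobile * w)
  cm_ref <- colSums(reference * w)
  A <- sweep(mobile, 2, cm_mob)
  B <- sweep(reference, 2, cm_ref)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (max(sv$d) <= 0 || sum(sv$d > max(sv$d) * 1e-8) < 2L) {
    stop("ill-conditioned: degenerate (collinear) configuration")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)  # mobile-frame -> reference-frame
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = cm_ref, center = cm_mob, rmsd = rmsd)
}

#' Apply a superposition result to coordinates
#'
#' @param xyz n x 3 coordinate matrix (nm).
#' @param sp Result of [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(sweep(as.matrix(xyz), 2, sp$center) %*% sp$rotation, 2,
        sp$translation, `+`)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series against a reference structure
#'
#' Every frame is superposed onto the reference using `fit_selection`, and
#' the RMSD is evaluated on `calc_selection` (the fit selection by
#' default). The conventional choice for hairpin work is the main-chain
#' selection (N, CA, O).
#'
#' @param traj A `hp_trajectory`.
#' @param reference A `hp_frame` with the same atom set.
#' @param fit_selection,calc_selection Selections as in [select_atoms()].
#' @param residue_range Optional residue range for both selections.
#' @return Object of class `descriptor_series`: list with `values` (nm),
#'   `times` (ps), `frame_interval`, `descriptor`.
#' @export
rmsd_series <- function(traj, reference, fit_selection = "main-chain",
                        calc_selection = fit_selection,
                        residue_range = NULL) {
  stopifnot(inherits(traj, "hp_trajectory"), inherits(reference, "hp_frame"))
  fit_idx <- select_atoms(traj, fit_selection, residue_range)
  calc_idx <- select_atoms(traj, calc_selection, residue_range)
  ref_fit_idx <- select_atoms(reference, fit_selection, residue_range)
  ref_calc_idx <- select_atoms(reference, calc_selection, residue_range)
  if (length(fit_idx) != length(ref_fit_idx) ||
      length(calc_idx) != length(ref_calc_idx)) {
    stop("selection mismatch between trajectory and reference")
  }
  ref_fit <- reference$xyz[ref_fit_idx, , drop = FALSE]
  ref_calc <- reference$xyz[ref_calc_idx, , drop = FALSE]
  vals <- vapply(traj$coords, function(xyz) {
    sp <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref_fit)
    fitted <- apply_superposition(xyz[calc_idx, , drop = FALSE], sp)
    rmsd_between(fitted, ref_calc)
  }, numeric(1))
  structure(list(values = vals, times = traj$times,
                 frame_interval = traj$frame_interval, descriptor = "RMSD"),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series> %s: %d frames, mean %.4f (sd %.4f) nm\n",
              x$descriptor, length(x$values), mean(x$values),
              if (length(x$values) > 1L) sd(x$values) else 0))
  invisible(x)
}

#' Radius of gyration of one frame
#'
#' `Rg = sqrt( sum w_i |r_i - r_com|^2 / sum w_i )`, mass-weighted by
#' default using standard atomic masses keyed on the first letter of the
#' atom name (the CB pseudo-atom counts as carbon).
#'
#' @param frm A `hp_frame`.
#' @param selection Selection as in [select_atoms()].
#' @param mass_weighted Use atomic masses as weights (default) or equal
#'   weights.
#' @param residue_range Optional residue range.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(frm, selection = "heavy",
                               mass_weighted = TRUE, residue_range = NULL) {
  stopifnot(inherits(frm, "hp_frame"))
  idx <- select_atoms(frm, selection, residue_range)
  xyz <- frm$xyz[idx, , drop = FALSE]
  w <- if (mass_weighted) atom_masses(frm$atoms$atom_name[idx]) else
    rep(1, length(idx))
  w <- w / sum(w)
  com <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
}

#' Radius-of-gyration time series
#'
#' @inheritParams radius_of_gyration
#' @param traj A `hp_trajectory`.
#' @return A `descriptor_series` (values in nm).
#' @export
rg_series <- function(traj, selection = "heavy", mass_weighted = TRUE,
                      residue_range = NULL) {
  stopifnot(inherits(traj, "hp_trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    radius_of_gyration(get_frame(traj, k), selection, mass_weighted,
                       residue_range)
  }, numeric(1))
  structure(list(values = vals, times = traj$times,
                 frame_interval = traj$frame_interval, descriptor = "Rg"),
            class = "descriptor_series")
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed onto the time-average structure computed from
#' `fit_selection`; the fit/average cycle is iterated twice (fit to the
#' mean of raw frames, re-average, re-fit), a standard convention. RMSF is
#' then `sqrt(mean |r_i - <r_i>|^2)` for each target atom. Fitting on a
#' residue subset (e.g. the N-side strand, residues 1..10 of a 19-mer)
#' exposes the relative rigidity of the two strands.
#'
#' @param traj A `hp_trajectory` with >= 2 frames.
#' @param fit_selection Selection used for superposition.
#' @param target_atoms Selection of atoms to report (default `"CA"`).
#' @param fit_residue_range Optional residue range restricting the fit.
#' @return Data frame with `atom_index`, `residue_index`, `atom_name`,
#'   `rmsf_nm`.
#' @export
rmsf <- function(traj, fit_selection = "main-chain", target_atoms = "CA",
                 fit_residue_range = NULL) {
  stopifnot(inherits(traj, "hp_trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  fit_idx <- select_atoms(traj, fit_selection, fit_residue_range)
  tgt_idx <- select_atoms(traj, target_atoms)
  coords <- traj$coords
  ref <- Reduce(`+`, lapply(coords, function(m) m[fit_idx, , drop = FALSE])) /
    length(coords)
  for (round in 1:2) {
    fitted <- lapply(coords, function(xyz) {
      sp <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref)
      apply_superposition(xyz, sp)
    })
    ref <- Reduce(`+`, lapply(fitted, function(m)
      m[fit_idx, , drop = FALSE])) / length(fitted)
  }
  tgt <- lapply(fitted, function(m) m[tgt_idx, , drop = FALSE])
  mean_tgt <- Reduce(`+`, tgt) / length(tgt)
  msd <- Reduce(`+`, lapply(tgt, function(m)
    rowSums((m - mean_tgt)^2))) / length(tgt)
  data.frame(atom_index = tgt_idx,
             residue_index = traj$atoms$residue_index[tgt_idx],
             atom_name = traj$atoms$atom_name[tgt_idx],
             rmsf_nm = sqrt(msd))
}
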