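#' @title Geometric tracking of register hydrogen bonds
#' @description Per-frame H...O lengths and formed/broken state of the
#'   eight inter-strand register bonds (HB1..HB8), and formed-bond count
#'   series with the mean (sd) summary used to compare hairpin stability.
#' @name hbonds
NULL

#' Default geometric hydrogen-bond criteria
#'
#' Donor-acceptor heavy-atom distance at most `max_da_distance` and
#' H-donor-acceptor angle at most `max_hda_angle` (common MD-analysis
#' convention).
#'
#' @param max_da_distance nm (default 0.35).
#' @param max_hda_angle degrees (default 30).
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  stopifnot(max_da_distance > 0, max_hda_angle > 0)
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criteria")
}

# donor/acceptor atom positions for one bond definition in one frame,
# reconstructing the amide H when the frame lacks it
hbond_atoms <- function(bb, bond) {
  di <- as.character(bond$donor_residue)
  ai <- as.character(bond$acceptor_residue)
  don <- bb$bb[[di]]; acc <- bb$bb[[ai]]
  if (is.null(don) || is.null(acc)) {
    stop("missing residue for bond ", bond$label)
  }
  if (is.null(don$H)) {
    stop("no donor hydrogen for bond ", bond$label,
         " (proline or chain-start donor)")
  }
  list(N = don$N, H = don$H, O = acc$O, C = acc$C)
}

#' Hydrogen-bond length (H...O distance) in one frame
#'
#' @param frm A `hp_frame`.
#' @param bond One row of [hbond_register()] output (or a list with
#'   `donor_residue`, `acceptor_residue`, `label`).
#' @return H...O distance in nm.
#' @export
hbond_length <- function(frm, bond) {
  bb <- backbone_table(frm)
  a <- hbond_atoms(bb, bond)
  sqrt(sum((a$H - a$O)^2))
}

#' Is a hydrogen bond formed in this frame?
#'
#' True when the N...O distance is at most the criteria's maximum
#' donor-acceptor distance and the H-N-O angle at most the maximum angle.
#'
#' @inheritParams hbond_length
#' @param criteria A [hbond_criteria()].
#' @return Logical.
#' @export
hbond_formed <- function(frm, bond, criteria = hbond_criteria()) {
  bb <- backbone_table(frm)
  a <- hbond_atoms(bb, bond)
  hbond_formed_atoms(a, criteria)
}

hbond_formed_atoms <- function(a, criteria) {
  d_no <- sqrt(sum((a$N - a$O)^2))
  if (d_no > criteria$max_da_distance) return(FALSE)
  v1 <- a$H - a$N; v2 <- a$O - a$N
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang <= criteria$max_hda_angle
}

#' Track register hydrogen bonds over a trajectory
#'
#' @param traj A `hp_trajectory`.
#' @param bonds Data frame of bond definitions ([hbond_register()]).
#' @param criteria A [hbond_criteria()].
#' @param stride Analyze every `stride`-th frame.
#' @return Object of class `hbond_traces`: per-bond length matrix (frames x
#'   bonds, nm), formed matrix, per-frame formed counts, `count_mean`,
#'   `count_sd`, per-bond `length_mean`/`length_sd`.
#' @export
hbond_trace <- function(traj, bonds, criteria = hbond_criteria(),
                        stride = 1L) {
  stopifnot(inherits(traj, "hp_trajectory"), nrow(bonds) >= 1L)
  ks <- seq(1L, n_frames(traj), by = stride)
  nb <- nrow(bonds)
  lengths <- matrix(NA_real_, length(ks), nb,
                    dimnames = list(NULL, bonds$label))
  formed <- matrix(FALSE, length(ks), nb,
                   dimnames = list(NULL, bonds$label))
  for (r in seq_along(ks)) {
    bb <- backbone_table(get_frame(traj, ks[r]))
    for (b in seq_len(nb)) {
      a <- hbond_atoms(bb, bonds[b, ])
      lengths[r, b] <- sqrt(sum((a$H - a$O)^2))
      formed[r, b] <- hbond_formed_atoms(a, criteria)
    }
  }
  counts <- rowSums(formed)
  structure(list(
    labels = bonds$label, times = traj$times[ks],
    lengths = lengths, formed = formed, counts = counts,
    count_mean = mean(counts),
    count_sd = if (length(counts) > 1L) sd(counts) else 0,
    length_mean = colMeans(lengths),
    length_sd = apply(lengths, 2, function(v)
      if (length(v) > 1L) sd(v) else 0),
    criteria = criteria), class = "hbond_traces")
}

#' @export
print.hbond_traces <- function(x, ...) {
  cat(sprintf("<hbond_traces> %d bonds, %d frames; count %.2f (%.2f)\n",
              length(x$labels), length(x$counts), x$count_mean, x$count_sd))
  tab <- data.frame(bond = x$labels,
                    length_nm = sprintf("%.3f (%.3f)", x$length_mean,
                                        x$length_sd))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-frame formed-bond count series
#'
#' Convenience wrapper around [hbond_trace()] returning just the counts.
#'
#' @inheritParams hbond_trace
#' @return List with `counts`, `times`, `mean`, `sd`.
#' @export
hbond_count_series <- function(traj, bonds, criteria = hbond_criteria(),
                               stride = 1L) {
  tr <- hbond_trace(traj, bonds, criteria, stride)
  list(counts = tr$counts, times = tr$times, mean = tr$count_mean,
       sd = tr$count_sd)
}
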