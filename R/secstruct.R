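#' @title DSSP-style secondary-structure assignment
#' @description Backbone hydrogen bonds by the Kabsch-Sander electrostatic
#'   criterion, bridge/ladder and turn rules for the codes E, B, H, G, T, C,
#'   and the per-frame beta-sheet formation rate used as the order
#'   parameter for sampling-convergence checks.
#' @name secstruct
NULL

KS_COUPLING <- 0.084 * 332  # kcal/mol * Angstrom
KS_CUTOFF <- -0.5           # kcal/mol

#' Kabsch-Sander hydrogen-bond energy
#'
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol with
#' distances in Angstrom; a hydrogen bond is declared when E < -0.5
#' kcal/mol. Inputs are in nm (converted internally).
#'
#' @param donor_n,donor_h Donor amide N and H positions (nm).
#' @param acceptor_c,acceptor_o Acceptor carbonyl C and O positions (nm).
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(donor_n, donor_h, acceptor_c, acceptor_o) {
  d <- function(a, b) sqrt(sum((a - b)^2)) * 10  # nm -> Angstrom
  r_on <- d(acceptor_o, donor_n); r_ch <- d(acceptor_c, donor_h)
  r_oh <- d(acceptor_o, donor_h); r_cn <- d(acceptor_c, donor_n)
  if (any(c(r_on, r_ch, r_oh, r_cn) <= 0)) stop("coincident atoms")
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Per-residue backbone coordinate table. Amide H is taken from the frame
# when present, otherwise reconstructed 1.01 Angstrom from N along the
# direction opposing the bisector of N->CA and N->C(prev); proline and a
# chain-initial residue without a preceding carbonyl have no donor.
backbone_table <- function(frm) {
  at <- frm$atoms
  core <- which(!(at$residue_name %in% CAP_NAMES) & at$residue_index >= 1L)
  res_idx <- sort(unique(at$residue_index[core]))
  get <- function(ri, an) {
    k <- which(at$residue_index == ri & at$atom_name == an)
    if (length(k) == 0L) return(NULL)
    frm$xyz[k[1L], ]
  }
  bb <- lapply(res_idx, function(ri) {
    need <- c("N", "CA", "C", "O")
    pos <- lapply(need, get, ri = ri)
    if (any(vapply(pos, is.null, logical(1)))) {
      stop("missing backbone atom(s) for residue ", ri)
    }
    names(pos) <- need
    pos$H <- get(ri, "H")
    pos$name <- at$residue_name[which(at$residue_index == ri)[1L]]
    pos
  })
  names(bb) <- res_idx
  # reconstruct missing amide hydrogens
  for (k in seq_along(bb)) {
    if (bb[[k]]$name == "PRO") { bb[[k]]$H <- NULL; next }
    if (!is.null(bb[[k]]$H)) next
    prev_c <- if (k > 1L) bb[[k - 1L]]$C else get(res_idx[k] - 1L, "C")
    if (is.null(prev_c)) next  # chain start: no donor
    n <- bb[[k]]$N
    u1 <- (n - prev_c); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- (n - bb[[k]]$CA); u2 <- u2 / sqrt(sum(u2^2))
    dir <- u1 + u2; dir <- dir / sqrt(sum(dir^2))
    bb[[k]]$H <- n + 0.101 * dir
  }
  list(bb = bb, residues = res_idx)
}

# Hydrogen-bond matrix: hb[i, j] is TRUE when the carbonyl of residue i
# accepts from the amide of residue j (Kabsch-Sander E < -0.5 kcal/mol),
# evaluated for |i - j| >= 2.
ks_hbond_matrix <- function(bb) {
  n <- length(bb$bb)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      don <- bb$bb[[j]]; acc <- bb$bb[[i]]
      if (is.null(don$H)) next
      e <- ks_hbond_energy(don$N, don$H, acc$C, acc$O)
      hb[i, j] <- e < KS_CUTOFF
    }
  }
  hb
}

#' Assign secondary structure to one frame
#'
#' DSSP-style rules on the Kabsch-Sander backbone hydrogen-bond pattern:
#' antiparallel/parallel bridges give B, two or more consecutive bridged
#' residues give E, runs of i->i+4 bonds give H, i->i+3 give G, isolated
#' turns give T, everything else C. Priority H > E > B > G > T > C.
#'
#' @param frm A `hp_frame` with backbone atoms N, CA, C, O per residue
#'   (amide H optional; reconstructed when absent).
#' @return Object of class `ss_assignment`: `codes` (character vector, one
#'   of E, B, H, G, T, C per residue), `residues`, `frame_time`.
#' @export
assign_secondary_structure <- function(frm) {
  stopifnot(inherits(frm, "hp_frame"))
  bb <- backbone_table(frm)
  n <- length(bb$bb)
  hb <- ks_hbond_matrix(bb)
  turn3 <- vapply(seq_len(n), function(i)
    i + 3L <= n && hb[i, i + 3L], logical(1))
  turn4 <- vapply(seq_len(n), function(i)
    i + 4L <= n && hb[i, i + 4L], logical(1))
  turn5 <- vapply(seq_len(n), function(i)
    i + 5L <= n && hb[i, i + 5L], logical(1))
  bridge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 2L) next
      par <- (i > 1L && i < n && hb[i - 1L, j] && hb[j, i + 1L]) ||
             (j > 1L && j < n && hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1L && i < n && j > 1L && j < n &&
                 hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) { bridge[i, j] <- TRUE; bridge[j, i] <- TRUE }
    }
  }
  bridged <- rowSums(bridge) > 0
  codes <- rep("C", n)
  # turns first (lowest priority overwritten later)
  for (i in seq_len(n)) {
    for (nn in c(3L, 4L, 5L)) {
      tt <- switch(as.character(nn), "3" = turn3, "4" = turn4, "5" = turn5)
      if (tt[i]) {
        span <- (i + 1L):(i + nn - 1L)
        codes[span[span <= n]] <- "T"
      }
    }
  }
  # 3-10 helix: two consecutive 3-turns
  for (i in 2L:n) {
    if (i <= n - 3L && turn3[i - 1L] && turn3[i]) {
      codes[i:(i + 2L)] <- "G"
    }
  }
  # strand: extended if part of a >= 2 run of bridged residues, else B
  r <- rle(bridged)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    span <- pos[k]:(pos[k] + r$lengths[k] - 1L)
    codes[span] <- if (length(span) >= 2L) "E" else "B"
  }
  # alpha helix on top
  for (i in 2L:n) {
    if (i <= n - 4L && turn4[i - 1L] && turn4[i]) {
      codes[i:(i + 3L)] <- "H"
    }
  }
  structure(list(codes = codes, residues = bb$residues,
                 frame_time = frm$time),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> %s\n", paste(x$codes, collapse = "")))
  invisible(x)
}

#' Beta-sheet formation rate of one assignment
#'
#' Fraction of residues assigned extended strand (E); `count_b = TRUE`
#' additionally counts isolated bridges (B).
#'
#' @param assignment A `ss_assignment`.
#' @param count_b Count B codes as sheet.
#' @return Fraction in `[0, 1]`.
#' @export
beta_sheet_rate <- function(assignment, count_b = FALSE) {
  stopifnot(inherits(assignment, "ss_assignment"))
  sheet <- assignment$codes == "E"
  if (count_b) sheet <- sheet | assignment$codes == "B"
  mean(sheet)
}

#' Per-frame beta-sheet rate series for a trajectory
#'
#' @param traj A `hp_trajectory`.
#' @param count_b Count B codes as sheet.
#' @param stride Analyze every `stride`-th frame.
#' @return List of class `sheet_rate_series` with `values`, `times`,
#'   `mean`, `sd`, and the per-frame code strings.
#' @export
sheet_rate_series <- function(traj, count_b = FALSE, stride = 1L) {
  stopifnot(inherits(traj, "hp_trajectory"))
  ks <- seq(1L, n_frames(traj), by = stride)
  assigns <- lapply(ks, function(k)
    assign_secondary_structure(get_frame(traj, k)))
  vals <- vapply(assigns, beta_sheet_rate, numeric(1), count_b = count_b)
  structure(list(values = vals, times = traj$times[ks],
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) sd(vals) else 0,
                 codes = vapply(assigns, function(a)
                   paste(a$codes, collapse = ""), character(1))),
            class = "sheet_rate_series")
}

#' @export
print.sheet_rate_series <- function(x, ...) {
  cat(sprintf("<sheet_rate_series> %d frames: %.3f (%.3f)\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}
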