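#' @title Structures, trajectories and PDB I/O
#' @description Internal containers for conformational ensembles (ordered
#'   backbone+CB atom records, coordinates in nm) and multi-model PDB
#'   reading/writing. All analysis code consumes these containers.
#' @name structure-io
NULL

SUPPORTED_ATOMS <- c("N", "H", "CA", "C", "O", "CB")
CAP_NAMES <- c("ACE", "NME", "NMA")

#' Construct a single structure frame
#'
#' @param atoms Data frame with columns `residue_index` (1-based; caps use
#'   0 and L+1), `residue_name` (3-letter code or cap name), `atom_name`
#'   (one of N, H, CA, C, O, CB).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param time Frame time in ps (optional).
#' @return A `hp_frame` object.
#' @export
frame <- function(atoms, xyz, time = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("residue_index", "residue_name", "atom_name") %in%
                  names(atoms)))
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == nrow(atoms), all(is.finite(xyz)))
  bad <- !atoms$atom_name %in% SUPPORTED_ATOMS
  if (any(bad)) {
    stop("unsupported atom name(s): ",
         paste(unique(atoms$atom_name[bad]), collapse = ", "))
  }
  structure(list(atoms = atoms, xyz = unname(xyz), time = time),
            class = "hp_frame")
}

#' @export
print.hp_frame <- function(x, ...) {
  cat(sprintf("<hp_frame> %d atoms, %d residues%s\n", nrow(x$atoms),
              length(unique(x$atoms$residue_index)),
              if (is.finite(x$time)) sprintf(", t = %g ps", x$time) else ""))
  invisible(x)
}

#' Construct a trajectory (ordered frame list with shared topology)
#'
#' @param frames List of `hp_frame` objects with identical atom tables, or a
#'   list of coordinate matrices plus an `atoms` table.
#' @param atoms Atom table if `frames` holds bare matrices.
#' @param frame_interval Time between frames, ps.
#' @param label Free-text label.
#' @param temperature Simulation temperature in K (optional).
#' @return A `hp_trajectory`: shared `atoms` table, list of nm coordinate
#'   matrices `coords`, `times`, `frame_interval`, `label`, `temperature`.
#' @export
trajectory <- function(frames, atoms = NULL, frame_interval = 1,
                       label = "", temperature = NA_real_) {
  stopifnot(length(frames) >= 1L)
  if (inherits(frames[[1]], "hp_frame")) {
    atoms <- frames[[1]]$atoms
    nat <- nrow(atoms)
    coords <- lapply(frames, function(f) {
      stopifnot(inherits(f, "hp_frame"))
      if (nrow(f$atoms) != nat ||
          !identical(f$atoms$atom_name, atoms$atom_name) ||
          !identical(f$atoms$residue_index, atoms$residue_index)) {
        stop("atom set mismatch across frames")
      }
      f$xyz
    })
  } else {
    stopifnot(is.data.frame(atoms))
    nat <- nrow(atoms)
    coords <- lapply(frames, function(m) {
      m <- as.matrix(m)
      if (nrow(m) != nat) stop("atom set mismatch across frames")
      unname(m)
    })
  }
  structure(
    list(atoms = atoms, coords = coords,
         times = (seq_along(coords) - 1) * frame_interval,
         frame_interval = frame_interval, label = label,
         temperature = temperature),
    class = "hp_trajectory"
  )
}

#' @export
print.hp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<hp_trajectory> %s: %d frames x %d atoms, dt = %g ps%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$coords), nrow(x$atoms), x$frame_interval,
    if (is.finite(x$temperature)) sprintf(", T = %g K", x$temperature) else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `hp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame from a trajectory
#' @param traj A `hp_trajectory`.
#' @param k Frame number (1-based).
#' @return A `hp_frame`.
#' @export
get_frame <- function(traj, k) {
  stopifnot(k >= 1L, k <= n_frames(traj))
  frame(traj$atoms, traj$coords[[k]], time = traj$times[k])
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()]. Coordinates are converted
#' from Angstrom to nm; atoms outside the supported backbone+CB set
#' (N, H, CA, C, O, CB) are dropped with a message reporting the count.
#' Residue numbering is taken from the file.
#'
#' @param path PDB file path.
#' @param frame_interval Time between models, ps.
#' @param label Trajectory label (defaults to the file name).
#' @param temperature Optional temperature in K.
#' @return A `hp_trajectory`.
#' @export
read_pdb_models <- function(path, frame_interval = 1, label = basename(path),
                            temperature = NA_real_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  n_atom_lines <- sum(startsWith(lines, "ATOM"))
  if (n_atom_lines == 0L) stop("empty structure: no ATOM records in ", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_starts)) {
      stop("atom set mismatch: unbalanced MODEL/ENDMDL blocks")
    }
    counts <- mapply(function(s, e) sum(startsWith(lines[s:e], "ATOM")),
                     model_starts, ends)
    if (length(unique(counts)) != 1L) {
      stop("atom set mismatch: models contain different atom counts")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$elety %in% SUPPORTED_ATOMS
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_pdb_models: skipped %d unsupported atom(s)",
                    n_skipped))
  }
  if (!any(keep)) stop("empty structure: no supported atoms in ", path)
  atoms <- data.frame(
    residue_index = at$resno[keep],
    residue_name = at$resid[keep],
    atom_name = at$elety[keep],
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  keep3 <- rep((which(keep) - 1L) * 3L, each = 3L) + rep(1:3, sum(keep))
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, keep3], ncol = 3L, byrow = TRUE) / 10
  })
  trajectory(coords, atoms = atoms, frame_interval = frame_interval,
             label = label, temperature = temperature)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-width PDB v3.3 columns,
#' coordinates converted from nm to Angstrom.
#'
#' @param traj A `hp_trajectory`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pdb_models <- function(traj, path) {
  stopifnot(inherits(traj, "hp_trajectory"))
  if (nrow(traj$atoms) == 0L) stop("empty structure: no atoms to write")
  at <- traj$atoms
  name4 <- ifelse(nchar(at$atom_name) < 4L,
                  sprintf(" %-3s", at$atom_name),
                  sprintf("%-4s", at$atom_name))
  elem <- substr(at$atom_name, 1L, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[m]] * 10  # nm -> Angstrom
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, substr(at$residue_name, 1L, 3L),
      at$residue_index, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices by name set and residue range
#'
#' Named selections: `"main-chain"` is N, CA, O (the backbone amide
#' nitrogen, chiral carbon and carbonyl oxygen; the carbonyl carbon can be
#' added with `include_c = TRUE`), `"CA"`, `"heavy"` (all but H), `"all"`.
#' A character vector of atom names acts as a custom selection. Capping
#' groups (residue index outside 1..L, or cap residue names) are excluded
#' from every named selection.
#'
#' @param x A `hp_frame` or `hp_trajectory`.
#' @param selection Selection name or character vector of atom names.
#' @param residue_range Optional length-2 integer vector `c(lo, hi)`.
#' @param include_c Include the carbonyl C in `"main-chain"`.
#' @return Integer vector of atom indices (stable order, no duplicates).
#' @export
select_atoms <- function(x, selection = "main-chain", residue_range = NULL,
                         include_c = FALSE) {
  atoms <- if (inherits(x, "hp_trajectory") || inherits(x, "hp_frame")) {
    x$atoms
  } else stop("x must be a hp_frame or hp_trajectory")
  names_set <- if (length(selection) == 1L &&
                   selection %in% c("main-chain", "CA", "all", "heavy")) {
    switch(selection,
      "main-chain" = if (include_c) c("N", "CA", "C", "O") else
        c("N", "CA", "O"),
      "CA" = "CA",
      "heavy" = setdiff(SUPPORTED_ATOMS, "H"),
      "all" = SUPPORTED_ATOMS)
  } else if (is.character(selection) && all(selection %in% SUPPORTED_ATOMS)) {
    unique(selection)
  } else {
    stop("unknown selection: ", paste(selection, collapse = ", "))
  }
  idx <- which(atoms$atom_name %in% names_set &
                 !(atoms$residue_name %in% CAP_NAMES) &
                 atoms$residue_index >= 1L)
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    idx <- idx[atoms$residue_index[idx] >= residue_range[1] &
                 atoms$residue_index[idx] <= residue_range[2]]
  }
  if (length(idx) == 0L) stop("empty selection")
  idx
}
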