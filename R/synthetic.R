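#' @title Coarse-grained hairpin model and replica-exchange sampler
#' @description Synthetic ensembles for the analysis chain: an ideal
#'   two-strand antiparallel hairpin built from backbone torsions, a
#'   Go-type energy whose attractive wells are generated from the
#'   sequence's non-covalent census, torsion-space Metropolis Monte Carlo,
#'   and a replica-exchange driver over a temperature ladder. Reduced
#'   energy units (kB = 1) inside the sampler; ladder temperatures in K are
#'   mapped to reduced temperature by T/300 so 300 K corresponds to reduced
#'   temperature 1.
#' @name synthetic-data
NULL

# Temperature ladder used by the replica-exchange protocol this package
# re-expresses at desk scale: 48 replicas spanning 300-450.5 K with
# neighbor gaps of 2.5-4 K.
LADDER_48 <- c(
  300, 302.5, 305, 307.5, 310, 312.5, 315, 317.5, 320, 322.5,
  325, 328, 331, 334, 337, 340, 343, 346, 349, 352,
  355, 358, 361, 364, 367, 370.5, 374, 377.5, 381, 384.5,
  388, 391.5, 395, 398.5, 402, 405.5, 409, 412.5, 416, 419.5,
  423, 426.5, 430.5, 434.5, 438.5, 442.5, 446.5, 450.5
)

# Ideal hairpin backbone torsions for a 19-residue peptide: antiparallel
# beta strands with a two-residue turn at positions 9-10. Tuned once by
# minimizing the register H...O distances of the built chain; frozen here
# as packaged constants (see the methods vignette).
IDEAL_PHI_19 <- c(-139, -138.8, -138.5, -138.9, -138, -139.7, -137.6,
                  -148.1, 60.1, -101.4, -119, -137.4, -138.2, -139.4,
                  -138.4, -139.3, -138.8, -139, -139)
IDEAL_PSI_19 <- c(135, 135.5, 134.9, 135.8, 134.3, 136.6, 130.9, 128.4,
                  -126.7, 17.9, 137.9, 135.6, 134.4, 135.9, 134.7, 135.3,
                  135, 135, 135)

#' Ideal hairpin torsion state
#'
#' Packaged backbone torsions that close a 19-residue chain into an
#' antiparallel hairpin with all eight register hydrogen bonds formed
#' (beta-strand angles on both strands, a two-residue turn at 9-10).
#'
#' @param L Chain length (only 19 is packaged).
#' @return List of class `torsion_state` with `phi`, `psi` (degrees).
#' @export
hairpin_torsions <- function(L = 19L) {
  if (L != 19L) stop("packaged ideal torsions exist only for L = 19")
  torsion_state(IDEAL_PHI_19, IDEAL_PSI_19)
}

#' Construct a torsion state
#'
#' @param phi,psi Per-residue backbone dihedrals in degrees, in
#'   `(-180, 180]`.
#' @return List of class `torsion_state`.
#' @export
torsion_state <- function(phi, psi) {
  stopifnot(length(phi) == length(psi),
            all(phi > -180 & phi <= 180), all(psi > -180 & psi <= 180))
  structure(list(phi = as.numeric(phi), psi = as.numeric(psi)),
            class = "torsion_state")
}

# Atom layout for a coarse-grained chain: per residue N, H (absent for the
# first residue and proline), CA, C, O, CB (absent for glycine). Returns
# the atom table plus 1-based index vectors (0 = absent) for the builder.
chain_layout <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  L <- length(seq)
  codes <- seq$residues$code
  names3 <- seq$residues$code3
  iN <- iH <- iCA <- iC <- iO <- iCB <- integer(L)
  residue_index <- integer(0); residue_name <- character(0)
  atom_name <- character(0)
  next_idx <- 1L
  add <- function(ri, an) {
    residue_index <<- c(residue_index, ri)
    residue_name <<- c(residue_name, names3[ri])
    atom_name <<- c(atom_name, an)
    idx <- next_idx
    next_idx <<- next_idx + 1L
    idx
  }
  for (i in seq_len(L)) {
    iN[i] <- add(i, "N")
    if (i > 1L && codes[i] != "P") iH[i] <- add(i, "H")
    iCA[i] <- add(i, "CA")
    iC[i] <- add(i, "C")
    iO[i] <- add(i, "O")
    if (codes[i] != "G") iCB[i] <- add(i, "CB")
  }
  list(atoms = data.frame(residue_index = residue_index,
                          residue_name = residue_name,
                          atom_name = atom_name,
                          stringsAsFactors = FALSE),
       iN = iN, iH = iH, iCA = iCA, iC = iC, iO = iO, iCB = iCB,
       natoms = next_idx - 1L)
}

#' Build a chain frame from backbone torsions
#'
#' Sequential internal-coordinate (NeRF) construction with standard bond
#' lengths and angles (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A, omega
#' fixed at 180 degrees); backbone N, H, CA, C, O plus a CB pseudo-atom
#' per non-glycine residue.
#'
#' @param seq A `peptide_sequence`.
#' @param torsions A `torsion_state` covering all residues (default: the
#'   packaged ideal hairpin).
#' @return A `hp_frame` (coordinates in nm).
#' @export
build_hairpin <- function(seq, torsions = hairpin_torsions(length(seq))) {
  stopifnot(inherits(torsions, "torsion_state"),
            length(torsions$phi) == length(seq))
  lay <- chain_layout(seq)
  xyz <- cpp_build_chain(torsions$phi, torsions$psi, lay$iN, lay$iH,
                         lay$iCA, lay$iC, lay$iO, lay$iCB, lay$natoms)
  frame(lay$atoms, xyz)
}

#' Measure backbone torsions of a frame
#'
#' @param frm A `hp_frame` with backbone N, CA, C atoms.
#' @return A `torsion_state`; terminal angles that are undefined are
#'   reported as the builder's convention (phi_1, psi_L from the placed
#'   geometry where measurable, else NA).
#' @export
measure_torsions <- function(frm) {
  bb <- backbone_table(frm)
  n <- length(bb$bb)
  dihed <- function(a, b, c, d) {
    b1 <- b - a; b2 <- c - b; b3 <- d - c
    n1 <- vec_cross(b1, b2); n2 <- vec_cross(b2, b3)
    m1 <- vec_cross(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- bb$bb[[i]]
    if (i > 1L) phi[i] <- dihed(bb$bb[[i - 1L]]$C, r$N, r$CA, r$C)
    if (i < n) psi[i] <- dihed(r$N, r$CA, r$C, bb$bb[[i + 1L]]$N)
  }
  list(phi = phi, psi = psi)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Parameters of the coarse-grained hairpin energy
#'
#' Attractive wells are bounded Gaussians `-w * exp(-((d - r0)/sigma)^2)`;
#' soft-sphere repulsion `k_rep * (1 - d/r_ev)^2` acts between CA/CB atoms
#' more than two residues apart; a weak cosine bias pulls torsions toward
#' the ideal-hairpin reference (a Go-type term standing in for local
#' backbone propensity). Units are reduced (kB = 1); the defaults place
#' the folding midpoint inside the 300-450 K analog ladder (see the
#' methods vignette for the calibration).
#'
#' @param w_hb Well depth per register hydrogen bond.
#' @param w_phob Well depth per hydrophobic pair (CB-CB).
#' @param w_ionic Well depth per ionic pair (CB-CB).
#' @param r0_hb Equilibrium H...O distance, nm.
#' @param sigma_hb Width of the H-bond well, nm.
#' @param r0_phob Equilibrium CB-CB distance of facing pairs, nm.
#' @param r0_ionic Equilibrium CB-CB distance of the turn ionic pair, nm.
#' @param sigma_phob Width of the contact wells, nm.
#' @param excluded_volume_radius Soft-sphere radius (nm) on CA/CB.
#' @param k_rep Repulsion strength.
#' @param torsion_bias_strength Per-angle bias weight.
#' @param turn_bias_strength Bias weight on the two turn residues.
#' @return List of class `toy_energy_params`.
#' @export
toy_energy_params <- function(w_hb = 3, w_phob = 6, w_ionic = 6,
                              r0_hb = 0.20, sigma_hb = 0.05,
                              r0_phob = 0.465, r0_ionic = 0.54,
                              sigma_phob = 0.15,
                              excluded_volume_radius = 0.32, k_rep = 25,
                              torsion_bias_strength = 1.5,
                              turn_bias_strength = 4.5) {
  p <- list(w_hb = w_hb, w_phob = w_phob, w_ionic = w_ionic,
            r0_hb = r0_hb, sigma_hb = sigma_hb, r0_phob = r0_phob,
            r0_ionic = r0_ionic, sigma_phob = sigma_phob,
            excluded_volume_radius = excluded_volume_radius,
            k_rep = k_rep, torsion_bias_strength = torsion_bias_strength,
            turn_bias_strength = turn_bias_strength)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))),
            r0_hb > 0, r0_phob > 0, excluded_volume_radius > 0)
  structure(p, class = "toy_energy_params")
}

# Census-derived well table (columns i, j, w, r0, sigma: atom indices into
# the chain layout) plus the repulsion atom set and torsion reference.
census_wells <- function(seq, params, lay = chain_layout(seq)) {
  hb <- hbond_register(seq)
  wells <- matrix(numeric(0), ncol = 5)
  for (k in seq_len(nrow(hb))) {
    hi <- lay$iH[hb$donor_residue[k]]
    oi <- lay$iO[hb$acceptor_residue[k]]
    if (hi == 0L) next  # proline donor: no well
    wells <- rbind(wells, c(hi, oi, params$w_hb, params$r0_hb,
                            params$sigma_hb))
  }
  phob <- hydrophobic_pairs(seq)
  for (k in seq_len(nrow(phob))) {
    ci <- lay$iCB[phob$i[k]]; cj <- lay$iCB[phob$j[k]]
    if (ci == 0L || cj == 0L) next
    wells <- rbind(wells, c(ci, cj, params$w_phob, params$r0_phob,
                            params$sigma_phob))
  }
  ion <- ionic_pairs(seq)
  for (k in seq_len(nrow(ion))) {
    ci <- lay$iCB[ion$i[k]]; cj <- lay$iCB[ion$j[k]]
    if (ci == 0L || cj == 0L) next
    wells <- rbind(wells, c(ci, cj, params$w_ionic, params$r0_ionic,
                            params$sigma_phob))
  }
  colnames(wells) <- c("i", "j", "w", "r0", "sigma")
  rep_sel <- which(lay$atoms$atom_name %in% c("CA", "CB"))
  L <- length(seq)
  w_tor <- rep(params$torsion_bias_strength, L)
  w_tor[c((L + 1) %/% 2, (L + 1) %/% 2 + 1L)] <- params$turn_bias_strength
  ideal <- hairpin_torsions(L)
  list(wells = wells, rep_idx = rep_sel,
       rep_res = lay$atoms$residue_index[rep_sel],
       phi0 = ideal$phi, psi0 = ideal$psi, w_tor = w_tor)
}

#' Coarse-grained energy of a torsion state or frame
#'
#' Sum of census-derived attraction wells (register H-bonds on H...O,
#' hydrophobic and ionic pairs on CB...CB), soft-sphere repulsion between
#' CA/CB atoms more than two residues apart, and the torsion bias. Reduced
#' units.
#'
#' @param state A `torsion_state` (or a `hp_frame` built by
#'   [build_hairpin()]; torsions are then measured from the frame).
#' @param params A [toy_energy_params()].
#' @param seq The `peptide_sequence` defining the census.
#' @return Energy (reduced units).
#' @export
toy_energy <- function(state, params, seq) {
  lay <- chain_layout(seq)
  if (inherits(state, "hp_frame")) {
    tor <- measure_torsions(state)
    phi <- ifelse(is.na(tor$phi), hairpin_torsions(length(seq))$phi, tor$phi)
    psi <- ifelse(is.na(tor$psi), hairpin_torsions(length(seq))$psi, tor$psi)
    xyz <- state$xyz
  } else {
    stopifnot(inherits(state, "torsion_state"))
    phi <- state$phi; psi <- state$psi
    xyz <- cpp_build_chain(phi, psi, lay$iN, lay$iH, lay$iCA, lay$iC,
                           lay$iO, lay$iCB, lay$natoms)
  }
  cw <- census_wells(seq, params, lay)
  cpp_toy_energy(xyz, cw$wells, cw$rep_idx, cw$rep_res,
                 params$excluded_volume_radius, params$k_rep,
                 phi, psi, cw$phi0, cw$psi0, cw$w_tor)
}

#' One or more Metropolis sweeps on a torsion state
#'
#' A sweep proposes L moves (mix of single-torsion perturbations and
#' crankshaft moves that rotate phi and psi of one residue in opposite
#' directions), each accepted with probability `min(1, exp(-dE/T))`.
#'
#' @param state A `torsion_state`.
#' @param temperature Reduced temperature (> 0).
#' @param params A [toy_energy_params()].
#' @param seq The `peptide_sequence`.
#' @param n_sweeps Number of sweeps.
#' @param max_step Maximum angular step, degrees.
#' @param p_crank Probability of a crankshaft move.
#' @return List: updated `state`, final `energy`, `acceptance` rate.
#' @export
mc_sweep <- function(state, temperature, params, seq, n_sweeps = 1L,
                     max_step = 20, p_crank = 0.3) {
  stopifnot(temperature > 0)
  lay <- chain_layout(seq)
  cw <- census_wells(seq, params, lay)
  out <- cpp_mc_segment(state$phi, state$psi, lay$iN, lay$iH, lay$iCA,
                        lay$iC, lay$iO, lay$iCB, lay$natoms, cw$wells,
                        cw$rep_idx, cw$rep_res,
                        params$excluded_volume_radius, params$k_rep,
                        cw$phi0, cw$psi0, cw$w_tor, temperature,
                        n_sweeps, 0L, max_step, p_crank)
  list(state = torsion_state(out$phi, out$psi), energy = out$energy,
       acceptance = out$n_accept / out$n_moves)
}

#' Replica temperature ladder
#'
#' `mode = "table2"` returns the packaged 48-replica ladder (300-450.5 K,
#' neighbor gaps 2.5-4 K); `mode = "geometric"` builds `n` temperatures in
#' geometric progression between `t_min` and `t_max`.
#'
#' @param t_min,t_max Ladder endpoints in K (geometric mode).
#' @param n Number of replicas (>= 2, geometric mode).
#' @param mode `"geometric"` or `"table2"`.
#' @return List of class `replica_ladder` with `temperatures` (K) and
#'   `n_replicas`.
#' @export
remd_ladder <- function(t_min = 300, t_max = 450.5, n = 8L,
                        mode = c("geometric", "table2")) {
  mode <- match.arg(mode)
  temps <- if (mode == "table2") {
    LADDER_48
  } else {
    stopifnot(t_min < t_max, n >= 2L)
    t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
  }
  structure(list(temperatures = temps, n_replicas = length(temps),
                 mode = mode),
            class = "replica_ladder")
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat(sprintf("<replica_ladder> %d replicas, %g-%g K (%s)\n",
              x$n_replicas, min(x$temperatures), max(x$temperatures),
              x$mode))
  invisible(x)
}

#' Replica-exchange Monte Carlo run
#'
#' Replicas propagate independently for `exchange_interval` sweeps between
#' exchange attempts; attempts alternate even/odd neighbor pairings and
#' accept swaps with probability
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))`. Ladder temperatures in K
#' are mapped to reduced sampler temperatures by T/300. Saved frames are
#' demultiplexed by temperature; one sweep is logged as 1 ps of nominal
#' time.
#'
#' @param seq A `peptide_sequence`.
#' @param params A [toy_energy_params()].
#' @param ladder A [remd_ladder()].
#' @param sweeps Total sweeps per replica.
#' @param exchange_interval Sweeps between exchange attempts.
#' @param seed Integer seed (all randomness flows from it).
#' @param save_stride Save one frame per this many sweeps.
#' @param burn_in Fraction of sweeps discarded from the returned
#'   trajectories (default 0.1).
#' @param init Initial `torsion_state` (default: the ideal hairpin).
#' @param flat If `TRUE`, sample a flat potential (all energy terms off);
#'   used for sampler diagnostics.
#' @return Object of class `remd_run`: `trajectories` (one `hp_trajectory`
#'   per ladder temperature), `energies` (per-temperature series),
#'   `ladder`, `exchange_attempts`/`exchange_accepts` per neighbor pair,
#'   `replica_temperature_history` (epochs x replicas, temperature index),
#'   `acceptance` (within-replica move acceptance), `seed`.
#' @export
remd_run <- function(seq, params, ladder, sweeps = 1000L,
                     exchange_interval = 10L, seed = 1L,
                     save_stride = 5L, burn_in = 0.1,
                     init = hairpin_torsions(length(seq)),
                     flat = FALSE) {
  stopifnot(inherits(ladder, "replica_ladder"), exchange_interval >= 1L,
            sweeps >= exchange_interval)
  set.seed(seed)
  n_rep <- ladder$n_replicas
  t_red <- ladder$temperatures / 300
  lay <- chain_layout(seq)
  cw <- census_wells(seq, params, lay)
  if (flat) {
    cw$wells <- matrix(numeric(0), ncol = 5)
    cw$w_tor <- rep(0, length(seq))
    k_rep <- 0
  } else {
    k_rep <- params$k_rep
  }
  # replica state: torsions + energy; temp_of_replica[r] = ladder slot
  phis <- lapply(seq_len(n_rep), function(r) init$phi)
  psis <- lapply(seq_len(n_rep), function(r) init$psi)
  energies <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    xyz <- cpp_build_chain(phis[[r]], psis[[r]], lay$iN, lay$iH, lay$iCA,
                           lay$iC, lay$iO, lay$iCB, lay$natoms)
    energies[r] <- cpp_toy_energy(xyz, cw$wells, cw$rep_idx, cw$rep_res,
                                  params$excluded_volume_radius, k_rep,
                                  phis[[r]], psis[[r]], cw$phi0, cw$psi0,
                                  cw$w_tor)
  }
  temp_of_replica <- seq_len(n_rep)
  n_epochs <- sweeps %/% exchange_interval
  temp_history <- matrix(0L, n_epochs, n_rep)
  attempts <- integer(n_rep - 1L)
  accepts <- integer(n_rep - 1L)
  frames_by_temp <- lapply(seq_len(n_rep), function(t) list())
  frame_energy_by_temp <- lapply(seq_len(n_rep), function(t) numeric(0))
  frame_sweep_by_temp <- lapply(seq_len(n_rep), function(t) numeric(0))
  n_acc_moves <- 0; n_moves <- 0
  for (ep in seq_len(n_epochs)) {
    for (r in seq_len(n_rep)) {
      tslot <- temp_of_replica[r]
      out <- cpp_mc_segment(phis[[r]], psis[[r]], lay$iN, lay$iH, lay$iCA,
                            lay$iC, lay$iO, lay$iCB, lay$natoms, cw$wells,
                            cw$rep_idx, cw$rep_res,
                            params$excluded_volume_radius, k_rep,
                            cw$phi0, cw$psi0, cw$w_tor, t_red[tslot],
                            exchange_interval, save_stride, 20, 0.3)
      phis[[r]] <- out$phi; psis[[r]] <- out$psi
      energies[r] <- out$energy
      n_acc_moves <- n_acc_moves + out$n_accept
      n_moves <- n_moves + out$n_moves
      nf <- length(out$frame_energies)
      if (nf > 0L) {
        fr <- out$frames
        for (s in seq_len(nf)) {
          frames_by_temp[[tslot]][[length(frames_by_temp[[tslot]]) + 1L]] <-
            fr[, , s]
        }
        frame_energy_by_temp[[tslot]] <-
          c(frame_energy_by_temp[[tslot]], out$frame_energies)
        frame_sweep_by_temp[[tslot]] <-
          c(frame_sweep_by_temp[[tslot]],
            (ep - 1L) * exchange_interval + seq_len(nf) * save_stride)
      }
    }
    temp_history[ep, ] <- temp_of_replica
    # alternate even/odd neighbor pairings
    first <- if (ep %% 2L == 1L) 1L else 2L
    pair_lo <- seq(first, n_rep - 1L, by = 2L)
    replica_at <- order(temp_of_replica)  # replica index at each temp slot
    for (lo in pair_lo) {
      ri <- replica_at[lo]; rj <- replica_at[lo + 1L]
      attempts[lo] <- attempts[lo] + 1L
      p <- swap_probability(1 / t_red[lo], 1 / t_red[lo + 1L],
                            energies[ri], energies[rj])
      if (runif(1) < p) {
        accepts[lo] <- accepts[lo] + 1L
        temp_of_replica[ri] <- lo + 1L
        temp_of_replica[rj] <- lo
        replica_at[lo] <- rj; replica_at[lo + 1L] <- ri
      }
    }
  }
  # assemble demultiplexed trajectories, discarding burn-in
  cut <- burn_in * sweeps
  trajs <- vector("list", n_rep)
  energies_by_temp <- vector("list", n_rep)
  for (t in seq_len(n_rep)) {
    keep <- which(frame_sweep_by_temp[[t]] > cut)
    if (length(keep) == 0L) {
      trajs[t] <- list(NULL)
      energies_by_temp[[t]] <- numeric(0)
      next
    }
    trajs[[t]] <- trajectory(frames_by_temp[[t]][keep], atoms = lay$atoms,
                             frame_interval = save_stride,
                             label = sprintf("%s @ %g K", seq$label,
                                             ladder$temperatures[t]),
                             temperature = ladder$temperatures[t])
    energies_by_temp[[t]] <- frame_energy_by_temp[[t]][keep]
  }
  structure(list(
    trajectories = trajs, energies = energies_by_temp, ladder = ladder,
    exchange_attempts = attempts, exchange_accepts = accepts,
    replica_temperature_history = temp_history,
    acceptance = n_acc_moves / n_moves, seed = seed,
    burn_in = burn_in, sweeps = sweeps), class = "remd_run")
}

#' @export
print.remd_run <- function(x, ...) {
  cat(sprintf(
    "<remd_run> %d replicas x %d sweeps; move acceptance %.2f; swap acceptance %s\n",
    x$ladder$n_replicas, x$sweeps, x$acceptance,
    paste(sprintf("%.2f", x$exchange_accepts /
                    pmax(1, x$exchange_attempts)), collapse = " ")))
  invisible(x)
}

#' Generate synthetic hairpin ensembles
#'
#' Runs the replica-exchange sampler for one of the two packaged peptide
#' profiles with census-derived wells: the EF1-like profile has 8
#' stabilizing pairs (4 hydrogen-bond register pairs, 3 hydrophobic pairs
#' including the outermost (3,16), 1 central ionic pair); the EF2-like
#' profile has 6 (no outermost hydrophobic pair, no ionic pair).
#'
#' @param profile `"EF1"` or `"EF2"`.
#' @param seed Integer seed.
#' @param sweeps,exchange_interval,save_stride,burn_in Sampler scale; the
#'   defaults are the package's desk-scale study conditions.
#' @param ladder A [remd_ladder()] (default: 8 geometric replicas spanning
#'   the 300-450.5 K analog range).
#' @param params A [toy_energy_params()].
#' @return A `remd_run` (trajectories demultiplexed per temperature; slot 1
#'   is the 300 K analog).
#' @export
generate_ensembles <- function(profile = c("EF1", "EF2"), seed = 1L,
                               sweeps = 6000L, exchange_interval = 10L,
                               save_stride = 4L, burn_in = 0.1,
                               ladder = remd_ladder(300, 450.5, 8L),
                               params = toy_energy_params()) {
  profile <- match.arg(profile)
  seq <- hairpin_peptide(profile)
  remd_run(seq, params, ladder, sweeps = sweeps,
           exchange_interval = exchange_interval, seed = seed,
           save_stride = save_stride, burn_in = burn_in)
}
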