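#' @title Metropolis and replica-exchange primitives
#' @description The acceptance rules used by the samplers, exposed on their
#'   own so their statistical properties (Boltzmann stationarity, detailed
#'   balance of the exchange move) can be verified on analytically solvable
#'   systems.
#' @name mc-primitives
NULL

#' Metropolis acceptance probability
#'
#' @param delta_e Energy change of the proposed move (reduced units).
#' @param temperature Temperature (reduced units, kB = 1), > 0.
#' @return `min(1, exp(-delta_e / temperature))`.
#' @export
metropolis_probability <- function(delta_e, temperature) {
  stopifnot(temperature > 0)
  pmin(1, exp(-delta_e / temperature))
}

#' Replica-exchange swap probability
#'
#' Probability of accepting a configuration swap between replicas at
#' inverse temperatures `beta_i`, `beta_j` with energies `E_i`, `E_j`:
#' `min(1, exp((beta_i - beta_j) * (E_i - E_j)))`. Equal energies always
#' swap.
#'
#' @param beta_i,beta_j Inverse temperatures (reduced units).
#' @param e_i,e_j Potential energies.
#' @return Acceptance probability in `[0, 1]`.
#' @export
swap_probability <- function(beta_i, beta_j, e_i, e_j) {
  pmin(1, exp((beta_i - beta_j) * (e_i - e_j)))
}

#' Metropolis sampling of a 2D potential
#'
#' Random-walk Metropolis on a user potential `U(x, y)` (reduced units,
#' kB = 1), used as the sampling engine for Boltzmann-inversion checks of
#' the free-energy landscape machinery.
#'
#' @param potential Function of `(x, y)` returning the potential energy.
#' @param n_steps Number of MC steps after burn-in.
#' @param temperature Reduced temperature.
#' @param x0,y0 Starting point.
#' @param step_size Proposal half-width (uniform moves).
#' @param burn_in Steps discarded before recording.
#' @return Data frame with columns `x`, `y` (`n_steps` rows).
#' @export
metropolis_2d <- function(potential, n_steps, temperature = 1,
                          x0 = 0, y0 = 0, step_size = 0.5,
                          burn_in = n_steps %/% 10L) {
  stopifnot(temperature > 0, n_steps >= 1L)
  total <- n_steps + burn_in
  xs <- numeric(n_steps); ys <- numeric(n_steps)
  x <- x0; y <- y0
  u <- potential(x, y)
  for (s in seq_len(total)) {
    xp <- x + runif(1, -step_size, step_size)
    yp <- y + runif(1, -step_size, step_size)
    up <- potential(xp, yp)
    if (up <= u || runif(1) < exp(-(up - u) / temperature)) {
      x <- xp; y <- yp; u <- up
    }
    if (s > burn_in) {
      xs[s - burn_in] <- x
      ys[s - burn_in] <- y
    }
  }
  data.frame(x = xs, y = ys)
}
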