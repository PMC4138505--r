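# Reference implementations of the three intracellular Ca2+ systems:
# the somatic shell, the spiny-dendrite shell, and the smooth-dendrite
# layered system with the floating set point y and the w/r switches.
# The compiled engine carries the same updates; tests cross-check the two.
#
# Sign convention: inward membrane currents are negative. The shell influx
# factor converts a Ca2+ current density (mA/cm2) into a concentration
# rate (mM/ms) for a shell of the given depth (um):
#   chan = 1e4 * max(0, -I_Ca) / (2 F depth).

.shell_factor <- function(depth_um, F = 96485.332) 1e4 / (2 * F * depth_um)

#' Somatic calcium shell state
#'
#' @param ca initial shell concentration, mM.
#' @param beta diffusion (decay) rate constant, 1/ms.
#' @param depth shell depth, um.
#' @param floor lower clamp, mM (100 nM).
#' @return list state.
#' @export
soma_ca_state <- function(ca = 5e-5, beta = 1, depth = 0.1, floor = 1e-4)
  list(ca = ca, beta = beta, depth = depth, floor = floor)

#' Advance the somatic calcium shell
#'
#' Explicit update: influx from the (P-type, GHK) Ca2+ current plus
#' first-order decay toward zero at rate beta, then the 100 nM floor.
#'
#' @param state from [soma_ca_state()].
#' @param i_ca somatic Ca2+ current density, mA/cm2 (inward negative).
#' @param dt step, ms.
#' @return updated state.
#' @export
step_soma_ca <- function(state, i_ca, dt) {
  stopifnot(dt > 0)
  sf <- .shell_factor(state$depth)
  ca <- state$ca + dt * (-sf * i_ca - state$beta * state$ca)
  state$ca <- max(ca, state$floor)
  state
}

#' Spiny-dendrite calcium state
#'
#' Saturable extrusion (kt, kd), first-order return to the fixed set point
#' y with time constant tau_r, and the clamped influx term.
#'
#' @param ca initial concentration, mM.
#' @param kt extrusion rate, mM/ms.
#' @param kd extrusion half-saturation, mM.
#' @param tau_r set-point relaxation, ms.
#' @param y fixed set point, mM.
#' @param depth shell depth, um.
#' @return list state.
#' @export
spiny_ca_state <- function(ca = 4e-5, kt = 4e-5, kd = 4e-5, tau_r = 2,
                           y = 4e-5, depth = 0.1)
  list(ca = ca, kt = kt, kd = kd, tau_r = tau_r, y = y, depth = depth)

#' Advance a spiny-dendrite calcium shell
#'
#' d[Ca]/dt = chan - kt [Ca]/([Ca]+kd) + (y - [Ca])/tau_r, with chan the
#' shell influx clamped at >= 0 (an outward Ca2+ current cannot deplete
#' the shell).
#'
#' @param state from [spiny_ca_state()].
#' @param i_ca summed dendritic Ca2+ current density, mA/cm2.
#' @param dt step, ms.
#' @return updated state.
#' @export
step_spiny_ca <- function(state, i_ca, dt) {
  stopifnot(dt > 0)
  chan <- .shell_factor(state$depth) * max(0, -i_ca)
  d <- chan - state$kt * state$ca / (state$ca + state$kd) +
    (state$y - state$ca) / state$tau_r
  state$ca <- state$ca + dt * d
  state
}

#' Smooth-dendrite layered calcium state
#'
#' Same fast shell as the spiny system (with kt = kd = 1e-4) but with a
#' floating set point y that itself accumulates calcium influx on a slow
#' timescale and relaxes to the fixed value z. The (g, tau_m) pair that
#' governs y is switched by w (CF-scale Ca2+ influx) and the live SK
#' conductance by r (CF synaptic current); see [update_w()] / [update_r()].
#'
#' @param ca,y initial concentrations, mM.
#' @param kt,kd,tau_r fast-shell parameters (mM/ms, mM, ms).
#' @param z fixed set point for y, mM.
#' @param f,s decay time constants of w and r, ms.
#' @param g_fast,tau_m_fast default (g, tau_m) pair.
#' @param g_slow,tau_m_slow CF-triggered pair (w > 0.1).
#' @param gsk_off,gsk_on SK maximal conductance (S/cm2) outside/inside the
#'   r window.
#' @param w_threshold Ca-influx magnitude trigger, mA/cm2.
#' @param r_threshold CF synaptic-current magnitude trigger, nA.
#' @param depth shell depth, um.
#' @return list state with elements ca, y, w, r, g, tau_m_y, gsk_live, ...
#' @export
smooth_ca_state <- function(ca = 4e-5, y = 2.4e-4, kt = 1e-4, kd = 1e-4,
                            tau_r = 2, z = 2.4e-4, f = 100, s = 1000,
                            g_fast = 1e5, tau_m_fast = 100,
                            g_slow = 1e4, tau_m_slow = 1000,
                            gsk_off = 1e-7, gsk_on = 0.72,
                            w_threshold = 0.06, r_threshold = 3,
                            depth = 0.1) {
  st <- list(ca = ca, y = y, w = 0, r = 0, kt = kt, kd = kd, tau_r = tau_r,
             z = z, f = f, s = s, g_fast = g_fast, tau_m_fast = tau_m_fast,
             g_slow = g_slow, tau_m_slow = tau_m_slow,
             gsk_off = gsk_off, gsk_on = gsk_on,
             w_threshold = w_threshold, r_threshold = r_threshold,
             depth = depth)
  .apply_switches(st)
}

.apply_switches <- function(state) {
  if (state$w > 0.1) {
    state$g <- state$g_slow; state$tau_m_y <- state$tau_m_slow
  } else {
    state$g <- state$g_fast; state$tau_m_y <- state$tau_m_fast
  }
  state$gsk_live <- if (state$r > 0.1) state$gsk_on else state$gsk_off
  state
}

#' Advance a smooth-dendrite calcium shell and its floating set point
#'
#' The fast shell follows the spiny dynamics (with the smooth constants);
#' the set point accumulates the same clamped influx divided by the live g
#' and the compartment-diameter scaling, and relaxes toward z with the
#' live tau_m:
#' \deqn{dy/dt = 4\cdot10^4 \max(0, -I_{Ca})/(d F g) + (z - y)/\tau_m}
#'
#' @param state from [smooth_ca_state()].
#' @param i_ca summed T+E+P dendritic Ca2+ current density, mA/cm2.
#' @param d compartment diameter, um.
#' @param dt step, ms.
#' @return updated state.
#' @export
step_smooth_ca <- function(state, i_ca, d, dt) {
  stopifnot(dt > 0)
  influx <- max(0, -i_ca)
  chan <- .shell_factor(state$depth) * influx
  dca <- chan - state$kt * state$ca / (state$ca + state$kd) +
    (state$y - state$ca) / state$tau_r
  dy <- 4e4 * influx / (d * 96485.332 * state$g) +
    (state$z - state$y) / state$tau_m_y
  state$ca <- state$ca + dt * dca
  state$y <- state$y + dt * dy
  state
}

#' CF-influx switch w
#'
#' w jumps to 1 whenever the magnitude of the (inward) summed Ca2+ current
#' crosses the threshold (0.06 mA/cm2 by default), otherwise decays as
#' exp(-dt/f) with f = 100 ms. The live (g, tau_m) pair follows the
#' w > 0.1 rule. A re-trigger before w reaches 0.1 restarts the full
#' lifespan (f ln 10, about 230 ms).
#'
#' @param state smooth calcium state.
#' @param i_ca summed Ca2+ current density, mA/cm2 (inward negative).
#' @param dt step, ms.
#' @return updated state.
#' @export
update_w <- function(state, i_ca, dt) {
  if (i_ca < 0 && -i_ca > state$w_threshold) state$w <- 1
  else state$w <- state$w * exp(-dt / state$f)
  .apply_switches(state)
}

#' CF-synaptic switch r
#'
#' r jumps to 1 whenever the CF synaptic current magnitude on the
#' compartment exceeds the threshold (3 nA), otherwise decays as
#' exp(-dt/s) with s = 1000 ms, giving a lifespan of s ln 10 (about
#' 2.3 s) so 1 Hz CF input keeps the SK conductance continuously enabled.
#'
#' @param state smooth calcium state.
#' @param i_syn_cf CF synaptic current on the compartment, nA.
#' @param dt step, ms.
#' @return updated state.
#' @export
update_r <- function(state, i_syn_cf, dt) {
  if (abs(i_syn_cf) > state$r_threshold) state$r <- 1
  else state$r <- state$r * exp(-dt / state$s)
  .apply_switches(state)
}
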