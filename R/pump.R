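# Somatic Na+/K+ pump electrogenesis and lagged intracellular Na+
# accumulation. The pump's net outward current follows a sigmoid of
# [Na+]i; the 3:2 stoichiometry fixes i_pump_Na = 3 i_pump and
# i_pump_K = -2 i_pump. The net Na+ current (resurgent influx minus pump
# efflux) feeds [Na+]i only after a fixed lag tau = 5 s, held in a FIFO
# delay buffer of exactly tau/dt entries.

#' Electrogenic pump current
#'
#' \eqn{i_{pump} = d_{pump} / (1 + \exp((40 - [Na^+]_i)/1))}, monotone
#' increasing in internal sodium with midpoint 40 mM.
#'
#' @param na_i intracellular sodium, mM.
#' @param density pump density, mA/cm2 (default 0.04).
#' @return net outward pump current density, mA/cm2.
#' @export
pump_current <- function(na_i, density = 0.04) {
  stopifnot(all(na_i > 0))
  density / (1 + exp((40 - na_i) / 1))
}

#' Pump/sodium state
#'
#' @param dt integration step, ms.
#' @param tau diffusion lag between Na+ entry and the pump, ms (5000).
#' @param na_i initial internal sodium, mM (floor 10).
#' @param density pump density, mA/cm2.
#' @param d_soma somatic diameter, um.
#' @param na_floor lower clamp on `na_i`, mM.
#' @param warm value used to prime the delay buffer (quasi-stationary
#'   start); `NULL` primes with the first pushed value.
#' @return list state with the FIFO `buffer` of length `tau/dt`.
#' @export
pump_state <- function(dt = 0.025, tau = 5000, na_i = 10, density = 0.04,
                       d_soma = 22, na_floor = 10, warm = NULL) {
  n <- round(tau / dt)
  if (abs(n - tau / dt) > 1e-9)
    stop("configuration error: tau must be an integer multiple of dt")
  list(na_i = na_i, density = density, d_soma = d_soma, dt = dt, tau = tau,
       na_floor = na_floor,
       buffer = if (is.null(warm)) NULL else rep(warm, n), n_buf = n,
       pos = 1L,
       i_pump = pump_current(na_i, density))
}

#' Advance the pump/sodium state by one step
#'
#' Pushes the instantaneous net outward Na+ current (resurgent current
#' plus the pump's 3 i_pump efflux) into the delay buffer, pops the
#' tau-old entry as I_Na_net,
#' and advances internal sodium by
#' \deqn{d[Na^+]_i/dt = -4\cdot 10^4 \, I_{Na\_net} / (d F)}
#' (d the somatic diameter in um, so a sustained inward current of
#' 0.1 mA/cm2 accumulates about 1.9 mM/s). Floors at 10 mM. The pump
#' currents reported are those used for this step (3:2 stoichiometry).
#'
#' @param state from [pump_state()].
#' @param i_na_r_now instantaneous resurgent Na+ current, mA/cm2.
#' @param dt step, ms (must equal the state's dt).
#' @return updated state with fields `na_i`, `i_pump`, `i_pump_na`,
#'   `i_pump_k`, `i_na_net` (the lagged value just applied).
#' @export
step_na_i <- function(state, i_na_r_now, dt) {
  if (abs(dt - state$dt) > 1e-12)
    stop("configuration error: delay buffer sized for a different dt")
  i_pump <- pump_current(state$na_i, state$density)
  # net outward Na+ current: resurgent influx (inward, negative) plus the
  # pump's Na+ efflux (outward, +3 i_pump); [Na+]i integrates its negative
  push <- i_na_r_now + 3 * i_pump
  if (is.null(state$buffer)) state$buffer <- rep(push, state$n_buf)
  inet <- state$buffer[state$pos]
  state$buffer[state$pos] <- push
  state$pos <- if (state$pos == state$n_buf) 1L else state$pos + 1L
  na <- state$na_i + dt * (-4e4 * inet / (state$d_soma * 96485.332))
  state$na_i <- max(na, state$na_floor)
  state$i_pump <- i_pump
  state$i_pump_na <- 3 * i_pump
  state$i_pump_k <- -2 * i_pump
  state$i_na_net <- inet
  state
}

#' Sodium reversal potential with the +70 mV floor
#'
#' Nernst potential for Na+ with the external concentration chosen so
#' that E_Na(10 mM) = +70 mV, clamped at no less than +70 mV. Because
#' [Na+]i itself is floored at 10 mM the clamp makes E_Na effectively
#' constant; the machinery exists for audit.
#'
#' @param na_i internal sodium, mM.
#' @param na_out external sodium, mM.
#' @param T temperature, degrees C.
#' @param floor clamp, mV.
#' @return reversal potential, mV.
#' @export
sodium_reversal <- function(na_i, na_out = 138.4, T = 36, floor = 70) {
  rt_f <- 8.314462 * (T + 273.15) / 96485.332 * 1000  # mV
  pmax(rt_f * log(na_out / na_i), floor)
}
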